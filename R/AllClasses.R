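#' @import methods
NULL

#' Parcellation of the brain into labelled ROIs
#'
#' An ordered set of regions of interest (ROIs), each assigned either to one
#' of the canonical resting-state networks (RSNs) or to the catch-all
#' `"other"` label covering the rest of cortex and subcortical areas.
#'
#' @slot rois data.frame with columns `roi_id` (unique character) and
#'   `network` (character).
#' @slot networks character vector of RSN names, excluding `"other"`.
#' @export
setClass("Parcellation",
  representation(rois = "data.frame", networks = "character"),
  validity = function(object) {
    r <- object@rois
    if (!all(c("roi_id", "network") %in% names(r)))
      return("'rois' needs columns roi_id, network")
    if (anyDuplicated(r$roi_id)) return("duplicate roi_id")
    bad <- setdiff(unique(r$network), c(object@networks, "other"))
    if (length(bad))
      return(paste("network labels not declared:", paste(bad, collapse = ", ")))
    TRUE
  })

#' Multivariate node time series for one subject
#'
#' @slot values numeric T x N matrix, one column per node, all finite.
#' @slot trSeconds sampling interval (repetition time) in seconds.
#' @export
setClass("NodeTimeSeries",
  representation(values = "matrix", trSeconds = "numeric"),
  validity = function(object) {
    if (nrow(object@values) < 2L) return("need at least 2 time points")
    if (!all(is.finite(object@values))) return("non-finite values")
    if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
      return("trSeconds must be a single positive number")
    TRUE
  })

#' Six-parameter rigid-body head-motion trace
#'
#' Rows are volumes; columns are x, y, z translations (mm) and roll, pitch,
#' yaw rotations (radians), in that order.
#'
#' @slot params numeric T x 6 matrix.
#' @export
setClass("MotionTrace",
  representation(params = "matrix"),
  validity = function(object) {
    if (ncol(object@params) != 6L) return("motion trace must have 6 columns")
    if (nrow(object@params) < 2L) return("need at least 2 volumes")
    if (!all(is.finite(object@params))) return("non-finite motion parameters")
    TRUE
  })

#' Confound design matrix for nuisance regression
#'
#' @slot columns numeric T x P design matrix (includes the intercept).
#' @slot labels character column labels; motion-derived columns carry the
#'   prefix `"motion"`.
#' @export
setClass("ConfoundDesign",
  representation(columns = "matrix", labels = "character"),
  validity = function(object) {
    if (ncol(object@columns) != length(object@labels))
      return("labels do not match columns")
    if (!all(is.finite(object@columns))) return("non-finite design values")
    TRUE
  })

#' A labelled set of 3-D spatial maps on a shared voxel grid
#'
#' Used for group templates, subject-specific network maps, and young-adult
#' reference maps alike.
#'
#' @slot maps list of numeric 3-D arrays, one per network, identical dims.
#' @slot labels character network labels, one per map, pairwise distinct.
#' @slot mask logical array of the shared grid shape, or length-0 logical
#'   when every voxel is in play.
#' @export
setClass("SpatialMapSet",
  representation(maps = "list", labels = "character", mask = "logical"),
  validity = function(object) {
    if (length(object@maps) < 1L) return("need at least one map")
    if (length(object@maps) != length(object@labels))
      return("labels do not match maps")
    if (anyDuplicated(object@labels)) return("duplicate map labels")
    d <- dim(object@maps[[1L]])
    if (is.null(d) || length(d) != 3L) return("maps must be 3-D arrays")
    for (m in object@maps) {
      if (!identical(dim(m), d)) return("maps do not share one grid shape")
      if (!all(is.finite(m))) return("non-finite voxel values")
    }
    if (length(object@mask) && !identical(dim(object@mask), d))
      return("mask shape differs from map shape")
    TRUE
  })

#' Subject connectivity matrix (Pearson r and Fisher z)
#'
#' @slot r numeric N x N symmetric Pearson correlation matrix, unit diagonal.
#' @slot z numeric N x N Fisher-transformed matrix, zero diagonal.
#' @slot nodeIds character node identifiers in parcellation order.
#' @export
setClass("ConnectivityMatrix",
  representation(r = "matrix", z = "matrix", nodeIds = "character"),
  validity = function(object) {
    n <- nrow(object@r)
    if (ncol(object@r) != n || !identical(dim(object@z), dim(object@r)))
      return("r and z must be square and congruent")
    if (length(object@nodeIds) != n) return("nodeIds do not match matrix")
    if (max(abs(object@r - t(object@r))) > 1e-12) return("r not symmetric")
    if (max(abs(diag(object@r) - 1)) > 1e-12) return("r diagonal must be 1")
    if (max(abs(diag(object@z))) > 0) return("z diagonal must be 0")
    TRUE
  })

#' Binary undirected graph from a thresholded connectivity matrix
#'
#' An edge joins nodes i and j iff r_ij strictly exceeds the
#' network-defining threshold; the diagonal is always zero.
#'
#' @slot adjacency numeric 0/1 symmetric matrix, zero diagonal.
#' @slot thresholdR the network-defining correlation threshold.
#' @export
setClass("BinaryGraph",
  representation(adjacency = "matrix", thresholdR = "numeric"),
  validity = function(object) {
    a <- object@adjacency
    if (nrow(a) != ncol(a)) return("adjacency must be square")
    if (!all(a %in% c(0, 1))) return("adjacency must be 0/1")
    if (any(diag(a) != 0)) return("diagonal must be zero")
    if (max(abs(a - t(a))) > 0) return("adjacency not symmetric")
    TRUE
  })

#' Ground-truth parameters of a synthetic cohort
#'
#' Holds every planted effect so downstream parameter-recovery tests know
#' exactly what signal was injected. Couplings are Pearson correlations;
#' all age slopes are per unit of standardized age (age - 50)/35.
#'
#' @slot withinBase baseline within-network node coupling per RSN (named).
#' @slot withinSlope age slope of within-network coupling per RSN (named).
#' @slot betweenBase baseline cross-network coupling (scalar or K x K).
#' @slot betweenSlope age slope of cross-network coupling (scalar or K x K).
#' @slot otherCoupling within-block coupling of non-RSN ("other") nodes.
#' @slot etaDecay age slope of the template-mixing weight driving planted
#'   map dissimilarity.
#' @slot lambda0 template-mixing weight at age 50.
#' @slot lambdaSd subject-level SD of the mixing weight (idiosyncratic
#'   network-integrity scatter around the age trend).
#' @slot mapNoiseSd voxel noise SD added to subject spatial maps.
#' @slot mediationA,mediationB,mediationCprime planted mediation paths
#'   (age -> connectivity mediator; mediator -> ACE-R; direct age -> ACE-R).
#' @slot sexCoef additive sex term in the cognition model.
#' @slot aceIntercept ACE-R total at standardized age 0 for mediator 0.
#' @slot noiseSd observation noise SD of ACE-R total.
#' @slot mediatorSd SD of the subject-level mediator deviation (which also
#'   perturbs that subject's within-network couplings).
#' @slot couplingShare how strongly the mediator deviation feeds back into
#'   the subject's within-network couplings.
#' @slot highMotionFraction fraction of subjects given a motion scale that
#'   violates the framewise-displacement criteria.
#' @slot motionScaleLow,motionScaleHigh random-walk step scales (mm).
#' @slot arPhi optional AR(1) coefficient of the node time series.
#' @slot seed master RNG seed of the cohort.
#' @export
setClass("CohortGroundTruth",
  representation(
    withinBase = "numeric", withinSlope = "numeric",
    betweenBase = "numeric", betweenSlope = "numeric",
    otherCoupling = "numeric",
    etaDecay = "numeric", lambda0 = "numeric", lambdaSd = "numeric",
    mapNoiseSd = "numeric",
    mediationA = "numeric", mediationB = "numeric",
    mediationCprime = "numeric", sexCoef = "numeric",
    aceIntercept = "numeric", noiseSd = "numeric", mediatorSd = "numeric",
    couplingShare = "numeric", highMotionFraction = "numeric",
    motionScaleLow = "numeric", motionScaleHigh = "numeric",
    arPhi = "numeric", seed = "numeric"),
  validity = function(object) {
    num <- c(object@withinBase, object@withinSlope, object@betweenBase,
             object@betweenSlope, object@otherCoupling, object@etaDecay,
             object@lambda0, object@lambdaSd, object@mapNoiseSd, object@mediationA,
             object@mediationB, object@mediationCprime, object@sexCoef,
             object@aceIntercept, object@noiseSd, object@mediatorSd,
             object@couplingShare, object@highMotionFraction,
             object@motionScaleLow, object@motionScaleHigh, object@arPhi,
             object@seed)
    if (!all(is.finite(num))) return("all ground-truth parameters must be finite")
    if (object@highMotionFraction < 0 || object@highMotionFraction > 1)
      return("highMotionFraction must lie in [0, 1]")
    TRUE
  })

#' Result of a (possibly bootstrapped) mediation fit
#'
#' Path coefficients of the three-regression mediation model plus, when a
#' bootstrap was run, per-path z statistics and two-sided percentile
#' p-values.
#'
#' @slot paths named numeric: a, b, cprime, c, ab.
#' @slot z named numeric bootstrap z per path (NA when no bootstrap).
#' @slot p named numeric bootstrap p per path (NA when no bootstrap).
#' @slot nBoot number of bootstrap samples (0 for a plain fit).
#' @slot seed bootstrap seed (NA for a plain fit).
#' @slot nRedrawn bootstrap draws discarded for a degenerate regressor.
#' @export
setClass("MediationResult",
  representation(paths = "numeric", z = "numeric", p = "numeric",
                 nBoot = "numeric", seed = "numeric", nRedrawn = "numeric"),
  validity = function(object) {
    need <- c("a", "b", "cprime", "c", "ab")
    if (!all(need %in% names(object@paths)))
      return("paths must contain a, b, cprime, c, ab")
    if (abs(object@paths["ab"] -
            (object@paths["c"] - object@paths["cprime"])) > 1e-8)
      return("ab must equal c - cprime for OLS with shared covariates")
    TRUE
  })
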