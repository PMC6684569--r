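#' @include AllClasses.R utils.R parcellation.R
NULL

## Resolve a scalar-or-named parameter to one value per RSN.
perNetwork <- function(x, networks, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(x, length(networks)), networks))
  stopIfNot(all(networks %in% names(x)),
            sprintf("'%s' must be a scalar or named for every network", what))
  x[networks]
}

#' Default ground truth for a synthetic cohort
#'
#' The planted study conditions: within-network node coupling declines with
#' age while cross-network coupling rises; subject spatial maps mix
#' increasingly into other networks with age (driving the similarity
#' statistic down); ACE-R total follows a mediation model in which part of
#' the age effect on cognition runs through a connectivity mediator. Effect
#' sizes are chosen so cohort-level partial correlations land in the
#' moderate |r| ~ 0.3-0.5 range typical of lifespan connectivity studies.
#'
#' @param seed master RNG seed of the cohort.
#' @param ... named overrides for any [CohortGroundTruth-class] slot.
#' @return a [CohortGroundTruth-class] object.
#' @examples
#' defaultGroundTruth(seed = 7, etaDecay = 0)
#' @export
defaultGroundTruth <- function(seed = 1L, ...) {
  args <- list(
    withinBase = 0.30, withinSlope = -0.15,
    betweenBase = 0.05, betweenSlope = 0.10,
    otherCoupling = 0.08,
    etaDecay = 0.15, lambda0 = 0.15, lambdaSd = 0.08, mapNoiseSd = 0.10,
    mediationA = -1.0, mediationB = 1.5, mediationCprime = -1.0,
    sexCoef = 0.0, aceIntercept = 96, noiseSd = 2.5,
    mediatorSd = 0.40, couplingShare = 0.30,
    highMotionFraction = 0.10, motionScaleLow = 0.02,
    motionScaleHigh = 0.08, arPhi = 0.0,
    seed = as.numeric(seed))
  dots <- list(...)
  stopIfNot(all(names(dots) %in% names(args)),
            paste("unknown ground-truth parameter:",
                  paste(setdiff(names(dots), names(args)), collapse = ", ")))
  args[names(dots)] <- dots
  do.call(new, c(list("CohortGroundTruth"), args))
}

#' Generate a synthetic cohort with planted age and mediation effects
#'
#' Samples demographics (age uniform over 21-86 years, sex
#' Bernoulli with the cohort's observed female share), a latent connectivity
#' mediator `M = a * zAge + u`, and ACE-R total
#' `intercept + c' * zAge + b * M + sexCoef * sex + noise` clipped to
#' \[0, 100\], where `zAge = (age - 50)/35`. The subject-level deviation `u`
#' also perturbs that subject's within-network couplings (via
#' `couplingShare`), so the downstream pipeline can recover the mediation
#' structure from measured connectivity. A per-subject motion scale is
#' assigned, high (FD-criteria-violating) with probability
#' `highMotionFraction`.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param truth a [CohortGroundTruth-class]; defaults to
#'   `defaultGroundTruth(seed)`.
#' @param seed master seed; defaults to `truth@seed`.
#' @param femaleShare Bernoulli probability of sex code 1.
#' @return list with `subjects` (data.frame: subject_id, age, sex,
#'   mediator, ace_r_total, motion_scale, cognitive_pass, included) and
#'   `truth`.
#' @examples
#' coh <- generateCohort(20, seed = 1)
#' head(coh$subjects)
#' @export
generateCohort <- function(nSubjects = 129L, truth = NULL, seed = NULL,
                           femaleShare = 93 / 129) {
  stopIfNot(is.numeric(nSubjects) && nSubjects >= 2,
            "'nSubjects' must be at least 2")
  if (is.null(truth)) truth <- defaultGroundTruth(if (is.null(seed)) 1L else seed)
  if (is.null(seed)) seed <- truth@seed
  n <- as.integer(nSubjects)
  subjects <- withSeed(childSeed(seed, 1L), {
    age <- stats::runif(n, 21, 86)
    sex <- stats::rbinom(n, 1L, femaleShare)
    u <- stats::rnorm(n, 0, truth@mediatorSd)
    mediator <- truth@mediationA * zAge(age) + u
    ace <- truth@aceIntercept +
      truth@mediationCprime * zAge(age) +
      truth@mediationB * mediator +
      truth@sexCoef * sex +
      stats::rnorm(n, 0, truth@noiseSd)
    ace <- clip(ace, 0, 100)
    high <- stats::runif(n) < truth@highMotionFraction
    data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      age = age, sex = sex, mediator = mediator,
      ace_r_total = ace,
      motion_scale = ifelse(high, truth@motionScaleHigh,
                            truth@motionScaleLow),
      cognitive_pass = ace >= 89,
      included = NA,
      stringsAsFactors = FALSE)
  })
  list(subjects = subjects, truth = truth)
}

## Block correlation matrix for one subject: within-RSN blocks follow the
## planted age slope plus the subject's mediator deviation; RSN x RSN cross
## blocks follow the between slope; blocks touching "other" stay flat.
subjectBlockCorrelation <- function(age, uDev, parc, truth) {
  nets <- c(networkLabels(parc), "other")
  wb <- perNetwork(truth@withinBase, networkLabels(parc), "withinBase")
  ws <- perNetwork(truth@withinSlope, networkLabels(parc), "withinSlope")
  K <- length(nets)
  z <- zAge(age)
  B <- matrix(truth@betweenBase + truth@betweenSlope * z, K, K)
  dimnames(B) <- list(nets, nets)
  if ("other" %in% nets) {
    B["other", ] <- truth@betweenBase
    B[, "other"] <- truth@betweenBase
    B["other", "other"] <- truth@otherCoupling
  }
  for (k in networkLabels(parc))
    B[k, k] <- wb[k] + ws[k] * z + truth@couplingShare * uDev
  bad <- which(abs(B) > 0.99, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("requested coupling for block %s-%s is outside (-0.99, 0.99)",
                 nets[bad[1, 1]], nets[bad[1, 2]]), call. = FALSE)
  idx <- match(roiTable(parc)$network, nets)
  S <- B[idx, idx]
  diag(S) <- 1
  S
}

#' Generate node time series for one subject
#'
#' Draws a T x N Gaussian sample whose correlation matrix has the planted
#' block structure: within-network coupling
#' `withinBase_k + withinSlope_k * zAge + couplingShare * u` and
#' cross-network coupling `betweenBase + betweenSlope * zAge` (blocks
#' involving non-RSN nodes stay at their baselines). The matrix is projected
#' to the nearest sampleable correlation matrix (eigenvalue clipping at
#' 1e-6, rescale to unit diagonal) before Cholesky sampling. Volumes are
#' i.i.d. by default; `truth@arPhi` adds AR(1) serial correlation.
#'
#' @param subject one-row data.frame from [generateCohort()] (needs `age`,
#'   `mediator`), or a bare numeric age.
#' @param parc a [Parcellation-class].
#' @param truth a [CohortGroundTruth-class].
#' @param nVolumes number of volumes (>= 20; default 193, the acquired 198
#'   minus the 5 dropped at ingestion).
#' @param trSeconds repetition time in seconds.
#' @param seed RNG seed for this subject's draw.
#' @return a [NodeTimeSeries-class].
#' @export
generateNodeTimeSeries <- function(subject, parc, truth, nVolumes = 193L,
                                   trSeconds = 2.5, seed = 1L) {
  stopIfNot(nVolumes >= 20, "'nVolumes' must be at least 20")
  if (is.data.frame(subject)) {
    age <- subject$age[1L]
    uDev <- subject$mediator[1L] - truth@mediationA * zAge(age)
  } else {
    age <- as.numeric(subject)
    uDev <- 0
  }
  S <- subjectBlockCorrelation(age, uDev, parc, truth)
  S <- nearestCorrelation(S)
  R <- chol(S)
  Tn <- as.integer(nVolumes)
  N <- nNodes(parc)
  X <- withSeed(seed, {
    Z <- matrix(stats::rnorm(Tn * N), Tn, N)
    if (truth@arPhi != 0) {
      phi <- truth@arPhi
      Z <- apply(Z, 2L, function(e)
        as.numeric(stats::filter(e, phi, method = "recursive"))) *
        sqrt(1 - phi^2)
    }
    Z %*% R
  })
  colnames(X) <- roiTable(parc)$roi_id
  new("NodeTimeSeries", values = X, trSeconds = trSeconds)
}

#' Generate a six-parameter head-motion trace
#'
#' Random-walk motion: translations step with SD `scale` mm and rotations
#' with SD `scale / 50` radians, so both contribute comparably to framewise
#' displacement at the 50 mm head-radius convention. A `scale` of 0 yields a
#' perfectly still subject (FD identically 0 downstream).
#'
#' @param subject optional one-row data.frame from [generateCohort()]
#'   carrying `motion_scale`; ignored when `scale` is given.
#' @param truth unused placeholder for symmetry with the other generators.
#' @param nVolumes number of volumes (>= 2).
#' @param scale random-walk step scale in mm.
#' @param seed RNG seed.
#' @return a [MotionTrace-class].
#' @export
generateMotionTrace <- function(subject = NULL, truth = NULL,
                                nVolumes = 193L, scale = NULL, seed = 1L) {
  stopIfNot(nVolumes >= 2, "'nVolumes' must be at least 2")
  if (is.null(scale)) {
    stopIfNot(is.data.frame(subject) && "motion_scale" %in% names(subject),
              "give 'scale' or a subject row with motion_scale")
    scale <- subject$motion_scale[1L]
  }
  stopIfNot(is.finite(scale) && scale >= 0, "'scale' must be finite and >= 0")
  Tn <- as.integer(nVolumes)
  params <- withSeed(seed, {
    steps <- cbind(matrix(stats::rnorm(Tn * 3, 0, scale), Tn, 3),
                   matrix(stats::rnorm(Tn * 3, 0, scale / 50), Tn, 3))
    steps[1L, ] <- 0
    apply(steps, 2L, cumsum)
  })
  colnames(params) <- c("x", "y", "z", "roll", "pitch", "yaw")
  new("MotionTrace", params = params)
}

#' Generate smooth group network templates on a small voxel grid
#'
#' Each template is a sum of Gaussian blobs at seeded random centres,
#' standardized to zero mean and unit SD — a compact stand-in for group-ICA
#' spatial components, adequate for testing map-level statistics.
#'
#' @param labels network labels, one template each.
#' @param gridDim 3-element grid dimensions (default 24 x 24 x 12).
#' @param nBlobs Gaussian blobs per template.
#' @param blobSd blob width in voxels.
#' @param seed RNG seed.
#' @return a [SpatialMapSet-class] of templates.
#' @export
generateTemplates <- function(labels = names(.rsnCounts),
                              gridDim = c(24L, 24L, 12L), nBlobs = 3L,
                              blobSd = 2.5, seed = 1L) {
  stopIfNot(length(gridDim) == 3L && all(gridDim >= 4),
            "'gridDim' must be 3 dimensions of at least 4 voxels")
  g <- expand.grid(x = seq_len(gridDim[1L]), y = seq_len(gridDim[2L]),
                   z = seq_len(gridDim[3L]))
  maps <- withSeed(seed, lapply(seq_along(labels), function(k) {
    v <- numeric(nrow(g))
    for (b in seq_len(nBlobs)) {
      ctr <- c(stats::runif(1, 1, gridDim[1L]), stats::runif(1, 1, gridDim[2L]),
               stats::runif(1, 1, gridDim[3L]))
      d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
      v <- v + exp(-d2 / (2 * blobSd^2))
    }
    array((v - mean(v)) / stats::sd(v), dim = gridDim)
  }))
  new("SpatialMapSet", maps = maps, labels = as.character(labels),
      mask = logical(0))
}

#' Generate subject-specific spatial maps with planted age decay
#'
#' The subject's map for network k is
#' `(1 - lambda) * template_k + lambda * mean(other templates) + noise`,
#' with mixing weight
#' `lambda = clip(lambda0 + etaDecay * zAge + N(0, lambdaSd), 0, 0.95)` --
#' an age trend plus idiosyncratic subject scatter.
#' A positive `etaDecay` therefore makes older subjects' maps drift away
#' from their templates, so the similarity statistic against a young-adult
#' reference declines with age.
#'
#' @param subject one-row data.frame (needs `age`) or a bare numeric age.
#' @param templates a [SpatialMapSet-class] of group templates.
#' @param truth a [CohortGroundTruth-class].
#' @param seed RNG seed for the voxel noise.
#' @return a [SpatialMapSet-class] of subject maps.
#' @export
generateSpatialMaps <- function(subject, templates, truth, seed = 1L) {
  stopIfNot(is(templates, "SpatialMapSet"),
            "'templates' must be a SpatialMapSet")
  age <- if (is.data.frame(subject)) subject$age[1L] else as.numeric(subject)
  tm <- spatialMaps(templates)
  d <- dim(tm[[1L]])
  maps <- withSeed(seed, {
  lam <- clip(truth@lambda0 + truth@etaDecay * zAge(age) +
                stats::rnorm(1, 0, truth@lambdaSd), 0, 0.95)
  lapply(seq_along(tm), function(k) {
    others <- if (length(tm) > 1L) Reduce(`+`, tm[-k]) / (length(tm) - 1L)
              else array(0, dim = d)
    (1 - lam) * tm[[k]] + lam * others +
      array(stats::rnorm(prod(d), 0, truth@mapNoiseSd), dim = d)
  })
  })
  new("SpatialMapSet", maps = maps, labels = networkLabels(templates),
      mask = templates@mask)
}
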