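#' @include AllClasses.R utils.R
NULL

## Flatten a SpatialMapSet to a voxel x K matrix, restricted to its mask.
mapMatrix <- function(maps) {
  m <- spatialMaps(maps)
  sel <- if (length(maps@mask)) as.vector(maps@mask) else TRUE
  do.call(cbind, lapply(m, function(a) as.vector(a)[sel]))
}

## Rebuild a SpatialMapSet from a voxel x K matrix (inverse of mapMatrix).
matrixToMaps <- function(B, template) {
  d <- dim(template@maps[[1L]])
  sel <- if (length(template@mask)) as.vector(template@mask) else
    rep(TRUE, prod(d))
  maps <- lapply(seq_len(ncol(B)), function(k) {
    v <- numeric(prod(d))
    v[sel] <- B[, k]
    array(v, dim = d)
  })
  new("SpatialMapSet", maps = maps, labels = networkLabels(template),
      mask = template@mask)
}

#' Dual regression, stage 1: spatial regression
#'
#' At every time point, the volume is fit by multivariate least squares onto
#' all K group templates jointly, yielding one coefficient time course per
#' template. Joint (not one-template-at-a-time) regression matters whenever
#' templates are spatially correlated.
#'
#' @param data voxel x T matrix (masked voxels in template order), or a
#'   [NodeTimeSeries-class] whose transposed values are voxels x T.
#' @param templates a [SpatialMapSet-class] of K group templates.
#' @return K x T matrix of component time courses (rows labelled).
#' @export
dualRegressionStage1 <- function(data, templates) {
  stopIfNot(is(templates, "SpatialMapSet"),
            "'templates' must be a SpatialMapSet")
  X <- mapMatrix(templates)
  data <- as.matrix(data)
  stopIfNot(nrow(data) == nrow(X),
            "data voxel count does not match template voxel count")
  tc <- lsFit(X, data, warnContext = "spatial templates (collinear?)")
  rownames(tc) <- networkLabels(templates)
  tc
}

#' Dual regression, stage 2: temporal regression
#'
#' Every voxel's series is fit by multivariate least squares onto all K
#' component time courses jointly, yielding K subject-specific spatial
#' maps. By convention the time courses are variance-normalized first
#' (`varianceNormalize = TRUE`), so map units are covariance with a
#' unit-variance course.
#'
#' @param data voxel x T matrix, as in [dualRegressionStage1()].
#' @param timecourses K x T matrix from stage 1.
#' @param templates the template [SpatialMapSet-class] (supplies grid,
#'   labels and mask for the output maps).
#' @param varianceNormalize scale each time course to unit variance before
#'   the fit.
#' @return a [SpatialMapSet-class] of K subject maps.
#' @export
dualRegressionStage2 <- function(data, timecourses, templates,
                                 varianceNormalize = TRUE) {
  stopIfNot(is(templates, "SpatialMapSet"),
            "'templates' must be a SpatialMapSet")
  data <- as.matrix(data)
  C <- as.matrix(timecourses)
  stopIfNot(ncol(data) == ncol(C),
            "data and time courses differ in T")
  stopIfNot(nrow(C) == length(networkLabels(templates)),
            "time-course count does not match template count")
  if (varianceNormalize) {
    s <- apply(C, 1L, stats::sd)
    stopIfNot(all(s > 0), "constant time course cannot be variance-normalized")
    C <- C / s
  }
  ## per-voxel OLS of y_v on t(C): beta = Y C^T (C C^T)^{-1}, computed
  ## through the shared QR of t(C)
  beta <- t(lsFit(t(C), t(data), warnContext = "time courses (collinear?)"))
  matrixToMaps(beta, templates)
}
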