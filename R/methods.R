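#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn nNodes ROIs in the parcellation.
#' @export
setMethod("nNodes", "Parcellation", function(x) nrow(x@rois))

#' @describeIn nNodes columns of the time-series matrix.
#' @export
setMethod("nNodes", "NodeTimeSeries", function(x) ncol(x@values))

#' @describeIn nNodes rows of the correlation matrix.
#' @export
setMethod("nNodes", "ConnectivityMatrix", function(x) nrow(x@r))

#' @describeIn networkLabels the declared RSN names (excluding "other").
#' @export
setMethod("networkLabels", "Parcellation", function(x) x@networks)

#' @describeIn networkLabels one label per map.
#' @export
setMethod("networkLabels", "SpatialMapSet", function(x) x@labels)

#' @describeIn values T x N signal matrix.
#' @export
setMethod("values", "NodeTimeSeries", function(x) x@values)

#' @describeIn values T x 6 motion-parameter matrix.
#' @export
setMethod("values", "MotionTrace", function(x) x@params)

#' @describeIn values T x P design matrix with column labels.
#' @export
setMethod("values", "ConfoundDesign", function(x) {
  m <- x@columns
  colnames(m) <- x@labels
  m
})

#' @describeIn corValues accessor.
#' @export
setMethod("corValues", "ConnectivityMatrix", function(x) x@r)

#' @describeIn zValues accessor.
#' @export
setMethod("zValues", "ConnectivityMatrix", function(x) x@z)

#' @describeIn pathCoefficients accessor.
#' @export
setMethod("pathCoefficients", "MediationResult", function(x) x@paths)

#' ROI table of a parcellation
#' @param parc a [Parcellation-class] object.
#' @return data.frame with columns roi_id, network.
#' @export
roiTable <- function(parc) {
  stopIfNot(is(parc, "Parcellation"), "'parc' must be a Parcellation")
  parc@rois
}

#' Maps of a spatial map set
#' @param x a [SpatialMapSet-class].
#' @param label optional single network label; if given, that 3-D array is
#'   returned instead of the full list.
#' @return list of 3-D arrays (named by label), or one array.
#' @export
spatialMaps <- function(x, label = NULL) {
  stopIfNot(is(x, "SpatialMapSet"), "'x' must be a SpatialMapSet")
  m <- x@maps
  names(m) <- x@labels
  if (is.null(label)) return(m)
  stopIfNot(label %in% x@labels, sprintf("no map labelled '%s'", label))
  m[[label]]
}

setMethod("show", "Parcellation", function(object) {
  tab <- table(object@rois$network)
  cat(sprintf("Parcellation: %d ROIs, %d networks (+ %d 'other' ROIs)\n",
              nrow(object@rois), length(object@networks),
              sum(object@rois$network == "other")))
  rsn <- tab[names(tab) != "other"]
  cat(paste(sprintf("  %s: %d", names(rsn), as.integer(rsn)), collapse = "\n"),
      "\n")
})

setMethod("show", "NodeTimeSeries", function(object) {
  cat(sprintf("NodeTimeSeries: %d volumes x %d nodes, TR = %.3g s\n",
              nrow(object@values), ncol(object@values), object@trSeconds))
})

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace: %d volumes (x, y, z mm; roll, pitch, yaw rad)\n",
              nrow(object@params)))
})

setMethod("show", "SpatialMapSet", function(object) {
  cat(sprintf("SpatialMapSet: %d maps on a %s grid%s\n  labels: %s\n",
              length(object@maps),
              paste(dim(object@maps[[1]]), collapse = " x "),
              if (length(object@mask))
                sprintf(" (%d voxels in mask)", sum(object@mask)) else "",
              paste(object@labels, collapse = ", ")))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  off <- object@r[upper.tri(object@r)]
  cat(sprintf("ConnectivityMatrix: %d x %d, off-diagonal r in [%.3f, %.3f]\n",
              nrow(object@r), ncol(object@r), min(off), max(off)))
})

setMethod("show", "BinaryGraph", function(object) {
  n <- nrow(object@adjacency)
  cat(sprintf("BinaryGraph: %d nodes, %d edges (r > %.2f)\n",
              n, sum(object@adjacency) / 2, object@thresholdR))
})

setMethod("show", "MediationResult", function(object) {
  p <- object@paths
  cat(sprintf("MediationResult: a = %.4g, b = %.4g, c' = %.4g, c = %.4g, ab = %.4g\n",
              p["a"], p["b"], p["cprime"], p["c"], p["ab"]))
  if (object@nBoot > 0)
    cat(sprintf("  bootstrap (%d samples): ab z = %.3f, p = %.4g\n",
                object@nBoot, object@z["ab"], object@p["ab"]))
})

setMethod("show", "CohortGroundTruth", function(object) {
  cat(sprintf(paste0(
    "CohortGroundTruth (seed %d)\n",
    "  within coupling: base %.2f, slope %.2f / unit age\n",
    "  between coupling: base %.2f, slope %.2f / unit age\n",
    "  map mixing: lambda0 %.2f, decay %.2f; mediation a=%.2f b=%.2f c'=%.2f\n"),
    as.integer(object@seed), mean(object@withinBase), mean(object@withinSlope),
    mean(object@betweenBase), mean(object@betweenSlope),
    object@lambda0, object@etaDecay,
    object@mediationA, object@mediationB, object@mediationCprime))
})
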