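#' @include AllClasses.R
NULL

#' Number of nodes / ROIs in an object
#' @param x a Parcellation, NodeTimeSeries or ConnectivityMatrix.
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Network labels carried by an object
#' @param x a Parcellation or SpatialMapSet.
#' @return character vector.
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' Extract the numeric payload of a container
#' @param x a NodeTimeSeries (T x N matrix), MotionTrace (T x 6 matrix) or
#'   ConfoundDesign (T x P matrix).
#' @return numeric matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Pearson correlation block of a connectivity matrix
#' @param x a ConnectivityMatrix.
#' @return numeric N x N matrix.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' Fisher-z block of a connectivity matrix
#' @param x a ConnectivityMatrix.
#' @return numeric N x N matrix with zero diagonal.
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' Mediation path coefficients
#' @param x a MediationResult.
#' @return named numeric vector (a, b, cprime, c, ab).
#' @export
setGeneric("pathCoefficients", function(x) standardGeneric("pathCoefficients"))
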