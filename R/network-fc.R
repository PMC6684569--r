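#' @include AllClasses.R utils.R parcellation.R
NULL

#' Fisher z-transform of correlation coefficients
#'
#' `z = atanh(r)`. Values with `|r| >= 1` (numerically perfect
#' correlations) are clipped to `1 - 1e-7` in magnitude with a warning so
#' the transform stays finite.
#'
#' @param r numeric vector or matrix of correlations.
#' @return transformed values of the same shape.
#' @examples
#' fisherZ(0.5)   # atanh(0.5)
#' @export
fisherZ <- function(r) {
  stopIfNot(all(is.finite(r)), "'r' must be finite")
  if (any(abs(r) >= 1)) {
    warning("correlations with |r| >= 1 clipped before Fisher transform",
            call. = FALSE)
    r <- clip(r, -(1 - 1e-7), 1 - 1e-7)
  }
  atanh(r)
}

networkIdx <- function(conn, parc, network) {
  idx <- networkNodes(parc, network)
  stopIfNot(length(idx) > 0, sprintf("network '%s' has no nodes", network))
  stopIfNot(nNodes(conn) == nNodes(parc),
            "connectivity matrix and parcellation differ in node count")
  idx
}

#' Within-network functional connectivity (WNFC)
#'
#' Mean Fisher-z connectivity over all unordered node pairs inside one
#' network; for a k-node network this averages exactly k(k-1)/2 values,
#' never including the diagonal.
#'
#' @param conn a [ConnectivityMatrix-class] in parcellation node order.
#' @param parc the matching [Parcellation-class].
#' @param network single network label with >= 2 nodes.
#' @return mean z with attribute `n_pairs`.
#' @export
wnfc <- function(conn, parc, network) {
  idx <- networkIdx(conn, parc, network)
  if (length(idx) < 2L)
    stop(sprintf("WNFC undefined: network '%s' has a single node", network),
         call. = FALSE)
  zb <- conn@z[idx, idx]
  vals <- zb[upper.tri(zb)]
  structure(mean(vals), n_pairs = length(vals))
}

#' Between-network functional connectivity (BNFC)
#'
#' Mean Fisher-z connectivity over all node pairs with one node in each of
#' two distinct networks; for networks of sizes k and l this averages
#' exactly k*l values.
#'
#' @param conn a [ConnectivityMatrix-class] in parcellation node order.
#' @param parc the matching [Parcellation-class].
#' @param network1,network2 two distinct network labels.
#' @return mean z with attribute `n_pairs`.
#' @export
bnfc <- function(conn, parc, network1, network2) {
  stopIfNot(network1 != network2, "BNFC needs two distinct networks")
  i <- networkIdx(conn, parc, network1)
  j <- networkIdx(conn, parc, network2)
  vals <- conn@z[i, j, drop = FALSE]
  structure(mean(vals), n_pairs = length(vals))
}

#' Full network-level connectivity table
#'
#' WNFC for every RSN and BNFC for every unordered RSN pair (91 pairs for
#' the 14 canonical networks), with pair counts; together the cells cover
#' each RSN-subset node pair exactly once.
#'
#' @param conn a [ConnectivityMatrix-class] in parcellation node order.
#' @param parc the matching [Parcellation-class].
#' @return data.frame with columns cell, type ("wnfc"/"bnfc"), network1,
#'   network2 (NA for wnfc), value, n_pairs.
#' @export
networkFCTable <- function(conn, parc) {
  nets <- networkLabels(parc)
  wn <- lapply(nets, function(k) {
    v <- wnfc(conn, parc, k)
    data.frame(cell = k, type = "wnfc", network1 = k, network2 = NA,
               value = as.numeric(v), n_pairs = attr(v, "n_pairs"),
               stringsAsFactors = FALSE)
  })
  pairs <- utils::combn(nets, 2L, simplify = FALSE)
  bn <- lapply(pairs, function(p) {
    v <- bnfc(conn, parc, p[1L], p[2L])
    data.frame(cell = paste(p, collapse = ":"), type = "bnfc",
               network1 = p[1L], network2 = p[2L],
               value = as.numeric(v), n_pairs = attr(v, "n_pairs"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(wn, bn))
}
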