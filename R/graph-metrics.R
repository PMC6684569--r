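#' @include AllClasses.R utils.R
NULL

#' Pearson connectivity matrix from node time series
#'
#' Computes the full N x N Pearson correlation matrix between node time
#' series together with its Fisher-z transform (diagonal set to 0 and
#' excluded from every downstream summary).
#'
#' @param ts a [NodeTimeSeries-class] with T >= 3 and no constant node.
#' @return a [ConnectivityMatrix-class].
#' @export
buildConnectivity <- function(ts) {
  stopIfNot(is(ts, "NodeTimeSeries"), "'ts' must be a NodeTimeSeries")
  X <- ts@values
  stopIfNot(nrow(X) >= 3, "need at least 3 time points")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant node series: correlation undefined for %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(X)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  z <- r
  diag(z) <- 0           # diagonal excluded from all summaries
  z <- fisherZ(z)
  ids <- colnames(X)
  if (is.null(ids)) ids <- sprintf("node_%d", seq_len(ncol(X)))
  new("ConnectivityMatrix", r = unname(r), z = unname(z), nodeIds = ids)
}

#' Threshold a connectivity matrix into a binary graph
#'
#' An undirected edge joins i and j iff `r_ij > thresholdR` (strictly);
#' ties at exactly the threshold are excluded, negative correlations never
#' form edges at the positive thresholds of the sweep.
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param thresholdR network-defining correlation threshold in (0, 1).
#' @return a [BinaryGraph-class].
#' @export
thresholdGraph <- function(conn, thresholdR) {
  stopIfNot(is(conn, "ConnectivityMatrix"),
            "'conn' must be a ConnectivityMatrix")
  stopIfNot(is.finite(thresholdR) && thresholdR > 0 && thresholdR < 1,
            "'thresholdR' must lie in (0, 1)")
  a <- (conn@r > thresholdR) * 1
  diag(a) <- 0
  new("BinaryGraph", adjacency = a, thresholdR = thresholdR)
}

asIgraph <- function(g) {
  stopIfNot(is(g, "BinaryGraph"), "'g' must be a BinaryGraph")
  igraph::graph_from_adjacency_matrix(g@adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all reachable ordered node pairs.
#' Unreachable pairs (disconnected graphs) are excluded from the mean and
#' counted in the `"n_unreachable_pairs"` attribute of the result.
#'
#' @param g a [BinaryGraph-class] with >= 2 nodes.
#' @return mean geodesic distance; errors when no pair is reachable.
#' @export
characteristicPathLength <- function(g) {
  ig <- asIgraph(g)
  n <- nrow(g@adjacency)
  stopIfNot(n >= 2, "need at least 2 nodes")
  D <- igraph::distances(ig)
  off <- D[row(D) != col(D)]
  reach <- is.finite(off)
  if (!any(reach))
    stop("characteristic path length undefined: no reachable pair",
         call. = FALSE)
  structure(mean(off[reach]), n_unreachable_pairs = sum(!reach))
}

#' Global efficiency
#'
#' Mean of inverse geodesic distances over all ordered node pairs, with
#' `1/Inf = 0` for unreachable pairs; 1 for a complete graph, 0 for an
#' empty one.
#'
#' @param g a [BinaryGraph-class] with >= 2 nodes.
#' @return efficiency in \[0, 1\].
#' @export
globalEfficiency <- function(g) {
  ig <- asIgraph(g)
  stopIfNot(nrow(g@adjacency) >= 2, "need at least 2 nodes")
  D <- igraph::distances(ig)
  off <- D[row(D) != col(D)]
  mean(1 / off)
}

#' Mean node degree
#' @param g a [BinaryGraph-class].
#' @return mean number of edges per node.
#' @export
meanDegree <- function(g) {
  stopIfNot(is(g, "BinaryGraph"), "'g' must be a BinaryGraph")
  mean(rowSums(g@adjacency))
}

#' Mean betweenness centrality (fractional)
#'
#' Node betweenness is the sum over source-target pairs (excluding the
#' node) of the fraction of shortest paths passing through it, normalized
#' by the number of pairs `(n-1)(n-2)/2` so a complete graph scores 0 and
#' the centre of a star scores 1. The mean over nodes is returned; raw
#' (unnormalized) values are available via `raw = TRUE`.
#'
#' @param g a [BinaryGraph-class] with >= 3 nodes.
#' @param raw return per-node unnormalized betweenness instead.
#' @return mean fractional betweenness, or a numeric vector when `raw`.
#' @export
meanBetweenness <- function(g, raw = FALSE) {
  ig <- asIgraph(g)
  n <- nrow(g@adjacency)
  stopIfNot(n >= 3, "need at least 3 nodes")
  b <- igraph::betweenness(ig, directed = FALSE, normalized = FALSE)
  if (raw) return(b)
  mean(b) / ((n - 1) * (n - 2) / 2)
}

#' Louvain modularity with restarts
#'
#' Runs Louvain community detection `restarts` times under a seeded RNG and
#' returns the partition with the highest modularity
#' `Q = sum_c (e_cc - a_c^2)`.
#'
#' @param g a [BinaryGraph-class] with >= 1 edge.
#' @param seed RNG seed (fixed seed gives a deterministic result).
#' @param restarts number of Louvain restarts.
#' @return list with `Q` and `membership` (integer community labels).
#' @export
modularityQ <- function(g, seed = 1L, restarts = 10L) {
  ig <- asIgraph(g)
  stopIfNot(igraph::ecount(ig) >= 1, "modularity needs at least one edge")
  withSeed(seed, {
    best <- NULL
    for (i in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(ig)
      q <- igraph::modularity(cl)
      if (is.null(best) || q > best$Q)
        best <- list(Q = q, membership = as.integer(igraph::membership(cl)))
    }
    best
  })
}

#' Network hierarchy exponent
#'
#' The hierarchy coefficient beta is the negative slope of the regression
#' of log nodal clustering coefficient on log degree, over nodes with
#' degree > 1 and positive clustering. Returns NA (with a message
#' attribute) when fewer than 2 distinct degrees qualify.
#'
#' @param g a [BinaryGraph-class].
#' @return beta, or NA when the fit is undefined.
#' @export
hierarchyBeta <- function(g) {
  ig <- asIgraph(g)
  k <- igraph::degree(ig)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  sel <- k > 1 & cc > 0
  if (sum(sel) < 2L || length(unique(k[sel])) < 2L)
    return(structure(NA_real_, reason = "too few nodes for hierarchy fit"))
  fit <- stats::lm.fit(cbind(1, log(k[sel])), log(cc[sel]))
  -fit$coefficients[2L]
}

#' Graph-metric battery over a threshold sweep
#'
#' Thresholds the connectivity matrix at each network-defining value
#' (default r = 0.20, 0.25, 0.30, 0.35, 0.40) and computes the whole
#' metric battery on each binary graph.
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param thresholds numeric vector of correlation thresholds.
#' @param seed seed for the Louvain restarts.
#' @return data.frame with one row per threshold: threshold, path_length,
#'   global_efficiency, mean_degree, mean_betweenness, modularity_q,
#'   hierarchy_beta, n_components, n_unreachable_pairs.
#' @export
graphMetricsSweep <- function(conn,
                              thresholds = c(0.20, 0.25, 0.30, 0.35, 0.40),
                              seed = 1L) {
  rows <- lapply(thresholds, function(thr) {
    g <- thresholdGraph(conn, thr)
    ig <- asIgraph(g)
    pl <- tryCatch(characteristicPathLength(g), error = function(e) NA_real_)
    q <- if (igraph::ecount(ig) >= 1) modularityQ(g, seed = seed)$Q
         else NA_real_
    data.frame(
      threshold = thr,
      path_length = as.numeric(pl),
      global_efficiency = globalEfficiency(g),
      mean_degree = meanDegree(g),
      mean_betweenness = meanBetweenness(g),
      modularity_q = q,
      hierarchy_beta = as.numeric(hierarchyBeta(g)),
      n_components = igraph::components(ig)$no,
      n_unreachable_pairs =
        if (is.na(pl[1])) NA_integer_
        else as.integer(attr(pl, "n_unreachable_pairs") %||% 0L))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
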