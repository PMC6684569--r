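# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately naive (explicit BFS, path
# enumeration, normal equations, exhaustive partition search) and share no
# code with the implementation under test.

# All-pairs BFS distances of a 0/1 adjacency matrix.
bfDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier)
        for (w in which(A[v, ] == 1))
          if (!is.finite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

bfPathLength <- function(A) {
  D <- bfDistances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

bfEfficiency <- function(A) {
  D <- bfDistances(A)
  off <- D[row(D) != col(D)]
  mean(1 / off)
}

# Number of shortest s -> t paths, by recursive enumeration.
bfSigma <- function(A, D, s, t) {
  if (s == t) return(1)
  if (!is.finite(D[s, t])) return(0)
  preds <- which(A[, t] == 1 & D[s, ] == D[s, t] - 1)
  sum(vapply(preds, function(w) bfSigma(A, D, s, w), numeric(1)))
}

# Raw betweenness of every node: sum over unordered pairs (s, t), both
# different from v, of the fraction of s-t geodesics passing through v.
bfBetweennessRaw <- function(A) {
  n <- nrow(A)
  D <- bfDistances(A)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] != D[s, t]) next
      b[v] <- b[v] +
        bfSigma(A, D, s, v) * bfSigma(A, D, v, t) / bfSigma(A, D, s, t)
    }
  }
  b
}

bfMeanBetweenness <- function(A) {
  n <- nrow(A)
  mean(bfBetweennessRaw(A)) / ((n - 1) * (n - 2) / 2)
}

# Modularity of a given partition: Q = sum_c (e_cc - a_c^2).
bfModularity <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(NA_real_)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    ecc <- sum(A[idx, idx]) / 2 / m
    ac <- sum(A[idx, ]) / (2 * m)
    q <- q + ecc - ac^2
  }
  q
}

# Exhaustive search over all set partitions (feasible to ~8 nodes).
bfBestModularity <- function(A) {
  n <- nrow(A)
  best <- -Inf
  assign <- integer(n)
  recurse <- function(i, k) {
    if (i > n) {
      best <<- max(best, bfModularity(A, assign[seq_len(n)]))
      return(invisible())
    }
    for (c in seq_len(k + 1)) {
      assign[i] <<- c
      recurse(i + 1, max(k, c))
    }
  }
  recurse(1, 0)
  best
}

# Least squares by explicit normal equations.
bfOls <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Random connected-ish undirected graph on n nodes.
randomAdjacency <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A <- A + t(A)
  diag(A) <- 0
  A
}

# Wrap a 0/1 adjacency matrix as the package's graph class.
asBinaryGraph <- function(A, thr = 0.5) {
  new("BinaryGraph", adjacency = A, thresholdR = thr)
}

# Connectivity matrix with exact planted z-domain blocks.
plantedZConnectivity <- function(parc, withinZ, betweenZ) {
  nets <- roiTable(parc)$network
  n <- length(nets)
  z <- matrix(betweenZ, n, n)
  for (k in unique(nets)) {
    idx <- which(nets == k)
    z[idx, idx] <- withinZ
  }
  diag(z) <- 0
  r <- tanh(z)
  diag(r) <- 1
  new("ConnectivityMatrix", r = r, z = z,
      nodeIds = roiTable(parc)$roi_id)
}

randomMap <- function(dim3 = c(6, 6, 4)) array(rnorm(prod(dim3)), dim = dim3)
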