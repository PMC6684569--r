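## Internal numerical helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded generators never perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic child-seed derivation: one master seed fans out to
## independent per-stage / per-subject streams. Kept below 2^31.
childSeed <- function(master, index) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 %% m
  as.integer((s + as.double(index) * 1299721 + 1) %% m)
}

## Moore-Penrose least squares used wherever a design may be rank deficient.
## Returns coefficients for Y ~ X (no implicit intercept). Columns are
## scaled to unit norm before the QR so that wildly different column scales
## (e.g. millimetre translations next to squared radian rotations) do not
## masquerade as rank deficiency; coefficients are unscaled afterwards.
lsFit <- function(X, Y, warnContext = "design") {
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  Xs <- sweep(X, 2L, nrm, "/")
  qx <- qr(Xs)
  if (qx$rank < ncol(Xs)) {
    warning(sprintf("rank-deficient %s: using pseudoinverse", warnContext),
            call. = FALSE)
    return(MASS::ginv(Xs) %*% Y / nrm)
  }
  qr.coef(qx, Y) / nrm
}

## Project a symmetric matrix to the nearest sampleable correlation matrix:
## clip eigenvalues at `epsilon`, then rescale to unit diagonal.
nearestCorrelation <- function(S, epsilon = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < epsilon) {
    v <- pmax(e$values, epsilon)
    S <- e$vectors %*% (v * t(e$vectors))
  }
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  (S + t(S)) / 2
}

## Standardized age used by every planted age effect: roughly [-0.83, 1.03]
## over the cohort's 21-86 year span, 0 at age 50.
zAge <- function(age) (age - 50) / 35

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
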