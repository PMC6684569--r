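#' @include AllClasses.R utils.R inference.R
NULL

## Fast OLS coefficients for the bootstrap's inner loop; falls back to the
## pseudoinverse on rank deficiency.
olsCoef <- function(X, y, warnContext) {
  f <- .lm.fit(X, y)
  if (f$rank < ncol(X)) {
    warning(sprintf("rank-deficient %s: using pseudoinverse", warnContext),
            call. = FALSE)
    return(as.numeric(MASS::ginv(X) %*% y))
  }
  cf <- numeric(ncol(X))
  cf[f$pivot] <- f$coefficients
  cf
}

## The three OLS fits of the mediation model; all share the same covariate
## set so the identity ab = c - c' holds exactly.
mediationPaths <- function(x, m, y, C) {
  X1 <- cbind(1, x, C)                    # mediator ~ x (+cov)      -> a
  X2 <- cbind(1, m, x, C)                 # y ~ mediator + x (+cov)  -> b, c'
  X3 <- X1                                # y ~ x (+cov)             -> c
  b1 <- olsCoef(X1, m, "mediator regression")
  b2 <- olsCoef(X2, y, "outcome regression")
  b3 <- olsCoef(X3, y, "total-effect regression")
  a <- b1[2L]; b <- b2[2L]; cprime <- b2[3L]; cc <- b3[2L]
  c(a = a, b = b, cprime = cprime, c = cc, ab = a * b)
}

#' Fit the three-regression mediation model (point estimates)
#'
#' Model: independent variable `x` (age) acts on outcome `y` (ACE-R total)
#' partly through mediator `m` (a connectivity measure). Three OLS fits
#' with shared covariates give `a` (x on m), `b` and `cprime` (m and x on
#' y), and `c` (x on y); the indirect effect is `ab = a * b`, which equals
#' `c - cprime` exactly for OLS with identical covariates.
#'
#' @param x,m,y numeric vectors of equal length.
#' @param covariates optional covariate matrix (e.g. sex), shared by all
#'   three regressions.
#' @return a [MediationResult-class] without bootstrap inference.
#' @export
fitMediation <- function(x, m, y, covariates = NULL) {
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  n <- length(x)
  stopIfNot(length(m) == n && length(y) == n, "inputs differ in length")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  k <- if (is.null(C)) 0L else ncol(C)
  stopIfNot(n > 3 + k, "too few observations for the mediation model")
  paths <- mediationPaths(x, m, y, C)
  nav <- stats::setNames(rep(NA_real_, 5L), names(paths))
  new("MediationResult", paths = paths, z = nav, p = nav,
      nBoot = 0, seed = NA_real_, nRedrawn = 0)
}

#' Bootstrap inference for the mediation model
#'
#' Resamples subjects with replacement `nBoot` times, refits all three
#' regressions per draw, and reports per path the bootstrap z
#' (mean / SD of the bootstrap distribution) and a two-sided percentile
#' p-value `2 * min(frac <= 0, frac >= 0)` floored at `2 / nBoot`. Draws in
#' which any regressor is constant are redrawn (count reported).
#'
#' @inheritParams fitMediation
#' @param nBoot number of bootstrap samples (>= 1000 recommended for
#'   inference-grade p-values; 10000 is the conventional choice).
#' @param seed RNG seed; fixed seed gives identical z and p on repeat.
#' @return a [MediationResult-class] with point estimates from the full
#'   sample and bootstrap z / p per path.
#' @export
bootstrapMediation <- function(x, m, y, covariates = NULL, nBoot = 10000L,
                               seed = 1L) {
  stopIfNot(is.numeric(nBoot) && nBoot >= 2, "'nBoot' must be at least 2")
  point <- fitMediation(x, m, y, covariates)
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n <- length(x)
  nBoot <- as.integer(nBoot)
  draws <- matrix(NA_real_, nBoot, 5L,
                  dimnames = list(NULL, c("a", "b", "cprime", "c", "ab")))
  nRedrawn <- 0L
  if (!is.null(C) && any(apply(C, 2L, stats::sd) == 0))
    stop("constant covariate: drop it before bootstrapping", call. = FALSE)
  withSeed(seed, {
    for (i in seq_len(nBoot)) {
      attempts <- 0L
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Ci <- if (is.null(C)) NULL else C[idx, , drop = FALSE]
        degenerate <- stats::sd(x[idx]) == 0 || stats::sd(m[idx]) == 0 ||
          (!is.null(Ci) && any(apply(Ci, 2L, stats::sd) == 0))
        if (!degenerate) break
        nRedrawn <- nRedrawn + 1L
        attempts <- attempts + 1L
        if (attempts > 1000L)
          stop("bootstrap cannot draw a non-degenerate resample",
               call. = FALSE)
      }
      draws[i, ] <- mediationPaths(x[idx], m[idx], y[idx], Ci)
    }
  })
  zf <- function(d) mean(d) / stats::sd(d)
  pf <- function(d) clip(2 * min(mean(d <= 0), mean(d >= 0)), 2 / nBoot, 1)
  zv <- apply(draws, 2L, zf)
  pv <- apply(draws, 2L, pf)
  res <- new("MediationResult", paths = point@paths, z = zv, p = pv,
             nBoot = nBoot, seed = as.numeric(seed), nRedrawn = nRedrawn)
  attr(res, "draws") <- draws
  res
}
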