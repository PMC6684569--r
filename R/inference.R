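#' @include AllClasses.R utils.R
NULL

residualize <- function(v, X) v - X %*% lsFit(X, v, warnContext = "covariates")

#' Partial correlation with covariate control
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' regressing each on the covariates (plus an intercept by default), with a
#' two-sided p-value from the t distribution on `n - 2 - k` degrees of
#' freedom (k covariates).
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional numeric matrix/data.frame/vector of
#'   covariates.
#' @param addIntercept include an intercept in the residualization.
#' @return list with `r`, `p`, `n`, `df`, `covariates` (count).
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50)
#' partialCorrelation(x, y)$r
#' @export
partialCorrelation <- function(x, y, covariates = NULL, addIntercept = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopIfNot(length(y) == n, "'x' and 'y' differ in length")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  k <- if (is.null(C)) 0L else ncol(C)
  stopIfNot(n > 2 + k, "too few observations for the requested covariates")
  X <- cbind(if (addIntercept) rep(1, n), C)
  if (!is.null(X)) {
    rx <- residualize(x, X)
    ry <- residualize(y, X)
  } else {
    rx <- x; ry <- y
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("partial correlation undefined: zero residual variance",
         call. = FALSE)
  r <- as.numeric(stats::cor(rx, ry))
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, p = p, n = n, df = df, covariates = k)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure at level `q`: with p-values sorted ascending, find the
#' largest i with `p_(i) <= i * q / m` and flag all ranks up to i.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical vector of significance flags, same order as `pvals`.
#' @export
bhFdr <- function(pvals, q = 0.05) {
  stopIfNot(all(is.finite(pvals)) && all(pvals >= 0 & pvals <= 1),
            "'pvals' must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the standardized values against the standard
#' normal, flagged at the 5% level. (Testing raw values against N(0, 1)
#' would reject trivially for any shifted or scaled sample; the
#' standardized variant is the meaningful normality check.)
#'
#' @param values numeric vector, n >= 5, non-constant.
#' @param alpha rejection level.
#' @return list with `statistic`, `p`, `reject`.
#' @export
ksNormality <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  stopIfNot(length(values) >= 5, "need at least 5 values")
  s <- stats::sd(values)
  stopIfNot(is.finite(s) && s > 0, "normality check undefined: zero variance")
  zz <- (values - mean(values)) / s
  kt <- suppressWarnings(stats::ks.test(zz, "pnorm"))
  list(statistic = as.numeric(kt$statistic), p = kt$p.value,
       reject = kt$p.value < alpha)
}
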