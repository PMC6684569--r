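#' @include AllClasses.R utils.R
NULL

#' Framewise displacement of a motion trace
#'
#' `FD_t = |dx| + |dy| + |dz| + r * (|droll| + |dpitch| + |dyaw|)` where the
#' deltas are volume-to-volume changes, rotations are converted to arc
#' length on a sphere of radius `headRadius`, and the first volume is
#' assigned FD = 0.
#'
#' @param trace a [MotionTrace-class].
#' @param headRadius sphere radius in mm used to convert rotations
#'   (default 50 mm, the usual convention).
#' @return numeric vector of per-volume FD in mm.
#' @examples
#' tr <- generateMotionTrace(nVolumes = 50, scale = 0.02, seed = 1)
#' mean(framewiseDisplacement(tr))
#' @export
framewiseDisplacement <- function(trace, headRadius = 50) {
  stopIfNot(is(trace, "MotionTrace"), "'trace' must be a MotionTrace")
  stopIfNot(is.finite(headRadius) && headRadius > 0,
            "'headRadius' must be a positive finite number")
  d <- abs(diff(trace@params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    headRadius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion screening decision for one subject
#'
#' A dataset is excluded when mean FD is at or above `meanThr`, or when the
#' fraction of volumes with FD above `volThr` exceeds `fracThr`. Defaults
#' implement the strict criteria: mean FD >= 0.2 mm, or more than 20% of
#' volumes with FD > 0.2 mm.
#'
#' @param fd numeric vector of per-volume FD (mm).
#' @param meanThr mean-FD exclusion threshold in mm.
#' @param fracThr maximum tolerated fraction of high-motion volumes.
#' @param volThr per-volume FD threshold in mm defining a high-motion volume.
#' @return list with `include` (logical), `mean_fd`, `frac_high`, and
#'   `reasons` (character, which criteria fired; empty when included).
#' @export
screenSubject <- function(fd, meanThr = 0.2, fracThr = 0.2, volThr = 0.2) {
  stopIfNot(length(fd) > 0 && all(is.finite(fd)) && all(fd >= 0),
            "'fd' must be non-empty, finite and non-negative")
  meanFd <- mean(fd)
  fracHigh <- mean(fd > volThr)
  reasons <- character(0)
  if (meanFd >= meanThr) reasons <- c(reasons, "mean_fd")
  if (fracHigh > fracThr) reasons <- c(reasons, "frac_high_fd")
  list(include = length(reasons) == 0L, mean_fd = meanFd,
       frac_high = fracHigh, reasons = reasons)
}

#' Build the nuisance-regression design matrix
#'
#' Assembles the 24 motion-derived regressors
#' `[R_t, R_t^2, R_{t-1}, R_{t-1}^2]` from the 6 rigid-body parameters,
#' the three nuisance signals (CSF, white matter, global), their first
#' differences, and an intercept: 31 columns in total. Lagged and
#' differenced columns keep T constant by zero-filling their first row.
#'
#' @param trace a [MotionTrace-class].
#' @param nuisance T x 3 matrix of CSF, WM and global signals (same T as
#'   the trace).
#' @return a [ConfoundDesign-class] with labelled columns; motion-derived
#'   labels carry the prefix `"motion_"`.
#' @export
buildConfoundDesign <- function(trace, nuisance) {
  stopIfNot(is(trace, "MotionTrace"), "'trace' must be a MotionTrace")
  nuisance <- as.matrix(nuisance)
  Tn <- nrow(trace@params)
  stopIfNot(nrow(nuisance) == Tn && ncol(nuisance) == 3L,
            "'nuisance' must be a T x 3 matrix matching the trace")
  stopIfNot(all(is.finite(nuisance)), "non-finite nuisance values")
  R <- trace@params
  lag1 <- rbind(0, R[-Tn, , drop = FALSE])
  motion <- cbind(R, R^2, lag1, lag1^2)
  pn <- colnames(R)
  if (is.null(pn)) pn <- c("x", "y", "z", "roll", "pitch", "yaw")
  motionLabels <- c(paste0("motion_", pn),
                    paste0("motion_", pn, "_sq"),
                    paste0("motion_", pn, "_lag"),
                    paste0("motion_", pn, "_lag_sq"))
  nuisLabels <- c("csf", "wm", "global")
  dNuis <- rbind(0, diff(nuisance))
  design <- cbind(motion, nuisance, dNuis, 1)
  labels <- c(motionLabels, nuisLabels, paste0("d_", nuisLabels), "intercept")
  new("ConfoundDesign", columns = unname(design), labels = labels)
}

#' Regress confounds out of node time series
#'
#' Replaces each node's series by its least-squares residual on the full
#' confound design. Residuals are orthogonal to every design column; a
#' rank-deficient design is handled by the pseudoinverse with a warning.
#'
#' @param ts a [NodeTimeSeries-class].
#' @param design a [ConfoundDesign-class] with matching T.
#' @return a [NodeTimeSeries-class] of residuals.
#' @export
regressConfounds <- function(ts, design) {
  stopIfNot(is(ts, "NodeTimeSeries"), "'ts' must be a NodeTimeSeries")
  stopIfNot(is(design, "ConfoundDesign"), "'design' must be a ConfoundDesign")
  X <- design@columns
  Y <- ts@values
  stopIfNot(nrow(X) == nrow(Y), "design and time series differ in T")
  beta <- lsFit(X, Y, warnContext = "confound design")
  res <- Y - X %*% beta
  colnames(res) <- colnames(Y)
  new("NodeTimeSeries", values = res, trSeconds = ts@trSeconds)
}

#' Band-pass filter node time series
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass,
#' defaulting to the 0.01-0.1 Hz band conventional for resting-state BOLD.
#' Zero-phase filtering avoids the phase shifts that would otherwise bias
#' connectivity estimates.
#'
#' @param ts a [NodeTimeSeries-class].
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   `0 <= lowHz < highHz < 1/(2 * trSeconds)`.
#' @return a filtered [NodeTimeSeries-class].
#' @export
bandpass <- function(ts, lowHz = 0.01, highHz = 0.1) {
  stopIfNot(is(ts, "NodeTimeSeries"), "'ts' must be a NodeTimeSeries")
  nyq <- 1 / (2 * ts@trSeconds)
  stopIfNot(is.finite(lowHz) && is.finite(highHz) &&
              lowHz >= 0 && lowHz < highHz && highHz < nyq,
            sprintf("band must satisfy 0 <= low < high < Nyquist (%.4g Hz)",
                    nyq))
  bf <- signal::butter(2, c(max(lowHz, 1e-6), highHz) / nyq, type = "pass")
  ## demean first: DC sits in the stop band, and removing it up front keeps
  ## the forward-backward pass free of edge transients
  out <- apply(ts@values, 2L, function(x) signal::filtfilt(bf, x - mean(x)))
  colnames(out) <- colnames(ts@values)
  new("NodeTimeSeries", values = out, trSeconds = ts@trSeconds)
}

#' Drop initial volumes from a time series
#'
#' Discards the first `n` volumes (scanner equilibration period) from a
#' node time series; applied at ingestion before any other temporal step.
#'
#' @param ts a [NodeTimeSeries-class].
#' @param n number of volumes to drop (default 5).
#' @return a [NodeTimeSeries-class].
#' @export
dropInitialVolumes <- function(ts, n = 5L) {
  stopIfNot(is(ts, "NodeTimeSeries"), "'ts' must be a NodeTimeSeries")
  stopIfNot(n >= 0 && n < nrow(ts@values) - 1L,
            "'n' must leave at least 2 volumes")
  if (n == 0L) return(ts)
  new("NodeTimeSeries", values = ts@values[-seq_len(n), , drop = FALSE],
      trSeconds = ts@trSeconds)
}
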