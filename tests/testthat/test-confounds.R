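constantTrace <- function(Tn = 20) {
  new("MotionTrace", params = matrix(0.3, Tn, 6,
      dimnames = list(NULL, c("x", "y", "z", "roll", "pitch", "yaw"))))
}

test_that("framewise displacement: constant trace, single steps, rotation arc", {
  expect_true(all(framewiseDisplacement(constantTrace()) == 0))

  tr <- constantTrace()
  tr@params[10, 1] <- tr@params[10, 1] + 0.1   # step in x at volume 10
  fd <- framewiseDisplacement(tr)
  expect_equal(fd[10], 0.1)
  expect_equal(fd[11], 0.1)                    # stepping back down
  expect_equal(fd[1], 0)
  expect_equal(sum(fd > 0), 2L)

  tr2 <- constantTrace()
  tr2@params[5, 4] <- tr2@params[5, 4] + 0.002 # 0.002 rad roll step
  fd2 <- framewiseDisplacement(tr2, headRadius = 50)
  expect_equal(fd2[5], 0.1)                    # 0.002 x 50 mm arc
})

test_that("FD is invariant to permuting the translation axes", {
  tr <- generateMotionTrace(nVolumes = 60, scale = 0.05, seed = 2)
  fd1 <- framewiseDisplacement(tr)
  perm <- tr
  perm@params <- perm@params[, c(3, 1, 2, 4, 5, 6)]
  expect_equal(framewiseDisplacement(perm), fd1)
})

test_that("screening applies the two-criterion exclusion rule", {
  # mean criterion alone
  dec <- screenSubject(rep(0.25, 100))
  expect_false(dec$include)
  expect_true("mean_fd" %in% dec$reasons)

  # fraction criterion alone: mean 0.10 but 25% of volumes above 0.2
  fd <- c(rep(0.25, 25), rep(0.05, 75))
  fd <- fd * 0.10 / mean(fd)          # rescale to mean exactly 0.10
  fd[fd > 0.2] <- 0.25                # keep the high volumes above 0.2
  fd <- c(rep(0.25, 25), rep((0.10 * 100 - 0.25 * 25) / 75, 75))
  dec2 <- screenSubject(fd)
  expect_equal(mean(fd), 0.10, tolerance = 1e-12)
  expect_false(dec2$include)
  expect_identical(dec2$reasons, "frac_high_fd")

  # below both thresholds: mean 0.19, 10% above 0.2
  fd3 <- c(rep(0.21, 10), rep((0.19 * 100 - 0.21 * 10) / 90, 90))
  dec3 <- screenSubject(fd3)
  expect_equal(mean(fd3), 0.19, tolerance = 1e-12)
  expect_true(dec3$include)

  # boundary: mean exactly at threshold is excluded (>=)
  expect_false(screenSubject(rep(0.2, 10))$include)
  # boundary: fraction exactly at threshold is included (strict >)
  fd4 <- c(rep(0.3, 2), rep(0.01, 8))
  expect_true(screenSubject(fd4)$include)
})

test_that("confound design has 24 motion regressors and 31 columns", {
  tr <- generateMotionTrace(nVolumes = 40, scale = 0.03, seed = 3)
  nuis <- matrix(rnorm(40 * 3), 40, 3)
  des <- buildConfoundDesign(tr, nuis)
  expect_identical(sum(startsWith(des@labels, "motion")), 24L)
  expect_identical(ncol(values(des)), 31L)
  expect_identical(des@labels[length(des@labels)], "intercept")
  # lag columns are zero-filled in row 1, keeping T constant
  expect_identical(nrow(values(des)), 40L)
  lagCols <- grepl("_lag", des@labels)
  expect_true(all(values(des)[1, lagCols] == 0))
  expect_error(buildConfoundDesign(tr, nuis[-1, ]), "T x 3")
})

test_that("confound regression leaves residuals orthogonal to the design", {
  set.seed(4)
  tr <- generateMotionTrace(nVolumes = 60, scale = 0.03, seed = 5)
  nuis <- matrix(rnorm(60 * 3), 60, 3)
  des <- buildConfoundDesign(tr, nuis)
  ts <- new("NodeTimeSeries", values = matrix(rnorm(60 * 7), 60, 7),
            trSeconds = 2.5)
  out <- regressConfounds(ts, des)
  ip <- crossprod(des@columns, values(out))
  expect_lt(max(abs(ip)), 1e-8 * max(abs(values(ts))) * nrow(values(ts)))

  # a series equal to a design column is annihilated
  ts2 <- new("NodeTimeSeries",
             values = cbind(des@columns[, 2], des@columns[, 27]),
             trSeconds = 2.5)
  expect_lt(max(abs(values(regressConfounds(ts2, des)))), 1e-10)

  # intercept-only design mean-centers
  int <- new("ConfoundDesign", columns = matrix(1, 60, 1),
             labels = "intercept")
  cent <- regressConfounds(ts, int)
  expect_equal(values(cent), scale(values(ts), scale = FALSE),
               ignore_attr = TRUE)

  # matches brute-force normal equations
  resOracle <- values(ts) -
    des@columns %*% bfOls(des@columns, values(ts))
  expect_equal(values(out), resOracle, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("confound regression is idempotent", {
  set.seed(6)
  tr <- generateMotionTrace(nVolumes = 50, scale = 0.02, seed = 7)
  des <- buildConfoundDesign(tr, matrix(rnorm(150), 50, 3))
  ts <- new("NodeTimeSeries", values = matrix(rnorm(250), 50, 5),
            trSeconds = 2.5)
  once <- regressConfounds(ts, des)
  twice <- regressConfounds(once, des)
  expect_equal(values(twice), values(once), tolerance = 1e-10)
})

test_that("band-pass keeps in-band sinusoids and attenuates out-of-band", {
  tr <- 2.5
  t <- (0:999) * tr
  mk <- function(f) new("NodeTimeSeries",
                        values = matrix(cos(2 * pi * f * t), ncol = 1),
                        trSeconds = tr)
  amp <- function(ts, f) {
    y <- values(ts)[, 1]
    X <- abs(fft(y)) / length(y) * 2
    X[round(f * length(y) * tr) + 1]
  }
  inBand <- bandpass(mk(0.05))
  expect_gt(amp(inBand, 0.05), 0.95)
  stopBand <- bandpass(mk(0.18))
  expect_lt(amp(stopBand, 0.18), 0.10)
  dc <- bandpass(new("NodeTimeSeries",
                     values = matrix(5, 1000, 1), trSeconds = tr))
  expect_lt(max(abs(values(dc))), 0.05)
  expect_error(bandpass(mk(0.05), 0.01, 0.25), "Nyquist")
})

test_that("initial-volume dropping shortens the series as configured", {
  ts <- new("NodeTimeSeries", values = matrix(rnorm(30), 10, 3),
            trSeconds = 2.5)
  expect_identical(nrow(values(dropInitialVolumes(ts, 5))), 5L)
  expect_identical(values(dropInitialVolumes(ts, 0)), values(ts))
  expect_error(dropInitialVolumes(ts, 9), "at least 2")
})
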