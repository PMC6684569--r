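smallParc <- function() {
  parcellation(data.frame(
    roi_id = sprintf("r%02d", 1:12),
    network = rep(c("netA", "netB", "other"), each = 4)),
    networks = c("netA", "netB"))
}

test_that("cohort generation is byte-identical under a fixed seed", {
  a <- generateCohort(25, seed = 42)
  b <- generateCohort(25, seed = 42)
  expect_identical(a$subjects, b$subjects)
  c <- generateCohort(25, seed = 43)
  expect_false(identical(a$subjects$age, c$subjects$age))
})

test_that("null mediation model with zero noise yields constant ACE-R", {
  truth <- defaultGroundTruth(seed = 5, mediationA = 0, mediationB = 0,
                              mediationCprime = 0, sexCoef = 0, noiseSd = 0)
  coh <- generateCohort(30, truth)
  expect_equal(var(coh$subjects$ace_r_total), 0)
  expect_true(all(coh$subjects$ace_r_total == truth@aceIntercept))
})

test_that("cohort invariants: age range, ACE-R range, screening flag", {
  coh <- generateCohort(200, seed = 7)
  s <- coh$subjects
  expect_true(all(s$age >= 21 & s$age <= 86))
  expect_true(all(s$ace_r_total >= 0 & s$ace_r_total <= 100))
  expect_true(all(s$ace_r_total[s$cognitive_pass] >= 89))
  expect_true(all(s$sex %in% c(0, 1)))
  expect_error(generateCohort(1), "at least 2")
})

test_that("planted negative total age effect shows in the ACE-R partial correlation", {
  signs <- vapply(1:20, function(s) {
    coh <- generateCohort(200, seed = s)
    pc <- partialCorrelation(coh$subjects$age, coh$subjects$ace_r_total,
                             covariates = coh$subjects$sex)
    pc$r < 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("zero couplings give uncorrelated node series", {
  truth <- defaultGroundTruth(seed = 1, withinBase = 0, withinSlope = 0,
                              betweenBase = 0, betweenSlope = 0,
                              otherCoupling = 0, couplingShare = 0)
  ts <- generateNodeTimeSeries(50, smallParc(), truth, nVolumes = 400,
                               seed = 3)
  r <- cor(values(ts))
  expect_lt(mean(abs(r[upper.tri(r)])), 3 / sqrt(400))
})

test_that("planted within coupling is recovered at large T", {
  truth <- defaultGroundTruth(seed = 1,
                              withinBase = c(netA = 0.5, netB = 0.2),
                              withinSlope = 0, betweenBase = 0,
                              betweenSlope = 0, otherCoupling = 0,
                              couplingShare = 0)
  ts <- generateNodeTimeSeries(50, smallParc(), truth, nVolumes = 10000,
                               seed = 9)
  r <- cor(values(ts))
  blockA <- r[1:4, 1:4][upper.tri(diag(4))]
  expect_equal(mean(blockA), 0.5, tolerance = 0.02)
})

test_that("negative within slope lowers empirical WNFC across age tertiles", {
  parc <- smallParc()
  truth <- defaultGroundTruth(seed = 2, couplingShare = 0,
                              withinSlope = -0.2)
  coh <- generateCohort(90, truth)
  w <- vapply(seq_len(90), function(i) {
    ts <- generateNodeTimeSeries(coh$subjects[i, ], parc, truth,
                                 nVolumes = 193, seed = 100 + i)
    as.numeric(wnfc(buildConnectivity(ts), parc, "netA"))
  }, numeric(1))
  tert <- cut(coh$subjects$age, quantile(coh$subjects$age, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  means <- tapply(w, tert, mean)
  expect_gt(means[[1]], means[[2]])
  expect_gt(means[[2]], means[[3]])
})

test_that("out-of-range couplings name the offending block", {
  truth <- defaultGroundTruth(seed = 1, withinBase = c(netA = 1.5, netB = 0))
  expect_error(generateNodeTimeSeries(40, smallParc(), truth, seed = 1),
               "netA")
})

test_that("motion traces: determinism, stillness, and exclusion fraction", {
  a <- generateMotionTrace(nVolumes = 100, scale = 0.05, seed = 11)
  b <- generateMotionTrace(nVolumes = 100, scale = 0.05, seed = 11)
  expect_identical(values(a), values(b))

  still <- generateMotionTrace(nVolumes = 50, scale = 0, seed = 1)
  expect_true(all(framewiseDisplacement(still) == 0))

  truth <- defaultGroundTruth(seed = 3, highMotionFraction = 0.5)
  coh <- generateCohort(100, truth)
  excl <- vapply(seq_len(100), function(i) {
    tr <- generateMotionTrace(coh$subjects[i, ], truth, nVolumes = 193,
                              seed = 200 + i)
    !screenSubject(framewiseDisplacement(tr))$include
  }, logical(1))
  expect_lt(abs(mean(excl) - 0.5), 0.10)
})

test_that("spatial maps: zero decay and zero noise reproduce the templates", {
  tm <- generateTemplates(labels = c("a", "b", "c"), seed = 4)
  truth <- defaultGroundTruth(seed = 1, etaDecay = 0, lambda0 = 0,
                              lambdaSd = 0, mapNoiseSd = 0)
  sm <- generateSpatialMaps(70, tm, truth, seed = 5)
  for (lab in c("a", "b", "c")) {
    expect_equal(spatialMaps(sm, lab), spatialMaps(tm, lab))
    expect_equal(etaSquared(spatialMaps(sm, lab), spatialMaps(tm, lab)), 1)
  }
})

test_that("planted map decay yields negative eta-age partial correlation", {
  tm <- generateTemplates(seed = 6, gridDim = c(12L, 12L, 8L))
  signs <- vapply(1:10, function(s) {
    truth <- defaultGroundTruth(seed = s)
    coh <- generateCohort(80, truth)
    maps <- lapply(seq_len(80), function(i)
      generateSpatialMaps(coh$subjects[i, ], tm, truth, seed = 500 + i))
    names(maps) <- coh$subjects$subject_id
    ref <- buildReference(maps, coh$subjects, 30)
    st <- similarityTable(maps, ref)
    eta <- st$eta_sq[st$rsn_label == "auditory"]
    partialCorrelation(eta, coh$subjects$age,
                       covariates = coh$subjects$sex)$r < 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("maps without planted decay carry no age signal", {
  set.seed(8)
  tm <- generateTemplates(labels = c("a", "b"), gridDim = c(8L, 8L, 6L),
                          seed = 7)
  truth <- defaultGroundTruth(seed = 1, etaDecay = 0, lambda0 = 0,
                              lambdaSd = 0, mapNoiseSd = 1.5)
  coh <- generateCohort(60, truth)
  eta <- vapply(seq_len(60), function(i) {
    sm <- generateSpatialMaps(coh$subjects[i, ], tm, truth, seed = 900 + i)
    etaSquared(spatialMaps(sm, "a"), spatialMaps(tm, "a"))
  }, numeric(1))
  young <- coh$subjects$age <= 40
  pv <- t.test(eta[young], eta[!young])$p.value
  expect_gt(pv, 0.01)
})
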