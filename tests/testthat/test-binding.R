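test_that("direct model hits its limits and matches the bisection oracle", {
  r0 <- 0.05; rb <- 0.25
  # no protein: free probe exactly
  expect_identical(directAnisotropy(13, 50, 0, r0, rb), r0)
  # saturation limit
  expect_equal(directAnisotropy(13, 50, 1e6 * 13, r0, rb), rb,
               tolerance = 1e-3)
  # assay configuration vs the independent single-site bisection oracle
  fbModel <- (directAnisotropy(13, 50, 250, 0, 1))
  fbOracle <- bisectDirectFb(13, 50, 250)
  expect_equal(fbModel, fbOracle, tolerance = 1e-9)
  expect_error(directAnisotropy(-1, 50, 10, r0, rb))
})

test_that("direct model is monotone in protein and bounded by the endpoints", {
  Pt <- c(0, 10^seq(-2, 5, length.out = 60))
  r <- directAnisotropy(13, 50, Pt, 0.05, 0.25)
  expect_true(all(diff(r) >= -1e-12))
  expect_true(all(r >= 0.05 - 1e-12 & r <= 0.25 + 1e-12))
})

test_that("competition closed form reduces correctly at its edges", {
  r0 <- 0.05; rb <- 0.25
  direct <- directAnisotropy(13, 50, 250, r0, rb)
  # no competitor: the binary system
  expect_equal(competitiveAnisotropy(5, 0, 50, 250, 13, r0, rb), direct,
               tolerance = 1e-9)
  # infinitely weak competitor at any dose
  weak <- competitiveAnisotropy(1e12 * 13, c(10, 1e3, 1e5), 50, 250, 13,
                                r0, rb)
  expect_equal(weak, rep(direct, 3), tolerance = 1e-6)
  # perfect competitor in excess sequesters all protein
  expect_lt(solveEquilibriumNumeric(13, 1e-9, 50, 500, 250), 1e-6)
  expect_identical(solveEquilibriumNumeric(13, 5, 50, 10, 0), 0)
})

test_that("closed form agrees with the numerical oracle pointwise", {
  Lt <- 10^seq(-1, 4, length.out = 12)
  a <- probeFractionBound(5, Lt, 50, 250, 13)
  b <- solveEquilibriumNumeric(13, 5, 50, Lt, 250)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("oracle conserves protein and ligand mass to 1e-10", {
  set.seed(5)
  for (i in 1:50) {
    Kd1 <- 10^runif(1, -2, 5); Kd2 <- 10^runif(1, -2, 5)
    Lt <- 10^runif(1, -1, 4); Lst <- 50; Pt <- 250
    fb <- solveEquilibriumNumeric(Kd1, Kd2, Lst, Lt, Pt)
    p <- Kd1 * fb / (1 - fb)
    PL1 <- Lst * p / (Kd1 + p)
    PL2 <- Lt * p / (Kd2 + p)
    expect_equal(p + PL1 + PL2, Pt, tolerance = 1e-10)
    expect_equal((Lst - PL1) + PL1, Lst, tolerance = 1e-10)
  }
})

test_that("competition model is monotone in dose and in competitor affinity", {
  Lt <- 10^seq(-1, 4, length.out = 40)
  r <- competitiveAnisotropy(5, Lt, 50, 250, 13, 0.05, 0.25)
  expect_true(all(diff(r) <= 1e-12))
  expect_true(all(r >= 0.05 - 1e-12 & r <= 0.25 + 1e-12))
  byKd2 <- vapply(10^seq(-1, 4, length.out = 20), function(k)
    competitiveAnisotropy(k, 300, 50, 250, 13, 0.05, 0.25), numeric(1))
  expect_true(all(diff(byKd2) >= -1e-12))
})

test_that("noiseless fits are self-consistent to 0.1%", {
  f <- fitDirect(simulateDirectTitration(Kd = 13, noiseSd = 0))
  expect_true(f@converged)
  expect_equal(fitEstimate(f), 13, tolerance = 1e-3)
  fc <- fitCompetition(simulateCompetitionTitration(Kd2 = 5, noiseSd = 0))
  expect_true(fc@converged)
  expect_equal(fitEstimate(fc), 5, tolerance = 1e-3)
})

test_that("Kd recovery is calibrated under assay noise", {
  est <- vapply(1:200, function(s)
    fitEstimate(fitDirect(simulateDirectTitration(Kd = 13, seed = s))),
    numeric(1))
  expect_gte(mean(abs(est - 13) / 13 < 0.15), 0.95)
  relErr <- vapply(1:200, function(s) {
    f <- fitCompetition(simulateCompetitionTitration(Kd2 = 5, seed = s))
    abs(fitEstimate(f) - 5) / 5
  }, numeric(1))
  expect_lt(median(relErr), 0.05)
})

test_that("weak-binder competition recovery stays within 20% at 2% noise", {
  relErr <- vapply(1:20, function(s) {
    f <- fitCompetition(simulateCompetitionTitration(Kd2 = 7800, seed = s))
    abs(fitEstimate(f) - 7800) / 7800
  }, numeric(1))
  expect_lt(median(relErr), 0.2)
})

test_that("flat curves are reported unidentifiable, never silently fitted", {
  flat <- TitrationCurve(seq(1, 2000, length.out = 12), rep(0.12, 12),
                         mode = "direct")
  f <- fitDirect(flat)
  expect_false(f@converged)
  expect_true("unidentifiable_flat_curve" %in% qcFlags(f))
})

test_that("curve-validity checks flag the assay failure modes", {
  clean <- simulateCompetitionTitration(Kd2 = 5, seed = 2)
  expect_length(validateCurve(clean, r0 = 0.05), 0)
  # competition baseline dipping 5 noise-sd below the free-probe value
  dip <- clean
  sd0 <- 0.02 * 0.2
  dip@r[length(dip@r)] <- 0.05 - 5 * sd0
  expect_true("baseline_below_free_probe" %in%
                validateCurve(dip, r0 = 0.05, noiseSd = sd0))
  # direct titration starting 10 noise-sd above the free-probe anisotropy
  dir <- simulateDirectTitration(Kd = 13, seed = 3)
  dir@r[1] <- 0.05 + 10 * sd0
  expect_true("start_anisotropy_mismatch" %in%
                validateCurve(dir, r0 = 0.05, noiseSd = sd0))
  # fitting a baseline-dipping curve surfaces the flag on the result
  fc <- fitCompetition(dip, fixEndpoints = c(0.05, 0.25))
  expect_true("baseline_below_free_probe" %in% qcFlags(fc))
})

test_that("invalid parameter regimes raise errors instead of NaN", {
  expect_error(probeFractionBound(-1, 10, 50, 250, 13), "positive")
  expect_error(probeFractionBound(5, -10, 50, 250, 13), "non-negative")
  expect_error(fitDirect(simulateCompetitionTitration(Kd2 = 5, noiseSd = 0)),
               "mode")
})
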