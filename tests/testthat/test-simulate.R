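test_that("generators are deterministic under a fixed seed", {
  a <- simulateDirectTitration(Kd = 13, seed = 4)
  b <- simulateDirectTitration(Kd = 13, seed = 4)
  expect_identical(a@r, b@r)
  expect_false(identical(a@r, simulateDirectTitration(Kd = 13, seed = 5)@r))
  t1 <- simulateLibrary(nPeptides = 30, seed = 8)
  t2 <- simulateLibrary(nPeptides = 30, seed = 8)
  expect_identical(libData(t1), libData(t2))
  s1 <- simulateCdSpectrum(0.5, noiseSd = 0.2, seed = 6)
  s2 <- simulateCdSpectrum(0.5, noiseSd = 0.2, seed = 6)
  expect_identical(s1@ellipticity, s2@ellipticity)
})

test_that("noiseless curves equal the closed-form models exactly", {
  d <- simulateDirectTitration(Kd = 13, noiseSd = 0, replicates = 1)
  expect_equal(d@r, directAnisotropy(13, 50, d@x, 0.05, 0.25))
  cc <- simulateCompetitionTitration(Kd2 = 20, noiseSd = 0, replicates = 1)
  expect_equal(cc@r, competitiveAnisotropy(20, cc@x, 50, 250, 13, 0.05, 0.25))
  # midpoint value agrees with the numerical oracle
  lt <- displacementMidpoint(13, 50, 250, 13)
  expect_equal(probeFractionBound(13, lt, 50, 250, 13),
               solveEquilibriumNumeric(13, 13, 50, lt, 250),
               tolerance = 1e-9)
  dr <- simulateDoseResponse(0.3, noiseSd = 0)
  expect_equal(dr@response, 100 / (1 + (0.3 / dr@conc)^1))
})

test_that("default competition grids span most of the dynamic range", {
  for (kd2 in c(1, 50, 7800)) {
    cc <- simulateCompetitionTitration(Kd2 = kd2, noiseSd = 0)
    expect_gt(diff(range(cc@r)) / (0.25 - 0.05), 0.8)
  }
})

test_that("library generator plants its structure exactly", {
  tab <- simulateLibrary(nPeptides = 100, seed = 13, fractionToxic = 0.2)
  df <- libData(tab)
  expect_identical(nrow(df), 100L)
  expect_identical(sum(df$truth_toxic), 20L)
  # toxic records carry measurable LDH/counterscreen potencies
  tox <- df[df$truth_toxic, ]
  expect_true(all(!grepl("^>", tox$ldh_ec50_uM)))
  expect_true(all(grepl("^>", df$ldh_ec50_uM[!df$truth_toxic])))
  # sequences parse and ground-truth columns are never read by the filter
  expect_silent(parsePeptide(df$sequence[1]))
  kept <- filterLibrary(tab)
  expect_true(nrow(libData(kept)) <= 100)
})

test_that("planted lipophilicity-permeability slope is recovered, null is null", {
  hits <- vapply(1:20, function(s) {
    tab <- simulateLibrary(nPeptides = 200, seed = s)
    ann <- annotateLibrary(filterLibrary(tab))
    co <- correlateLibrary(ann, "logd", "cell_ratio", logY = TRUE)
    co$r < -0.6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  nullr <- vapply(1:20, function(s) {
    tab <- simulateLibrary(nPeptides = 200, seed = 1000 + s,
                           permeabilitySlope = 0)
    ann <- annotateLibrary(filterLibrary(tab))
    abs(correlateLibrary(ann, "logd", "cell_ratio", logY = TRUE)$r)
  }, numeric(1))
  expect_gte(mean(nullr < 0.2), 0.9)
})

test_that("planted censored potencies surface as bounds after fitting", {
  d <- simulateDoseResponse(500, noiseSd = 3, seed = 17)
  f <- fitEc50(d)
  expect_true(isCensored(ec50(f)))
  expect_equal(censoredBound(ec50(f)), "gt")
})
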