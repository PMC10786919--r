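test_that("control normalization matches the assay conventions", {
  expect_equal(normalizeResponse(800, 800, 100), 100)
  expect_equal(normalizeResponse(100, 800, 100), 0)
  # a compound can exceed the positive control (277% efficacy)
  expect_equal(normalizeResponse(100 + 2.77 * 700, 800, 100), 277)
  expect_error(normalizeResponse(5, 3, 3), "degenerate controls")
})

test_that("normalization is invariant under affine rescaling of the signal", {
  set.seed(9)
  raw <- runif(10, 100, 900)
  base <- normalizeResponse(raw, 900, 100)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); b <- runif(1, -50, 50)
    expect_equal(normalizeResponse(a * raw + b, a * 900 + b, a * 100 + b),
                 base)
  }
})

test_that("noiseless 4PL curves are recovered essentially exactly", {
  d <- simulateDoseResponse(0.3, hill = 1, top = 100, noiseSd = 0)
  f <- fitEc50(d)
  expect_true(f@converged)
  expect_false(isCensored(ec50(f)))
  expect_equal(censoredValue(ec50(f)), 0.3, tolerance = 1e-3)
  expect_equal(f@hill, 1, tolerance = 1e-3)
})

test_that("EC50 recovery is calibrated on the plate design at 3% noise", {
  err <- vapply(1:100, function(s) {
    f <- fitEc50(simulateDoseResponse(0.3, noiseSd = 3, seed = s))
    abs(censoredValue(ec50(f)) - 0.3) / 0.3
  }, numeric(1))
  expect_gte(mean(err < 0.2), 0.9)
  expect_lt(median(err), 0.1)
})

test_that("responses that never reach half the top are censored at the ceiling", {
  # flat at baseline
  flat <- DoseResponseCurve(50 / 3^(9:0), rep(1.5, 10))
  ff <- fitEc50(flat)
  expect_true(isCensored(ec50(ff)))
  expect_equal(censoredValue(ec50(ff)), 50)
  expect_equal(censoredBound(ec50(ff)), "gt")
  # potency planted above the tested range
  high <- simulateDoseResponse(500, noiseSd = 0)
  fh <- fitEc50(high)
  expect_true(isCensored(ec50(fh)))
  expect_false(is.na(fh@efficacy))   # efficacy reported even when censored
})

test_that("proliferation curves fit with the top fixed at 100% inhibition", {
  d <- simulateDoseResponse(2, top = 100, assay = "proliferation",
                            noiseSd = 0)
  f <- fitEc50(d)
  expect_equal(f@details$top, 100)
  expect_equal(censoredValue(ec50(f)), 2, tolerance = 1e-3)
})

test_that("half-life estimation handles decay, stability and bad input", {
  # exact halving each hour
  hl <- halfLife(c(0, 1, 2), c(100, 50, 25))
  expect_false(isCensored(hl))
  expect_equal(censoredValue(hl), 1)
  # 30-minute half-life sampled at the stability-assay time points
  set.seed(21)
  errs <- replicate(50, {
    t <- c(0, 1, 2, 4, 22)
    pct <- 100 * 2^(-t / 0.5)
    pct[-1] <- pct[-1] * exp(rnorm(4, 0, 0.05))
    abs(censoredValue(halfLife(t, pct)) - 0.5) / 0.5
  })
  expect_lt(median(errs), 0.25)
  # no decay: censored beyond the assay window
  stable <- halfLife(c(0, 1, 2, 4, 22), c(100, 101, 99, 100.5, 99.5))
  expect_true(isCensored(stable))
  expect_equal(censoredValue(stable), 22)
  expect_error(halfLife(c(0, 1, 2), c(100, 50, -3)), "non-positive")
  expect_error(halfLife(c(1, 2, 3), c(100, 50, 25)), "must be 0")
})
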