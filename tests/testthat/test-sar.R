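test_that("cell ratio harmonizes units and propagates censoring", {
  # template: 0.47 uM cellular EC50 over 5.0 nM Kd
  expect_equal(censoredValue(cellRatio(0.47, 5.0)), 94)
  expect_equal(censoredValue(cellRatio(0.005, 5.0)), 1)
  r <- cellRatio(parseCensored(">50"), 5)
  expect_equal(censoredValue(r), 10000)
  expect_equal(censoredBound(r), "gt")
  expect_error(cellRatio(0.47, parseCensored("<1")), "censored denominator")
})

test_that("on-target index, serum shift and fold improvement match the worked examples", {
  wx <- workedExamplesData()
  row <- function(nm) wx[wx$name == nm, ]
  # optimized di-alkyne peptide: no off-target effect up to the ceiling
  oi <- onTargetIndex(row("MP-467")$prolif_off_uM, row("MP-467")$prolif_on_uM)
  expect_gt(censoredValue(oi), 3800)
  expect_equal(censoredBound(oi), "gt")
  # all-D lead: ~20-fold therapeutic window
  ti <- onTargetIndex(row("MP-042")$prolif_off_uM, row("MP-042")$prolif_on_uM)
  expect_equal(censoredValue(ti), 20.7, tolerance = 0.01)
  expect_false(isCensored(ti))
  # di-Phe tail: >20x right-shift under serum
  ss <- serumShift(row("MP-040")$cell_ec50_10pct_uM,
                   row("MP-040")$cell_ec50_0pct_uM)
  expect_gt(censoredValue(ss), 20)
  # all-D series: inactive parent to 0.28 uM, an >178-fold improvement
  fi <- foldImprovement(row("MP-769")$cell_ec50_10pct_uM,
                        row("MP-042")$cell_ec50_10pct_uM)
  expect_gt(censoredValue(fi), 178)
  expect_equal(censoredBound(fi), "gt")
  # identities
  expect_equal(censoredValue(onTargetIndex(2, 2)), 1)
  expect_equal(censoredValue(serumShift(0.5, 0.5)), 1)
  expect_equal(censoredValue(foldImprovement(3, 3)), 1)
  expect_error(foldImprovement(10, parseCensored(">50")),
               "censored denominator")
})

test_that("solubility follows the peak-area formula", {
  expect_equal(solubilityFromAreas(1000, 1000, 100), 100)
  expect_equal(solubilityFromAreas(500, 1000, 100), 50)
  expect_equal(solubilityFromAreas(0, 1000, 100), 0)
  expect_error(solubilityFromAreas(10, 0, 100), "positive")
})

test_that("library filter applies the binding and margin rules at the bound", {
  tab <- LibraryTable(data.frame(
    name = c("clean", "weak", "toxic"),
    kd_nM = c("5", "20000", "5"),
    cell_ec50_0pct_uM = c("0.5", "0.5", "0.5"),
    counterscreen_ec50_uM = c(">50", ">50", "2"),
    ldh_ec50_uM = c(">50", ">50", ">50"),
    stringsAsFactors = FALSE))
  kept <- filterLibrary(tab)
  expect_identical(libData(kept)$name, "clean")
  expect_match(filterLog(kept)[length(filterLog(kept))], "3 -> 1")
})

test_that("filter survivor count matches an independent recount of planted violations", {
  tab <- plantedFilterTable(n = 100, nBad = 37, seed = 11)
  kept <- filterLibrary(tab)
  # independent brute-force recount, rule by rule
  df <- libData(tab)
  ok <- 0L
  for (i in seq_len(nrow(df))) {
    kd <- parseCensored(df$kd_nM[i]); cell <- parseCensored(df$cell_ec50_0pct_uM[i])
    cs <- parseCensored(df$counterscreen_ec50_uM[i])
    ldh <- parseCensored(df$ldh_ec50_uM[i])
    if (censoredValue(kd) < 10000 &&
        censoredValue(cell) * 10 <= censoredValue(cs) &&
        censoredValue(cell) * 10 <= censoredValue(ldh)) ok <- ok + 1L
  }
  expect_identical(nrow(libData(kept)), ok)
  expect_identical(ok, 63L)
  # idempotence: filtering a filtered table changes nothing
  again <- filterLibrary(kept)
  expect_identical(libData(again), libData(kept))
})

test_that("correlation excludes censored pairs and reports exclusions", {
  tab <- LibraryTable(data.frame(
    name = sprintf("p%d", 1:6),
    logd = as.character(1:6),
    y = c("2", "4", "6", "8", ">10", "12"),
    stringsAsFactors = FALSE))
  co <- correlateLibrary(tab, "logd", "y")
  expect_equal(co$r, 1, tolerance = 1e-12)
  expect_identical(co$n, 5L)
  expect_identical(co$n.excluded, 1L)
  const <- LibraryTable(data.frame(name = c("a", "b", "c"),
                                   logd = c("1", "1", "1"),
                                   y = c("1", "2", "3")))
  expect_error(correlateLibrary(const, "logd", "y"), "constant")
  expect_error(correlateLibrary(tab, "logd", "missing_col"), "missing")
})

test_that("tumor volume and growth inhibition follow the study formulas", {
  expect_equal(tumorVolume(1, 1, 1), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(tumorVolume(2, 3, 4), tumorVolume(4, 3, 2))
  # the as-printed formula is 8x the ellipsoid volume from diameters
  expect_equal(tumorVolume(2, 3, 4) / tumorVolume(2, 3, 4, "ellipsoid"), 8)
  expect_error(tumorVolume(0, 1, 1), "positive")

  expect_equal(tgiPercent(c(100, 400), c(100, 400)), 0)
  expect_equal(tgiPercent(c(100, 100), c(100, 400)), 100)
  expect_equal(tgiPercent(c(100, 201), c(100, 400)), 100 * (1 - 101 / 300))
  expect_error(tgiPercent(c(100, 200), c(100, 90)), "did not grow")
})
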