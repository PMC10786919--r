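#' Synthetic data generators
#'
#' Every input type the analysis consumes can be generated with known ground
#' truth: direct and competition titrations (forward model = the exact
#' binding equations), dose-response plates (forward model = the 4PL), CD
#' spectra (two-basis helix/coil mixing) and whole library tables with
#' planted statistical structure. All generators take an explicit seed and
#' are bit-identical under the same seed; ground truth travels in a
#' \code{truth} slot/columns that no analysis stage reads.
#'
#' @name synthetic-data
NULL

.logGrid <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

#' Simulate a direct protein titration
#'
#' Forward model is the exact 1:1 depletion-corrected anisotropy equation
#' plus i.i.d. Gaussian noise. Defaults mirror the binding assay
#' configuration: 50 nM labeled probe, a 12-point protein grid spanning the
#' transition, and noise of 2\% of the dynamic range.
#'
#' @param Kd true dissociation constant (nM).
#' @param Lst total labeled probe (nM).
#' @param PtGrid protein concentrations (nM); default 12-point log grid
#'   1-2000 nM.
#' @param r0,rb anisotropy endpoints.
#' @param noiseSd Gaussian noise sd on anisotropy; default 2\% of
#'   \code{rb - r0}.
#' @param replicates independent measurements per concentration (default 3,
#'   the assay convention of reporting at least triplicate measurements).
#' @param seed integer seed (required when \code{noiseSd > 0}).
#' @return A [TitrationCurve-class] with the truth embedded in metadata.
#' @export
simulateDirectTitration <- function(Kd = 13, Lst = 50, PtGrid = NULL,
                                    r0 = 0.05, rb = 0.25,
                                    noiseSd = 0.02 * (rb - r0),
                                    replicates = 3, seed = NULL) {
  if (is.null(PtGrid)) PtGrid <- .logGrid(1, 2000, 12)
  PtGrid <- sort(rep(PtGrid, each = replicates))
  r <- directAnisotropy(Kd, Lst, PtGrid, r0, rb)
  if (noiseSd > 0) {
    if (is.null(seed)) stop("seed is required when injecting noise")
    set.seed(seed)
    r <- r + stats::rnorm(length(r), 0, noiseSd)
  }
  TitrationCurve(PtGrid, r, mode = "direct", Lst = Lst, r0 = NA_real_,
                 rb = NA_real_,
                 truth = list(Kd = Kd, r0 = r0, rb = rb, noiseSd = noiseSd,
                              seed = seed))
}

#' Simulate a competition titration
#'
#' Forward model is the exact ternary-equilibrium solution. Defaults mirror
#' the competition assay configuration: 50 nM labeled probe, 250 nM protein,
#' probe Kd 13.0 nM, competitor grid spanning 0.01-1000 times its Kd.
#'
#' @param Kd2 true competitor dissociation constant (nM).
#' @param Lst,Pt,Kd1 assay constants (nM).
#' @param LtGrid competitor concentrations (nM); by default a 12-point log
#'   grid centered on the displacement midpoint (the total competitor at
#'   which the probe bound fraction halves, from the exact mass balance),
#'   spanning a factor of 30 on either side — the way a competition dilution
#'   series is centered on the expected IC50 in practice.
#' @inheritParams simulateDirectTitration
#' @param replicates independent measurements per concentration.
#' @return A [TitrationCurve-class] object.
#' @export
simulateCompetitionTitration <- function(Kd2, Lst = 50, Pt = 250, Kd1 = 13,
                                         LtGrid = NULL, r0 = 0.05, rb = 0.25,
                                         noiseSd = 0.02 * (rb - r0),
                                         replicates = 3, seed = NULL) {
  if (is.null(LtGrid)) {
    mid <- displacementMidpoint(Kd2, Lst, Pt, Kd1)
    LtGrid <- .logGrid(mid / 30, mid * 30, 12)
  }
  LtGrid <- sort(rep(LtGrid, each = replicates))
  r <- competitiveAnisotropy(Kd2, LtGrid, Lst, Pt, Kd1, r0, rb)
  if (noiseSd > 0) {
    if (is.null(seed)) stop("seed is required when injecting noise")
    set.seed(seed)
    r <- r + stats::rnorm(length(r), 0, noiseSd)
  }
  TitrationCurve(LtGrid, r, mode = "competition", Lst = Lst, Pt = Pt,
                 Kd1 = Kd1, truth = list(Kd2 = Kd2, r0 = r0, rb = rb,
                                         noiseSd = noiseSd, seed = seed))
}

#' Simulate a dose-response curve
#'
#' Forward model is the four-parameter logistic with bottom 0. The default
#' concentration scheme replicates the plate design: 10-point, 3-fold
#' serial dilution from a 10 mM DMSO stock giving a 50 uM top in-well
#' concentration.
#'
#' @param ec50uM true EC50 (uM).
#' @param hill Hill slope.
#' @param top top plateau (percent).
#' @param conc concentration series (uM); default the 10-point 3x scheme.
#' @param assay assay label.
#' @param noiseSd Gaussian noise sd in percent (default 3).
#' @param seed integer seed.
#' @return A [DoseResponseCurve-class] object.
#' @export
simulateDoseResponse <- function(ec50uM, hill = 1, top = 100, conc = NULL,
                                 assay = "p53_reporter", noiseSd = 3,
                                 seed = NULL) {
  if (is.null(conc)) conc <- 50 / 3^(9:0)
  conc <- sort(conc)
  resp <- .fourPL(conc, ec50uM, hill, top, 0)
  if (noiseSd > 0) {
    if (is.null(seed)) stop("seed is required when injecting noise")
    set.seed(seed)
    resp <- resp + stats::rnorm(length(resp), 0, noiseSd)
  }
  DoseResponseCurve(conc, resp, assay = assay,
                    truth = list(ec50uM = ec50uM, hill = hill, top = top,
                                 noiseSd = noiseSd, seed = seed))
}

.helixShape <- function(lambda) {
  g <- function(mu, s) exp(-(lambda - mu)^2 / (2 * s^2))
  neg <- g(222, 9.5) + 0.95 * g(208, 8.5)
  negAt222 <- 1 + 0.95 * exp(-(222 - 208)^2 / (2 * 8.5^2))
  list(neg = neg / negAt222, pos = g(191, 5.5))
}

.coilShape <- function(lambda) {
  g <- function(mu, s) exp(-(lambda - mu)^2 / (2 * s^2))
  -42000 * g(198, 7) + 800 * g(230, 30)
}

#' Simulate a CD spectrum as a helix/coil two-basis mixture
#'
#' MRE(lambda) = w * H(lambda) + (1 - w) * C(lambda), where the helix basis
#' H has the canonical double minimum (208/222 nm) scaled so that
#' H(222) equals the chain-length-corrected helix limit used by
#' [fractionHelix()], and the coil basis C has the deep ~198 nm minimum
#' with C(222) near the coil reference. The MRE mixture is converted back
#' to measured millidegrees using the stated concentration, path length and
#' residue count, so the round trip through [meanResidueEllipticity()] and
#' [fractionHelix()] recovers the mixing weight.
#'
#' @param helixWeight mixing weight in [0, 1].
#' @param nResidues,concuM,pathCm acquisition parameters.
#' @param wavelength grid in nm (default 190-300 by 1).
#' @param noiseSd Gaussian noise sd in millidegrees.
#' @param seed integer seed.
#' @return A [CdSpectrum-class] object.
#' @export
simulateCdSpectrum <- function(helixWeight, nResidues = 16, concuM = 50,
                               pathCm = 0.2, wavelength = 190:300,
                               noiseSd = 0, seed = NULL) {
  stopifnot(helixWeight >= 0, helixWeight <= 1)
  hs <- .helixShape(wavelength)
  H <- .thetaHelix(nResidues) * hs$neg + 65000 * hs$pos
  C <- .coilShape(wavelength)
  mre <- helixWeight * H + (1 - helixWeight) * C
  mdeg <- mre * 10 * pathCm * (concuM * 1e-6) * (nResidues - 1L)
  if (noiseSd > 0) {
    if (is.null(seed)) stop("seed is required when injecting noise")
    set.seed(seed)
    mdeg <- mdeg + stats::rnorm(length(mdeg), 0, noiseSd)
  }
  CdSpectrum(wavelength, mdeg, concuM, nResidues, pathCm,
             truth = list(helixWeight = helixWeight, noiseSd = noiseSd,
                          seed = seed))
}

.tailArchetypes <- c(
  SAA      = "SAA",
  A6       = "AAAAAA",
  A5dA     = "AAAAA[dA]",
  EEAAAA   = "EEAAAA",
  aMeE     = "AA[aMeE]AA[dA]",
  G6       = "GGGGGG",
  Sar5     = "A[Sar][Sar][Sar][Sar][Sar]",
  P6       = "PPPPPP",
  AdA3     = "A[dA]A[dA]A[dA]"
)

.templateBody <- "[KN3][bA]LTF[R8]EYWAQ[Cba][S5]"

#' Generate random stapled peptide sequences
#'
#' Draws library-style sequences: the stapled template core with a tail from
#' the archetype set (poly-Ala, Glu-containing, helix-breaking Gly/Pro/Sar,
#' alternating-D, ...), exercising the whole residue vocabulary including
#' non-naturals. Used for parser round-trip and classifier property tests.
#'
#' @param n number of peptides.
#' @param seed integer seed.
#' @return character vector of sequence notations.
#' @export
simulatePeptideNotations <- function(n, seed) {
  set.seed(seed)
  subs <- c("A", "E", "Q", "S", "N", "D", "[Aib]", "[hS]", "[Gla]", "[dA]")
  vapply(seq_len(n), function(i) {
    tail <- sample(.tailArchetypes, 1)
    extra <- if (stats::runif(1) < 0.5)
      paste0(sample(subs, sample(1:3, 1), replace = TRUE), collapse = "") else ""
    paste0("Ac-", .templateBody, tail, extra, "-NH2")
  }, character(1))
}

#' Simulate a peptide library table with planted structure
#'
#' Generates a library emulating the statistical structure the SAR analysis
#' assumes: lipophilicity (LogD) drives permeability with a configurable
#' slope on the log10 cell ratio; an exact count of records is planted as
#' toxic (potent LDH/counterscreen activity, the frequent fate of
#' net-positive sequences); poorly soluble (high-LogD) peptides receive
#' strongly serum-shifted potencies. Potencies above the censor limit are
#' written as \code{">limit"}. Hidden \code{truth_*} columns carry every
#' planted relationship; no analysis stage reads them.
#'
#' @param nPeptides number of records.
#' @param seed integer seed (mandatory).
#' @param logdRange range of experimental LogD values.
#' @param permeabilitySlope d log10(cell ratio) / d LogD (default -0.8:
#'   higher lipophilicity, lower cell ratio, better permeability).
#' @param noiseSd sd of the lognormal scatter on the cell ratio (log10
#'   units, default 0.3).
#' @param censorLimituM assay ceiling (default 50 uM).
#' @param fractionToxic fraction of records planted with off-target
#'   toxicity (exact count \code{round(fractionToxic * nPeptides)}).
#' @return A [LibraryTable-class] object.
#' @export
simulateLibrary <- function(nPeptides = 200, seed,
                            logdRange = c(-1, 3.5),
                            permeabilitySlope = -0.8, noiseSd = 0.3,
                            censorLimituM = 50, fractionToxic = 0.1) {
  stopifnot(nPeptides >= 1, !missing(seed), noiseSd >= 0)
  set.seed(seed)
  n <- nPeptides
  cens <- function(v) ifelse(v > censorLimituM,
                             paste0(">", censorLimituM), format(v, digits = 6))
  tailIdx <- sample(seq_along(.tailArchetypes), n, replace = TRUE)
  seqs <- paste0("Ac-", .templateBody, .tailArchetypes[tailIdx], "-NH2")
  logd <- stats::runif(n, logdRange[1], logdRange[2])
  kd <- 10^stats::rnorm(n, log10(5), 0.6)
  l10ratio <- 2.0 + permeabilitySlope * logd + stats::rnorm(n, 0, noiseSd)
  cell0 <- kd * 10^l10ratio / 1000                       # uM
  poorSol <- logd > 3
  sol <- ifelse(poorSol, stats::runif(n, 1, 10), stats::runif(n, 90, 200))
  shift <- ifelse(poorSol, stats::runif(n, 10, 40),
                  10^stats::rnorm(n, log10(2), 0.15))
  cell10 <- cell0 * shift
  nTox <- round(fractionToxic * n)
  toxic <- rep(FALSE, n)
  if (nTox > 0) toxic[sample.int(n, nTox)] <- TRUE
  ldh <- ifelse(toxic, stats::runif(n, 2, 20), Inf)
  cs <- ifelse(toxic, stats::runif(n, 2, 20), Inf)
  prolifOn <- cell10 * stats::runif(n, 1, 3)
  prolifOff <- ifelse(toxic, prolifOn * stats::runif(n, 2, 10), Inf)
  df <- data.frame(
    name = sprintf("SIM-%04d", seq_len(n)),
    sequence = seqs,
    kd_nM = format(kd, digits = 6),
    cell_ec50_0pct_uM = cens(cell0),
    cell_ec50_10pct_uM = cens(cell10),
    ldh_ec50_uM = cens(ldh),
    counterscreen_ec50_uM = cens(cs),
    prolif_on_uM = cens(prolifOn),
    prolif_off_uM = cens(prolifOff),
    logd = logd,
    alogp = logd + stats::rnorm(n, 0, 0.3),
    solubility_uM = format(sol, digits = 5),
    helicity_pct = stats::runif(n, 15, 55),
    truth_log10_cell_ratio = l10ratio,
    truth_toxic = toxic,
    truth_serum_shift = shift,
    stringsAsFactors = FALSE)
  LibraryTable(df, log = sprintf(
    "simulateLibrary(n=%d, seed=%d, slope=%g, noise=%g, toxic=%d)",
    n, seed, permeabilitySlope, noiseSd, nTox))
}
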