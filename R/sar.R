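#' Cell ratio: cellular EC50 over binding Kd
#'
#' Permeability proxy used for library analysis: the cellular EC50 (uM)
#' divided by the biochemical dissociation constant (nM), after exact
#' unit harmonization (1 uM = 1000 nM). A large cell ratio means the
#' cellular potency lags far behind the binding affinity, i.e. the peptide
#' is poorly permeable. Censoring propagates: a \code{">"} cellular EC50
#' gives a \code{">"} ratio; a censored Kd is an error.
#'
#' @param cellEc50uM cellular EC50 in uM ([Censored-class] or coercible).
#' @param kdnM binding Kd in nM.
#' @return unitless [Censored-class] ratio.
#' @examples
#' cellRatio(0.47, 5.0)   # 94
#' @export
cellRatio <- function(cellEc50uM, kdnM) {
  num <- censoredScale(asCensored(cellEc50uM), 1000, "nM")
  censoredRatio(num, asCensored(kdnM))
}

#' On-target index: off-target over on-target proliferation EC50
#'
#' Fold separation between proliferation potency in a p53-deficient line
#' (off-target) and a p53 wild-type line (on-target). A \code{">"} (or
#' \code{">>"}) off-target EC50 yields a \code{">"} index; a censored
#' on-target EC50 is an error (the index would be unbounded in an unknown
#' direction).
#'
#' @param offuM,onuM proliferation EC50s in uM.
#' @return unitless [Censored-class] index.
#' @export
onTargetIndex <- function(offuM, onuM) {
  censoredRatio(asCensored(offuM), asCensored(onuM))
}

#' Serum shift: EC50 ratio between serum and serum-free conditions
#'
#' Fold right-shift of the cellular EC50 from the 0\%-serum, 4-hour assay to
#' the 10\%-serum, 16-hour assay; a proxy for serum protein binding.
#'
#' @param ec50SerumuM EC50 under 10\% serum (uM).
#' @param ec50FreeuM EC50 under 0\% serum (uM).
#' @return unitless [Censored-class] ratio with censor propagation.
#' @export
serumShift <- function(ec50SerumuM, ec50FreeuM) {
  censoredRatio(asCensored(ec50SerumuM), asCensored(ec50FreeuM))
}

#' Fold improvement of a potency relative to a reference
#'
#' \code{reference / improved}; a \code{">"} reference (e.g. an inactive
#' parent censored at the assay ceiling) yields a \code{">"} fold
#' improvement. An improved value that is itself censored above is an error.
#'
#' @param referenceuM,improveduM potencies in the same units.
#' @return unitless [Censored-class] fold change.
#' @export
foldImprovement <- function(referenceuM, improveduM) {
  censoredRatio(asCensored(referenceuM), asCensored(improveduM))
}

#' Kinetic solubility from chromatographic peak areas
#'
#' \code{Solubility [uM] = (peak area of sample / peak area of standard) *
#' standard concentration}, the standard being prepared at full nominal
#' concentration in organic solvent.
#'
#' @param areaSample,areaStandard chromatographic peak areas;
#'   \code{areaStandard} must be positive.
#' @param standardConcuM standard concentration in uM (assay default 100).
#' @return solubility in uM.
#' @export
solubilityFromAreas <- function(areaSample, areaStandard,
                                standardConcuM = 100) {
  if (areaStandard <= 0) stop("standard peak area must be positive")
  if (areaSample < 0) stop("negative sample peak area")
  (areaSample / areaStandard) * standardConcuM
}

#' Xenograft tumor volume from caliper diameters
#'
#' Computed as reported for the xenograft study: \code{4*pi*a*b*c/3} with
#' a, b, c the measured diameters in mm. Note this is 8 times the volume of
#' an ellipsoid with those diameters (\code{pi*a*b*c/6}); set
#' \code{formula = "ellipsoid"} for the dimensionally conventional variant.
#'
#' @param a,b,c measured diameters (mm), all positive; order irrelevant.
#' @param formula \code{"as_reported"} (default) or \code{"ellipsoid"}.
#' @return volume in mm^3.
#' @export
tumorVolume <- function(a, b, c, formula = c("as_reported", "ellipsoid")) {
  formula <- match.arg(formula)
  if (any(c(a, b, c) <= 0)) stop("diameters must be positive")
  switch(formula,
         as_reported = 4 * pi * a * b * c / 3,
         ellipsoid = pi * a * b * c / 6)
}

#' Tumor growth inhibition percentage
#'
#' \code{TGI = 100 * (1 - dT/dV)} where dT and dV are the mean tumor-volume
#' growth (endpoint minus baseline at the last common time point) of the
#' treated and vehicle groups. 0\% means growth identical to vehicle, 100\%
#' complete stasis; regression below baseline can exceed 100\%.
#'
#' @param treatedMeanVolumes,vehicleMeanVolumes mean tumor volumes (mm^3)
#'   over the same time points, baseline first.
#' @return TGI percentage.
#' @export
tgiPercent <- function(treatedMeanVolumes, vehicleMeanVolumes) {
  if (length(treatedMeanVolumes) != length(vehicleMeanVolumes) ||
      length(treatedMeanVolumes) < 2L)
    stop("treated and vehicle series must share >= 2 time points")
  if (treatedMeanVolumes[1] <= 0 || vehicleMeanVolumes[1] <= 0)
    stop("baseline volumes must be positive")
  dT <- treatedMeanVolumes[length(treatedMeanVolumes)] - treatedMeanVolumes[1]
  dV <- vehicleMeanVolumes[length(vehicleMeanVolumes)] - vehicleMeanVolumes[1]
  if (dV <= 0) stop("vehicle group did not grow; TGI undefined")
  100 * (1 - dT / dV)
}

#' Construct a library table
#'
#' @param data data.frame with a unique \code{name} column; potency-like
#'   columns may contain censored entries as strings (\code{">50"}, ...).
#' @param log character vector of provenance lines.
#' @return A [LibraryTable-class] object.
#' @export
LibraryTable <- function(data, log = character()) {
  new("LibraryTable", data = as.data.frame(data), log = log)
}

#' @describeIn LibraryTable the underlying data.frame.
#' @param x a [LibraryTable-class] object.
#' @export
libData <- function(x) x@data

#' @describeIn LibraryTable the append-only provenance log.
#' @export
filterLog <- function(x) x@log

setMethod("show", "LibraryTable", function(object) {
  cat("LibraryTable:", nrow(object@data), "peptides,",
      ncol(object@data), "columns\n")
  if (length(object@log))
    cat(paste0("  log: ", object@log, collapse = "\n"), "\n")
})

.censColumn <- function(df, col) {
  if (!col %in% names(df))
    stop("library table is missing required column '", col, "'")
  lapply(df[[col]], parseCensored)
}

.atBound <- function(cv) cv@value   # censored entries evaluated at the bound

#' Filter a library to clean, on-target binders
#'
#' The selection used for permeability/lipophilicity analysis: keep peptides
#' whose binding Kd is below \code{kdMaxuM} and whose cellular EC50 is at
#' least \code{margin}-fold more potent than both the counterscreen and the
#' LDH EC50 (to exclude polypharmacology). Censored \code{">"} entries are
#' evaluated at their bound, i.e. an inactive counterscreen (\code{">50"})
#' passes the margin at 50. Records with a missing required value are
#' dropped. The filter is idempotent and appends its before/after counts to
#' the table's provenance log.
#'
#' @param table a [LibraryTable-class] object with columns \code{kd_nM},
#'   \code{cell_ec50_0pct_uM}, \code{counterscreen_ec50_uM},
#'   \code{ldh_ec50_uM}.
#' @param kdMaxuM Kd cutoff in uM (default 10).
#' @param margin required fold separation (default 10).
#' @param cellColumn which cellular EC50 column carries the activity.
#' @return filtered [LibraryTable-class].
#' @export
filterLibrary <- function(table, kdMaxuM = 10, margin = 10,
                          cellColumn = "cell_ec50_0pct_uM") {
  stopifnot(is(table, "LibraryTable"))
  df <- table@data
  kd <- .censColumn(df, "kd_nM")
  cell <- .censColumn(df, cellColumn)
  cs <- .censColumn(df, "counterscreen_ec50_uM")
  ldh <- .censColumn(df, "ldh_ec50_uM")
  keep <- vapply(seq_len(nrow(df)), function(i) {
    v <- c(.atBound(kd[[i]]), .atBound(cell[[i]]),
           .atBound(cs[[i]]), .atBound(ldh[[i]]))
    if (any(is.na(v))) return(FALSE)
    v[1] < kdMaxuM * 1000 &&
      v[2] * margin <= v[3] &&
      v[2] * margin <= v[4]
  }, logical(1))
  LibraryTable(df[keep, , drop = FALSE],
               log = c(table@log,
                       sprintf("filter(kd<%guM, %gx margins): %d -> %d records",
                               kdMaxuM, margin, nrow(df), sum(keep))))
}

#' Correlation between two library columns
#'
#' Pearson (default) or Spearman correlation between two columns, optionally
#' log10-transforming potency-like quantities. Censored entries are excluded
#' from the computation and counted.
#'
#' @param table a [LibraryTable-class] object.
#' @param xColumn,yColumn column names.
#' @param logX,logY log10-transform before correlating.
#' @param method "pearson" or "spearman".
#' @return list with \code{r}, \code{p.value}, \code{n},
#'   \code{n.excluded} (censored or missing pairs).
#' @export
correlateLibrary <- function(table, xColumn, yColumn,
                             logX = FALSE, logY = FALSE,
                             method = c("pearson", "spearman")) {
  stopifnot(is(table, "LibraryTable"))
  method <- match.arg(method)
  xs <- .censColumn(table@data, xColumn)
  ys <- .censColumn(table@data, yColumn)
  ok <- vapply(seq_along(xs), function(i)
    !is.na(xs[[i]]@value) && !is.na(ys[[i]]@value) &&
      !isCensored(xs[[i]]) && !isCensored(ys[[i]]), logical(1))
  x <- vapply(xs[ok], censoredValue, numeric(1))
  y <- vapply(ys[ok], censoredValue, numeric(1))
  if (logX) x <- log10(x)
  if (logY) y <- log10(y)
  if (length(x) < 3L) stop("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant column: correlation undefined")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p.value = ct$p.value,
       n = length(x), n.excluded = sum(!ok))
}
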