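#' Read a titration CSV
#'
#' Dialect: mandatory header with columns \code{titrant_nM} and
#' \code{anisotropy}, optional \code{replicate}. Assay metadata (mode, probe
#' concentration, protein concentration, probe Kd) comes from arguments or
#' from a JSON sidecar with the same keys.
#'
#' @param path CSV path.
#' @param mode "direct" or "competition".
#' @param Lst,Pt,Kd1 assay constants (nM); sidecar values take precedence
#'   only for keys not supplied explicitly.
#' @param sidecar optional path to a JSON metadata file.
#' @return A [TitrationCurve-class] object (replicates kept as repeated
#'   concentrations, sorted).
#' @export
readTitrationCsv <- function(path, mode = NULL, Lst = NULL, Pt = NULL,
                             Kd1 = NULL, sidecar = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("titrant_nM", "anisotropy")
  if (!all(need %in% names(df)))
    stop("titration CSV must have columns: ", paste(need, collapse = ", "),
         " (line 1 of ", path, ")")
  for (col in need) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(df$titrant_nM) | !is.finite(df$anisotropy))
  if (length(bad))
    stop("non-numeric titration data at line ", bad[1] + 1L, " of ", path)
  meta <- list(mode = mode, Lst = Lst, Pt = Pt, Kd1 = Kd1)
  if (!is.null(sidecar)) {
    sc <- jsonlite::fromJSON(sidecar)
    for (k in names(meta)) if (is.null(meta[[k]]) && !is.null(sc[[k]]))
      meta[[k]] <- sc[[k]]
  }
  if (is.null(meta$mode)) stop("titration mode must be declared")
  ord <- order(df$titrant_nM)
  TitrationCurve(df$titrant_nM[ord], df$anisotropy[ord], mode = meta$mode,
                 Lst = if (is.null(meta$Lst)) 50 else meta$Lst,
                 Pt = if (is.null(meta$Pt)) NA_real_ else meta$Pt,
                 Kd1 = if (is.null(meta$Kd1)) NA_real_ else meta$Kd1)
}

#' @describeIn readTitrationCsv write a titration curve to CSV.
#' @param curve a [TitrationCurve-class] object.
#' @export
writeTitrationCsv <- function(curve, path) {
  utils::write.csv(data.frame(titrant_nM = curve@x, anisotropy = curve@r),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response plate CSV
#'
#' Dialect: columns \code{conc_uM}, \code{raw_signal}, \code{well_type}
#' (\code{sample}, \code{max_control}, \code{min_control}). Control wells
#' are averaged and used to normalize the sample wells to percent activity.
#'
#' @param path CSV path.
#' @param assay assay label.
#' @return A [DoseResponseCurve-class] object.
#' @export
readPlateCsv <- function(path, assay = "p53_reporter") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conc_uM", "raw_signal", "well_type")
  if (!all(need %in% names(df)))
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  maxC <- mean(df$raw_signal[df$well_type == "max_control"])
  minC <- mean(df$raw_signal[df$well_type == "min_control"])
  if (!is.finite(maxC) || !is.finite(minC))
    stop("plate CSV needs max_control and min_control wells")
  smp <- df[df$well_type == "sample", ]
  smp <- stats::aggregate(raw_signal ~ conc_uM, smp, mean)
  smp <- smp[order(smp$conc_uM), ]
  DoseResponseCurve(smp$conc_uM, smp$raw_signal, assay = assay,
                    maxControl = maxC, minControl = minC)
}

#' Read a peptide library CSV
#'
#' One row per peptide; censored potencies encoded as \code{">50"},
#' \code{">>50"}, \code{"<1"}. Column names follow the documented schema
#' (\code{name}, \code{sequence}, \code{kd_nM}, \code{cell_ec50_0pct_uM},
#' \code{cell_ec50_10pct_uM}, \code{ldh_ec50_uM},
#' \code{counterscreen_ec50_uM}, \code{prolif_on_uM}, \code{prolif_off_uM},
#' \code{logd}, \code{alogp}, \code{solubility_uM}, \code{helicity_pct});
#' only \code{name} is mandatory at read time, individual operations
#' validate the columns they need.
#'
#' @param path CSV path.
#' @return A [LibraryTable-class] object.
#' @export
readLibraryCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"name" %in% names(df)) stop("library CSV needs a 'name' column")
  for (col in intersect(c("logd", "alogp", "helicity_pct"), names(df)))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  LibraryTable(df, log = paste0("read: ", basename(path)))
}

#' @describeIn readLibraryCsv write a library table (data only) to CSV.
#' @param table a [LibraryTable-class] object.
#' @export
writeLibraryCsv <- function(table, path) {
  utils::write.csv(table@data, path, row.names = FALSE)
  invisible(path)
}

#' Read a CD spectrum CSV
#'
#' Dialect: columns \code{wavelength_nm}, \code{ellipticity_mdeg};
#' acquisition metadata via arguments.
#'
#' @param path CSV path.
#' @param concuM,nResidues,pathCm acquisition parameters.
#' @return A [CdSpectrum-class] object.
#' @export
readCdCsv <- function(path, concuM, nResidues, pathCm = 0.2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "ellipticity_mdeg")
  if (!all(need %in% names(df)))
    stop("CD CSV must have columns: ", paste(need, collapse = ", "))
  CdSpectrum(df$wavelength_nm, df$ellipticity_mdeg, concuM, nResidues, pathCm)
}

#' Reference data: the C-terminal tail series
#'
#' Literature-reported characterization of the azide-template tail series
#' (template core with C-terminal extensions of varying helical propensity):
#' binding Kd, cellular EC50s under both serum conditions, the reported
#' aqueous-helicity and solubility values, and the published tail
#' helical-propensity class. Tails are given as space-separated registry
#' codes. Used as the fixture for the tail-propensity classifier.
#'
#' @return data.frame, one row per peptide.
#' @export
tailSeriesData <- function() {
  utils::read.csv(system.file("extdata", "tail_series.csv",
                              package = "stapleSAR"),
                  stringsAsFactors = FALSE, colClasses = "character")
}

#' Reference data: worked-example assay values
#'
#' Literature-reported potencies for the peptides used in the worked
#' examples of the derived indices (cell ratio, serum shift, on-target
#' index, fold improvement): the azide template MP-081, the di-Phe tail
#' variant MP-040, the optimized di-alkyne peptide MP-467, and the all-D
#' series parent MP-769 with its optimized descendant MP-042. Censored
#' entries use the ">"/">>" encoding.
#'
#' @return data.frame, one row per peptide.
#' @export
workedExamplesData <- function() {
  utils::read.csv(system.file("extdata", "worked_examples.csv",
                              package = "stapleSAR"),
                  stringsAsFactors = FALSE, colClasses = "character")
}
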