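#' Annotate a peptide library with derived sequence and SAR metrics
#'
#' For each record, parses the sequence notation (when present) to add net
#' charge, tail helical-propensity class and hydrophobic moment, and
#' combines the assay columns into the derived indices: cell ratio
#' (cellular EC50 / binding Kd), serum shift (10\% / 0\% serum EC50) and
#' on-target index (off-target / on-target proliferation EC50), each with
#' censor propagation. Per-row failures (unparseable sequence, censored
#' denominators, missing values) are collected into an \code{errors}
#' attribute-style column, never fatal, and the affected derived cells are
#' left \code{NA}.
#'
#' @param table a [LibraryTable-class] object.
#' @return A [LibraryTable-class] with added columns \code{net_charge},
#'   \code{tail_class}, \code{moment}, \code{cell_ratio},
#'   \code{serum_shift}, \code{on_target_index}, \code{row_error}.
#' @export
annotateLibrary <- function(table) {
  stopifnot(is(table, "LibraryTable"))
  df <- table@data
  n <- nrow(df)
  out <- data.frame(net_charge = rep(NA_integer_, n),
                    tail_class = rep(NA_character_, n),
                    moment = rep(NA_real_, n),
                    cell_ratio = rep(NA_character_, n),
                    serum_shift = rep(NA_character_, n),
                    on_target_index = rep(NA_character_, n),
                    row_error = rep("", n), stringsAsFactors = FALSE)
  addErr <- function(i, e) {
    msg <- conditionMessage(e)
    out$row_error[i] <<- if (nzchar(out$row_error[i]))
      paste(out$row_error[i], msg, sep = "; ") else msg
  }
  getc <- function(i, col) {
    if (!col %in% names(df)) return(Censored(NA_real_))
    parseCensored(df[[col]][i])
  }
  for (i in seq_len(n)) {
    if ("sequence" %in% names(df) && nzchar(df$sequence[i]) &&
        !is.na(df$sequence[i])) {
      tryCatch({
        p <- parsePeptide(df$sequence[i], name = df$name[i])
        out$net_charge[i] <- netCharge(p)
        out$moment[i] <- hydrophobicMoment(p)
        tl <- tailResidues(p)
        if (length(tl)) out$tail_class[i] <- classifyTailPropensity(tl)
      }, error = function(e) addErr(i, e))
    }
    tryCatch({
      cr <- cellRatio(getc(i, "cell_ec50_0pct_uM"), getc(i, "kd_nM"))
      out$cell_ratio[i] <- formatCensored(cr)
    }, error = function(e) addErr(i, e))
    tryCatch({
      ss <- serumShift(getc(i, "cell_ec50_10pct_uM"),
                       getc(i, "cell_ec50_0pct_uM"))
      out$serum_shift[i] <- formatCensored(ss)
    }, error = function(e) addErr(i, e))
    tryCatch({
      oi <- onTargetIndex(getc(i, "prolif_off_uM"), getc(i, "prolif_on_uM"))
      out$on_target_index[i] <- formatCensored(oi)
    }, error = function(e) addErr(i, e))
  }
  LibraryTable(cbind(df, out),
               log = c(table@log, sprintf("annotate: %d records, %d row errors",
                                          n, sum(nzchar(out$row_error)))))
}

#' Fit a binding curve from a titration CSV and report
#'
#' Thin orchestration over [readTitrationCsv()] and [fitDirect()] /
#' [fitCompetition()]: reads the file, fits, and returns (optionally
#' writes) a machine-readable report with the estimate, standard error,
#' endpoints and QC flags.
#'
#' @inheritParams readTitrationCsv
#' @param outJson optional path; when given the report is written as JSON.
#' @return report list (invisibly when \code{outJson} is written).
#' @export
fitBindingFile <- function(path, mode = NULL, Lst = NULL, Pt = NULL,
                           Kd1 = NULL, sidecar = NULL, outJson = NULL) {
  curve <- readTitrationCsv(path, mode, Lst, Pt, Kd1, sidecar)
  fit <- if (curve@mode == "direct") fitDirect(curve) else fitCompetition(curve)
  rep <- list(input = path, mode = curve@mode, n_points = length(curve@x),
              estimate_nM = fit@estimate, se_nM = fit@se,
              r0 = fit@r0, rb = fit@rb, converged = fit@converged,
              qc_flags = fit@qcFlags)
  if (!is.null(outJson)) {
    jsonlite::write_json(rep, outJson, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}

#' Annotate a library CSV and write derived metrics plus a JSON summary
#'
#' Orchestrates [readLibraryCsv()], [annotateLibrary()], [filterLibrary()]
#' and [correlateLibrary()]: writes the annotated table as tidy CSV and a
#' summary JSON with record counts, the filter log and the
#' lipophilicity/permeability correlation (LogD vs log10 cell ratio over
#' the filtered records) when the needed columns are present.
#'
#' @param path input library CSV.
#' @param outCsv optional output CSV path for the annotated table.
#' @param outJson optional output path for the summary JSON.
#' @return list with the annotated [LibraryTable-class] and the summary.
#' @export
annotateLibraryFile <- function(path, outCsv = NULL, outJson = NULL) {
  tab <- readLibraryCsv(path)
  if (nrow(tab@data) == 0L) {
    warning("empty library table")
    summary <- list(n_records = 0L)
    ann <- tab
  } else {
    ann <- annotateLibrary(tab)
    summary <- list(n_records = nrow(ann@data),
                    n_row_errors = sum(nzchar(ann@data$row_error)))
    haveFilterCols <- all(c("kd_nM", "cell_ec50_0pct_uM",
                            "counterscreen_ec50_uM", "ldh_ec50_uM") %in%
                          names(tab@data))
    if (haveFilterCols) {
      filt <- filterLibrary(tab)
      summary$filter_log <- filt@log
      summary$n_filtered <- nrow(filt@data)
      if ("logd" %in% names(filt@data) && nrow(filt@data) >= 3) {
        filtAnn <- annotateLibrary(filt)
        co <- tryCatch(correlateLibrary(filtAnn, "logd", "cell_ratio",
                                        logY = TRUE),
                       error = function(e) NULL)
        if (!is.null(co)) summary$logd_cell_ratio_correlation <- co
      }
    }
  }
  if (!is.null(outCsv)) writeLibraryCsv(ann, outCsv)
  if (!is.null(outJson))
    jsonlite::write_json(summary, outJson, auto_unbox = TRUE, digits = NA)
  list(table = ann, summary = summary)
}

#' Helical-wheel table for a sequence notation
#'
#' @param notation extended peptide notation (see [parsePeptide()]).
#' @return data.frame as from [helicalWheel()], plus the hydrophobic moment
#'   as an attribute \code{"moment"}.
#' @export
wheelTable <- function(notation) {
  p <- parsePeptide(notation)
  w <- helicalWheel(p)
  attr(w, "moment") <- hydrophobicMoment(p)
  w
}
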