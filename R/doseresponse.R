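#' Control-based normalization of a raw assay signal
#'
#' Percent activity relative to plate controls:
#' \code{100 * (raw - min_control) / (max_control - min_control)}.
#' The conventions of the cellular assays: the p53 reporter is normalized to
#' the activity induced by a saturating concentration of the template
#' peptide, LDH release to a lytic-peptide control, and the counterscreen to
#' the tetracycline-induced signal. Values above 100\% are legal (a compound
#' can exceed the control, e.g. 277\% counterscreen efficacy).
#'
#' @param raw raw signal (vectorized).
#' @param maxControl,minControl raw control signals; must differ.
#' @return percent activity.
#' @export
normalizeResponse <- function(raw, maxControl, minControl) {
  if (!is.finite(maxControl) || !is.finite(minControl) ||
      maxControl == minControl)
    stop("degenerate controls: max and min control signals must differ")
  100 * (raw - minControl) / (maxControl - minControl)
}

#' Construct a dose-response curve
#'
#' @param conc concentrations in uM, strictly increasing.
#' @param response normalized percent activity (or raw signal together with
#'   \code{maxControl}/\code{minControl}, which triggers normalization).
#' @param assay assay type.
#' @param maxControl,minControl optional raw control signals.
#' @param truth simulator ground truth (internal).
#' @return A [DoseResponseCurve-class] object.
#' @export
DoseResponseCurve <- function(conc, response,
                              assay = c("p53_reporter", "LDH",
                                        "counterscreen", "proliferation"),
                              maxControl = NA_real_, minControl = NA_real_,
                              truth = list()) {
  assay <- match.arg(assay)
  if (!is.na(maxControl) && !is.na(minControl))
    response <- normalizeResponse(response, maxControl, minControl)
  new("DoseResponseCurve", conc = as.numeric(conc),
      response = as.numeric(response), assay = assay,
      maxControl = maxControl, minControl = minControl, truth = truth)
}

setMethod("show", "DoseResponseCurve", function(object) {
  cat("DoseResponseCurve (", object@assay, "), ", length(object@conc),
      " points, ", signif(min(object@conc), 3), "-",
      signif(max(object@conc), 3), " uM\n", sep = "")
})

.fourPL <- function(conc, ec50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Four-parameter logistic EC50 fit with censoring at the assay ceiling
#'
#' Fits \code{response = bottom + (top - bottom) / (1 + (EC50/conc)^hill)}
#' by Levenberg-Marquardt least squares with \code{log10(EC50)}
#' parameterized. Defaults mirror the assay reporting conventions: bottom
#' fixed at 0\% and top free (reporter efficacy can exceed 100\%);
#' proliferation curves are fitted with the top fixed at 100\% inhibition.
#' When the response never crosses half of the fitted top within the tested
#' range (or the fitted EC50 lies above it), the EC50 is reported censored
#' \code{">"} at the highest tested concentration; the efficacy at the top
#' tested concentration is reported either way.
#'
#' @param curve a [DoseResponseCurve-class] object with >= 5 concentrations.
#' @param topConstraint optional fixed top (percent).
#' @return An [Ec50Fit-class] object.
#' @export
fitEc50 <- function(curve, topConstraint = NULL) {
  stopifnot(is(curve, "DoseResponseCurve"))
  conc <- curve@conc; resp <- curve@response
  if (length(conc) < 5L) stop("need at least 5 concentrations")
  fixTop <- !is.null(topConstraint) ||
    curve@assay == "proliferation"
  topFix <- if (!is.null(topConstraint)) topConstraint else 100
  maxConc <- max(conc)

  start <- c(l10 = log10(stats::median(conc)), hill = 1)
  if (!fixTop) start <- c(start, top = max(resp, 1))
  resFun <- function(p) {
    top <- if (fixTop) topFix else p[["top"]]
    resp - .fourPL(conc, 10^p[["l10"]], p[["hill"]], top, 0)
  }
  fit <- try(minpack.lm::nls.lm(par = start, fn = resFun,
             control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  failed <- inherits(fit, "try-error") || !fit$info %in% 1:4
  if (failed) {
    return(new("Ec50Fit", ec50 = Censored(maxConc, "gt", "uM"),
               hill = NA_real_, efficacy = max(resp[conc == maxConc]),
               converged = FALSE, details = list(reason = "fit failed")))
  }
  p <- fit$par
  ec50 <- 10^p[["l10"]]
  top <- if (fixTop) topFix else p[["top"]]
  effTop <- .fourPL(maxConc, ec50, p[["hill"]], top, 0)
  crosses <- max(resp) >= 0.5 * top && top > 0
  # a fitted maximal effect below 20% activity cannot support a potency
  # claim; report the ceiling as a bound instead of a spurious midpoint
  cens <- !crosses || ec50 > maxConc || top < 20
  new("Ec50Fit",
      ec50 = if (cens) Censored(maxConc, "gt", "uM")
             else Censored(ec50, "none", "uM"),
      hill = unname(p[["hill"]]), efficacy = unname(effTop),
      converged = TRUE,
      details = list(top = unname(top), deviance = fit$deviance,
                     uncensored_ec50 = unname(ec50)))
}

setMethod("show", "Ec50Fit", function(object) {
  cat("Ec50Fit:", formatCensored(object@ec50),
      "| hill", signif(object@hill, 3),
      "| efficacy", signif(object@efficacy, 3), "%",
      "| converged:", object@converged, "\n")
})

#' @describeIn fitEc50 EC50 accessor ([Censored-class]).
#' @param object an [Ec50Fit-class] object.
#' @export
ec50 <- function(object) object@ec50

#' Stability half-life from a percent-remaining time course
#'
#' Log-linear least squares of \code{ln(percent remaining)} against time;
#' \eqn{t_{1/2} = \ln 2 / k} with \eqn{k} the fitted decay rate. Chosen over
#' a nonlinear exponential fit for robustness at the 4-5 time points of the
#' whole-cell-homogenate and plasma stability assays. When the decay is not
#' significant (slope p > \code{alpha}, or positive slope), the half-life is
#' censored \code{">"} the last time point, matching the reporting of stable
#' compounds (e.g. a parent with half-life beyond the assay window).
#'
#' @param timepoints hours; the first must be 0.
#' @param pctRemaining percent remaining, normalized to 100 at time 0;
#'   strictly positive.
#' @param alpha significance threshold for "no decay" (default 0.05).
#' @return A [Censored-class] half-life in hours.
#' @export
halfLife <- function(timepoints, pctRemaining, alpha = 0.05) {
  if (length(timepoints) != length(pctRemaining) || length(timepoints) < 3L)
    stop("need at least 3 matched time points")
  if (timepoints[1] != 0) stop("first time point must be 0 h")
  if (abs(pctRemaining[1] - 100) > 1e-6)
    stop("percent remaining must be normalized to 100 at time 0")
  if (any(pctRemaining <= 0)) stop("non-positive percent remaining")
  fit <- stats::lm(log(pctRemaining) ~ timepoints)
  slope <- stats::coef(fit)[["timepoints"]]
  if (slope >= 0) return(Censored(max(timepoints), "gt", "h"))
  pval <- suppressWarnings(
    stats::coef(summary(fit))["timepoints", "Pr(>|t|)"])
  if (is.na(pval) || pval > alpha)
    return(Censored(max(timepoints), "gt", "h"))
  Censored(log(2) / (-slope), "none", "h")
}
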