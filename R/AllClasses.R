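#' @import methods
NULL

#' Censored assay value
#'
#' A scalar assay readout that may be a bound rather than a point estimate.
#' Dose-response and binding tables routinely contain entries such as
#' \code{">50"} (potency weaker than the highest tested concentration) or
#' \code{">>50"} (no measurable activity at the ceiling); ratios built from
#' such values must carry the bound along rather than silently treating the
#' ceiling as an estimate.
#'
#' @slot value numeric(1); the point estimate, or the censoring limit when
#'   \code{bound != "none"}.
#' @slot bound one of \code{"none"}, \code{"gt"} (greater than), \code{"ggt"}
#'   (much greater than; arithmetic treats it as \code{"gt"}, display keeps
#'   the distinct glyph), \code{"lt"} (less than).
#' @slot units free-text unit label (e.g. \code{"uM"}, \code{"nM"}).
#'
#' @seealso [parseCensored()], [censoredRatio()]
#' @export
setClass("Censored",
  representation(value = "numeric", bound = "character", units = "character"),
  prototype(value = NA_real_, bound = "none", units = ""))

setValidity("Censored", function(object) {
  if (length(object@value) != 1L) return("value must be a scalar")
  if (length(object@bound) != 1L ||
      !object@bound %in% c("none", "gt", "ggt", "lt"))
    return("bound must be one of none/gt/ggt/lt")
  TRUE
})

#' Stapled peptide
#'
#' An ordered residue sequence with explicit terminal caps and zero or more
#' covalent side-chain crosslinks (staples). Residue codes index into the
#' residue property registry (see [residueRegistry()]); non-natural residues
#' use multi-character codes (\code{R8}, \code{S5}, \code{Cba}, \code{Gla},
#' ...), D-enantiomers are prefixed \code{d}.
#'
#' @slot name peptide identifier.
#' @slot residues character vector of registry codes, N- to C-terminal.
#' @slot nTermCap \code{"acetyl"} or \code{"free"}.
#' @slot cTermCap \code{"amide"} or \code{"free_acid"}.
#' @slot staples data.frame with columns \code{pos1}, \code{pos2},
#'   \code{chemistry} (\code{olefin_i4}, \code{olefin_i7}, \code{dialkyne},
#'   \code{lactam}, \code{triazole}) and \code{span}.
#'
#' @seealso [parsePeptide()], [netCharge()], [helicalWheel()]
#' @export
setClass("Peptide",
  representation(name = "character", residues = "character",
                 nTermCap = "character", cTermCap = "character",
                 staples = "data.frame"),
  prototype(name = "", nTermCap = "acetyl", cTermCap = "amide",
            staples = data.frame(pos1 = integer(), pos2 = integer(),
                                 chemistry = character(), span = integer())))

.stapleSpans <- c(olefin_i4 = 4L, olefin_i7 = 7L, dialkyne = 7L,
                  lactam = 4L, triazole = 7L)

setValidity("Peptide", function(object) {
  n <- length(object@residues)
  if (n < 1L) return("peptide must contain at least one residue")
  reg <- residueRegistry()
  bad <- setdiff(object@residues, reg$code)
  if (length(bad))
    return(paste0("unknown residue token(s): ", paste(bad, collapse = ", ")))
  if (!object@nTermCap %in% c("acetyl", "free"))
    return("nTermCap must be 'acetyl' or 'free'")
  if (!object@cTermCap %in% c("amide", "free_acid"))
    return("cTermCap must be 'amide' or 'free_acid'")
  st <- object@staples
  if (nrow(st)) {
    if (!all(c("pos1", "pos2", "chemistry", "span") %in% names(st)))
      return("staples must have columns pos1, pos2, chemistry, span")
    if (any(st$pos1 < 1L | st$pos2 > n | st$pos1 >= st$pos2))
      return("staple positions must reference valid residue indices")
    if (any(st$span != st$pos2 - st$pos1))
      return("staple span must equal the difference of its positions")
    if (!all(st$chemistry %in% names(.stapleSpans)))
      return("unknown staple chemistry")
    if (any(st$span != .stapleSpans[st$chemistry]))
      return(paste0("staple span inconsistent with chemistry (expected i,i+",
                    paste(.stapleSpans[st$chemistry], collapse = "/"), ")"))
  }
  TRUE
})

#' Fluorescence-anisotropy titration curve
#'
#' A concentration series of measured anisotropy values, either a direct
#' titration (protein titrated against a fixed concentration of fluorescently
#' labeled probe) or a competition titration (unlabeled ligand titrated
#' against a preformed protein/probe complex).
#'
#' @slot x titrant concentrations in nM (protein for \code{mode = "direct"},
#'   total competitor for \code{mode = "competition"}).
#' @slot r measured anisotropy values (unitless).
#' @slot mode \code{"direct"} or \code{"competition"}.
#' @slot r0,rb anisotropy endpoints (free probe / saturated complex); may be
#'   \code{NA} when they are to be fitted.
#' @slot config named list of assay constants: \code{Lst} (total labeled
#'   probe, nM) and, for competition curves, \code{Pt} (total protein, nM)
#'   and \code{Kd1} (probe dissociation constant, nM).
#' @slot truth named list of simulator ground truth (empty for real data);
#'   no fitting routine reads it.
#'
#' @export
setClass("TitrationCurve",
  representation(x = "numeric", r = "numeric", mode = "character",
                 r0 = "numeric", rb = "numeric", config = "list",
                 truth = "list"),
  prototype(r0 = NA_real_, rb = NA_real_, config = list(), truth = list()))

setValidity("TitrationCurve", function(object) {
  if (length(object@x) != length(object@r))
    return("x and r must have equal length")
  if (any(object@x < 0)) return("concentrations must be non-negative")
  if (is.unsorted(object@x)) return("x must be non-decreasing")
  if (!object@mode %in% c("direct", "competition"))
    return("mode must be 'direct' or 'competition'")
  if (object@mode == "competition" &&
      !all(c("Lst", "Pt", "Kd1") %in% names(object@config)))
    return("competition curves need config entries Lst, Pt, Kd1")
  if (object@mode == "competition" &&
      object@config$Pt <= object@config$Lst)
    return("competition model assumes Pt > Lst")
  TRUE
})

#' Nonlinear fit result
#'
#' @slot estimate fitted dissociation constant (nM) or EC50 (assay units).
#' @slot se approximate standard error of the estimate (delta method from the
#'   log-scale fit).
#' @slot r0,rb fitted or fixed anisotropy endpoints (binding fits).
#' @slot residualNorm residual sum of squares at the optimum.
#' @slot converged logical convergence flag.
#' @slot qcFlags character vector of curve-validity flags (see
#'   [validateCurve()]).
#' @slot model \code{"direct"} or \code{"competition"}.
#' @slot details list with fitter diagnostics.
#'
#' @export
setClass("FitResult",
  representation(estimate = "numeric", se = "numeric", r0 = "numeric",
                 rb = "numeric", residualNorm = "numeric",
                 converged = "logical", qcFlags = "character",
                 model = "character", details = "list"),
  prototype(se = NA_real_, r0 = NA_real_, rb = NA_real_,
            residualNorm = NA_real_, converged = FALSE,
            qcFlags = character(), details = list()))

#' Dose-response curve
#'
#' Normalized percent-activity readings over a concentration series from a
#' cell-based assay.
#'
#' @slot conc compound concentrations in uM, strictly increasing.
#' @slot response normalized percent activity (may exceed 100).
#' @slot assay one of \code{"p53_reporter"}, \code{"LDH"},
#'   \code{"counterscreen"}, \code{"proliferation"}.
#' @slot maxControl,minControl raw control signals used for normalization
#'   (may be \code{NA} when the curve is already normalized).
#' @slot truth simulator ground truth (empty for real data).
#'
#' @export
setClass("DoseResponseCurve",
  representation(conc = "numeric", response = "numeric", assay = "character",
                 maxControl = "numeric", minControl = "numeric",
                 truth = "list"),
  prototype(assay = "p53_reporter", maxControl = NA_real_,
            minControl = NA_real_, truth = list()))

setValidity("DoseResponseCurve", function(object) {
  if (length(object@conc) != length(object@response))
    return("conc and response must have equal length")
  if (any(object@conc <= 0)) return("concentrations must be positive")
  if (is.unsorted(object@conc, strictly = TRUE))
    return("conc must be strictly increasing")
  if (any(!is.finite(object@response)))
    return("responses must be finite")
  if (!object@assay %in% c("p53_reporter", "LDH", "counterscreen",
                           "proliferation"))
    return("unknown assay type")
  TRUE
})

#' Four-parameter logistic EC50 fit
#'
#' @slot ec50 [Censored-class] potency in uM; censored \code{">"} the highest
#'   tested concentration when the response never crosses half of the fitted
#'   top within the tested range.
#' @slot hill Hill slope.
#' @slot efficacy fitted percent activity at the highest tested
#'   concentration (reported even when the EC50 is censored).
#' @slot converged logical.
#' @slot details fitter diagnostics.
#'
#' @export
setClass("Ec50Fit",
  representation(ec50 = "Censored", hill = "numeric", efficacy = "numeric",
                 converged = "logical", details = "list"),
  prototype(hill = NA_real_, efficacy = NA_real_, converged = FALSE,
            details = list()))

#' Circular-dichroism spectrum
#'
#' @slot wavelength wavelengths in nm, strictly monotone.
#' @slot ellipticity measured ellipticity in millidegrees.
#' @slot concuM peptide concentration in uM.
#' @slot nResidues number of residues.
#' @slot pathCm cuvette path length in cm.
#' @slot truth simulator ground truth (empty for real data).
#'
#' @export
setClass("CdSpectrum",
  representation(wavelength = "numeric", ellipticity = "numeric",
                 concuM = "numeric", nResidues = "integer",
                 pathCm = "numeric", truth = "list"),
  prototype(truth = list()))

setValidity("CdSpectrum", function(object) {
  if (length(object@wavelength) != length(object@ellipticity))
    return("wavelength and ellipticity must have equal length")
  d <- diff(object@wavelength)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    return("wavelengths must be strictly monotone")
  if (object@concuM <= 0 || object@pathCm <= 0 || object@nResidues <= 0)
    return("concentration, path length and residue count must be positive")
  TRUE
})

#' Peptide library table
#'
#' One row per peptide with its sequence notation and assay readouts.
#' Potency-like columns are stored as character so that censored entries
#' (\code{">50"}, \code{">>50"}, \code{"<1"}) survive round trips; use
#' [parseCensored()] to interpret an entry. The filter log is append-only
#' provenance: every filtering operation records its before/after counts.
#'
#' @slot data data.frame, one row per peptide; \code{name} must be unique.
#' @slot log character vector of provenance lines.
#'
#' @seealso [readLibraryCsv()], [filterLibrary()], [annotateLibrary()]
#' @export
setClass("LibraryTable",
  representation(data = "data.frame", log = "character"),
  prototype(log = character()))

setValidity("LibraryTable", function(object) {
  if (!"name" %in% names(object@data))
    return("library table needs a 'name' column")
  if (anyDuplicated(object@data$name))
    return("peptide names must be unique")
  TRUE
})
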