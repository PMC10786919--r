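#' Construct a censored value
#'
#' @param value numeric scalar; the estimate, or the censoring limit.
#' @param bound "none", "gt", "ggt" or "lt".
#' @param units unit label.
#' @return A [Censored-class] object.
#' @examples
#' Censored(50, "gt", "uM")   # reported as ">50 uM"
#' @export
Censored <- function(value, bound = "none", units = "") {
  new("Censored", value = as.numeric(value), bound = bound, units = units)
}

#' Parse a censored table entry
#'
#' Interprets the encodings used in library CSVs: \code{">50"} and
#' \code{"> 50"} (greater than), \code{">>50"} (much greater than),
#' \code{"<1"} (less than), plain numbers, and \code{""}/\code{"NA"}/
#' \code{"N.D."}/\code{"P.B."} (missing).
#'
#' @param x character or numeric scalar.
#' @param units unit label attached to the result.
#' @return A [Censored-class] object (value \code{NA} when missing).
#' @export
parseCensored <- function(x, units = "") {
  if (is(x, "Censored")) return(x)
  if (is.numeric(x)) return(Censored(x, "none", units))
  s <- trimws(as.character(x))
  if (!length(s) || is.na(s) || s %in% c("", "NA", "N.D.", "ND", "P.B.", "PB"))
    return(Censored(NA_real_, "none", units))
  bound <- "none"
  if (startsWith(s, ">>")) { bound <- "ggt"; s <- substring(s, 3) }
  else if (startsWith(s, ">")) { bound <- "gt"; s <- substring(s, 2) }
  else if (startsWith(s, "<")) { bound <- "lt"; s <- substring(s, 2) }
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (is.na(v)) stop("cannot parse censored value: '", x, "'")
  Censored(v, bound, units)
}

#' @describeIn parseCensored coerce anything censored-like to [Censored-class].
#' @export
asCensored <- function(x, units = "") parseCensored(x, units)

#' Format a censored value for display
#'
#' @param x a [Censored-class] object.
#' @param digits significant digits.
#' @return character scalar such as \code{">50 uM"}.
#' @export
formatCensored <- function(x, digits = 4) {
  if (is.na(x@value)) return(NA_character_)
  glyph <- c(none = "", gt = ">", ggt = ">>", lt = "<")[x@bound]
  paste0(glyph, signif(x@value, digits),
         if (nzchar(x@units)) paste0(" ", x@units) else "")
}

setMethod("show", "Censored", function(object) {
  cat("Censored value:", formatCensored(object), "\n")
})

#' @describeIn formatCensored TRUE when the value is a bound, not an estimate.
#' @export
isCensored <- function(x) x@bound != "none"

#' Extract the numeric value of a censored quantity
#'
#' @param x a [Censored-class] object.
#' @return numeric scalar (the estimate or the censoring limit).
#' @export
censoredValue <- function(x) x@value

#' @describeIn censoredValue the bound flag ("none"/"gt"/"ggt"/"lt").
#' @export
censoredBound <- function(x) x@bound

.effBound <- function(b) if (b == "ggt") "gt" else b

#' Scale a censored value by a positive factor
#'
#' Unit harmonization helper: multiplying preserves the bound direction.
#'
#' @param x a [Censored-class] object.
#' @param k positive scalar.
#' @param units unit label of the result.
#' @return A [Censored-class] object.
#' @export
censoredScale <- function(x, k, units = x@units) {
  stopifnot(k > 0)
  Censored(x@value * k, x@bound, units)
}

#' Ratio of two possibly censored values with bound propagation
#'
#' Computes \code{numerator/denominator}. A \code{">"} (or \code{">>"})
#' numerator yields a \code{">"} ratio; a \code{"<"} numerator yields a
#' \code{"<"} ratio. A censored denominator is an error: a bound in the
#' denominator cannot produce a one-sided bound of known direction on the
#' scale the library indices are interpreted on.
#'
#' @param num,den [Censored-class] objects (or values coercible via
#'   [parseCensored()]), already in the same units.
#' @param units unit label of the ratio (default unitless).
#' @return A [Censored-class] ratio.
#' @export
censoredRatio <- function(num, den, units = "") {
  num <- asCensored(num); den <- asCensored(den)
  if (is.na(num@value) || is.na(den@value))
    stop("both numerator and denominator must be present")
  if (isCensored(den))
    stop("censored denominator (", formatCensored(den),
         "): ratio bound direction undefined")
  if (den@value == 0) stop("zero denominator")
  Censored(num@value / den@value, .effBound(num@bound), units)
}
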