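#' Construct a CD spectrum
#'
#' @param wavelength wavelengths in nm.
#' @param ellipticity ellipticity in millidegrees.
#' @param concuM peptide concentration (uM).
#' @param nResidues number of residues.
#' @param pathCm cuvette path length (cm).
#' @param truth simulator ground truth (internal).
#' @return A [CdSpectrum-class] object.
#' @export
CdSpectrum <- function(wavelength, ellipticity, concuM, nResidues,
                       pathCm = 0.2, truth = list()) {
  new("CdSpectrum", wavelength = as.numeric(wavelength),
      ellipticity = as.numeric(ellipticity), concuM = concuM,
      nResidues = as.integer(nResidues), pathCm = pathCm, truth = truth)
}

setMethod("show", "CdSpectrum", function(object) {
  cat("CdSpectrum:", length(object@wavelength), "points,",
      min(object@wavelength), "-", max(object@wavelength), "nm;",
      object@concuM, "uM,", object@nResidues, "residues,",
      object@pathCm, "cm path\n")
})

#' Mean residue ellipticity
#'
#' Converts measured ellipticity (millidegrees) to mean residue ellipticity
#' in deg cm^2 dmol^-1:
#' \deqn{MRE(\lambda) = \theta_{mdeg}(\lambda) / (10 \, l \, C \, n_b)}
#' with \eqn{l} the path length in cm, \eqn{C} the molar peptide
#' concentration and \eqn{n_b} the number of chromophores, by default the
#' peptide-bond count \eqn{n - 1} (switchable to \eqn{n}).
#'
#' @param spectrum a [CdSpectrum-class] object.
#' @param bonds \code{"n_minus_1"} (default) or \code{"n"}.
#' @return data.frame with columns \code{wavelength} and \code{mre}.
#' @export
meanResidueEllipticity <- function(spectrum, bonds = c("n_minus_1", "n")) {
  bonds <- match.arg(bonds)
  nb <- if (bonds == "n_minus_1") spectrum@nResidues - 1L else spectrum@nResidues
  if (nb < 1L) stop("need at least 2 residues for the n-1 convention")
  molar <- spectrum@concuM * 1e-6
  data.frame(wavelength = spectrum@wavelength,
             mre = spectrum@ellipticity / (10 * spectrum@pathCm * molar * nb))
}

#' @describeIn meanResidueEllipticity MRE interpolated at one wavelength
#'   (default 222 nm).
#' @param wavelength query wavelength in nm.
#' @export
mreAt <- function(spectrum, wavelength = 222, bonds = c("n_minus_1", "n")) {
  m <- meanResidueEllipticity(spectrum, bonds)
  if (wavelength < min(m$wavelength) || wavelength > max(m$wavelength))
    stop("wavelength outside the recorded range")
  stats::approx(m$wavelength, m$mre, xout = wavelength)$y
}

.thetaHelix <- function(n, thetaHelixInf = -40000, wing = 2.5)
  thetaHelixInf * (1 - wing / n)

#' Fraction helix from the 222 nm band
#'
#' Single-wavelength helix estimator: with reference values
#' \eqn{\theta_{helix}(n) = -40000 (1 - 2.5/n)} (chain-length-corrected
#' fully helical limit) and \eqn{\theta_{coil} = +640} deg cm^2 dmol^-1,
#' \deqn{f_H = \frac{MRE_{222} - \theta_{coil}}
#'                  {\theta_{helix}(n) - \theta_{coil}}}
#' clamped to [0, 100]\%. Monotone: a more negative 222 nm band means more
#' helix. Alternative reference constants can be supplied.
#'
#' @param mre222 mean residue ellipticity at 222 nm (deg cm^2 dmol^-1), or a
#'   [CdSpectrum-class] object (then extracted via [mreAt()]).
#' @param nResidues number of residues (>= 4).
#' @param thetaCoil,thetaHelixInf,wing reference constants.
#' @return percent helix in [0, 100].
#' @export
fractionHelix <- function(mre222, nResidues, thetaCoil = 640,
                          thetaHelixInf = -40000, wing = 2.5) {
  if (is(mre222, "CdSpectrum")) {
    nResidues <- mre222@nResidues
    mre222 <- mreAt(mre222, 222)
  }
  if (nResidues < 4L) stop("helix estimator needs >= 4 residues")
  th <- .thetaHelix(nResidues, thetaHelixInf, wing)
  fh <- (mre222 - thetaCoil) / (th - thetaCoil)
  100 * pmin(pmax(fh, 0), 1)
}
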