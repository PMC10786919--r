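#' Direct 1:1 binding anisotropy model
#'
#' Exact (depletion-corrected) anisotropy of a fluorescent probe titrated
#' with protein under a single-site 1:1 model:
#' \deqn{r = r_0 + (r_b - r_0)\frac{(K_d + L_t + P_t) -
#'   \sqrt{(K_d + L_t + P_t)^2 - 4 L_t P_t}}{2 L_t}}
#' where \eqn{L_t} is the total probe and \eqn{P_t} the total protein
#' concentration. The output lies in \eqn{[r_0, r_b]} and is non-decreasing
#' in \eqn{P_t}.
#'
#' @param Kd dissociation constant (nM), > 0.
#' @param Lt total labeled probe (nM), > 0.
#' @param Pt total protein (nM), >= 0; may be a vector.
#' @param r0,rb anisotropy of free probe / saturated complex.
#' @return anisotropy value(s), same length as \code{Pt}.
#' @export
directAnisotropy <- function(Kd, Lt, Pt, r0, rb) {
  if (Kd <= 0 || Lt <= 0 || any(Pt < 0)) stop("Kd, Lt must be > 0; Pt >= 0")
  s <- Kd + Lt + Pt
  disc <- pmax(s^2 - 4 * Lt * Pt, 0)
  fb <- (s - sqrt(disc)) / (2 * Lt)
  r0 + (rb - r0) * pmin(pmax(fb, 0), 1)
}

#' Probe fraction bound in the ternary competition equilibrium (closed form)
#'
#' Exact solution of the coupled equilibria P + L* <-> PL* (probe,
#' \eqn{K_{d1}}) and P + L <-> PL (competitor, \eqn{K_{d2}}). Free protein
#' is the relevant real root of the cubic
#' \eqn{p^3 + d p^2 + e p + f = 0} with
#' \deqn{d = K_{d1} + K_{d2} + L_{st} + L_t - P_t}
#' \deqn{e = K_{d1}(L_t - P_t) + K_{d2}(L_{st} - P_t) + K_{d1} K_{d2}}
#' \deqn{f = -K_{d1} K_{d2} P_t}
#' obtained trigonometrically as
#' \eqn{p = (2\sqrt{d^2 - 3e}\cos(\theta/3) - d)/3} with
#' \eqn{\theta = \arccos[(-2d^3 + 9de - 27f) / (2\sqrt{(d^2-3e)^3})]},
#' then polished with two Newton steps on the same cubic (the trigonometric
#' form loses relative precision through cancellation when the bound
#' fraction is very small). The probe fraction bound is
#' \eqn{p / (K_{d1} + p)}.
#'
#' @param Kd2 competitor dissociation constant (nM), > 0.
#' @param Lt total competitor (nM), >= 0; may be a vector.
#' @param Lst total labeled probe (nM).
#' @param Pt total protein (nM); the model assumes \code{Pt > Lst}.
#' @param Kd1 probe dissociation constant (nM).
#' @return probe fraction bound in [0, 1], same length as \code{Lt}.
#' @seealso [solveEquilibriumNumeric()] for the independent mass-balance
#'   oracle this closed form is certified against.
#' @export
probeFractionBound <- function(Kd2, Lt, Lst, Pt, Kd1) {
  if (Kd1 <= 0 || Kd2 <= 0) stop("dissociation constants must be positive")
  if (Lst < 0 || Pt < 0 || any(Lt < 0)) stop("concentrations must be non-negative")
  vapply(Lt, function(lt) {
    if (Pt == 0) return(0)
    d <- Kd1 + Kd2 + Lst + lt - Pt
    e <- Kd1 * (lt - Pt) + Kd2 * (Lst - Pt) + Kd1 * Kd2
    f <- -Kd1 * Kd2 * Pt
    q <- d^2 - 3 * e
    if (q <= 0) stop("invalid parameter regime: d^2 - 3e <= 0")
    s <- sqrt(q)
    arg <- (-2 * d^3 + 9 * d * e - 27 * f) / (2 * s^3)
    if (arg > 1 || arg < -1) {
      if (abs(arg) - 1 > 1e-9)
        stop("arccos argument ", arg, " outside [-1, 1]: invalid regime")
      arg <- max(min(arg, 1), -1)
    }
    p <- (2 * s * cos(acos(arg) / 3) - d) / 3
    # Polish the analytic root on the cubic itself. The physical root (free
    # protein) lies in [0, Pt]: g(0) = f < 0 and g(Pt) > 0, so Newton steps
    # are safeguarded by bisection on that bracket, which also rescues the
    # trigonometric form in regimes where cancellation degrades it.
    cubic <- function(p) ((p + d) * p + e) * p + f
    lo <- 0; hi <- Pt
    p <- min(max(p, lo), hi)
    for (i in 1:100) {
      g <- cubic(p)
      if (g > 0) hi <- p else lo <- p
      gp <- (3 * p + 2 * d) * p + e
      pn <- if (gp != 0) p - g / gp else NA_real_
      if (!is.finite(pn) || pn <= lo || pn >= hi) pn <- (lo + hi) / 2
      if (abs(pn - p) <= 1e-15 * (Kd1 + pn)) { p <- pn; break }
      p <- pn
    }
    p / (Kd1 + p)
  }, numeric(1))
}

#' Competitive anisotropy model
#'
#' Anisotropy observed when an unlabeled competitor is titrated against a
#' preformed protein/probe complex: \eqn{r = r_0 + (r_b - r_0) f_b} with
#' \eqn{f_b} the exact probe fraction bound from [probeFractionBound()].
#' With no competitor (\code{Lt = 0}) the value reduces to the direct 1:1
#' model at the probe's own dissociation constant. Non-increasing in
#' \code{Lt}, non-decreasing in \code{Kd2}.
#'
#' @inheritParams probeFractionBound
#' @param r0,rb anisotropy endpoints.
#' @return anisotropy value(s).
#' @export
competitiveAnisotropy <- function(Kd2, Lt, Lst, Pt, Kd1, r0, rb) {
  r0 + (rb - r0) * probeFractionBound(Kd2, Lt, Lst, Pt, Kd1)
}

#' Numerical mass-balance oracle for the competition equilibrium
#'
#' Independent of the closed form: solves the free-protein mass balance
#' \deqn{P_t = p + L_{st}\,p/(K_{d1}+p) + L_t\,p/(K_{d2}+p)}
#' by bracketed scalar root finding on \eqn{[0, P_t]} (the left side is
#' strictly increasing in \eqn{p}, so the bracket always contains exactly
#' one root), followed by Newton refinement to machine precision. Protein
#' and ligand mass are conserved to better than 1e-10 relative.
#'
#' @param Kd1,Kd2 dissociation constants (nM), > 0.
#' @param Lst total labeled probe (nM).
#' @param Lt total competitor (nM); may be a vector.
#' @param Pt total protein (nM).
#' @return probe fraction bound in [0, 1], same length as \code{Lt}.
#' @export
solveEquilibriumNumeric <- function(Kd1, Kd2, Lst, Lt, Pt) {
  if (Kd1 <= 0 || Kd2 <= 0) stop("dissociation constants must be positive")
  if (Lst < 0 || Pt < 0 || any(Lt < 0)) stop("concentrations must be non-negative")
  vapply(Lt, function(lt) {
    if (Pt == 0) return(0)
    g <- function(p) p * (1 + Lst / (Kd1 + p) + lt / (Kd2 + p)) - Pt
    p <- stats::uniroot(g, c(0, Pt), tol = .Machine$double.eps * max(Pt, 1))$root
    for (i in 1:4) {                       # Newton refinement
      gp <- 1 + Lst * Kd1 / (Kd1 + p)^2 + lt * Kd2 / (Kd2 + p)^2
      p <- p - g(p) / gp
      if (p < 0) p <- 0
    }
    p / (Kd1 + p)
  }, numeric(1))
}

#' Competitor concentration at which the probe bound fraction halves
#'
#' Exact algebra on the mass balance: with target probe bound fraction
#' \eqn{f = f_0/2} (half the no-competitor value), the free protein is
#' \eqn{p = K_{d1} f/(1-f)} and the required total competitor
#' \deqn{L_t = (P_t - p - L_{st} f)\,(K_{d2} + p)/p.}
#' Used to center simulated competition dilution series the way an assay
#' centers its series on the expected IC50.
#'
#' @inheritParams probeFractionBound
#' @return total competitor concentration (nM).
#' @export
displacementMidpoint <- function(Kd2, Lst, Pt, Kd1) {
  f0 <- probeFractionBound(Kd2, 0, Lst, Pt, Kd1)
  f <- f0 / 2
  p <- Kd1 * f / (1 - f)
  (Pt - p - Lst * f) * (Kd2 + p) / p
}

#' Construct a titration curve
#'
#' @param x titrant concentrations (nM), non-decreasing.
#' @param r anisotropy values.
#' @param mode "direct" or "competition".
#' @param Lst total labeled probe (nM).
#' @param Pt total protein (nM; competition mode).
#' @param Kd1 probe dissociation constant (nM; competition mode).
#' @param r0,rb known anisotropy endpoints (NA to fit them).
#' @param truth simulator ground-truth list (internal use).
#' @return A [TitrationCurve-class] object.
#' @export
TitrationCurve <- function(x, r, mode = c("direct", "competition"),
                           Lst = 50, Pt = NA_real_, Kd1 = NA_real_,
                           r0 = NA_real_, rb = NA_real_, truth = list()) {
  mode <- match.arg(mode)
  cfg <- if (mode == "competition") list(Lst = Lst, Pt = Pt, Kd1 = Kd1)
         else list(Lst = Lst)
  new("TitrationCurve", x = as.numeric(x), r = as.numeric(r), mode = mode,
      r0 = r0, rb = rb, config = cfg, truth = truth)
}

setMethod("show", "TitrationCurve", function(object) {
  cat("TitrationCurve (", object@mode, "), ", length(object@x), " points, ",
      "titrant ", signif(min(object@x), 3), "-", signif(max(object@x), 3),
      " nM\n", sep = "")
  cfg <- object@config
  cat("  config:", paste(names(cfg), unlist(cfg), sep = "=", collapse = ", "), "\n")
})

.estimateNoise <- function(r) {
  if (length(r) < 3L) return(0)
  stats::mad(diff(r)) / sqrt(2)
}

#' Curve-validity checks for titration data
#'
#' Assay conventions for a trustworthy 1:1 or competition fit:
#' \itemize{
#'   \item \code{baseline_below_free_probe}: the competition baseline falls
#'     more than \code{k} noise-sd below the free-probe anisotropy,
#'     indicating an unintended probe/ligand interaction;
#'   \item \code{start_anisotropy_mismatch}: the first point of a direct
#'     titration differs from the free-probe anisotropy by more than
#'     \code{k} noise-sd;
#'   \item \code{non_monotonic_beyond_noise}: the curve reverses direction
#'     by more than \code{k} noise-sd against the expected monotonicity
#'     (increasing for direct, decreasing for competition).
#' }
#'
#' @param curve a [TitrationCurve-class] object.
#' @param r0 free-probe anisotropy; defaults to the curve's stored value.
#' @param noiseSd measurement noise sd; estimated from first differences
#'   when not supplied.
#' @param k flag threshold in noise-sd units (default 3).
#' @return character vector of flags (empty when clean).
#' @export
validateCurve <- function(curve, r0 = NULL, noiseSd = NULL, k = 3) {
  if (!length(curve@r)) stop("empty curve")
  if (is.null(r0)) r0 <- curve@r0
  if (is.null(noiseSd) || is.na(noiseSd)) noiseSd <- .estimateNoise(curve@r)
  tol <- k * max(noiseSd, .Machine$double.eps)
  flags <- character()
  if (!is.na(r0)) {
    if (curve@mode == "competition" && min(curve@r) < r0 - tol)
      flags <- c(flags, "baseline_below_free_probe")
    if (curve@mode == "direct" && abs(curve@r[1] - r0) > tol)
      flags <- c(flags, "start_anisotropy_mismatch")
  }
  # monotonicity is judged on per-concentration means so that replicate
  # scatter at a repeated concentration is not mistaken for a reversal
  mu <- tapply(curve@r, curve@x, mean)
  mu <- mu[order(as.numeric(names(mu)))]
  reps <- length(curve@r) / length(mu)
  d <- diff(as.numeric(mu))
  rev <- if (curve@mode == "direct") -d else d
  if (any(rev > tol / sqrt(reps) * sqrt(2)))
    flags <- c(flags, "non_monotonic_beyond_noise")
  flags
}

.lmFit <- function(resFun, start, lower = NULL, upper = NULL) {
  minpack.lm::nls.lm(par = start, fn = resFun,
                     control = minpack.lm::nls.lm.control(maxiter = 200))
}

.fitCore <- function(curve, model, startLogKd, fixEndpoints) {
  r <- curve@r
  fitEnds <- is.null(fixEndpoints)
  if (fitEnds) {
    start <- c(logKd = startLogKd, r0 = min(r), rb = max(r))
    resFun <- function(p) r - model(exp(p[["logKd"]]), p[["r0"]], p[["rb"]])
  } else {
    start <- c(logKd = startLogKd)
    resFun <- function(p) r - model(exp(p[["logKd"]]),
                                    fixEndpoints[1], fixEndpoints[2])
  }
  fit <- .lmFit(resFun, start)
  p <- fit$par
  kd <- exp(p[["logKd"]])
  covOk <- !inherits(try(ch <- chol(fit$hessian), silent = TRUE), "try-error")
  seLog <- if (covOk) {
    s2 <- fit$deviance / max(length(r) - length(p), 1)
    sqrt(diag(chol2inv(ch)) * s2)[1]
  } else NA_real_
  list(kd = kd, se = kd * seLog,
       r0 = if (fitEnds) p[["r0"]] else fixEndpoints[1],
       rb = if (fitEnds) p[["rb"]] else fixEndpoints[2],
       dev = fit$deviance,
       converged = fit$info %in% 1:4, fit = fit)
}

.startKd <- function(x, r) {
  mid <- (min(r) + max(r)) / 2
  ord <- order(x)
  xo <- x[ord]; ro <- r[ord]
  i <- which(diff(sign(ro - mid)) != 0)
  if (length(i)) max(xo[i[1]], 1e-6) else max(stats::median(xo), 1e-6)
}

#' Fit the direct 1:1 binding model to a titration curve
#'
#' Levenberg-Marquardt least squares on the exact depletion-corrected model
#' ([directAnisotropy()]) with the dissociation constant parameterized on
#' the log scale (positivity by construction). Endpoints are fitted by
#' default and can be fixed. Standard errors come from the Jacobian at the
#' optimum (delta method for the back-transformed Kd). A curve with no
#' usable dynamic range is reported as unidentifiable rather than fitted.
#'
#' @param curve a [TitrationCurve-class] object with \code{mode = "direct"};
#'   \code{x} is the protein concentration grid, \code{config$Lst} the probe
#'   concentration.
#' @param fixEndpoints optional numeric \code{c(r0, rb)} to hold fixed.
#' @return A [FitResult-class] object; \code{converged} is honest and QC
#'   flags from [validateCurve()] are attached.
#' @export
fitDirect <- function(curve, fixEndpoints = NULL) {
  stopifnot(is(curve, "TitrationCurve"))
  if (curve@mode != "direct") stop("curve mode must be 'direct'")
  if (length(curve@x) < 5L) stop("need at least 5 points to fit")
  Lst <- curve@config$Lst
  noise <- .estimateNoise(curve@r)
  if (diff(range(curve@r)) <= max(4 * noise, 1e-12)) {
    return(new("FitResult", estimate = NA_real_, converged = FALSE,
               qcFlags = "unidentifiable_flat_curve", model = "direct"))
  }
  model <- function(kd, r0, rb) directAnisotropy(kd, Lst, curve@x, r0, rb)
  res <- .fitCore(curve, model, log(.startKd(curve@x, curve@r)), fixEndpoints)
  resNoise <- sqrt(res$dev / max(length(curve@r) - 3, 1))
  flags <- validateCurve(curve, r0 = res$r0, noiseSd = resNoise)
  new("FitResult", estimate = res$kd, se = res$se, r0 = res$r0, rb = res$rb,
      residualNorm = res$dev, converged = res$converged && res$kd > 0,
      qcFlags = flags, model = "direct",
      details = list(info = res$fit$info, message = res$fit$message))
}

#' Fit the exact competition model for a competitor dissociation constant
#'
#' As [fitDirect()], but on the exact ternary-equilibrium model
#' ([competitiveAnisotropy()]) with the probe affinity \code{Kd1}, probe
#' concentration \code{Lst} and protein concentration \code{Pt} held fixed
#' at their assay values (taken from the curve's config; \code{Kd1} comes
#' from a prior direct titration).
#'
#' @param curve a [TitrationCurve-class] object with
#'   \code{mode = "competition"}; \code{x} is the total competitor grid.
#' @param fixEndpoints optional numeric \code{c(r0, rb)}.
#' @return A [FitResult-class] object for \code{Kd2}.
#' @export
fitCompetition <- function(curve, fixEndpoints = NULL) {
  stopifnot(is(curve, "TitrationCurve"))
  if (curve@mode != "competition") stop("curve mode must be 'competition'")
  if (length(curve@x) < 5L) stop("need at least 5 points to fit")
  cfg <- curve@config
  noise <- .estimateNoise(curve@r)
  if (diff(range(curve@r)) <= max(4 * noise, 1e-12)) {
    return(new("FitResult", estimate = NA_real_, converged = FALSE,
               qcFlags = "unidentifiable_flat_curve", model = "competition"))
  }
  model <- function(kd2, r0, rb)
    competitiveAnisotropy(kd2, curve@x, cfg$Lst, cfg$Pt, cfg$Kd1, r0, rb)
  res <- .fitCore(curve, model, log(.startKd(curve@x, curve@r)), fixEndpoints)
  resNoise <- sqrt(res$dev / max(length(curve@r) - 3, 1))
  flags <- validateCurve(curve, r0 = res$r0, noiseSd = resNoise)
  new("FitResult", estimate = res$kd, se = res$se, r0 = res$r0, rb = res$rb,
      residualNorm = res$dev, converged = res$converged && res$kd > 0,
      qcFlags = flags, model = "competition",
      details = list(info = res$fit$info, message = res$fit$message))
}

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@model, "):",
      if (is.na(object@estimate)) "no estimate"
      else paste0("Kd = ", signif(object@estimate, 4), " nM (se ",
                  signif(object@se, 3), ")"),
      "\n  converged:", object@converged)
  if (length(object@qcFlags))
    cat("\n  qc:", paste(object@qcFlags, collapse = ", "))
  cat("\n")
})

#' @describeIn fitDirect fitted estimate accessor.
#' @param object a [FitResult-class] object.
#' @export
fitEstimate <- function(object) object@estimate

#' @describeIn fitDirect QC flag accessor.
#' @export
qcFlags <- function(object) object@qcFlags
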