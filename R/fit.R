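# Weighted nonlinear least-squares fitting of correlation curves.

.fitWeights <- function(curve, weights) {
  if (is.null(weights)) weights <- gSD(curve)
  if (is.null(weights)) return(rep(1, length(curve@lags)))
  if (length(weights) != length(curve@lags))
    stop("weights must match the curve length")
  if (any(weights < 0)) stop("weights (per-lag sd) must be positive")
  pos <- weights[weights > 0]
  if (!length(pos)) return(rep(1, length(curve@lags)))
  # guard: a zero sd would give an infinite weight
  pmax(weights, min(pos) * 1e-3)
}

.lmControl <- minpack.lm::nls.lm.control(
  ftol = 1e-14, ptol = 1e-14, gtol = 0, maxiter = 500)

# deterministic multiplicative perturbations for bounded restarts
.RESTARTS <- list(c(1, 1), c(0.5, 2), c(2, 0.5), c(5, 0.2))

.noFit <- function(modelId, kappa, note) {
  new("DiffusionFit", nMolecules = NA_real_, tauD = NA_real_,
      fraction = numeric(), dCoef = NA_real_, kappaUsed = kappa,
      chiSqReduced = NA_real_, converged = FALSE, modelId = modelId,
      note = note)
}

#' Fit a 3D free-diffusion model to a correlation curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt with positivity
#' bounds): minimises sum(((g_obs - g_model)/sd)^2). Initial guesses are
#' n0 = 1/g(first lag) and tauD0 = the first lag at which g drops to half
#' its first-lag value. The structure parameter kappa is fixed from the
#' calibrated volume, not refit. Non-convergence after 3 bounded restarts
#' from perturbed initials, or a non-positive amplitude (an all-noise
#' curve), yields an explicit no-fit result with parameters withheld.
#'
#' @param curve a \linkS4class{CorrelationCurve} with >= 8 lags.
#' @param volume the calibrated \linkS4class{ObservationVolume}.
#' @param modelId "one_component_3d" (default) or "two_component_3d".
#' @param weights optional per-lag sd; defaults to the curve's \code{sd}
#'   slot when present, otherwise unweighted.
#' @return A \linkS4class{DiffusionFit}.
#' @export
fitCorrelation <- function(curve, volume,
                           modelId = c("one_component_3d", "two_component_3d"),
                           weights = NULL) {
  stopifnot(is(curve, "CorrelationCurve"), is(volume, "ObservationVolume"))
  validObject(curve); validObject(volume)
  modelId <- match.arg(modelId)
  tau <- curve@lags
  gobs <- curve@g
  if (length(tau) < 8L) stop("need at least 8 lags to fit")
  kappa <- volume@kappa
  sdv <- .fitWeights(curve, weights)

  g1 <- gobs[1L]
  amp <- mean(gobs[seq_len(min(3L, length(gobs)))])
  if (!is.finite(amp) || amp <= 0 || g1 <= 0)
    return(.noFit(modelId, kappa, "amplitude <= 0: no fit attempted"))

  n0 <- 1 / g1
  half <- which(gobs <= g1 / 2)
  tauD0 <- if (length(half)) tau[half[1L]] else stats::median(tau)

  fitOnce <- function(start, lower, upper, fn) {
    res <- try(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = function(p) (gobs - fn(p)) / sdv, control = .lmControl),
      silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    if (!res$info %in% 1:4) return(NULL)
    res
  }

  if (modelId == "one_component_3d") {
    fn <- function(p) modelG3D(tau, p[1L], p[2L], kappa)
    lower <- c(1e-9, min(tau) * 1e-6)
    upper <- c(1e12, max(tau) * 1e6)
    best <- NULL
    for (pert in .RESTARTS) {
      start <- pmin(pmax(c(n0 * pert[1L], tauD0 * pert[2L]), lower), upper)
      res <- fitOnce(start, lower, upper, fn)
      if (!is.null(res) && (is.null(best) || res$deviance < best$deviance))
        best <- res
      if (!is.null(best)) break
    }
    if (is.null(best))
      return(.noFit(modelId, kappa, "no convergence after bounded restarts"))
    p <- best$par
    dof <- max(length(tau) - 2L, 1L)
    new("DiffusionFit", nMolecules = p[1L], tauD = p[2L],
        fraction = numeric(),
        dCoef = diffusionCoefficient(p[2L], volume@wXY), kappaUsed = kappa,
        chiSqReduced = best$deviance / dof, converged = TRUE,
        modelId = modelId, note = "")
  } else {
    fn <- function(p) modelG3DTwo(tau, p[1L], p[2L], p[3L], p[4L], kappa)
    lower <- c(1e-9, 0, min(tau) * 1e-6, min(tau) * 1e-6)
    upper <- c(1e12, 1, max(tau) * 1e6, max(tau) * 1e6)
    best <- NULL
    for (pert in .RESTARTS) {
      start <- c(n0 * pert[1L], 0.5, tauD0 * pert[2L] / 4, tauD0 * pert[2L] * 4)
      start <- pmin(pmax(start, lower), upper)
      res <- fitOnce(start, lower, upper, fn)
      if (!is.null(res) && (is.null(best) || res$deviance < best$deviance))
        best <- res
    }
    if (is.null(best))
      return(.noFit(modelId, kappa, "no convergence after bounded restarts"))
    p <- best$par
    dof <- max(length(tau) - 4L, 1L)
    new("DiffusionFit", nMolecules = p[1L], tauD = p[3:4],
        fraction = p[2L],
        dCoef = diffusionCoefficient(p[3:4], volume@wXY), kappaUsed = kappa,
        chiSqReduced = best$deviance / dof, converged = TRUE,
        modelId = modelId, note = "")
  }
}

#' Calibrate the observation volume from a reference-dye curve
#'
#' Fits a one-component model with free kappa to the autocorrelation of a
#' calibration dye of known diffusion coefficient, then inverts
#' w_xy = sqrt(4 D tauD). This is how the observation volume is determined
#' before each experiment.
#'
#' @param curve autocorrelation curve of the calibration dye.
#' @param knownD the dye's diffusion coefficient in um^2/s, > 0.
#' @param weights optional per-lag sd.
#' @return An \linkS4class{ObservationVolume}.
#' @export
calibrateVolume <- function(curve, knownD, weights = NULL) {
  stopifnot(is(curve, "CorrelationCurve"))
  if (!is.numeric(knownD) || length(knownD) != 1L || knownD <= 0)
    stop("knownD must be a single positive diffusion coefficient (um^2/s)")
  validObject(curve)
  tau <- curve@lags
  gobs <- curve@g
  if (length(tau) < 8L) stop("need at least 8 lags to calibrate")
  sdv <- .fitWeights(curve, weights)
  g1 <- gobs[1L]
  if (g1 <= 0) stop("calibration curve has non-positive amplitude")
  n0 <- 1 / g1
  half <- which(gobs <= g1 / 2)
  tauD0 <- if (length(half)) tau[half[1L]] else stats::median(tau)
  lower <- c(1e-9, min(tau) * 1e-6, 1 + 1e-6)
  upper <- c(1e12, max(tau) * 1e6, 100)
  best <- NULL
  for (pert in .RESTARTS) {
    start <- pmin(pmax(c(n0 * pert[1L], tauD0 * pert[2L], 5), lower), upper)
    res <- try(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = function(p) (gobs - modelG3D(tau, p[1L], p[2L], p[3L])) / sdv,
      control = .lmControl), silent = TRUE)
    if (!inherits(res, "try-error") && res$info %in% 1:4 &&
        (is.null(best) || res$deviance < best$deviance))
      best <- res
  }
  if (is.null(best)) stop("calibration fit did not converge")
  observationVolume(wXY = sqrt(4 * knownD * best$par[2L]),
                    kappa = best$par[3L])
}
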