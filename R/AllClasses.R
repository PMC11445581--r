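#' @useDynLib fccstools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Avogadro's number (1/mol) and Boltzmann's constant (J/K), CODATA exact values.
.AVOGADRO <- 6.02214076e23
.BOLTZMANN <- 1.380649e-23

.COMPARTMENTS <- c("chromatin", "spindle", "centrosome", "cytoplasm",
                   "whole_cell", "polar_chromosome", "other")
.CURVE_KINDS <- c("auto_g", "auto_r", "cross")

#' Confocal observation volume
#'
#' Geometry of the effective confocal detection volume: a 3D Gaussian with
#' lateral 1/e^2 radius \code{wXY} (micrometres) and axial elongation given
#' by the structure parameter \code{kappa} = w_z / w_xy, so that
#' w_z = kappa * w_xy.
#'
#' @slot wXY numeric(1), lateral 1/e^2 radius in micrometres, > 0.
#' @slot kappa numeric(1), structure parameter, > 1.
#' @export
setClass("ObservationVolume",
         representation(wXY = "numeric", kappa = "numeric"))

setValidity("ObservationVolume", function(object) {
  msg <- character()
  if (length(object@wXY) != 1L || !is.finite(object@wXY) || object@wXY <= 0)
    msg <- c(msg, "wXY must be a single finite positive number (micrometres)")
  if (length(object@kappa) != 1L || !is.finite(object@kappa) || object@kappa <= 1)
    msg <- c(msg, "kappa must be a single finite number > 1")
  if (length(msg)) msg else TRUE
})

#' Sample environment for Stokes-Einstein conversions
#'
#' @slot temperatureK numeric(1), absolute temperature in kelvin, > 0.
#' @slot viscosityPaS numeric(1), dynamic viscosity in Pa s, > 0.
#' @export
setClass("SampleEnvironment",
         representation(temperatureK = "numeric", viscosityPaS = "numeric"))

setValidity("SampleEnvironment", function(object) {
  msg <- character()
  if (length(object@temperatureK) != 1L || !is.finite(object@temperatureK) ||
      object@temperatureK <= 0)
    msg <- c(msg, "temperatureK must be a single positive number")
  if (length(object@viscosityPaS) != 1L || !is.finite(object@viscosityPaS) ||
      object@viscosityPaS <= 0)
    msg <- c(msg, "viscosityPaS must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Binned photon-count time series for one detection channel
#'
#' @slot channel character(1) label, e.g. "green" or "red".
#' @slot binWidth numeric(1), bin width in seconds, > 0.
#' @slot counts numeric vector of non-negative integer-valued counts,
#'   length >= 2.
#' @export
setClass("PhotonCountTrace",
         representation(channel = "character", binWidth = "numeric",
                        counts = "numeric"))

setValidity("PhotonCountTrace", function(object) {
  msg <- character()
  if (length(object@channel) != 1L || is.na(object@channel))
    msg <- c(msg, "channel must be a single label")
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive number (seconds)")
  cts <- object@counts
  if (length(cts) < 2L)
    msg <- c(msg, "counts must have length >= 2")
  else if (anyNA(cts) || any(!is.finite(cts)) || any(cts < 0) ||
           any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Correlation curve G(tau)
#'
#' Auto- or cross-correlation of intensity fluctuations versus lag time,
#' with optional per-lag standard deviations used as fit weights. Lag 0 is
#' never part of a curve (shot-noise dominated).
#'
#' @slot kind one of "auto_g", "auto_r", "cross".
#' @slot lags numeric, lag times in seconds, strictly increasing, > 0.
#' @slot g numeric, dimensionless correlation amplitudes, same length.
#' @slot sd numeric, optional per-lag standard deviation (length 0 when
#'   absent), non-negative.
#' @export
setClass("CorrelationCurve",
         representation(kind = "character", lags = "numeric", g = "numeric",
                        sd = "numeric"),
         prototype(sd = numeric()))

setValidity("CorrelationCurve", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .CURVE_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.CURVE_KINDS, collapse = ", ")))
  lg <- object@lags
  if (!length(lg) || anyNA(lg) || any(lg <= 0) || is.unsorted(lg, strictly = TRUE))
    msg <- c(msg, "lags must be strictly increasing and positive")
  if (length(object@g) != length(lg))
    msg <- c(msg, "g must have the same length as lags")
  if (length(object@sd) && (length(object@sd) != length(lg) ||
                            any(object@sd < 0, na.rm = TRUE)))
    msg <- c(msg, "sd, if present, must match lags and be non-negative")
  if (length(msg)) msg else TRUE
})

#' Fit of a 3D free-diffusion model to a correlation curve
#'
#' @slot nMolecules fitted mean number of molecules in the observation
#'   volume (for the two-component model, the total N).
#' @slot tauD fitted diffusion time(s) in seconds (length 2 for the
#'   two-component model).
#' @slot fraction amplitude fraction of the first component (length 0 for
#'   the one-component model).
#' @slot dCoef diffusion coefficient(s) in um^2/s, w_xy^2 / (4 tauD).
#' @slot kappaUsed structure parameter used (fixed from calibration).
#' @slot chiSqReduced reduced chi-square of the fit.
#' @slot converged logical flag; when FALSE, parameters are NA and
#'   \code{note} explains why.
#' @slot modelId "one_component_3d" or "two_component_3d".
#' @slot note diagnostic message ("" when converged).
#' @export
setClass("DiffusionFit",
         representation(nMolecules = "numeric", tauD = "numeric",
                        fraction = "numeric", dCoef = "numeric",
                        kappaUsed = "numeric", chiSqReduced = "numeric",
                        converged = "logical", modelId = "character",
                        note = "character"),
         prototype(fraction = numeric(), note = ""))

setValidity("DiffusionFit", function(object) {
  msg <- character()
  if (!object@modelId %in% c("one_component_3d", "two_component_3d"))
    msg <- c(msg, "modelId must be one_component_3d or two_component_3d")
  if (isTRUE(object@converged)) {
    if (anyNA(object@nMolecules) || any(object@nMolecules <= 0))
      msg <- c(msg, "converged fit must have positive nMolecules")
    if (anyNA(object@tauD) || any(object@tauD <= 0))
      msg <- c(msg, "converged fit must have positive tauD")
  }
  if (length(msg)) msg else TRUE
})

#' Mass-action binding equilibrium of two species
#'
#' Free and complexed concentrations (molar) of a binding pair A + B <-> AB
#' at dissociation constant \code{kd}, satisfying conservation
#' aFree + complex = aTotal, bFree + complex = bTotal and the mass-action
#' relation aFree * bFree = kd * complex.
#'
#' @slot aTotal,bTotal,kd,aFree,bFree,complex numeric(1), molar, >= 0.
#' @export
setClass("EquilibriumState",
         representation(aTotal = "numeric", bTotal = "numeric", kd = "numeric",
                        aFree = "numeric", bFree = "numeric",
                        complex = "numeric"))

setValidity("EquilibriumState", function(object) {
  vals <- c(object@aTotal, object@bTotal, object@kd, object@aFree,
            object@bFree, object@complex)
  msg <- character()
  if (length(vals) != 6L || anyNA(vals) || any(vals < 0))
    msg <- c(msg, "all concentrations and kd must be single non-negative numbers")
  else {
    tol <- 1e-9 * max(object@aTotal, object@bTotal, 1e-300)
    if (abs(object@aFree + object@complex - object@aTotal) > tol ||
        abs(object@bFree + object@complex - object@bTotal) > tol)
      msg <- c(msg, "mass conservation violated")
  }
  if (length(msg)) msg else TRUE
})

#' Dual-colour FCCS interaction result
#'
#' Zero-lag amplitudes, derived absolute concentrations, cross-correlation
#' quotient q and dissociation constant. When the cross amplitude is
#' inconsistent with the autocorrelations (negative inferred free
#' concentration, typically noise), \code{valid} is FALSE, the offending
#' concentrations are reported unclipped, and \code{kd} is withheld (NA).
#'
#' @slot gG0,gR0,gX0 zero-lag amplitudes (dimensionless).
#' @slot cGreenFree,cRedFree,cComplex molar concentrations.
#' @slot kd molar; Inf when no complex is detected; NA when withheld.
#' @slot boundFractionG,boundFractionR bound fractions of each species.
#' @slot q cross-correlation quotient (max of the bound fractions).
#' @slot valid logical consistency flag.
#' @slot note diagnostics.
#' @export
setClass("InteractionResult",
         representation(gG0 = "numeric", gR0 = "numeric", gX0 = "numeric",
                        cGreenFree = "numeric", cRedFree = "numeric",
                        cComplex = "numeric", kd = "numeric",
                        boundFractionG = "numeric", boundFractionR = "numeric",
                        q = "numeric", valid = "logical", note = "character"),
         prototype(note = ""))

#' Anaphase-aligned single-cell degradation trace
#'
#' Fluorescence intensity versus movie frame for one cell and subcellular
#' compartment, with frame 0 at anaphase (chromatid separation) and
#' negative frames before it.
#'
#' @slot frames integer vector of strictly consecutive frame numbers.
#' @slot intensities numeric, same length as frames (arbitrary units; raw
#'   traces are non-negative, corrected traces may dip below 0 with noise).
#' @slot background numeric, scalar or per-frame background level.
#' @slot compartment one of chromatin, spindle, centrosome, cytoplasm,
#'   whole_cell, polar_chromosome, other.
#' @slot frameInterval numeric(1), seconds between frames.
#' @slot cellId character(1).
#' @export
setClass("DegradationTrace",
         representation(frames = "integer", intensities = "numeric",
                        background = "numeric", compartment = "character",
                        frameInterval = "numeric", cellId = "character"),
         prototype(background = 0, compartment = "whole_cell",
                   frameInterval = 30, cellId = "cell"))

setValidity("DegradationTrace", function(object) {
  msg <- character()
  fr <- object@frames
  if (length(fr) < 2L || anyNA(fr) || any(diff(fr) != 1L))
    msg <- c(msg, "frames must be strictly consecutive integers (length >= 2)")
  if (length(object@intensities) != length(fr) || anyNA(object@intensities) ||
      any(!is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite and match frames in length")
  if (!length(object@background) %in% c(1L, length(fr)) ||
      anyNA(object@background))
    msg <- c(msg, "background must be scalar or per-frame")
  if (length(object@compartment) != 1L ||
      !object@compartment %in% .COMPARTMENTS)
    msg <- c(msg, sprintf("compartment must be one of %s",
                          paste(.COMPARTMENTS, collapse = ", ")))
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number (seconds)")
  if (length(msg)) msg else TRUE
})

#' Result of the degradation-kinetics pipeline for one trace
#'
#' @slot onsetFrame integer(1); the first frame of the first sliding
#'   window whose slope falls strictly below the threshold, or NA when no
#'   onset is detected (a valid result for flat/control traces).
#' @slot initialSpeed slope of the onset window (normalised intensity per
#'   frame); NA when no onset.
#' @slot maxSpeed steepest 5-point slope around the minimum of the first
#'   derivative (normalised intensity per frame).
#' @slot maxSpeedFrame integer(1) frame at which the derivative is minimal.
#' @slot params list of the analysis parameters used.
#' @export
setClass("KineticsResult",
         representation(onsetFrame = "integer", initialSpeed = "numeric",
                        maxSpeed = "numeric", maxSpeedFrame = "integer",
                        params = "list"),
         prototype(params = list()))

#' Fluorescence line profile along a centrosome-to-centrosome axis
#'
#' @slot positions numeric, distance in pixels along the axis, strictly
#'   increasing from 0.
#' @slot values numeric intensities (background-subtracted; in [0,1] once
#'   min-max scaled).
#' @slot channel character(1).
#' @slot thicknessPx integer(1), averaging thickness perpendicular to the
#'   axis.
#' @slot scaled logical(1), whether values have been min-max scaled.
#' @export
setClass("LineProfile",
         representation(positions = "numeric", values = "numeric",
                        channel = "character", thicknessPx = "integer",
                        scaled = "logical"),
         prototype(channel = "green", scaled = FALSE))

setValidity("LineProfile", function(object) {
  msg <- character()
  if (is.unsorted(object@positions, strictly = TRUE))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@values) != length(object@positions))
    msg <- c(msg, "values must match positions in length")
  if (isTRUE(object@scaled) &&
      (min(object@values) < -1e-12 || max(object@values) > 1 + 1e-12))
    msg <- c(msg, "scaled values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Fluorescent species for Brownian-dynamics simulation
#'
#' @slot label character(1).
#' @slot diffusionCoefficient um^2/s, > 0.
#' @slot concentration molar, >= 0.
#' @slot brightnessG,brightnessR peak counts/s per molecule at the centre
#'   of the observation volume, per channel, >= 0.
#' @export
setClass("SpeciesSpec",
         representation(label = "character", diffusionCoefficient = "numeric",
                        concentration = "numeric", brightnessG = "numeric",
                        brightnessR = "numeric"))

setValidity("SpeciesSpec", function(object) {
  msg <- character()
  num <- c(object@diffusionCoefficient, object@concentration,
           object@brightnessG, object@brightnessR)
  if (anyNA(num) || any(!is.finite(num)))
    msg <- c(msg, "all numeric fields must be finite")
  else {
    if (object@diffusionCoefficient <= 0)
      msg <- c(msg, "diffusionCoefficient must be > 0")
    if (object@concentration < 0)
      msg <- c(msg, "concentration must be >= 0")
    if (object@brightnessG < 0 || object@brightnessR < 0)
      msg <- c(msg, "brightness values must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of a Brownian-dynamics photon simulation
#'
#' Molecules diffuse in a periodic cuboid with half-widths
#' \code{boxMultiplier} * (w_xy, w_xy, w_z); photon counts per bin are
#' Poisson with rate given by the 3D Gaussian detection profile.
#'
#' @slot volume ObservationVolume.
#' @slot boxMultiplier dimensionless, >= 3.
#' @slot binWidth s, photon binning time.
#' @slot duration s, total simulated time.
#' @slot seed integer seed; fully determines the output.
#' @slot timestep s, Brownian propagation step, <= binWidth (binWidth must
#'   be an integer multiple).
#' @export
setClass("SimulationConfig",
         representation(volume = "ObservationVolume", boxMultiplier = "numeric",
                        binWidth = "numeric", duration = "numeric",
                        seed = "integer", timestep = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!is.finite(object@boxMultiplier) || object@boxMultiplier < 3)
    msg <- c(msg, "boxMultiplier must be >= 3")
  if (!is.finite(object@binWidth) || object@binWidth <= 0 ||
      !is.finite(object@duration) || object@duration <= object@binWidth)
    msg <- c(msg, "need duration > binWidth > 0")
  if (!is.finite(object@timestep) || object@timestep <= 0 ||
      object@timestep > object@binWidth + 1e-15)
    msg <- c(msg, "timestep must satisfy 0 < timestep <= binWidth")
  else {
    k <- object@binWidth / object@timestep
    if (abs(k - round(k)) > 1e-9)
      msg <- c(msg, "binWidth must be an integer multiple of timestep")
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Ground-truth record of a synthetic dataset
#'
#' A serialisable record of every parameter of the generating call,
#' sufficient to regenerate the dataset bit-identically with the same
#' implementation.
#'
#' @slot kind character(1), which generator produced it.
#' @slot params named list of generating parameters (seed included).
#' @export
setClass("SyntheticTruth",
         representation(kind = "character", params = "list"))
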