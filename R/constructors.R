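#' Create an ObservationVolume
#'
#' @param wXY lateral 1/e^2 radius in micrometres (> 0).
#' @param kappa structure parameter w_z / w_xy (> 1).
#' @return An \linkS4class{ObservationVolume}.
#' @examples
#' vol <- observationVolume(wXY = 0.2, kappa = 5)
#' effectiveVolume(vol)   # litres, ~0.22 fL
#' @export
observationVolume <- function(wXY, kappa) {
  new("ObservationVolume", wXY = as.numeric(wXY), kappa = as.numeric(kappa))
}

#' Create a SampleEnvironment
#'
#' @param temperatureK absolute temperature (K).
#' @param viscosityPaS dynamic viscosity (Pa s); water at 37 C is about
#'   6.9e-4, cytoplasm is typically taken a few-fold higher.
#' @return A \linkS4class{SampleEnvironment}.
#' @export
sampleEnvironment <- function(temperatureK, viscosityPaS) {
  new("SampleEnvironment", temperatureK = as.numeric(temperatureK),
      viscosityPaS = as.numeric(viscosityPaS))
}

#' Create a PhotonCountTrace
#'
#' @param counts non-negative integer photon counts per bin.
#' @param binWidth bin width in seconds.
#' @param channel channel label.
#' @return A \linkS4class{PhotonCountTrace}.
#' @export
photonCountTrace <- function(counts, binWidth, channel = "green") {
  new("PhotonCountTrace", channel = channel, binWidth = as.numeric(binWidth),
      counts = as.numeric(counts))
}

#' Create a CorrelationCurve
#'
#' @param lags lag times in seconds (strictly increasing, positive).
#' @param g correlation values.
#' @param kind one of "auto_g", "auto_r", "cross".
#' @param sd optional per-lag standard deviations.
#' @return A \linkS4class{CorrelationCurve}.
#' @export
correlationCurve <- function(lags, g, kind = "auto_g", sd = numeric()) {
  new("CorrelationCurve", kind = kind, lags = as.numeric(lags),
      g = as.numeric(g), sd = as.numeric(sd))
}

#' Create a DegradationTrace
#'
#' @param frames consecutive integer frame numbers, anaphase = 0.
#' @param intensities fluorescence intensities (a.u.).
#' @param background scalar or per-frame background (a.u.).
#' @param compartment subcellular compartment label.
#' @param frameInterval seconds between frames.
#' @param cellId cell identifier.
#' @return A \linkS4class{DegradationTrace}.
#' @export
degradationTrace <- function(frames, intensities, background = 0,
                             compartment = "whole_cell", frameInterval = 30,
                             cellId = "cell") {
  new("DegradationTrace", frames = as.integer(frames),
      intensities = as.numeric(intensities),
      background = as.numeric(background), compartment = compartment,
      frameInterval = as.numeric(frameInterval), cellId = cellId)
}

#' Create a SpeciesSpec
#'
#' @param label species label.
#' @param diffusionCoefficient um^2/s.
#' @param concentration molar.
#' @param brightnessG,brightnessR peak counts/s per molecule in the green
#'   and red detection channels.
#' @return A \linkS4class{SpeciesSpec}.
#' @export
speciesSpec <- function(label, diffusionCoefficient, concentration,
                        brightnessG = 0, brightnessR = 0) {
  new("SpeciesSpec", label = label,
      diffusionCoefficient = as.numeric(diffusionCoefficient),
      concentration = as.numeric(concentration),
      brightnessG = as.numeric(brightnessG),
      brightnessR = as.numeric(brightnessR))
}

#' Create a SimulationConfig
#'
#' @param volume an \linkS4class{ObservationVolume}.
#' @param binWidth photon bin width (s).
#' @param duration simulated time (s).
#' @param seed integer seed.
#' @param boxMultiplier periodic-box half-widths as multiples of
#'   (w_xy, w_xy, w_z); the default 4 keeps the closed-box depression of
#'   the correlation amplitude at about 1 percent.
#' @param timestep Brownian step (s); defaults to binWidth (exact Gaussian
#'   propagation makes larger sub-steps unnecessary for free diffusion).
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(volume, binWidth, duration, seed,
                             boxMultiplier = 4, timestep = binWidth) {
  new("SimulationConfig", volume = volume,
      boxMultiplier = as.numeric(boxMultiplier),
      binWidth = as.numeric(binWidth), duration = as.numeric(duration),
      seed = as.integer(seed), timestep = as.numeric(timestep))
}
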