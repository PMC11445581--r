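# End-to-end analysis helpers: dual-colour trace pair -> amplitudes ->
# interaction result, plus seeded recovery experiments used to validate
# the whole chain against generator ground truth.

#' Default binding-pair species at mass-action equilibrium
#'
#' Builds the three diffusing populations (free green, free red, green-red
#' complex) for a binding pair at the given totals and dissociation
#' constant. Defaults model endogenously tagged Cyclin B1 (green,
#' free D = 15 um^2/s for the ~100 kDa Cyclin B1-Cdk1 complex) binding the
#' APC/C (red, D = 6.44 um^2/s as measured for APC8-mScarlet; the bound
#' complex, dominated by the ~1.2 MDa APC/C, is set slightly slower at
#' 6.0 um^2/s). Brightness is equal within each channel with no spectral
#' cross-talk.
#'
#' @param kd dissociation constant (molar).
#' @param aTotal,bTotal total concentrations (molar); ~100 nM is the
#'   measured cellular scale for both partners.
#' @param dFreeG,dFreeR,dComplex diffusion coefficients (um^2/s).
#' @param brightness peak counts/s per molecule (per channel).
#' @return list with \code{species} (list of \linkS4class{SpeciesSpec})
#'   and \code{state} (the \linkS4class{EquilibriumState}).
#' @export
bindingPairSpecies <- function(kd, aTotal = 100e-9, bTotal = 100e-9,
                               dFreeG = 15, dFreeR = 6.44, dComplex = 6.0,
                               brightness = 12000) {
  state <- solveEquilibrium(aTotal, bTotal, kd)
  species <- list(
    speciesSpec("free_green", dFreeG, state@aFree, brightnessG = brightness),
    speciesSpec("free_red", dFreeR, state@bFree, brightnessR = brightness),
    speciesSpec("complex", dComplex, state@complex,
                brightnessG = brightness, brightnessR = brightness))
  list(species = species, state = state)
}

#' Dual-colour FCCS analysis of a photon-trace pair
#'
#' Correlates the two channels (auto-green, auto-red, cross) with the
#' multi-tau correlator and segment-based noise estimates, fits the
#' one-component 3D diffusion model to each curve, converts the fitted
#' zero-lag amplitudes (1/N) to absolute concentrations, and derives the
#' cross-correlation quotient and dissociation constant.
#'
#' @param green,red \linkS4class{PhotonCountTrace} pair.
#' @param volume the calibrated \linkS4class{ObservationVolume}.
#' @param pointsPerOctave multi-tau lags per octave.
#' @param nSegments segments for the per-lag noise estimate.
#' @return list with \code{curves}, \code{fits} (each per kind) and
#'   \code{interaction} (an \linkS4class{InteractionResult}; NULL when any
#'   fit fails).
#' @export
analyzeDualColour <- function(green, red, volume, pointsPerOctave = 8,
                              nSegments = 10) {
  curves <- list(
    auto_g = estimateCurveNoise(green, green, nSegments, pointsPerOctave,
                                kind = "auto_g"),
    auto_r = estimateCurveNoise(red, red, nSegments, pointsPerOctave,
                                kind = "auto_r"),
    cross = estimateCurveNoise(green, red, nSegments, pointsPerOctave,
                               kind = "cross"))
  fits <- lapply(curves, fitCorrelation, volume = volume)
  if (!all(vapply(fits, isConverged, logical(1))))
    return(list(curves = curves, fits = fits, interaction = NULL))
  amps <- vapply(fits, function(f) 1 / f@nMolecules, numeric(1))
  interaction <- interactionFromAmplitudes(
    gG0 = amps[["auto_g"]], gR0 = amps[["auto_r"]], gX0 = amps[["cross"]],
    vEff = effectiveVolume(volume))
  list(curves = curves, fits = fits, interaction = interaction)
}

#' Seeded dissociation-constant recovery experiment
#'
#' For each seed, simulates a dual-colour photon-trace pair for a binding
#' pair at the given ground-truth kd and totals, runs the full analysis
#' chain ([analyzeDualColour()]) and returns the recovered kd values.
#' The median over seeds is the estimator validated against ground truth.
#'
#' @param kdTruth ground-truth dissociation constant (molar).
#' @param seeds integer vector of simulation seeds (>= 20 recommended).
#' @param duration trace duration per seed (s).
#' @param binWidth photon bin width (s).
#' @param volume observation volume (default w_xy = 0.2 um, kappa = 5).
#' @param aTotal,bTotal totals (molar).
#' @param boxMultiplier periodic-box size multiplier.
#' @return numeric vector of recovered kd (molar), one per seed; NA where
#'   the result was flagged or a fit failed.
#' @export
kdRecoveryExperiment <- function(kdTruth, seeds = 1:20, duration = 30,
                                 binWidth = 1e-4,
                                 volume = observationVolume(0.2, 5),
                                 aTotal = 100e-9, bTotal = 100e-9,
                                 boxMultiplier = 4) {
  pair <- bindingPairSpecies(kdTruth, aTotal, bTotal)
  vapply(seeds, function(sd) {
    cfg <- simulationConfig(volume, binWidth = binWidth, duration = duration,
                            seed = sd, boxMultiplier = boxMultiplier)
    tr <- simulatePhotonTraces(pair$species, cfg)
    res <- analyzeDualColour(tr$green, tr$red, volume)
    if (is.null(res$interaction) || !res$interaction@valid)
      return(NA_real_)
    res$interaction@kd
  }, numeric(1))
}

#' Seeded diffusion-coefficient recovery experiment
#'
#' Simulates a single freely diffusing species at the given diffusion
#' coefficient, correlates and fits each trace, and returns the fitted D
#' per seed; the median is compared with the ground truth.
#'
#' @param dTruth ground-truth diffusion coefficient (um^2/s).
#' @param seeds integer simulation seeds.
#' @param concentration species concentration (molar).
#' @param duration trace duration (s).
#' @param binWidth photon bin width (s).
#' @param volume observation volume.
#' @param boxMultiplier periodic-box size multiplier.
#' @param brightness peak counts/s per molecule.
#' @return numeric vector of fitted D (um^2/s), NA where a fit failed.
#' @export
diffusionRecoveryExperiment <- function(dTruth, seeds = 1:20,
                                        concentration = 50e-9, duration = 15,
                                        binWidth = 1e-4,
                                        volume = observationVolume(0.2, 5),
                                        boxMultiplier = 4,
                                        brightness = 12000) {
  sp <- speciesSpec("tracer", dTruth, concentration, brightnessG = brightness)
  vapply(seeds, function(sd) {
    cfg <- simulationConfig(volume, binWidth = binWidth, duration = duration,
                            seed = sd, boxMultiplier = boxMultiplier)
    tr <- simulatePhotonTraces(list(sp), cfg)
    curve <- estimateCurveNoise(tr$green, tr$green, kind = "auto_g")
    fit <- fitCorrelation(curve, volume)
    if (!isConverged(fit)) return(NA_real_)
    fit@dCoef
  }, numeric(1))
}
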