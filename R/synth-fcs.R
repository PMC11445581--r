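# Synthetic FCS data: Brownian-dynamics photon traces and closed-form
# model curves with recorded ground truth.

#' Simulate dual-channel photon-count traces
#'
#' Brownian dynamics of point emitters in a periodic cuboid with
#' half-widths boxMultiplier * (w_xy, w_xy, w_z). Each species contributes
#' round(concentration * N_A * V_box) molecules. Per timestep, molecules
#' take independent Gaussian displacements with per-axis standard
#' deviation sqrt(2 D dt) (the exact free-diffusion propagator, valid for
#' any step size); the expected photon rate per channel is
#' sum(brightness * W(r)) with
#' W(r) = exp(-2 (x^2 + y^2) / w_xy^2 - 2 z^2 / w_z^2), and counts per bin
#' are Poisson draws from the integrated rate. The seed fully determines
#' the output.
#'
#' @param species list of \linkS4class{SpeciesSpec} (>= 1; zero total
#'   concentration is allowed and yields all-zero traces).
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{green}, \code{red}
#'   (\linkS4class{PhotonCountTrace}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @examples
#' vol <- observationVolume(0.2, 5)
#' cfg <- simulationConfig(vol, binWidth = 2e-4, duration = 1, seed = 1)
#' sp <- speciesSpec("dye", 100, 10e-9, brightnessG = 1e4)
#' tr <- simulatePhotonTraces(list(sp), cfg)
#' mean(counts(tr$green))
#' @export
simulatePhotonTraces <- function(species, config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (!is.list(species) || !length(species))
    stop("need at least one SpeciesSpec")
  for (sp in species) {
    if (!is(sp, "SpeciesSpec")) stop("species must be SpeciesSpec objects")
    validObject(sp)
  }
  vol <- config@volume
  bx <- config@boxMultiplier * vol@wXY
  bz <- config@boxMultiplier * waistZ(vol)
  boxLitres <- (2 * bx) * (2 * bx) * (2 * bz) * 1e-15
  nMol <- vapply(species, function(sp)
    as.integer(round(sp@concentration * .AVOGADRO * boxLitres)), integer(1))
  nBins <- as.integer(floor(config@duration / config@binWidth))
  nSub <- as.integer(round(config@binWidth / config@timestep))
  res <- simulate_photon_traces_cpp(
    nMol = nMol,
    dCoef = vapply(species, function(sp) sp@diffusionCoefficient, numeric(1)),
    brightG = vapply(species, function(sp) sp@brightnessG, numeric(1)),
    brightR = vapply(species, function(sp) sp@brightnessR, numeric(1)),
    wXY = vol@wXY, wZ = waistZ(vol), bx = bx, by = bx, bz = bz,
    binWidth = config@binWidth, nBins = nBins, nSubsteps = nSub,
    seed = as.double(config@seed))
  truth <- new("SyntheticTruth", kind = "photon_traces", params = list(
    species = lapply(species, function(sp) list(
      label = sp@label, diffusion_coefficient = sp@diffusionCoefficient,
      concentration = sp@concentration, brightness_g = sp@brightnessG,
      brightness_r = sp@brightnessR)),
    n_molecules = nMol, w_xy_um = vol@wXY, kappa = vol@kappa,
    box_multiplier = config@boxMultiplier, box_volume_l = boxLitres,
    bin_width_s = config@binWidth, duration_s = nBins * config@binWidth,
    timestep_s = config@binWidth / nSub, seed = config@seed))
  list(green = photonCountTrace(res$green, config@binWidth, "green"),
       red = photonCountTrace(res$red, config@binWidth, "red"),
       truth = truth)
}

#' Closed-form dual-colour model curves (fast path for fitter tests)
#'
#' Builds the noiseless auto-green, auto-red and cross curves implied by
#' the single-component 3D diffusion shape composed with the dual-colour
#' amplitude relations, for free-green, free-red and complex populations
#' of N_g, N_r and N_gr molecules, optionally adding i.i.d. Gaussian noise.
#'
#' @param params named list with \code{nG}, \code{nR}, \code{nGR} (molecule
#'   numbers, >= 0), \code{tauDG}, \code{tauDR}, \code{tauDGR} (diffusion
#'   times, s) and \code{kappa}.
#' @param lagsSec lag times in seconds, strictly increasing, positive.
#' @param noiseSd per-lag Gaussian noise sd (scalar or per-lag; 0 = exact).
#' @param seed integer seed for the noise.
#' @return list of three \linkS4class{CorrelationCurve}s (\code{autoG},
#'   \code{autoR}, \code{cross}) and a \code{truth} record.
#' @export
makeModelCurves <- function(params, lagsSec, noiseSd = 0, seed = 1L) {
  need <- c("nG", "nR", "nGR", "tauDG", "tauDR", "tauDGR", "kappa")
  if (!all(need %in% names(params)))
    stop("params must contain ", paste(need, collapse = ", "))
  p <- lapply(params[need], as.numeric)
  .assertFinite(unlist(p), "model parameters")
  if (p$nG < 0 || p$nR < 0 || p$nGR < 0)
    stop("molecule numbers must be >= 0")
  if (any(lagsSec <= 0) || is.unsorted(lagsSec, strictly = TRUE))
    stop("lags must be strictly increasing and positive")
  ngT <- p$nG + p$nGR
  nrT <- p$nR + p$nGR
  if (ngT <= 0 || nrT <= 0)
    stop("each channel needs at least one fluorescent population")
  xg <- .g3dShape(lagsSec, p$tauDG, p$kappa)
  xr <- .g3dShape(lagsSec, p$tauDR, p$kappa)
  xx <- .g3dShape(lagsSec, p$tauDGR, p$kappa)
  gAutoG <- (p$nG * xg + p$nGR * xx) / ngT^2
  gAutoR <- (p$nR * xr + p$nGR * xx) / nrT^2
  gCross <- p$nGR * xx / (ngT * nrT)
  if (any(noiseSd < 0)) stop("noiseSd must be >= 0")
  if (any(noiseSd > 0)) {
    noise <- .withSeed(seed, list(
      stats::rnorm(length(lagsSec), 0, noiseSd),
      stats::rnorm(length(lagsSec), 0, noiseSd),
      stats::rnorm(length(lagsSec), 0, noiseSd)))
    gAutoG <- gAutoG + noise[[1L]]
    gAutoR <- gAutoR + noise[[2L]]
    gCross <- gCross + noise[[3L]]
  }
  truth <- new("SyntheticTruth", kind = "model_curves",
               params = c(p, list(noise_sd = noiseSd, seed = seed)))
  list(autoG = correlationCurve(lagsSec, gAutoG, "auto_g"),
       autoR = correlationCurve(lagsSec, gAutoR, "auto_r"),
       cross = correlationCurve(lagsSec, gCross, "cross"),
       truth = truth)
}
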