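# Conversions between fitted correlation parameters and physical
# quantities. All pairwise invertible to <= 1e-12 relative.

#' Effective confocal observation volume in litres
#'
#' \deqn{V_{eff} = \pi^{3/2} w_{xy}^2 w_z}
#' with waists in micrometres (1 um^3 = 1e-15 L).
#'
#' @param volume an \linkS4class{ObservationVolume}.
#' @return volume in litres.
#' @examples
#' effectiveVolume(observationVolume(0.2, 5)) * 1e15  # ~0.2227 fL
#' @export
effectiveVolume <- function(volume) {
  stopifnot(is(volume, "ObservationVolume"))
  validObject(volume)
  pi^1.5 * volume@wXY^2 * waistZ(volume) * 1e-15
}

#' Concentration from a fitted molecule number
#'
#' C = N / (N_Avogadro * V_eff).
#'
#' @param n mean number of molecules in the observation volume, >= 0.
#' @param vEff effective volume in litres, > 0.
#' @return molar concentration.
#' @export
concentrationFromN <- function(n, vEff) {
  stopifnot(all(n >= 0), vEff > 0)
  n / (.AVOGADRO * vEff)
}

#' Molecule number from a concentration
#'
#' Inverse of [concentrationFromN()].
#'
#' @param concentration molar, >= 0.
#' @param vEff effective volume in litres, > 0.
#' @return mean number of molecules in the volume.
#' @export
nFromConcentration <- function(concentration, vEff) {
  stopifnot(all(concentration >= 0), vEff > 0)
  concentration * .AVOGADRO * vEff
}

#' Diffusion coefficient from a diffusion time
#'
#' D = w_xy^2 / (4 tauD).
#'
#' @param tauD diffusion time in seconds, > 0.
#' @param wXY lateral waist in micrometres, > 0.
#' @return diffusion coefficient in um^2/s.
#' @export
diffusionCoefficient <- function(tauD, wXY) {
  stopifnot(all(tauD > 0), wXY > 0)
  wXY^2 / (4 * tauD)
}

#' Hydrodynamic radius via Stokes-Einstein
#'
#' \deqn{R_h = k_B T / (6 \pi \eta D)}
#'
#' @param dCoef diffusion coefficient in um^2/s, > 0.
#' @param env a \linkS4class{SampleEnvironment} (temperature and viscosity).
#' @return hydrodynamic radius in nanometres.
#' @examples
#' hydrodynamicRadius(16.22, sampleEnvironment(310, 1e-3))  # ~14 nm
#' @export
hydrodynamicRadius <- function(dCoef, env) {
  stopifnot(all(dCoef > 0), is(env, "SampleEnvironment"))
  validObject(env)
  dm2 <- dCoef * 1e-12                      # um^2/s -> m^2/s
  .BOLTZMANN * env@temperatureK / (6 * pi * env@viscosityPaS * dm2) * 1e9
}

#' Diffusion coefficient from a hydrodynamic radius
#'
#' Inverse of [hydrodynamicRadius()].
#'
#' @param radiusNm hydrodynamic radius in nanometres, > 0.
#' @inheritParams hydrodynamicRadius
#' @return diffusion coefficient in um^2/s.
#' @export
diffusionFromRadius <- function(radiusNm, env) {
  stopifnot(all(radiusNm > 0), is(env, "SampleEnvironment"))
  .BOLTZMANN * env@temperatureK /
    (6 * pi * env@viscosityPaS * radiusNm * 1e-9) * 1e12
}
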