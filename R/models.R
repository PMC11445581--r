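# Closed-form correlation models for free 3D diffusion through a 3D
# Gaussian observation volume.

# dimensionless decay shape, X(0) = 1
.g3dShape <- function(tau, tauD, kappa) {
  1 / (1 + tau / tauD) / sqrt(1 + tau / (kappa^2 * tauD))
}

#' Single-component 3D free-diffusion correlation model
#'
#' \deqn{G(\tau) = \frac{1}{N} \left(1 + \tau/\tau_D\right)^{-1}
#'   \left(1 + \tau/(\kappa^2 \tau_D)\right)^{-1/2}}
#'
#' The zero-lag amplitude is 1/N, the inverse of the mean number of
#' molecules in the observation volume.
#'
#' @param tau lag time(s), seconds, >= 0.
#' @param n mean number of molecules in the observation volume, > 0.
#' @param tauD diffusion time, seconds, > 0.
#' @param kappa structure parameter w_z / w_xy, > 1.
#' @return G(tau), dimensionless.
#' @examples
#' modelG3D(0, n = 10, tauD = 1e-3, kappa = 5)        # 0.1
#' modelG3D(1e-3, n = 10, tauD = 1e-3, kappa = 5)     # ~0.04903
#' @export
modelG3D <- function(tau, n, tauD, kappa) {
  stopifnot(n > 0, tauD > 0, kappa > 1, all(tau >= 0))
  .g3dShape(tau, tauD, kappa) / n
}

#' Two-component 3D free-diffusion correlation model
#'
#' Fraction-weighted sum of two single-component decays sharing the
#' structure parameter:
#' \deqn{G(\tau) = \frac{1}{N}\left[f X(\tau;\tau_{D,1}) +
#'   (1-f) X(\tau;\tau_{D,2})\right]}
#' Used for mixed populations such as a chromatin-bound plus a freely
#' diffusing pool.
#'
#' @inheritParams modelG3D
#' @param fraction amplitude fraction of the first component, in [0, 1].
#' @param tauD1,tauD2 diffusion times of the two components, seconds, > 0.
#' @return G(tau), dimensionless.
#' @export
modelG3DTwo <- function(tau, n, fraction, tauD1, tauD2, kappa) {
  stopifnot(n > 0, tauD1 > 0, tauD2 > 0, kappa > 1,
            fraction >= 0, fraction <= 1, all(tau >= 0))
  (fraction * .g3dShape(tau, tauD1, kappa) +
     (1 - fraction) * .g3dShape(tau, tauD2, kappa)) / n
}
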