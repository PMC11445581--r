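# Dual-colour FCCS amplitude algebra: equilibrium forward model and its
# inversion to absolute concentrations, bound fractions, the
# cross-correlation quotient q and the dissociation constant.
#
# With equal brightness within each channel and no spectral cross-talk,
# s = N_Avogadro * V_eff and molecule numbers N = C * s:
#   G_g(0) = 1 / (N_gfree + N_complex)
#   G_r(0) = 1 / (N_rfree + N_complex)
#   G_x(0) = N_complex / ((N_gfree + N_complex) * (N_rfree + N_complex))
# which invert to
#   c_complex = G_x(0) / (s * G_g(0) * G_r(0))
#   c_gfree   = 1 / (s * G_g(0)) - c_complex
#   c_rfree   = 1 / (s * G_r(0)) - c_complex

#' Solve a two-species mass-action binding equilibrium
#'
#' For A + B <-> AB with dissociation constant kd, the complex
#' concentration is the physical root of the quadratic
#' \deqn{[AB] = \frac{(A + B + K_D) - \sqrt{(A + B + K_D)^2 - 4AB}}{2}}
#' evaluated in the numerically stable form 2AB / (S + sqrt(S^2 - 4AB)).
#' kd = 0 is handled as the infinite-affinity limit, complex = min(A, B).
#'
#' @param aTotal,bTotal total concentrations (molar), >= 0.
#' @param kd dissociation constant (molar), >= 0.
#' @return An \linkS4class{EquilibriumState}.
#' @examples
#' solveEquilibrium(100e-9, 100e-9, 80e-9)  # complex ~42 nM
#' @export
solveEquilibrium <- function(aTotal, bTotal, kd) {
  stopifnot(is.finite(aTotal), is.finite(bTotal), is.finite(kd),
            aTotal >= 0, bTotal >= 0, kd >= 0)
  if (kd == 0 || aTotal == 0 || bTotal == 0) {
    cplx <- min(aTotal, bTotal)
  } else {
    s <- aTotal + bTotal + kd
    disc <- sqrt(max(s^2 - 4 * aTotal * bTotal, 0))
    cplx <- 2 * aTotal * bTotal / (s + disc)
  }
  new("EquilibriumState", aTotal = aTotal, bTotal = bTotal, kd = kd,
      aFree = aTotal - cplx, bFree = bTotal - cplx, complex = cplx)
}

#' Forward FCCS amplitudes of an equilibrium state
#'
#' The zero-lag auto- and cross-correlation amplitudes a dual-colour FCCS
#' measurement would report for the given free/complex concentrations in a
#' given observation volume (green species = A, red species = B).
#'
#' @param state an \linkS4class{EquilibriumState}.
#' @param vEff effective volume in litres, > 0.
#' @return named numeric: \code{gG0}, \code{gR0}, \code{gX0}.
#' @export
equilibriumAmplitudes <- function(state, vEff) {
  stopifnot(is(state, "EquilibriumState"), vEff > 0)
  validObject(state)
  ngT <- nFromConcentration(state@aFree + state@complex, vEff)
  nrT <- nFromConcentration(state@bFree + state@complex, vEff)
  nx <- nFromConcentration(state@complex, vEff)
  if (ngT == 0 || nrT == 0)
    stop("amplitudes undefined for a channel with zero total concentration")
  c(gG0 = 1 / ngT, gR0 = 1 / nrT, gX0 = nx / (ngT * nrT))
}

#' Absolute concentrations from FCCS amplitudes
#'
#' Inverts the standard dual-colour amplitude relations (equal brightness
#' within each channel, no cross-talk). A cross amplitude inconsistent
#' with the autocorrelations (negative inferred free concentration,
#' typically noise) is reported unclipped so that bias remains visible in
#' aggregate statistics; consumers should check \code{valid}.
#'
#' @param gG0,gR0 zero-lag autocorrelation amplitudes, > 0.
#' @param gX0 zero-lag cross-correlation amplitude, >= 0.
#' @param vEff effective volume in litres, > 0.
#' @return named list: \code{cGreenFree}, \code{cRedFree}, \code{cComplex}
#'   (molar) and \code{valid}.
#' @export
amplitudesToConcentrations <- function(gG0, gR0, gX0, vEff) {
  stopifnot(is.finite(gG0), is.finite(gR0), is.finite(gX0),
            gG0 > 0, gR0 > 0, gX0 >= 0, vEff > 0)
  s <- .AVOGADRO * vEff
  cComplex <- gX0 / (s * gG0 * gR0)
  cGreenFree <- 1 / (s * gG0) - cComplex
  cRedFree <- 1 / (s * gR0) - cComplex
  list(cGreenFree = cGreenFree, cRedFree = cRedFree, cComplex = cComplex,
       valid = cGreenFree >= 0 && cRedFree >= 0)
}

#' Dissociation constant from concentrations
#'
#' kd = free_A * free_B / complex; a zero complex concentration yields
#' +Inf, reported as "non-interacting".
#'
#' @param cGreenFree,cRedFree,cComplex molar concentrations, >= 0.
#' @return kd in molar, possibly Inf.
#' @export
kdFromConcentrations <- function(cGreenFree, cRedFree, cComplex) {
  stopifnot(cGreenFree >= 0, cRedFree >= 0, cComplex >= 0)
  if (cComplex == 0) return(Inf)
  cGreenFree * cRedFree / cComplex
}

#' Cross-correlation quotient and bound fractions
#'
#' bound_fraction_green = gX0 / gR0 (fraction of the green species bound),
#' bound_fraction_red = gX0 / gG0, and q = the larger of the two (the
#' limiting autocorrelation normalises the quotient).
#'
#' @inheritParams amplitudesToConcentrations
#' @return named numeric: \code{boundFractionG}, \code{boundFractionR},
#'   \code{q}.
#' @export
crossCorrelationQuotient <- function(gG0, gR0, gX0) {
  stopifnot(gG0 > 0, gR0 > 0, gX0 >= 0)
  bfG <- gX0 / gR0
  bfR <- gX0 / gG0
  c(boundFractionG = bfG, boundFractionR = bfR, q = max(bfG, bfR))
}

#' Full interaction analysis from three amplitudes
#'
#' Combines [amplitudesToConcentrations()], [kdFromConcentrations()] and
#' [crossCorrelationQuotient()] into one \linkS4class{InteractionResult}.
#' When the inferred free concentrations are negative the result is
#' flagged and kd is withheld (NA).
#'
#' @inheritParams amplitudesToConcentrations
#' @return An \linkS4class{InteractionResult}.
#' @export
interactionFromAmplitudes <- function(gG0, gR0, gX0, vEff) {
  conc <- amplitudesToConcentrations(gG0, gR0, gX0, vEff)
  quo <- crossCorrelationQuotient(gG0, gR0, gX0)
  if (conc$valid) {
    kd <- kdFromConcentrations(conc$cGreenFree, conc$cRedFree, conc$cComplex)
    note <- ""
  } else {
    kd <- NA_real_
    note <- "negative inferred free concentration; kd withheld"
  }
  new("InteractionResult", gG0 = gG0, gR0 = gR0, gX0 = gX0,
      cGreenFree = conc$cGreenFree, cRedFree = conc$cRedFree,
      cComplex = conc$cComplex, kd = kd,
      boundFractionG = unname(quo["boundFractionG"]),
      boundFractionR = unname(quo["boundFractionR"]),
      q = unname(quo["q"]), valid = conc$valid, note = note)
}
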