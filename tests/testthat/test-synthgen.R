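# Synthetic generators: determinism, analytic expectations, and agreement
# with the closed-form correlation model.

test_that("photon simulation is deterministic and honours degenerate input", {
  vol <- defaultVolume()
  cfg <- simulationConfig(vol, binWidth = 2e-4, duration = 0.5, seed = 99)
  sp <- speciesSpec("x", 10, 20e-9, brightnessG = 1e4, brightnessR = 5e3)
  a <- simulatePhotonTraces(list(sp), cfg)
  b <- simulatePhotonTraces(list(sp), cfg)
  expect_identical(counts(a$green), counts(b$green))
  expect_identical(counts(a$red), counts(b$red))

  # different seed changes the trace
  cfg2 <- simulationConfig(vol, binWidth = 2e-4, duration = 0.5, seed = 100)
  c2 <- simulatePhotonTraces(list(sp), cfg2)
  expect_false(identical(counts(a$green), counts(c2$green)))

  # no emitters -> all-zero traces
  empty <- simulatePhotonTraces(
    list(speciesSpec("none", 10, 0, brightnessG = 1e4)), cfg)
  expect_true(all(counts(empty$green) == 0))
  expect_true(all(counts(empty$red) == 0))

  # dark red channel
  expect_true(all(counts(a$red) > 0 | counts(a$red) == 0))
  darksp <- speciesSpec("g_only", 10, 20e-9, brightnessG = 1e4)
  dark <- simulatePhotonTraces(list(darksp), cfg)
  expect_true(all(counts(dark$red) == 0))

  expect_error(speciesSpec("bad", Inf, 1e-9), "finite")
})

test_that("mean count rate matches the numerically integrated expectation", {
  # oracle: <rate> = brightness * N_box * mean over the box of W(r), the
  # box average computed by numerical integration of the separable Gaussian
  vol <- defaultVolume()
  mult <- 4
  sp <- speciesSpec("tracer", 20, 10e-9, brightnessG = 1.5e4)
  cfg <- simulationConfig(vol, binWidth = 5e-4, duration = 60, seed = 5,
                          boxMultiplier = mult)
  tr <- simulatePhotonTraces(list(sp), cfg)
  nMol <- truthParams(tr$truth)$n_molecules[1L]
  axisMean <- function(w, half) {
    stats::integrate(function(x) exp(-2 * x^2 / w^2), -half, half,
                     rel.tol = 1e-10)$value / (2 * half)
  }
  wxy <- waistXY(vol); wz <- waistZ(vol)
  meanW <- axisMean(wxy, mult * wxy)^2 * axisMean(wz, mult * wz)
  expectedRate <- 1.5e4 * nMol * meanW
  empirical <- mean(counts(tr$green)) / binWidth(tr$green)
  expect_equal(empirical, expectedRate, tolerance = 0.05)
})

test_that("simulated autocorrelation matches the diffusion model", {
  # A closed simulation box with fixed molecule number carries a constant
  # canonical offset of -1/N_box in G(tau); a boxMultiplier of 6 puts that
  # offset (~5e-4 here) well below the 15% agreement band even at 10 tauD.
  vol <- defaultVolume()
  d <- 6.44
  conc <- 50e-9
  nSeeds <- 12
  tauDTrue <- waistXY(vol)^2 / (4 * d)
  nTrue <- nFromConcentration(conc, effectiveVolume(vol))
  sp <- speciesSpec("tracer", d, conc, brightnessG = 1.5e4)
  gsum <- NULL
  for (seed in seq_len(nSeeds)) {
    cfg <- simulationConfig(vol, binWidth = 2e-4, duration = 8, seed = seed,
                            boxMultiplier = 6)
    tr <- simulatePhotonTraces(list(sp), cfg)
    curve <- correlateMultiTau(tr$green, tr$green)
    gsum <- if (is.null(gsum)) gValues(curve) else gsum + gValues(curve)
  }
  gbar <- gsum / nSeeds
  lg <- lags(curve)
  keep <- lg >= tauDTrue / 10 & lg <= 10 * tauDTrue
  gModel <- modelG3D(lg[keep], nTrue, tauDTrue, structureParameter(vol))
  expect_true(all(abs(gbar[keep] / gModel - 1) <= 0.15))
})

test_that("model curves obey the amplitude relations and round-trip", {
  tau <- logLags(1e-5, 0.1, 60)
  # no co-diffusing species: cross identically zero
  mc0 <- makeModelCurves(list(nG = 10, nR = 8, nGR = 0, tauDG = 1e-3,
                              tauDR = 2e-3, tauDGR = 2e-3, kappa = 5), tau)
  expect_true(all(gValues(mc0$cross) == 0))

  # single green component: amplitude 1/N as lag -> 0
  mc1 <- makeModelCurves(list(nG = 10, nR = 1e-12, nGR = 0, tauDG = 1e-3,
                              tauDR = 1e-3, tauDGR = 1e-3, kappa = 5),
                         c(1e-9, tau))
  expect_equal(gValues(mc1$autoG)[1L], 0.1, tolerance = 1e-5)
  expect_equal(gValues(mc1$autoG), modelG3D(c(1e-9, tau), 10, 1e-3, 5),
               tolerance = 1e-12)

  # noiseless triple through the downstream pipeline recovers the inputs
  vol <- defaultVolume()
  vEff <- effectiveVolume(vol)
  eq <- solveEquilibrium(100e-9, 100e-9, 80e-9)
  s <- 6.02214076e23 * vEff
  mc <- makeModelCurves(list(nG = eq@aFree * s, nR = eq@bFree * s,
                             nGR = eq@complex * s, tauDG = 1e-3,
                             tauDR = 1e-3, tauDGR = 1e-3, kappa = 5), tau)
  fits <- lapply(mc[c("autoG", "autoR", "cross")], fitCorrelation,
                 volume = vol)
  expect_true(all(vapply(fits, isConverged, logical(1))))
  res <- interactionFromAmplitudes(1 / nMolecules(fits$autoG),
                                   1 / nMolecules(fits$autoR),
                                   1 / nMolecules(fits$cross), vEff)
  expect_equal(kdValue(res), 80e-9, tolerance = 1e-9)
  expect_equal(res@cComplex, eq@complex, tolerance = 1e-9)

  # reproducible noise, and negative molecule numbers rejected
  mcN1 <- makeModelCurves(list(nG = 10, nR = 8, nGR = 2, tauDG = 1e-3,
                               tauDR = 2e-3, tauDGR = 2e-3, kappa = 5), tau,
                          noiseSd = 1e-3, seed = 3)
  mcN2 <- makeModelCurves(list(nG = 10, nR = 8, nGR = 2, tauDG = 1e-3,
                               tauDR = 2e-3, tauDGR = 2e-3, kappa = 5), tau,
                          noiseSd = 1e-3, seed = 3)
  expect_identical(gValues(mcN1$autoG), gValues(mcN2$autoG))
  expect_error(makeModelCurves(list(nG = -1, nR = 8, nGR = 2, tauDG = 1e-3,
                                    tauDR = 2e-3, tauDGR = 2e-3, kappa = 5),
                               tau), ">= 0")
})

test_that("degradation traces equal their closed form exactly", {
  # pure linear bleaching ramp (the translation-blocked control)
  ctrl <- simulateDegradationTrace(baseline = 2, bleachRate = 0.004,
                                   onsetFrame = 0L, decayRate = 0,
                                   noiseSd = 0, frameRange = c(-30L, 30L))
  fr <- frames(ctrl$trace)
  expect_equal(intensities(ctrl$trace), 2 * (1 - 0.004 * (fr + 30)))

  # constant before onset, strictly decreasing after
  dec <- simulateDegradationTrace(baseline = 1, bleachRate = 0,
                                  onsetFrame = 5L, decayRate = 0.1,
                                  noiseSd = 0, frameRange = c(-20L, 30L))
  v <- intensities(dec$trace)
  fr <- frames(dec$trace)
  expect_true(all(v[fr <= 5L] == 1))
  expect_true(all(diff(v[fr >= 5L]) < 0))
  expect_equal(v, ifelse(fr <= 5, 1, exp(-0.1 * (fr - 5))))

  # determinism of the noisy trace, and precondition checks
  n1 <- simulateDegradationTrace(noiseSd = 0.02, decayRate = 0.1,
                                 onsetFrame = 3L, seed = 11)
  n2 <- simulateDegradationTrace(noiseSd = 0.02, decayRate = 0.1,
                                 onsetFrame = 3L, seed = 11)
  expect_identical(intensities(n1$trace), intensities(n2$trace))
  expect_error(simulateDegradationTrace(bleachRate = 0.02,
                                        frameRange = c(0L, 60L),
                                        onsetFrame = 10L, decayRate = 0.1),
               "bleach")
  expect_error(simulateDegradationTrace(onsetFrame = 100L, decayRate = 0.1,
                                        frameRange = c(-10L, 10L)),
               "onsetFrame")
  expect_equal(truthParams(n1$truth)$onset_frame, 3L)
})

test_that("line-profile images are Gaussian sums with stored truth", {
  # no peaks: constant background
  img0 <- simulateLineProfileImage(background = 3, noiseSd = 0,
                                   imageSize = c(32L, 32L))
  expect_true(all(img0$images$green == 3))

  # three collinear peaks: profile maxima at the stored centres (+-1 px)
  peaks <- list(list(center = c(16, 32), sd = 2.5, amplitude = 5,
                     channel = "green"),
                list(center = c(32, 32), sd = 3.0, amplitude = 3,
                     channel = "green"),
                list(center = c(48, 32), sd = 2.5, amplitude = 5,
                     channel = "green"))
  res <- simulateLineProfileImage(peaks, background = 1, noiseSd = 0,
                                  imageSize = c(64L, 64L))
  prof <- extractLineProfile(res$images$green, c(8, 32), c(56, 32),
                             thicknessPx = 10L, background = 1)
  v <- prof@values
  locmax <- which(diff(sign(diff(v))) == -2) + 1L
  found <- prof@positions[locmax] + 8    # axis starts at x = 8
  expect_equal(length(found), 3L)
  expect_true(all(abs(sort(found) - c(16, 32, 48)) <= 1))

  # analytic oracle at the central row, thickness 1
  prof1 <- extractLineProfile(res$images$green, c(8, 32), c(56, 32),
                              thicknessPx = 1L, background = 0)
  xs <- 8 + prof1@positions
  oracle <- 1 +
    5 * exp(-(xs - 16)^2 / (2 * 2.5^2)) +
    3 * exp(-(xs - 32)^2 / (2 * 3.0^2)) +
    5 * exp(-(xs - 48)^2 / (2 * 2.5^2))
  expect_equal(prof1@values, oracle, tolerance = 1e-12)

  # determinism with noise; invalid peaks rejected
  na <- simulateLineProfileImage(peaks, noiseSd = 0.5, seed = 4)
  nb <- simulateLineProfileImage(peaks, noiseSd = 0.5, seed = 4)
  expect_identical(na$images$green, nb$images$green)
  expect_error(simulateLineProfileImage(list(list(center = c(99, 2), sd = 1,
                                                  amplitude = 1)),
                                        imageSize = c(32L, 32L)), "outside")
  expect_error(simulateLineProfileImage(list(list(center = c(5, 5), sd = 0,
                                                  amplitude = 1))), "sd")
})
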