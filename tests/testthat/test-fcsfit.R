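# Diffusion models, nonlinear fitting, and unit conversions.

test_that("modelG3D matches its closed form", {
  expect_equal(modelG3D(0, n = 10, tauD = 1e-3, kappa = 5), 0.1)
  # at tau = tauD: (1/n) * 1/2 * (1 + 1/kappa^2)^(-1/2)
  expect_equal(modelG3D(1e-3, n = 10, tauD = 1e-3, kappa = 5),
               0.05 / sqrt(1.04))
  expect_equal(modelG3D(1e-3, n = 10, tauD = 1e-3, kappa = 5), 0.04903,
               tolerance = 1e-4)
  # strictly decreasing in tau
  for (kappa in c(2, 5, 10)) {
    g <- modelG3D(logLags(1e-6, 1, 200), n = 3, tauD = 2e-3, kappa = kappa)
    expect_true(all(diff(g) < 0))
  }
  # two-component model collapses to one component at equal tauD
  tau <- logLags()
  expect_equal(modelG3DTwo(tau, 10, 0.3, 1e-3, 1e-3, 5),
               modelG3D(tau, 10, 1e-3, 5))
})

test_that("noiseless model curves are fitted back exactly", {
  vol <- defaultVolume()
  tau <- logLags(1e-5, 0.1, 80)
  curve <- correlationCurve(tau, modelG3D(tau, 13.4, 1.55e-3, 5), "auto_g")
  fit <- fitCorrelation(curve, vol)
  expect_true(isConverged(fit))
  expect_equal(nMolecules(fit), 13.4, tolerance = 1e-6)
  expect_equal(tauD(fit), 1.55e-3, tolerance = 1e-6)
  expect_equal(dCoef(fit), diffusionCoefficient(1.55e-3, 0.2),
               tolerance = 1e-6)
})

test_that("fit round trip holds across randomised parameter draws", {
  vol <- defaultVolume()
  tau <- logLags(1e-5, 0.1, 60)
  draws <- withr::with_seed(42, data.frame(
    n = exp(runif(25, log(0.5), log(200))),
    tauD = exp(runif(25, log(5e-5), log(5e-3)))))
  for (i in seq_len(nrow(draws))) {
    curve <- correlationCurve(tau, modelG3D(tau, draws$n[i], draws$tauD[i], 5),
                              "auto_g")
    fit <- fitCorrelation(curve, vol)
    expect_true(isConverged(fit))
    expect_equal(nMolecules(fit), draws$n[i], tolerance = 1e-6)
    expect_equal(tauD(fit), draws$tauD[i], tolerance = 1e-6)
  }
})

test_that("two-component fits reproduce a two-component curve", {
  vol <- defaultVolume()
  tau <- logLags(1e-6, 0.5, 100)
  gtrue <- modelG3DTwo(tau, 20, 0.4, 5e-5, 5e-3, 5)
  fit <- fitCorrelation(correlationCurve(tau, gtrue, "auto_g"), vol,
                        "two_component_3d")
  expect_true(isConverged(fit))
  refit <- modelG3DTwo(tau, nMolecules(fit), fit@fraction, tauD(fit)[1L],
                       tauD(fit)[2L], 5)
  expect_lt(max(abs(refit - gtrue)), 1e-8)
})

test_that("an amplitude-free curve yields an explicit no-fit signal", {
  vol <- defaultVolume()
  flat <- correlationCurve(logLags(1e-5, 0.1, 20), rep(0, 20), "auto_g")
  fit <- fitCorrelation(flat, vol)
  expect_false(isConverged(fit))
  expect_true(is.na(nMolecules(fit)))
  expect_match(fit@note, "amplitude")
})

test_that("effective volume follows the Gaussian-volume formula", {
  expect_equal(effectiveVolume(observationVolume(0.2, 5)) * 1e15,
               pi^1.5 * 0.04 * 1.0, tolerance = 1e-12)
  expect_equal(effectiveVolume(observationVolume(0.2, 5)) * 1e15, 0.2227,
               tolerance = 1e-3)
  expect_error(observationVolume(1, 1), "kappa")
  expect_equal(effectiveVolume(observationVolume(0.4, 5)),
               8 * effectiveVolume(observationVolume(0.2, 5)))
})

test_that("concentration conversions are exact and invertible", {
  vEff <- effectiveVolume(observationVolume(0.2, 5))
  expect_equal(concentrationFromN(13.41, vEff) * 1e9, 100, tolerance = 1e-3)
  expect_equal(concentrationFromN(0, vEff), 0)
  for (c0 in c(1e-9, 100e-9, 5e-6)) {
    expect_equal(concentrationFromN(nFromConcentration(c0, vEff), vEff), c0,
                 tolerance = 1e-12)
  }
})

test_that("diffusion coefficient and Stokes-Einstein conversions check out", {
  expect_equal(diffusionCoefficient(1.553e-3, 0.2), 6.44, tolerance = 1e-3)
  expect_equal(diffusionCoefficient(4 * 1.553e-3, 0.2),
               diffusionCoefficient(1.553e-3, 0.2) / 4)
  env <- sampleEnvironment(310, 1e-3)
  expect_equal(hydrodynamicRadius(16.22, env), 14.0, tolerance = 1e-3)
  envHalf <- sampleEnvironment(310, 5e-4)
  expect_equal(hydrodynamicRadius(16.22, envHalf),
               2 * hydrodynamicRadius(16.22, env))
  expect_equal(diffusionFromRadius(hydrodynamicRadius(6.44, env), env), 6.44,
               tolerance = 1e-12)
})

test_that("volume calibration inverts a known-dye fit", {
  # dye with D = 400 um^2/s in a w_xy = 0.2 um, kappa = 5 volume:
  # tauD = w^2 / (4 D) = 2.5e-5 s
  tau <- logLags(5e-7, 5e-3, 80)
  curve <- correlationCurve(tau, modelG3D(tau, 5, 2.5e-5, 5), "auto_g")
  vol <- calibrateVolume(curve, knownD = 400)
  expect_equal(waistXY(vol), 0.2, tolerance = 1e-6)
  expect_equal(structureParameter(vol), 5, tolerance = 1e-4)
  expect_equal(sqrt(4 * 400 * 2.5e-5), 0.2)
  expect_error(calibrateVolume(curve, knownD = -1), "knownD")
})
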