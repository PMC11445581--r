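# Degradation-trace pipeline: normalisation, bleaching correction,
# smoothing, onset and maximum-speed detection, profiles and compartments.

test_that("normalisation pins the reference frame to 1", {
  tr <- degradationTrace(-30:10, rep(2, 41), background = 0)
  norm <- normalizeTrace(tr, -20L)
  expect_equal(intensities(norm), rep(1, 41))

  tr2 <- degradationTrace(-30:10, seq(4, 2, length.out = 41), background = 2)
  norm2 <- normalizeTrace(tr2, -20L)
  expect_equal(intensities(norm2)[match(-20L, frames(norm2))], 1)
  # idempotent once normalised (background already removed)
  expect_equal(intensities(normalizeTrace(norm2, -20L)), intensities(norm2))

  expect_error(normalizeTrace(tr, 50L), "not present")
  trBad <- degradationTrace(-30:10, rep(1, 41), background = 5)
  expect_error(normalizeTrace(trBad, -20L), "> 0")
})

test_that("control-based bleach correction recovers the decay closed form", {
  sim <- simulateDegradationTrace(baseline = 100, bleachRate = 0.003,
                                  onsetFrame = 2L, decayRate = 0.08,
                                  noiseSd = 0, frameRange = c(-35L, 30L))
  ctrl <- simulateDegradationTrace(baseline = 80, bleachRate = 0.003,
                                   onsetFrame = 2L, decayRate = 0,
                                   noiseSd = 0, frameRange = c(-35L, 30L))
  normT <- normalizeTrace(sim$trace, -20L)
  normC <- normalizeTrace(ctrl$trace, -20L)
  corrected <- bleachCorrectControl(normT, normC)
  fr <- frames(corrected)
  expect_equal(intensities(corrected),
               ifelse(fr <= 2, 1, exp(-0.08 * (fr - 2))), tolerance = 1e-9)

  # self-correction gives a constant 1; unit control is the identity
  expect_equal(intensities(bleachCorrectControl(normC, normC)),
               rep(1, length(fr)))
  unit <- degradationTrace(fr, rep(1, length(fr)))
  expect_equal(intensities(bleachCorrectControl(normT, unit)),
               intensities(normT))
  short <- degradationTrace(-5:5, rep(1, 11))
  expect_error(bleachCorrectControl(normT, short), "same frames")
})

test_that("linear bleach correction flattens a noiseless control exactly", {
  ctrl <- simulateDegradationTrace(baseline = 1, bleachRate = 0.002,
                                   onsetFrame = 0L, decayRate = 0,
                                   noiseSd = 0, frameRange = c(-40L, 40L))
  norm <- normalizeTrace(ctrl$trace, -20L)
  flat <- bleachCorrectLinear(norm, c(-30L, -25L))
  expect_equal(intensities(flat), rep(1, length(frames(flat))),
               tolerance = 1e-9)

  # already-flat trace is unchanged
  unit <- degradationTrace(-40:40, rep(1, 81))
  expect_equal(intensities(bleachCorrectLinear(unit)), rep(1, 81),
               tolerance = 1e-12)

  # degrading trace: pre-onset residual slope ~ 0 after correction
  sim <- simulateDegradationTrace(baseline = 1, bleachRate = 0.002,
                                  onsetFrame = 5L, decayRate = 0.1,
                                  noiseSd = 0, frameRange = c(-40L, 40L))
  corr <- bleachCorrectLinear(normalizeTrace(sim$trace, -20L))
  pre <- intensities(corr)[frames(corr) <= 0]
  expect_lt(abs(slopeOracle(pre)), 1e-3)

  expect_error(bleachCorrectLinear(norm, c(-100L, -95L)), "window")
})

test_that("trailing moving average has exact arithmetic", {
  expect_identical(movingAverage(c(3, 1, 4), 1L), c(3, 1, 4))
  expect_equal(movingAverage(rep(2.5, 10), 4L), rep(2.5, 7))
  expect_equal(movingAverage(c(1, 1, 1, 0), 4L), 0.75)
  expect_equal(movingAverage(1:6, 3L), c(2, 3, 4, 5))
})

test_that("onset detection matches the hand-computed worked example", {
  # 1.0 up to frame -10, then falling 0.1/frame; no smoothing
  fr <- -30:0
  vals <- ifelse(fr <= -10, 1, 1 - 0.1 * (fr + 10))
  tr <- degradationTrace(fr, vals)
  res <- detectOnset(tr, smoothWindow = 1L)
  expect_identical(onsetFrame(res), -11L)
  expect_equal(initialSpeed(res), -0.08, tolerance = 1e-12)

  # the two preceding windows sit at -0.02 and exactly -0.05: the strict
  # threshold must not trigger on either
  w13 <- vals[match(-13:-9, fr)]
  w12 <- vals[match(-12:-8, fr)]
  expect_equal(slopeOracle(w13), -0.02, tolerance = 1e-12)
  expect_equal(slopeOracle(w12), -0.05, tolerance = 1e-12)
  expect_equal(initialSpeed(res), slopeOracle(vals[match(-11:-7, fr)]),
               tolerance = 1e-12)

  # flat trace: absence is a valid result
  flat <- degradationTrace(-20:20, rep(1, 41))
  resFlat <- detectOnset(flat)
  expect_true(is.na(onsetFrame(resFlat)))
  expect_true(is.na(initialSpeed(resFlat)))
})

test_that("onset window slopes equal independent least-squares fits", {
  sim <- simulateDegradationTrace(baseline = 1, bleachRate = 0,
                                  onsetFrame = 0L, decayRate = 0.12,
                                  noiseSd = 0, frameRange = c(-15L, 15L))
  res <- detectOnset(sim$trace, smoothWindow = 4L)
  sm <- movingAverage(intensities(sim$trace), 4L)
  smFrames <- frames(sim$trace)[4:length(frames(sim$trace))]
  i <- match(onsetFrame(res), smFrames)
  expect_equal(initialSpeed(res), slopeOracle(sm[i:(i + 4L)]),
               tolerance = 1e-12)
})

test_that("max speed is exact on linear decays and zero on constants", {
  lin <- degradationTrace(-10:20, 1 - 0.08 * (-10:20 + 10))
  res <- maxDegradationSpeed(lin)
  expect_equal(maxSpeed(res), -0.08, tolerance = 1e-12)

  # exact ties (binary-representable slope) resolve to the earliest
  # derivative frame: window start + 1 after trailing smoothing
  linExact <- degradationTrace(-10:20, 8 - 0.125 * (-10:20 + 10))
  resExact <- maxDegradationSpeed(linExact)
  expect_identical(maxSpeed(resExact), -0.125)
  expect_identical(resExact@maxSpeedFrame, frames(linExact)[5L])

  const <- degradationTrace(-10:20, rep(0.7, 31))
  expect_equal(maxSpeed(maxDegradationSpeed(const)), 0)
})

test_that("max speed tracks the analytic steepest-chord oracle", {
  for (k in c(0.05, 0.1, 0.2)) {
    sim <- simulateDegradationTrace(baseline = 1, bleachRate = 0,
                                    onsetFrame = 0L, decayRate = k,
                                    noiseSd = 0, frameRange = c(-20L, 30L))
    est <- maxSpeed(maxDegradationSpeed(sim$trace, smoothWindow = 4L))
    oracle <- steepest5Slope(movingAverage(intensities(sim$trace), 4L))
    expect_equal(est, oracle, tolerance = 0.1)
    expect_lt(est, 0)
  }
})

test_that("detected onset stays within 2 frames of truth under noise", {
  hits <- 0L
  for (seed in 1:100) {
    sim <- simulateDegradationTrace(baseline = 1, bleachRate = 0,
                                    onsetFrame = 3L, decayRate = 0.1,
                                    noiseSd = 0.02,
                                    frameRange = c(-40L, 40L), seed = seed)
    res <- detectOnset(sim$trace, smoothWindow = 4L)
    if (!is.na(onsetFrame(res)) && abs(onsetFrame(res) - 3L) <= 2L)
      hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("line profiles interpolate exactly on grid-aligned input", {
  img <- matrix(7, 20, 30)
  prof <- extractLineProfile(img, c(2, 10), c(28, 10), thicknessPx = 5L)
  expect_equal(prof@values, rep(7, length(prof@positions)))

  img2 <- matrix(seq_len(20 * 30), 20, 30)   # arbitrary integer image
  prof2 <- extractLineProfile(img2, c(3, 12), c(25, 12), thicknessPx = 1L)
  expect_equal(prof2@values, img2[12, 3:25])

  expect_error(extractLineProfile(img, c(2, 10), c(2, 10)), "differ")
  expect_error(extractLineProfile(img, c(2, 2), c(29, 2), thicknessPx = 10L),
               "outside")
})

test_that("min-max scaling attains 0 and 1 and is idempotent", {
  expect_equal(minmaxScale(c(2, 4, 6)), c(0, 0.5, 1))
  v <- withr::with_seed(1, runif(50))
  sc <- minmaxScale(v)
  expect_equal(range(sc), c(0, 1))
  expect_equal(minmaxScale(sc), sc)
  expect_error(minmaxScale(rep(3, 5)), "constant")
})

test_that("compartment means split signal by mask", {
  img <- matrix(4, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:5, 3:5] <- TRUE
  m <- compartmentMeans(img, mask)
  expect_equal(unname(m["meanInside"]), unname(m["meanOutside"]))

  img2 <- mask * 5 + 1
  m2 <- compartmentMeans(img2, mask, background = 1)
  expect_equal(unname(m2["meanInside"]), 5)
  expect_equal(unname(m2["meanOutside"]), 0)

  expect_error(compartmentMeans(img, matrix(TRUE, 10, 10)), "mask")
  expect_error(compartmentMeans(img, matrix(FALSE, 10, 10)), "mask")
})
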