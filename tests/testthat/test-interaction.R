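# Mass-action equilibrium and the FCCS amplitude -> concentration -> Kd
# algebra.

test_that("equilibrium solver returns the physical quadratic root", {
  # quadratic oracle evaluated directly
  A <- 100e-9; B <- 100e-9; K <- 80e-9
  oracle <- ((A + B + K) - sqrt((A + B + K)^2 - 4 * A * B)) / 2
  eq <- solveEquilibrium(A, B, K)
  expect_equal(eq@complex, oracle, tolerance = 1e-12)
  expect_equal(eq@complex * 1e9, 42.02, tolerance = 1e-4)
  expect_equal(eq@aFree * 1e9, 57.98, tolerance = 1e-4)

  # infinite-affinity limit and an absent partner
  eq0 <- solveEquilibrium(100e-9, 100e-9, 0)
  expect_equal(eq0@complex, 100e-9)
  expect_equal(eq0@aFree, 0)
  eqA0 <- solveEquilibrium(0, 50e-9, 80e-9)
  expect_equal(eqA0@complex, 0)
  expect_equal(eqA0@bFree, 50e-9)
})

test_that("equilibrium states conserve mass and satisfy mass action", {
  draws <- withr::with_seed(7, data.frame(
    a = 10^runif(100, -10, -6), b = 10^runif(100, -10, -6),
    kd = 10^runif(100, -10, -6)))
  for (i in seq_len(nrow(draws))) {
    eq <- solveEquilibrium(draws$a[i], draws$b[i], draws$kd[i])
    expect_equal(eq@aFree + eq@complex, draws$a[i],
                 tolerance = 1e-12)
    expect_equal(eq@bFree + eq@complex, draws$b[i],
                 tolerance = 1e-12)
    expect_equal(eq@aFree * eq@bFree, draws$kd[i] * eq@complex,
                 tolerance = 1e-9)
    expect_true(all(c(eq@aFree, eq@bFree, eq@complex) >= 0))
  }
})

test_that("amplitude relations invert the forward model exactly", {
  vEff <- effectiveVolume(defaultVolume())
  eq <- solveEquilibrium(100e-9, 100e-9, 80e-9)
  amp <- equilibriumAmplitudes(eq, vEff)
  expect_equal(unname(amp["gG0"]), 0.07455, tolerance = 1e-3)
  expect_equal(unname(amp["gX0"]), 0.03133, tolerance = 1e-3)

  conc <- amplitudesToConcentrations(amp[["gG0"]], amp[["gR0"]], amp[["gX0"]],
                                     vEff)
  expect_true(conc$valid)
  expect_equal(conc$cComplex, eq@complex, tolerance = 1e-9)
  expect_equal(conc$cGreenFree, eq@aFree, tolerance = 1e-9)
  expect_equal(conc$cRedFree, eq@bFree, tolerance = 1e-9)
  expect_equal(kdFromConcentrations(conc$cGreenFree, conc$cRedFree,
                                    conc$cComplex), 80e-9, tolerance = 1e-9)

  # no cross-correlation (the G2-phase case): everything is free
  conc0 <- amplitudesToConcentrations(amp[["gG0"]], amp[["gR0"]], 0, vEff)
  expect_equal(conc0$cComplex, 0)
  expect_equal(conc0$cGreenFree, 1 / (6.02214076e23 * vEff * amp[["gG0"]]))
})

test_that("kd handles sentinels and scales homogeneously", {
  expect_equal(kdFromConcentrations(57.98e-9, 57.98e-9, 42.02e-9) * 1e9, 80,
               tolerance = 2e-3)
  expect_identical(kdFromConcentrations(1e-9, 1e-9, 0), Inf)
  k1 <- kdFromConcentrations(3e-9, 5e-9, 2e-9)
  expect_equal(kdFromConcentrations(3e-8, 5e-8, 2e-8), 10 * k1)
  expect_error(kdFromConcentrations(-1e-9, 1e-9, 1e-9))
})

test_that("cross-correlation quotient reports bound fractions", {
  expect_equal(unname(crossCorrelationQuotient(0.1, 0.1, 0)["q"]), 0)
  vEff <- effectiveVolume(defaultVolume())
  amp <- equilibriumAmplitudes(solveEquilibrium(100e-9, 100e-9, 80e-9), vEff)
  quo <- crossCorrelationQuotient(amp[["gG0"]], amp[["gR0"]], amp[["gX0"]])
  expect_equal(unname(quo["boundFractionG"]), 0.4202, tolerance = 1e-3)
  expect_equal(unname(quo["boundFractionR"]), 0.4202, tolerance = 1e-3)
  # fully bound, equal totals: q = 1
  ampSat <- equilibriumAmplitudes(solveEquilibrium(100e-9, 100e-9, 0), vEff)
  quoSat <- crossCorrelationQuotient(ampSat[["gG0"]], ampSat[["gR0"]],
                                     ampSat[["gX0"]])
  expect_equal(unname(quoSat["q"]), 1)
})

test_that("inferred kd decreases strictly with the cross amplitude", {
  vEff <- effectiveVolume(defaultVolume())
  gG0 <- 0.075; gR0 <- 0.08
  gx <- seq(0.005, 0.05, length.out = 20)
  kds <- vapply(gx, function(g) {
    conc <- amplitudesToConcentrations(gG0, gR0, g, vEff)
    kdFromConcentrations(conc$cGreenFree, conc$cRedFree, conc$cComplex)
  }, numeric(1))
  expect_true(all(diff(kds) < 0))
})

test_that("inconsistent amplitudes flag the result and withhold kd", {
  vEff <- effectiveVolume(defaultVolume())
  # cross amplitude larger than both autos implies negative free pools
  res <- interactionFromAmplitudes(0.05, 0.05, 0.2, vEff)
  expect_false(res@valid)
  expect_true(is.na(kdValue(res)))
  expect_lt(res@cGreenFree, 0)    # reported unclipped
  # a consistent set passes through
  amp <- equilibriumAmplitudes(solveEquilibrium(100e-9, 100e-9, 80e-9), vEff)
  res2 <- interactionFromAmplitudes(amp[["gG0"]], amp[["gR0"]], amp[["gX0"]],
                                    vEff)
  expect_true(res2@valid)
  expect_equal(kdValue(res2), 80e-9, tolerance = 1e-9)
})
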