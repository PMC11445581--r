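# shared fixtures: all synthetic, built in code

defaultVolume <- function() observationVolume(wXY = 0.2, kappa = 5)

# log-spaced lag grid spanning the diffusion-time decades
logLags <- function(from = 1e-5, to = 0.1, n = 60) {
  exp(seq(log(from), log(to), length.out = n))
}

# a seeded random Poisson photon trace
randomTrace <- function(n, mean = 5, seed = 1, binWidth = 1e-4,
                        channel = "green") {
  withr::with_seed(seed,
    photonCountTrace(rpois(n, mean), binWidth, channel))
}

# least-squares slope of y on consecutive integers (independent oracle for
# the sliding-window slopes)
slopeOracle <- function(y) {
  x <- seq_along(y)
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

# steepest 5-point least-squares slope of a vector (analytic oracle for
# maximum degradation speed)
steepest5Slope <- function(values) {
  n <- length(values)
  min(vapply(seq_len(n - 4L), function(i)
    slopeOracle(values[i:(i + 4L)]), numeric(1)))
}
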