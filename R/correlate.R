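# Correlation estimators.
#
# The normalised fluctuation correlation at an integer bin offset k is
# estimated over all overlapping pairs with per-lag means of each truncated
# segment:
#
#   G(k) = mean(a[1..n-k] * b[k+1..n]) / (mean(a[1..n-k]) * mean(b[k+1..n])) - 1
#
# which equals <dIa dIb> / (<Ia><Ib>) with dI = I - <I>. The truncated-
# segment means remove the linear-trend bias of a single global mean. Lag 0
# (shot-noise dominated) is never reported.

.checkTracePair <- function(a, b) {
  stopifnot(is(a, "PhotonCountTrace"), is(b, "PhotonCountTrace"))
  validObject(a); validObject(b)
  if (abs(a@binWidth - b@binWidth) > 1e-15 * a@binWidth)
    stop("traces must share the same bin width")
  if (length(a@counts) != length(b@counts))
    stop("traces must have the same length")
  if (all(a@counts == 0) || all(b@counts == 0))
    stop("all-zero trace: correlation is undefined (zero mean intensity)")
  invisible(TRUE)
}

.inferKind <- function(a, b) {
  if (!identical(a@counts, b@counts)) return("cross")
  if (identical(a@channel, "red")) "auto_r" else "auto_g"
}

# core estimator on plain numeric vectors, integer bin lags
.gAtLags <- function(x, y, lagBins) {
  n <- length(x)
  vapply(lagBins, function(k) {
    ia <- x[seq_len(n - k)]
    ib <- y[seq.int(k + 1L, n)]
    ma <- mean(ia); mb <- mean(ib)
    if (ma == 0 || mb == 0)
      stop("zero mean in truncated segment: correlation undefined at lag ", k)
    mean(ia * ib) / (ma * mb) - 1
  }, numeric(1))
}

#' Brute-force correlation estimator (reference oracle)
#'
#' Computes the exact sample estimator of the normalised fluctuation
#' (cross-)correlation at the requested integer bin offsets, over all
#' overlapping pairs. With \code{b = a} this is the autocorrelation. This
#' is the slow, transparent reference against which the multi-tau
#' correlator is verified.
#'
#' @param a,b \linkS4class{PhotonCountTrace} objects of equal length and
#'   bin width.
#' @param lagBins integer bin offsets, all >= 1 and < trace length.
#' @param kind curve kind; inferred from the traces when NULL.
#' @return A \linkS4class{CorrelationCurve}.
#' @seealso [correlateMultiTau()]
#' @export
correlateDirect <- function(a, b = a, lagBins, kind = NULL) {
  .checkTracePair(a, b)
  lagBins <- as.integer(lagBins)
  if (!length(lagBins) || any(lagBins < 1L) ||
      any(lagBins >= length(a@counts)) || is.unsorted(lagBins, strictly = TRUE))
    stop("lagBins must be strictly increasing integers in [1, length - 1]")
  g <- .gAtLags(a@counts, b@counts, lagBins)
  correlationCurve(lagBins * a@binWidth, g,
                   kind = if (is.null(kind)) .inferKind(a, b) else kind)
}

# multi-tau lag grid for a trace of n bins: first 2m native lags, then m
# lags per octave with bin width doubled by pairwise averaging.
# Returns a list of blocks: each with lagBins (in current-octave bins),
# level (octave index, 0 = native).
.multitauGrid <- function(n, m, maxLagBins = Inf) {
  blocks <- list()
  if (n > 2L) {
    first <- seq_len(min(2L * m, n - 1L))
    first <- first[first <= maxLagBins]
    if (length(first))
      blocks[[1L]] <- list(level = 0L, lagBins = first)
  }
  level <- 1L
  nlev <- n %/% 2L
  while (nlev > 2L * m + 1L) {
    lagBins <- seq.int(m + 1L, 2L * m)
    lagBins <- lagBins[lagBins < nlev & lagBins * 2^level <= maxLagBins]
    if (!length(lagBins)) break
    blocks[[length(blocks) + 1L]] <- list(level = level, lagBins = lagBins)
    level <- level + 1L
    nlev <- nlev %/% 2L
  }
  blocks
}

.rebinPair <- function(x) {
  n2 <- length(x) %/% 2L
  x <- x[seq_len(2L * n2)]
  (x[seq.int(1L, 2L * n2, by = 2L)] + x[seq.int(2L, 2L * n2, by = 2L)]) / 2
}

.multitauG <- function(x, y, blocks) {
  out <- list()
  level <- 0L
  for (blk in blocks) {
    while (level < blk$level) {
      x <- .rebinPair(x); y <- .rebinPair(y)
      level <- level + 1L
    }
    out[[length(out) + 1L]] <-
      list(lags = blk$lagBins * 2^blk$level, g = .gAtLags(x, y, blk$lagBins))
  }
  list(lagsNative = unlist(lapply(out, `[[`, "lags")),
       g = unlist(lapply(out, `[[`, "g")))
}

#' Multi-tau correlator
#'
#' Production correlator with a quasi-logarithmic lag grid: the first
#' \code{2 * pointsPerOctave} lags at native bin width, then
#' \code{pointsPerOctave} lags per octave with the bin width doubled by
#' pairwise averaging (averaging, not summing, so the normalised estimator
#' is unchanged in expectation). Values at the native-resolution lags are
#' computed by the same estimator as [correlateDirect()] and agree with it
#' exactly.
#'
#' @inheritParams correlateDirect
#' @param pointsPerOctave lags per octave (the correlator's m; default 8).
#' @param maxLag optional maximum lag in seconds.
#' @return A \linkS4class{CorrelationCurve}.
#' @export
correlateMultiTau <- function(a, b = a, pointsPerOctave = 8, kind = NULL,
                              maxLag = Inf) {
  .checkTracePair(a, b)
  m <- as.integer(pointsPerOctave)
  if (m < 1L) stop("pointsPerOctave must be >= 1")
  n <- length(a@counts)
  maxLagBins <- if (is.finite(maxLag)) floor(maxLag / a@binWidth) else Inf
  blocks <- .multitauGrid(n, m, maxLagBins)
  if (!length(blocks)) stop("trace too short for the requested lag grid")
  res <- .multitauG(a@counts, b@counts, blocks)
  correlationCurve(res$lagsNative * a@binWidth, res$g,
                   kind = if (is.null(kind)) .inferKind(a, b) else kind)
}

#' Per-lag noise of a correlation curve by segmenting
#'
#' Splits the trace pair into \code{nSegments} equal-length segments,
#' correlates each segment on a common multi-tau grid (built for the
#' segment length, so every lag fits in a segment), and attaches
#' sd(tau) = sd over segments / sqrt(nSegments) to the full-trace curve at
#' those lags. The returned g values are the full-trace estimates.
#'
#' @inheritParams correlateMultiTau
#' @param nSegments number of segments (>= 2).
#' @return A \linkS4class{CorrelationCurve} with the \code{sd} slot filled.
#' @export
estimateCurveNoise <- function(a, b = a, nSegments = 10, pointsPerOctave = 8,
                               kind = NULL) {
  .checkTracePair(a, b)
  nSegments <- as.integer(nSegments)
  if (nSegments < 2L) stop("need at least 2 segments")
  n <- length(a@counts)
  segLen <- n %/% nSegments
  m <- as.integer(pointsPerOctave)
  blocks <- .multitauGrid(segLen, m)
  if (!length(blocks))
    stop("segments shorter than the smallest usable lag grid; reduce nSegments")
  maxLagNative <- max(unlist(lapply(blocks, function(b) b$lagBins * 2^b$level)))
  if (maxLagNative >= segLen)
    stop("segment length must exceed the maximum lag")
  full <- .multitauG(a@counts, b@counts, blocks)
  segG <- vapply(seq_len(nSegments), function(i) {
    idx <- seq.int((i - 1L) * segLen + 1L, i * segLen)
    .multitauG(a@counts[idx], b@counts[idx], blocks)$g
  }, numeric(length(full$g)))
  sdv <- apply(segG, 1L, stats::sd) / sqrt(nSegments)
  correlationCurve(full$lagsNative * a@binWidth, full$g,
                   kind = if (is.null(kind)) .inferKind(a, b) else kind,
                   sd = sdv)
}
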