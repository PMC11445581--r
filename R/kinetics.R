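# Single-cell degradation-kinetics pipeline: normalisation, bleaching
# correction, smoothing, maximum degradation speed and onset detection.
#
# Conventions: anaphase = frame 0, "N frames prior to anaphase" = frame -N.
# Slopes are in normalised intensity per frame (the onset threshold is
# applied per frame regardless of the acquisition interval; frameInterval
# is carried in the trace metadata so callers may rescale).

.traceValue <- function(trace, frame) {
  i <- match(frame, trace@frames)
  if (is.na(i)) stop("frame ", frame, " not present in trace")
  i
}

.bgVector <- function(trace) {
  if (length(trace@background) == 1L)
    rep(trace@background, length(trace@frames)) else trace@background
}

# least-squares slope of y against consecutive integer x
.lsqSlope <- function(y) {
  n <- length(y)
  x <- seq_len(n) - (n + 1) / 2
  sum(x * (y - mean(y))) / sum(x^2)
}

#' Normalise a degradation trace to a reference frame
#'
#' out(t) = (I(t) - bg) / (I(ref) - bg), so out(referenceFrame) = 1
#' exactly. The reference is conventionally 20 or 25 frames before
#' anaphase (frame -20 / -25), before degradation starts.
#'
#' @param trace a \linkS4class{DegradationTrace}.
#' @param referenceFrame frame whose (background-subtracted) value becomes
#'   1; must be present in the trace.
#' @param subtractBackground subtract the trace's background first
#'   (default TRUE).
#' @return the normalised \linkS4class{DegradationTrace} (background 0).
#' @export
normalizeTrace <- function(trace, referenceFrame = -20L,
                           subtractBackground = TRUE) {
  stopifnot(is(trace, "DegradationTrace"))
  validObject(trace)
  i <- .traceValue(trace, as.integer(referenceFrame))
  vals <- trace@intensities - if (subtractBackground) .bgVector(trace) else 0
  ref <- vals[i]
  if (!is.finite(ref) || ref <= 0)
    stop("reference value (after background subtraction) must be > 0")
  degradationTrace(trace@frames, vals / ref, background = 0,
                   compartment = trace@compartment,
                   frameInterval = trace@frameInterval, cellId = trace@cellId)
}

#' Bleach-correct a trace with a matched control measurement
#'
#' Divides the trace by a normalised control trace acquired at the same
#' subcellular location in cells where degradation is blocked
#' (cycloheximide + MG132), so only photobleaching remains in the control.
#'
#' @param trace normalised \linkS4class{DegradationTrace}.
#' @param control normalised control trace over the same frame range, all
#'   values > 0.
#' @return the corrected \linkS4class{DegradationTrace}.
#' @export
bleachCorrectControl <- function(trace, control) {
  stopifnot(is(trace, "DegradationTrace"), is(control, "DegradationTrace"))
  validObject(trace); validObject(control)
  if (!identical(trace@frames, control@frames))
    stop("trace and control must cover the same frames")
  if (any(control@intensities <= 0))
    stop("control trace must be strictly positive")
  degradationTrace(trace@frames, trace@intensities / control@intensities,
                   background = 0, compartment = trace@compartment,
                   frameInterval = trace@frameInterval, cellId = trace@cellId)
}

#' Bleach-correct a trace with a pre-anaphase straight-line fit
#'
#' Fits a least-squares line to the trace inside \code{fitWindow}
#' (inclusive; the default [-30, -25] covers 6 pre-degradation frames),
#' extrapolates it to every frame, and divides the trace by it.
#'
#' @param trace normalised \linkS4class{DegradationTrace}.
#' @param fitWindow integer c(first, last) frames of the fit window; must
#'   lie inside the trace and precede the degradation onset.
#' @return the corrected \linkS4class{DegradationTrace}.
#' @export
bleachCorrectLinear <- function(trace, fitWindow = c(-30L, -25L)) {
  stopifnot(is(trace, "DegradationTrace"))
  validObject(trace)
  fitWindow <- as.integer(fitWindow)
  if (fitWindow[2L] <= fitWindow[1L]) stop("fitWindow must be increasing")
  idx <- match(seq.int(fitWindow[1L], fitWindow[2L]), trace@frames)
  if (anyNA(idx)) stop("fit window not fully inside the trace")
  fit <- stats::lm.fit(cbind(1, trace@frames[idx]), trace@intensities[idx])
  line <- fit$coefficients[1L] + fit$coefficients[2L] * trace@frames
  if (any(line <= 0))
    stop("fitted bleach line reaches <= 0 inside the trace range")
  degradationTrace(trace@frames, trace@intensities / line, background = 0,
                   compartment = trace@compartment,
                   frameInterval = trace@frameInterval, cellId = trace@cellId)
}

#' Trailing moving average
#'
#' Mean over the trailing window (values at t - window + 1 ... t); only
#' positions with full support are retained, so the first window - 1
#' entries are dropped and frame labels are preserved for the rest.
#'
#' @param values numeric vector, length >= window.
#' @param window window size (>= 1; 1 = identity). The pipeline default
#'   is 4.
#' @return the smoothed values (length length(values) - window + 1).
#' @export
movingAverage <- function(values, window = 4L) {
  window <- as.integer(window)
  stopifnot(window >= 1L, length(values) >= window)
  if (window == 1L) return(values)
  cs <- cumsum(c(0, values))
  (cs[seq.int(window + 1L, length(values) + 1L)] -
      cs[seq_len(length(values) - window + 1L)]) / window
}

# smooth a trace, keeping frame labels of retained (trailing) positions
.smoothedSeries <- function(trace, smoothWindow) {
  v <- movingAverage(trace@intensities, smoothWindow)
  f <- trace@frames[seq.int(smoothWindow, length(trace@frames))]
  if (smoothWindow == 1L) f <- trace@frames
  list(frames = f, values = v)
}

#' Maximum degradation speed of a trace
#'
#' Smooths the trace with a trailing \code{smoothWindow}-value average,
#' takes the first difference, locates its minimum (ties resolved to the
#' earliest frame), and fits a least-squares line through the 5 smoothed
#' values centred on that frame (window clamped at the trace ends). The
#' maximum degradation speed is the slope of that line, in normalised
#' intensity per frame (negative for a degrading trace).
#'
#' @param trace normalised, bleach-corrected \linkS4class{DegradationTrace}.
#' @param smoothWindow smoothing window (default 4).
#' @param useSmoothed fit the 5-point line on the smoothed values (default
#'   TRUE); FALSE uses the raw trace values at the same frames.
#' @return A \linkS4class{KineticsResult} with \code{maxSpeed} and
#'   \code{maxSpeedFrame} filled (onset slots NA).
#' @export
maxDegradationSpeed <- function(trace, smoothWindow = 4L, useSmoothed = TRUE) {
  stopifnot(is(trace, "DegradationTrace"))
  validObject(trace)
  smoothWindow <- as.integer(smoothWindow)
  if (length(trace@frames) < smoothWindow + 5L)
    stop("trace too short for max-speed estimation")
  sm <- .smoothedSeries(trace, smoothWindow)
  d <- diff(sm$values)
  imin <- which.min(d)                  # which.min takes the earliest tie
  centre <- imin + 1L                   # frame where the drop lands
  lo <- max(1L, centre - 2L)
  hi <- min(length(sm$values), centre + 2L)
  if (hi - lo + 1L < 5L) {              # clamp to a full 5-point window
    lo <- max(1L, min(lo, length(sm$values) - 4L))
    hi <- lo + 4L
  }
  y <- if (useSmoothed) sm$values[lo:hi]
       else trace@intensities[match(sm$frames[lo:hi], trace@frames)]
  new("KineticsResult", onsetFrame = NA_integer_, initialSpeed = NA_real_,
      maxSpeed = .lsqSlope(y), maxSpeedFrame = sm$frames[centre],
      params = list(smooth_window = smoothWindow, use_smoothed = useSmoothed))
}

#' Detect the degradation onset of a trace
#'
#' Smooths the trace with a trailing \code{smoothWindow}-value average,
#' slides a \code{slopeWindow}-value window left to right, and fits a
#' least-squares line in each. The onset is the first frame of the first
#' window whose slope is strictly below \code{slopeThreshold} (a window at
#' exactly the threshold does not trigger); the initial degradation speed
#' is that window's slope. Absence of such a window is a valid result
#' (onset NA), e.g. for flat or control traces.
#'
#' @param trace normalised, bleach-corrected \linkS4class{DegradationTrace}.
#' @param smoothWindow smoothing window (default 4; 1 = no smoothing).
#' @param slopeWindow sliding-window length (default 5).
#' @param slopeThreshold onset threshold in normalised intensity per frame
#'   (default -0.05).
#' @return A \linkS4class{KineticsResult} (max-speed slots NA).
#' @export
detectOnset <- function(trace, smoothWindow = 4L, slopeWindow = 5L,
                        slopeThreshold = -0.05) {
  stopifnot(is(trace, "DegradationTrace"))
  validObject(trace)
  smoothWindow <- as.integer(smoothWindow)
  slopeWindow <- as.integer(slopeWindow)
  if (length(trace@frames) < smoothWindow + slopeWindow)
    stop("trace too short for onset detection")
  sm <- .smoothedSeries(trace, smoothWindow)
  nW <- length(sm$values) - slopeWindow + 1L
  onset <- NA_integer_
  speed <- NA_real_
  for (i in seq_len(nW)) {
    s <- .lsqSlope(sm$values[seq.int(i, i + slopeWindow - 1L)])
    if (s < slopeThreshold) {
      onset <- sm$frames[i]
      speed <- s
      break
    }
  }
  new("KineticsResult", onsetFrame = onset, initialSpeed = speed,
      maxSpeed = NA_real_, maxSpeedFrame = NA_integer_,
      params = list(smooth_window = smoothWindow,
                    slope_window = slopeWindow,
                    slope_threshold = slopeThreshold))
}

#' Run the full degradation-kinetics pipeline on a raw trace
#'
#' Convenience wrapper: normalise to \code{referenceFrame}, bleach-correct
#' (control trace or pre-anaphase linear fit), then detect the onset and
#' the maximum degradation speed.
#'
#' @param trace raw \linkS4class{DegradationTrace}.
#' @param referenceFrame normalisation reference frame.
#' @param bleachMode "control", "linear" or "none".
#' @param control normalised control trace (for \code{bleachMode =
#'   "control"}).
#' @param bleachFitWindow fit window for \code{bleachMode = "linear"}.
#' @param smoothWindow,slopeWindow,slopeThreshold see [detectOnset()].
#' @return A \linkS4class{KineticsResult} with both onset and max-speed
#'   slots filled.
#' @export
analyzeDegradation <- function(trace, referenceFrame = -20L,
                               bleachMode = c("linear", "control", "none"),
                               control = NULL,
                               bleachFitWindow = c(-30L, -25L),
                               smoothWindow = 4L, slopeWindow = 5L,
                               slopeThreshold = -0.05) {
  bleachMode <- match.arg(bleachMode)
  norm <- normalizeTrace(trace, referenceFrame)
  corr <- switch(bleachMode,
                 linear = bleachCorrectLinear(norm, bleachFitWindow),
                 control = {
                   if (is.null(control)) stop("control trace required")
                   bleachCorrectControl(norm, control)
                 },
                 none = norm)
  ons <- detectOnset(corr, smoothWindow, slopeWindow, slopeThreshold)
  spd <- maxDegradationSpeed(corr, smoothWindow)
  new("KineticsResult", onsetFrame = ons@onsetFrame,
      initialSpeed = ons@initialSpeed, maxSpeed = spd@maxSpeed,
      maxSpeedFrame = spd@maxSpeedFrame,
      params = list(smooth_window = smoothWindow,
                    slope_window = slopeWindow,
                    slope_threshold = slopeThreshold,
                    reference_frame = as.integer(referenceFrame),
                    bleach_mode = bleachMode))
}
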