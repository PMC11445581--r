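# Synthetic degradation trajectories and line-profile images with
# recorded ground truth.

#' Simulate an anaphase-aligned degradation trace
#'
#' The noiseless model is
#' \deqn{I(t) = \mathrm{baseline} \cdot b(t) \cdot d(t) + \mathrm{background}}
#' where b(t) = 1 - bleachRate * (t - first) (linear photobleaching, the
#' form the straight-line correction assumes; \code{bleachShape =
#' "exponential"} gives exp(-bleachRate (t - first)) instead) and d(t) = 1
#' up to and including \code{onsetFrame}, then decays with rate
#' \code{decayRate} per frame (exponential by default; the in-cell decay
#' shape is not firmly established, so "linear" is offered as well).
#' Gaussian noise of sd \code{noiseSd} is added on top.
#'
#' @param baseline pre-degradation intensity (a.u.), > 0.
#' @param bleachRate bleaching loss per frame (fraction/frame); the linear
#'   bleach term must stay positive over the frame range.
#' @param onsetFrame degradation onset frame (anaphase = 0); must lie
#'   strictly inside the frame range unless \code{decayRate} = 0.
#' @param decayRate degradation rate (fraction/frame), >= 0; 0 gives a
#'   pure-bleach control trace (the cycloheximide + MG132 condition).
#' @param noiseSd additive Gaussian noise sd (a.u.).
#' @param frameRange integer c(first, last), anaphase = 0.
#' @param frameInterval seconds per frame.
#' @param seed integer seed.
#' @param compartment,cellId metadata labels.
#' @param background constant offset (a.u.) recorded in the trace.
#' @param decayShape "exponential" (default) or "linear".
#' @param bleachShape "linear" (default) or "exponential".
#' @return list with \code{trace} (\linkS4class{DegradationTrace}) and
#'   \code{truth} (\linkS4class{SyntheticTruth}).
#' @export
simulateDegradationTrace <- function(baseline = 1, bleachRate = 0,
                                     onsetFrame = 0L, decayRate = 0,
                                     noiseSd = 0, frameRange = c(-40L, 40L),
                                     frameInterval = 30, seed = 1L,
                                     compartment = "whole_cell",
                                     cellId = "synthetic", background = 0,
                                     decayShape = c("exponential", "linear"),
                                     bleachShape = c("linear", "exponential")) {
  decayShape <- match.arg(decayShape)
  bleachShape <- match.arg(bleachShape)
  .assertFinite(c(baseline, bleachRate, onsetFrame, decayRate, noiseSd,
                  frameRange, background), "trace parameters")
  stopifnot(baseline > 0, decayRate >= 0, noiseSd >= 0)
  first <- as.integer(frameRange[1L]); last <- as.integer(frameRange[2L])
  if (last <= first) stop("frameRange must satisfy first < last")
  onsetFrame <- as.integer(onsetFrame)
  if (decayRate > 0 && (onsetFrame <= first || onsetFrame > last))
    stop("need first < onsetFrame <= last (or decayRate = 0 for a control)")
  fr <- seq.int(first, last)
  bleach <- switch(bleachShape,
                   linear = 1 - bleachRate * (fr - first),
                   exponential = exp(-bleachRate * (fr - first)))
  if (any(bleach <= 0))
    stop("bleach term reaches <= 0 inside the frame range")
  decay <- rep(1, length(fr))
  after <- fr > onsetFrame
  if (decayRate > 0) {
    decay[after] <- switch(decayShape,
                           exponential = exp(-decayRate * (fr[after] - onsetFrame)),
                           linear = pmax(0, 1 - decayRate * (fr[after] - onsetFrame)))
  }
  intens <- baseline * bleach * decay + background
  if (noiseSd > 0)
    intens <- intens + .withSeed(seed, stats::rnorm(length(fr), 0, noiseSd))
  truth <- new("SyntheticTruth", kind = "degradation_trace", params = list(
    baseline = baseline, bleach_rate = bleachRate, onset_frame = onsetFrame,
    decay_rate = decayRate, noise_sd = noiseSd,
    frame_range = c(first, last), frame_interval_s = frameInterval,
    background = background, decay_shape = decayShape,
    bleach_shape = bleachShape, compartment = compartment, seed = seed))
  list(trace = degradationTrace(fr, intens, background = background,
                                compartment = compartment,
                                frameInterval = frameInterval,
                                cellId = cellId),
       truth = truth)
}

#' Simulate a two-channel line-profile image
#'
#' Sums isotropic 2D Gaussian peaks over a constant background with
#' optional Gaussian pixel noise; emulates a summed-z projection of a
#' metaphase cell showing the centrosome-chromatin-centrosome three-peak
#' geometry. Truth records the peak centres.
#'
#' @param peaks list of peaks, each a list with \code{center} = c(x, y) in
#'   pixel coordinates (inside the image), \code{sd} (px, > 0),
#'   \code{amplitude} (a.u.) and \code{channel} label.
#' @param background constant offset (a.u.).
#' @param noiseSd Gaussian pixel noise sd (a.u.).
#' @param imageSize integer c(nx, ny) in pixels.
#' @param seed integer seed.
#' @return list with \code{images} (named list of ny x nx matrices, one
#'   per channel; x indexes columns, y rows) and \code{truth}.
#' @export
simulateLineProfileImage <- function(peaks = list(), background = 0,
                                     noiseSd = 0, imageSize = c(64L, 64L),
                                     seed = 1L) {
  nx <- as.integer(imageSize[1L]); ny <- as.integer(imageSize[2L])
  stopifnot(nx >= 2L, ny >= 2L, noiseSd >= 0, is.finite(background))
  channels <- unique(c("green",
                       vapply(peaks, function(p)
                         if (is.null(p$channel)) "green" else p$channel,
                         character(1))))
  xs <- matrix(rep(seq_len(nx), each = ny), nrow = ny)
  ys <- matrix(rep(seq_len(ny), times = nx), nrow = ny)
  images <- stats::setNames(
    lapply(channels, function(ch) matrix(background, ny, nx)), channels)
  for (p in peaks) {
    ch <- if (is.null(p$channel)) "green" else p$channel
    cx <- p$center[1L]; cy <- p$center[2L]
    if (cx < 1 || cx > nx || cy < 1 || cy > ny)
      stop("peak centre outside the image")
    if (!is.finite(p$sd) || p$sd <= 0) stop("peak sd must be > 0")
    images[[ch]] <- images[[ch]] +
      p$amplitude * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * p$sd^2))
  }
  if (noiseSd > 0) {
    images <- .withSeed(seed, lapply(images, function(img)
      img + matrix(stats::rnorm(nx * ny, 0, noiseSd), ny, nx)))
  }
  truth <- new("SyntheticTruth", kind = "line_profile_image", params = list(
    peaks = peaks, background = background, noise_sd = noiseSd,
    image_size = c(nx, ny), seed = seed))
  list(images = images, truth = truth)
}
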