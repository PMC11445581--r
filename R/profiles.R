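# Confocal line-profile extraction and compartment quantification on 2D
# projected images. Images are matrices indexed [y, x] (row = y, column =
# x), with pixel centres at integer coordinates starting at (1, 1).

.bilinear <- function(image, x, y) {
  ny <- nrow(image); nx <- ncol(image)
  if (any(x < 1 - 1e-9) || any(x > nx + 1e-9) ||
      any(y < 1 - 1e-9) || any(y > ny + 1e-9))
    stop("sample point outside the image")
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  image[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    image[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    image[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    image[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Extract a thick line profile between two points
#'
#' Samples the image at unit spacing along the segment from \code{p0} to
#' \code{p1} (e.g. centrosome to centrosome). At each sample position the
#' value is the mean of bilinear interpolations at \code{thicknessPx}
#' perpendicular offsets centred on the axis (for the default thickness
#' 10: offsets -4.5, -3.5, ..., +4.5 px). The background is subtracted
#' from the profile; min-max scaling is a separate step
#' ([minmaxScale()]).
#'
#' @param image numeric matrix, indexed [y, x].
#' @param p0,p1 numeric c(x, y) endpoints in pixel coordinates, inside the
#'   image, p0 != p1.
#' @param thicknessPx averaging thickness in pixels (>= 1).
#' @param background scalar background (a.u.) subtracted from the profile.
#' @param channel label stored in the result.
#' @return A \linkS4class{LineProfile}.
#' @export
extractLineProfile <- function(image, p0, p1, thicknessPx = 10L,
                               background = 0, channel = "green") {
  stopifnot(is.matrix(image), is.numeric(image))
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 2L || length(p1) != 2L) stop("p0, p1 must be c(x, y)")
  if (all(p0 == p1)) stop("p0 and p1 must differ")
  thicknessPx <- as.integer(thicknessPx)
  if (thicknessPx < 1L) stop("thicknessPx must be >= 1")
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  u <- d / len                          # unit vector along the axis
  perp <- c(-u[2L], u[1L])              # unit normal
  offsets <- seq_len(thicknessPx) - (thicknessPx + 1) / 2
  positions <- seq(0, floor(len))
  vals <- vapply(positions, function(t) {
    ctr <- p0 + t * u
    xs <- ctr[1L] + offsets * perp[1L]
    ys <- ctr[2L] + offsets * perp[2L]
    mean(.bilinear(image, xs, ys))
  }, numeric(1))
  new("LineProfile", positions = positions, values = vals - background,
      channel = channel, thicknessPx = thicknessPx, scaled = FALSE)
}

#' Min-max scale values to [0, 1]
#'
#' (x - min) / (max - min); the output always attains both 0 and 1.
#' Constant input has no defined scaling and is an error.
#'
#' @param values numeric vector with max > min.
#' @return scaled values in [0, 1].
#' @export
minmaxScale <- function(values) {
  if (is(values, "LineProfile")) {
    out <- values
    out@values <- minmaxScale(values@values)
    out@scaled <- TRUE
    return(out)
  }
  rng <- range(values)
  if (!all(is.finite(rng)) || rng[2L] <= rng[1L])
    stop("min-max scaling undefined for constant input")
  (values - rng[1L]) / (rng[2L] - rng[1L])
}

#' Background-subtracted mean intensity inside and outside a mask
#'
#' Quantifies a signal inside a manually drawn region of interest (e.g.
#' the chromatids of polar chromosomes) and in the rest of the image.
#' Tracked per frame and normalised to a pre-anaphase reference, this
#' yields in/out-of-DNA degradation traces.
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same dimensions; neither empty nor
#'   covering the full image.
#' @param background scalar background (a.u.).
#' @return named numeric: \code{meanInside}, \code{meanOutside}.
#' @export
compartmentMeans <- function(image, mask, background = 0) {
  stopifnot(is.matrix(image), is.logical(mask),
            identical(dim(image), dim(mask)))
  nin <- sum(mask)
  if (nin == 0L || nin == length(mask))
    stop("mask must be non-empty and not cover the full image")
  c(meanInside = mean(image[mask]) - background,
    meanOutside = mean(image[!mask]) - background)
}
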