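#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence channel as the
#' grayscale morphological opening of the image with a ball-shaped
#' (non-flat, spherical) structuring element of the given radius, and
#' subtracts it. This removes uneven illumination and broad tissue
#' fluorescence while preserving features narrower than the ball, such as
#' punctate sperm-head fluorescence and thin chitinous walls.
#'
#' The background estimate never exceeds the image (opening is
#' anti-extensive), so the result is non-negative and pixel-wise bounded by
#' the input; any residual negative values from the border handling are
#' clipped to 0.
#'
#' @param channel numeric matrix of pixel intensities.
#' @param radius ball radius in pixels (default 25, the standard smoothing
#'   radius for these micrographs).
#' @param ball_height_scale intensity units of ball height per pixel of
#'   ball radius; 1 gives a sphere in (px, px, intensity) space. At 14-bit
#'   intensities the ball is nearly flat, as intended for background
#'   estimation.
#' @return matrix of the same shape: `pmax(channel - background, 0)`.
#' @export
subtract_background <- function(channel, radius = 25, ball_height_scale = 1) {
  channel <- as.matrix(channel)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("radius must be a single number >= 1")
  if (2 * radius + 1 > min(dim(channel)))
    stop("ball radius larger than the image")
  bg <- .ball_opening(channel, as.numeric(radius),
                      as.numeric(ball_height_scale))
  bg <- pmax(bg, 0)
  pmax(channel - bg, 0)
}
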