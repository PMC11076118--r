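#' Intermodes histogram threshold
#'
#' The classic iterated-mean-smoothing bimodality algorithm: masked pixel
#' intensities are binned into a 256-bin histogram spanning the 14-bit
#' range, the histogram is repeatedly smoothed with a 3-point moving mean
#' until exactly two local maxima remain, and the threshold is the
#' intensity at the midpoint between the two modes.
#'
#' If the histogram never becomes bimodal within `max_iter` smoothing
#' passes (typical of blank tracts, whose histograms are unimodal), an
#' error of class `gfpsperm_bimodality_error` is signalled; callers such as
#' [occupancy_metrics()] catch it and apply their configured fallback.
#'
#' @param image numeric matrix of corrected intensities.
#' @param roi_mask logical matrix selecting the pixels to threshold (default
#'   all pixels).
#' @param n_bins histogram bins (default 256).
#' @param max_intensity top of the intensity scale (default 14-bit, 16383).
#' @param max_iter smoothing iteration cap (default 10000).
#' @return single numeric threshold on the intensity scale, with attributes
#'   `modes` (the two mode bins, 0-based) and `iterations`.
#' @export
intermodes_threshold <- function(image, roi_mask = NULL, n_bins = 256L,
                                 max_intensity = MAX_INTENSITY,
                                 max_iter = 10000L) {
  image <- as.matrix(image)
  vals <- if (is.null(roi_mask)) as.vector(image) else image[roi_mask]
  if (length(unique(vals)) < 2L)
    stop("need >= 2 distinct intensity values to threshold")
  bin_width <- (max_intensity + 1) / n_bins
  idx <- pmin(pmax(floor(vals / bin_width), 0), n_bins - 1L)
  h <- tabulate(idx + 1L, nbins = n_bins)
  y <- as.numeric(h)

  local_maxima <- function(y) {
    n <- length(y)
    yl <- c(0, y[-n]); yr <- c(y[-1], 0)
    which(y > yl & y > yr)
  }

  iter <- 0L
  repeat {
    peaks <- local_maxima(y)
    if (length(peaks) == 2L) break
    if (iter >= max_iter) {
      cond <- structure(
        class = c("gfpsperm_bimodality_error", "error", "condition"),
        list(message = sprintf(
          "histogram not bimodal after %d smoothing iterations (%d maxima)",
          iter, length(peaks)),
          call = sys.call(-1), n_maxima = length(peaks)))
      stop(cond)
    }
    n <- length(y)
    y <- (c(0, y[-n]) + y + c(y[-1], 0)) / 3
    iter <- iter + 1L
  }
  modes <- peaks - 1L  # 0-based bins
  thr_bin <- mean(modes)
  structure((thr_bin + 0.5) * bin_width,
            modes = modes, iterations = iter)
}
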