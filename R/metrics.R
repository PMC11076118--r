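#' Quantification configuration
#'
#' Bundles the tunable parameters of the quantification chain.
#'
#' @param radius rolling-ball radius in pixels.
#' @param min_component_px smallest 8-connected above-threshold component
#'   that counts as observable sperm presence.
#' @param eps smallest usable red reference mean (see
#'   [compute_correction_factor()]).
#' @param threshold_fallback what to do when the intermodes histogram never
#'   becomes bimodal: `"empty"` treats the ROI as having no fluorescent
#'   pixels (cover 0, presence FALSE) and flags the fallback.
#' @return a list of class `quant_config`.
#' @export
quant_config <- function(radius = 25, min_component_px = 4L, eps = 1e-6,
                         threshold_fallback = c("empty")) {
  threshold_fallback <- match.arg(threshold_fallback)
  structure(list(radius = radius,
                 min_component_px = as.integer(min_component_px),
                 eps = eps, threshold_fallback = threshold_fallback),
            class = "quant_config")
}

#' Occupancy metrics within a polygon ROI
#'
#' Computes, over the rasterized ROI of a corrected (background-subtracted,
#' crosstalk-corrected) image: the mean and median pixel intensity over all
#' ROI pixels; the intermodes threshold; the percentage cover, i.e. the
#' fraction of ROI pixels strictly above the threshold times 100; and a
#' presence flag, true iff at least one 8-connected above-threshold
#' component of at least `min_component_px` pixels exists inside the ROI.
#'
#' When the intensity histogram never becomes bimodal (blank tracts), the
#' configured fallback treats the ROI as containing no fluorescent pixels;
#' the result is flagged via `threshold_failed = TRUE` and a missing
#' `threshold_value`.
#'
#' @param corrected numeric matrix from [correct_autofluorescence()].
#' @param roi a [polygon_roi()] for the site.
#' @param config a [quant_config()].
#' @return an object of class `occupancy_metrics`: fields `mean_intensity`,
#'   `median_intensity`, `percent_cover`, `presence`, `threshold_value`,
#'   `roi_area_px`, `threshold_failed`.
#' @export
occupancy_metrics <- function(corrected, roi, config = quant_config()) {
  corrected <- as.matrix(corrected)
  mask <- rasterize_roi(roi, dim(corrected))
  vals <- corrected[mask]
  area <- sum(mask)

  thr <- tryCatch(intermodes_threshold(corrected, mask),
                  gfpsperm_bimodality_error = function(e) e,
                  error = function(e) {
                    if (length(unique(vals)) < 2L) e else stop(e)
                  })
  failed <- inherits(thr, "condition")
  if (failed) {
    above <- mask & FALSE
    thr_value <- NA_real_
  } else {
    above <- mask & (corrected > as.numeric(thr))
    thr_value <- as.numeric(thr)
  }

  sizes <- .component_sizes(above)
  structure(list(
    mean_intensity = mean(vals),
    median_intensity = median(vals),
    percent_cover = 100 * sum(above) / area,
    presence = any(sizes >= config$min_component_px),
    threshold_value = thr_value,
    roi_area_px = area,
    threshold_failed = failed),
    class = "occupancy_metrics")
}

#' Quantify one sample end to end
#'
#' Runs the full quantification chain on one channel stack, in fixed
#' order: rolling-ball background subtraction of the green and red
#' channels, correction-factor estimation in the reference ROI, scaled
#' subtraction of the red channel from the green, then occupancy metrics
#' for each site ROI present (`total_tract` and/or `spermatheca`). A
#' structured log of every intermediate scalar (Int_GFP, Int_Auto, factor,
#' per-site threshold) is attached for provenance.
#'
#' @param stack a [channel_stack()].
#' @param rois named list of [polygon_roi()] objects; must contain an
#'   `autofluorescence_reference` ROI and at least one site ROI.
#' @param config a [quant_config()].
#' @return object of class `sample_quantification`: `metrics` (named list
#'   of [occupancy_metrics()] per site), `log` (intermediate scalars),
#'   `corrected` (the corrected green image).
#' @export
quantify_sample <- function(stack, rois, config = quant_config()) {
  stopifnot(inherits(stack, "channel_stack"))
  labels <- vapply(rois, `[[`, "", "label")
  names(rois) <- labels
  if (!"autofluorescence_reference" %in% labels)
    stop("missing autofluorescence_reference ROI")
  sites <- intersect(c("total_tract", "spermatheca"), labels)
  if (length(sites) == 0L) stop("no site ROI (total_tract or spermatheca)")

  green_bs <- subtract_background(stack$green, config$radius)
  red_bs <- subtract_background(stack$red, config$radius)
  stack_bs <- stack
  stack_bs$green <- green_bs
  stack_bs$red <- red_bs
  cf <- compute_correction_factor(stack_bs, rois$autofluorescence_reference,
                                  eps = config$eps)
  corrected <- correct_autofluorescence(green_bs, red_bs, cf)

  metrics <- lapply(sites, function(s)
    occupancy_metrics(corrected, rois[[s]], config))
  names(metrics) <- sites

  log <- list(int_gfp = cf$int_gfp, int_auto = cf$int_auto,
              factor = cf$factor,
              thresholds = lapply(metrics, `[[`, "threshold_value"),
              threshold_failed = lapply(metrics, `[[`, "threshold_failed"))
  structure(list(metrics = metrics, log = log, corrected = corrected),
            class = "sample_quantification")
}
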