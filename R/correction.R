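#' Autofluorescence correction factor from a reference ROI
#'
#' Chitinous structures (spermathecal duct ring, tubule walls) fluoresce in
#' both the green (GFP) and red channels with a fixed intensity ratio. The
#' correction factor is estimated by drawing a reference ROI on a structure
#' showing strong red autofluorescence but no sperm-derived GFP, measuring
#' the mean intensity of both background-subtracted channels inside it, and
#' dividing the green mean (Int_GFP) by the red mean (Int_Auto).
#'
#' @param stack a `channel_stack` (see [channel_stack()]); both fluorescence
#'   channels are expected to be background-subtracted already.
#' @param ref_roi a [polygon_roi()] labelled `autofluorescence_reference`.
#' @param eps smallest usable red mean; below this the reference ROI is
#'   rejected as carrying no autofluorescence signal.
#' @return an object of class `correction_factor` with fields `int_gfp`,
#'   `int_auto`, `factor`.
#' @export
compute_correction_factor <- function(stack, ref_roi, eps = 1e-6) {
  stopifnot(inherits(stack, "channel_stack"), inherits(ref_roi, "polygon_roi"))
  if (ref_roi$label != "autofluorescence_reference")
    stop("reference ROI must be labelled 'autofluorescence_reference'")
  mask <- rasterize_roi(ref_roi, dim(stack$green))
  int_gfp <- mean(stack$green[mask])
  int_auto <- mean(stack$red[mask])
  if (!is.finite(int_auto) || int_auto <= eps)
    stop("unusable reference ROI: red mean intensity <= ", eps)
  structure(list(int_gfp = int_gfp, int_auto = int_auto,
                 factor = int_gfp / int_auto),
            class = "correction_factor")
}

#' Subtract scaled autofluorescence from the green channel
#'
#' Multiplies the red (autofluorescence) channel by the correction factor
#' and subtracts it from the green (GFP) channel, leaving primarily
#' sperm-derived GFP fluorescence. Negative results are clipped to 0, so
#' the output is pixel-wise bounded above by the green input.
#'
#' @param green,red numeric matrices of identical shape
#'   (background-subtracted).
#' @param cf a `correction_factor` from [compute_correction_factor()], or a
#'   single non-negative number.
#' @return corrected green-channel matrix.
#' @export
correct_autofluorescence <- function(green, red, cf) {
  if (inherits(cf, "correction_factor")) cf <- cf$factor
  stopifnot(is.numeric(cf), length(cf) == 1L, cf >= 0)
  green <- as.matrix(green); red <- as.matrix(red)
  if (!identical(dim(green), dim(red)))
    stop("green and red channels differ in shape")
  pmax(green - cf * red, 0)
}
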