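#' Two-channel micrograph container
#'
#' Holds one sample's bright-field, green (GFP, 520 nm collection) and red
#' (autofluorescence, 624 nm collection) intensity images plus acquisition
#' metadata. Intensities live on a 14-bit scale, 0..16383.
#'
#' @param brightfield,green,red numeric matrices of identical shape.
#' @param bit_depth bit depth of the intensity scale (default 14).
#' @param exposure_ms named numeric vector of per-channel exposure times.
#' @param site_context `"total_tract"` or `"spermatheca"`; intensities are
#'   never compared across acquisition contexts.
#' @return an object of class `channel_stack`.
#' @export
channel_stack <- function(brightfield, green, red, bit_depth = 14L,
                          exposure_ms = c(brightfield = 5, red = 100,
                                          green = 150),
                          site_context = c("total_tract", "spermatheca")) {
  site_context <- match.arg(site_context)
  brightfield <- as.matrix(brightfield)
  green <- as.matrix(green)
  red <- as.matrix(red)
  if (!identical(dim(brightfield), dim(green)) ||
      !identical(dim(green), dim(red)))
    stop("all channels must share the same shape")
  top <- 2^bit_depth - 1
  for (ch in list(brightfield, green, red))
    if (min(ch) < 0 || max(ch) > top)
      stop("channel intensities outside [0, ", top, "]")
  structure(list(brightfield = brightfield, green = green, red = red,
                 bit_depth = as.integer(bit_depth),
                 exposure_ms = exposure_ms, site_context = site_context),
            class = "channel_stack")
}

#' Parameters for synthetic tract micrographs
#'
#' Describes the physical scene behind one synthetic two-channel
#' micrograph: punctate GFP sperm-head fluorescence, chitinous structures
#' fluorescing in both channels with a fixed green/red crosstalk ratio,
#' smooth low-order polynomial illumination, and a shot + read noise model.
#'
#' The default geometry places a large total-tract polygon, a small
#' spermathecal polygon, and two thin chitinous bands (the duct-base ring
#' proxy and the spermathecal outer wall) on a 128 x 128 frame; sperm
#' puncta are scattered in a bursal cloud and a spermathecal cloud.
#'
#' @param image_shape `(height, width)` in pixels.
#' @param n_puncta GFP sperm-head count in the bursal cloud.
#' @param n_puncta_spermatheca sperm-head count in the spermathecal cloud.
#' @param bursa_cloud_radius,sperm_cloud_radius radius (px) of the discs
#'   over which sperm heads scatter; occupancy scales with cloud area,
#'   density stays high enough that clouds are internally confluent.
#' @param punctum_amplitude_range intensity range (14-bit units) for peak
#'   amplitudes, drawn uniformly.
#' @param punctum_sigma Gaussian spot width in pixels.
#' @param chitin_structures list of `list(polygon = matrix, amplitude = )`
#'   entries; `NULL` uses the default scene.
#' @param crosstalk_k green/red intensity ratio of autofluorescent
#'   material (> 0); ground truth for the correction factor.
#' @param illumination_field coefficients `(c0, cx, cy, cxx, cxy, cyy)` of
#'   a quadratic multiplicative illumination surface in centred fractional
#'   coordinates.
#' @param noise_model `list(gain = , read_sd = )` for Poisson shot noise
#'   (photons per intensity unit gain) plus Gaussian read noise, or `NULL`
#'   for noise-free rendering.
#' @param seed integer seed; fully determines the rendered scene.
#' @return a list of class `imaging_params`.
#' @export
imaging_params <- function(image_shape = c(128L, 128L),
                           n_puncta = 460L,
                           n_puncta_spermatheca = 98L,
                           bursa_cloud_radius = 13,
                           sperm_cloud_radius = 6,
                           punctum_amplitude_range = c(1000, 1400),
                           punctum_sigma = 0.9,
                           chitin_structures = NULL,
                           crosstalk_k = 0.3,
                           illumination_field = c(1, 0.1, -0.08,
                                                  -0.15, 0, -0.1),
                           noise_model = list(gain = 2, read_sd = 10),
                           seed = 1L) {
  stopifnot(crosstalk_k > 0, punctum_sigma > 0,
            length(punctum_amplitude_range) == 2L,
            all(punctum_amplitude_range >= 0),
            all(punctum_amplitude_range <= MAX_INTENSITY),
            n_puncta >= 0, n_puncta_spermatheca >= 0)
  if (is.null(chitin_structures))
    chitin_structures <- default_chitin_structures(image_shape)
  structure(list(image_shape = as.integer(image_shape),
                 n_puncta = as.integer(n_puncta),
                 n_puncta_spermatheca = as.integer(n_puncta_spermatheca),
                 bursa_cloud_radius = bursa_cloud_radius,
                 sperm_cloud_radius = sperm_cloud_radius,
                 punctum_amplitude_range = punctum_amplitude_range,
                 punctum_sigma = punctum_sigma,
                 chitin_structures = chitin_structures,
                 crosstalk_k = crosstalk_k,
                 illumination_field = illumination_field,
                 noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "imaging_params")
}

# Regular n-gon approximation of an ellipse, vertices (x, y).
ellipse_polygon <- function(cx, cy, rx, ry, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

# Thin rotated rectangle band from (x1, y1) to (x2, y2), given width.
band_polygon <- function(x1, y1, x2, y2, width) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  nx <- -dy / len * width / 2; ny <- dx / len * width / 2
  rbind(c(x1 + nx, y1 + ny), c(x2 + nx, y2 + ny),
        c(x2 - nx, y2 - ny), c(x1 - nx, y1 - ny))
}

default_scene_geometry <- function(image_shape = c(128L, 128L)) {
  s <- min(image_shape) / 128
  list(
    tract = ellipse_polygon(56 * s, 66 * s, 42 * s, 50 * s),
    spermatheca = ellipse_polygon(100 * s, 36 * s, 11 * s, 11 * s, n = 16L),
    bursa_cloud = c(cx = 48 * s, cy = 70 * s),
    sperm_cloud = c(cx = 100 * s, cy = 36 * s),
    duct_band = c(78 * s, 52 * s, 93 * s, 42 * s, 7 * s),
    wall_band = c(114 * s, 24 * s, 114 * s, 50 * s, 6 * s))
}

default_chitin_structures <- function(image_shape = c(128L, 128L)) {
  g <- default_scene_geometry(image_shape)
  list(
    list(polygon = do.call(band_polygon, as.list(g$duct_band)),
         amplitude = 6000),
    list(polygon = do.call(band_polygon, as.list(g$wall_band)),
         amplitude = 5000))
}

# Evaluate the quadratic illumination surface on the pixel grid (clipped
# to be positive).
illumination_surface <- function(coef, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  u <- matrix(rep((seq_len(w) - 0.5) / w - 0.5, each = h), h, w)
  v <- matrix(rep((seq_len(h) - 0.5) / h - 0.5, times = w), h, w)
  f <- coef[1] + coef[2] * u + coef[3] * v +
    coef[4] * u^2 + coef[5] * u * v + coef[6] * v^2
  pmax(f, 0.05)
}

# Rasterize a bare polygon matrix with the same even-odd pixel-centre rule
# used for ROIs (no label/validity machinery).
rasterize_polygon <- function(vertices, image_shape) {
  roi <- polygon_roi("total_tract", vertices)
  rasterize_roi(roi, image_shape)
}

# Additive field of isotropic 2-D Gaussian spots, rendered on local
# windows of +/- 5 sigma.
render_puncta <- function(coords, amplitudes, sigma, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  field <- matrix(0, h, w)
  if (is.null(coords) || nrow(coords) == 0L) return(field)
  win <- ceiling(5 * sigma)
  for (i in seq_len(nrow(coords))) {
    cx <- coords[i, 1]; cy <- coords[i, 2]
    xs <- max(1L, floor(cx - win)):min(w, ceiling(cx + win) + 1L)
    ys <- max(1L, floor(cy - win)):min(h, ceiling(cy + win) + 1L)
    gx <- (xs - 0.5) - cx
    gy <- (ys - 0.5) - cy
    field[ys, xs] <- field[ys, xs] +
      amplitudes[i] * outer(exp(-gy^2 / (2 * sigma^2)),
                            exp(-gx^2 / (2 * sigma^2)))
  }
  field
}

# Footprint mask: pixels whose centre lies within sigma * sqrt(2 ln 10)
# of any punctum centre (the 10%-of-peak contour).
puncta_footprint_mask <- function(coords, sigma, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  mask <- matrix(FALSE, h, w)
  if (is.null(coords) || nrow(coords) == 0L) return(mask)
  r <- sigma * sqrt(2 * log(10))
  win <- ceiling(r)
  for (i in seq_len(nrow(coords))) {
    cx <- coords[i, 1]; cy <- coords[i, 2]
    xs <- max(1L, floor(cx - win)):min(w, ceiling(cx + win) + 1L)
    ys <- max(1L, floor(cy - win)):min(h, ceiling(cy + win) + 1L)
    d2 <- outer(((ys - 0.5) - cy)^2, ((xs - 0.5) - cx)^2, `+`)
    mask[ys, xs] <- mask[ys, xs] | (d2 <= r^2)
  }
  mask
}

apply_noise <- function(clean, noise_model) {
  if (is.null(noise_model)) return(pmin(pmax(clean, 0), MAX_INTENSITY))
  gain <- noise_model$gain
  shot <- if (!is.null(gain) && gain > 0) {
    gain * matrix(rpois(length(clean), pmax(clean, 0) / gain), nrow(clean))
  } else clean
  out <- shot + rnorm(length(clean), 0, noise_model$read_sd)
  pmin(pmax(round(out), 0), MAX_INTENSITY)
}

#' Simulate one ground-truthed tract micrograph
#'
#' Renders a synthetic two-channel fluorescence micrograph of a female
#' reproductive tract: the green channel is
#' `illumination x (puncta + k x chitin) + noise`, the red channel is
#' `illumination x chitin + noise`, where `k` is the autofluorescence
#' crosstalk ratio. Returns the channel stack, the three analysis ROIs
#' (total tract, spermatheca, and a punctum-free reference ROI inside the
#' first chitin structure), and a ground-truth record for validating the
#' quantification chain.
#'
#' @param params an [imaging_params()].
#' @return list with elements `stack` ([channel_stack()]), `rois` (named
#'   list of three [polygon_roi()]), and `truth` (class `imaging_truth`:
#'   `punctum_coordinates`, `punctum_amplitudes`, `crosstalk_k`,
#'   `background_field`, `true_sperm_mask`, `true_cover_percent` per site).
#' @export
simulate_tract_image <- function(params) {
  stopifnot(inherits(params, "imaging_params"))
  shape <- params$image_shape
  geom <- default_scene_geometry(shape)
  with_seed(params$seed, {
    coords <- rbind(
      sample_disc(params$n_puncta,
                  c(geom$bursa_cloud, r = params$bursa_cloud_radius)),
      sample_disc(params$n_puncta_spermatheca,
                  c(geom$sperm_cloud, r = params$sperm_cloud_radius)))
    n_total <- nrow(coords)
    amps <- if (n_total > 0)
      runif(n_total, params$punctum_amplitude_range[1],
            params$punctum_amplitude_range[2]) else numeric(0)

    illum <- illumination_surface(params$illumination_field, shape)
    chitin_field <- matrix(0, shape[1], shape[2])
    chitin_masks <- vector("list", length(params$chitin_structures))
    for (i in seq_along(params$chitin_structures)) {
      st <- params$chitin_structures[[i]]
      m <- rasterize_polygon(st$polygon, shape)
      chitin_masks[[i]] <- m
      chitin_field <- chitin_field + st$amplitude * m
    }
    puncta_field <- render_puncta(coords, amps, params$punctum_sigma, shape)

    green_clean <- illum * (puncta_field + params$crosstalk_k * chitin_field)
    red_clean <- illum * chitin_field
    bf_clean <- illum * (11000 - 0.4 * chitin_field)

    ref_roi <- place_reference_roi(params, coords, geom, shape)

    stack <- channel_stack(
      brightfield = apply_noise(bf_clean, params$noise_model),
      green = apply_noise(pmin(green_clean, MAX_INTENSITY),
                          params$noise_model),
      red = apply_noise(red_clean, params$noise_model))

    rois <- list(
      total_tract = polygon_roi("total_tract", geom$tract),
      spermatheca = polygon_roi("spermatheca", geom$spermatheca),
      autofluorescence_reference = ref_roi)

    mask <- puncta_footprint_mask(coords, params$punctum_sigma, shape)
    cover <- vapply(rois[c("total_tract", "spermatheca")], function(r) {
      rm <- rasterize_roi(r, shape)
      100 * sum(mask & rm) / sum(rm)
    }, 0)

    truth <- structure(list(
      punctum_coordinates = coords,
      punctum_amplitudes = amps,
      crosstalk_k = params$crosstalk_k,
      background_field = illum,
      chitin_masks = chitin_masks,
      true_sperm_mask = mask,
      true_cover_percent = cover),
      class = "imaging_truth")
    list(stack = stack, rois = rois, truth = truth)
  })
}

# Uniform points in a disc (rejection-free: sqrt radius sampling).
sample_disc <- function(n, disc) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  r <- disc["r"] * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(disc["cx"] + r * cos(th), disc["cy"] + r * sin(th))
}

# Slide candidate reference rectangles along the first chitin band until
# one contains no punctum footprint; bounded retries, then error.
place_reference_roi <- function(params, coords, geom, shape,
                                max_tries = 25L) {
  b <- geom$duct_band
  x1 <- b[1]; y1 <- b[2]; x2 <- b[3]; y2 <- b[4]; width <- b[5]
  foot <- if (nrow(coords) > 0L)
    puncta_footprint_mask(coords, params$punctum_sigma, shape) else NULL
  for (i in seq_len(max_tries)) {
    f1 <- (i - 1) / max_tries
    f2 <- f1 + 0.5  # half-band-length windows sliding along the band
    if (f2 > 1) f2 <- 1
    cand <- band_polygon(x1 + f1 * (x2 - x1), y1 + f1 * (y2 - y1),
                         x1 + f2 * (x2 - x1), y1 + f2 * (y2 - y1),
                         width - 3)
    roi <- polygon_roi("autofluorescence_reference", cand)
    m <- rasterize_roi(roi, shape)
    if (is.null(foot) || !any(m & foot)) return(roi)
  }
  stop("could not place a punctum-free autofluorescence reference ROI")
}
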