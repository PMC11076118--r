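# Independent brute-force oracles, deliberately written as plain scalar
# loops so they share no code path with the package implementation.

# Even-odd ray cast at every pixel centre.
brute_rasterize <- function(vertices, shape) {
  h <- shape[1]; w <- shape[2]
  n <- nrow(vertices)
  mask <- matrix(FALSE, h, w)
  for (col in seq_len(w)) {
    for (row in seq_len(h)) {
      px <- col - 0.5; py <- row - 0.5
      crossings <- 0L
      for (i in seq_len(n)) {
        j <- if (i == 1L) n else i - 1L
        x1 <- vertices[i, 1]; y1 <- vertices[i, 2]
        x2 <- vertices[j, 1]; y2 <- vertices[j, 2]
        if ((y1 > py) != (y2 > py)) {
          xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
          if (px < xint) crossings <- crossings + 1L
        }
      }
      mask[row, col] <- (crossings %% 2L) == 1L
    }
  }
  mask
}

# Ball structuring element as an offset table (dx, dy, height).
ball_se <- function(radius, scale = 1) {
  r <- floor(radius)
  rows <- list(); k <- 1L
  for (dx in -r:r) {
    for (dy in -r:r) {
      d2 <- dx^2 + dy^2
      if (d2 <= radius^2) {
        rows[[k]] <- c(dx, dy, scale * sqrt(radius^2 - d2))
        k <- k + 1L
      }
    }
  }
  do.call(rbind, rows)
}

brute_ball_filter <- function(img, se, erode = TRUE) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (col in seq_len(w)) {
    for (row in seq_len(h)) {
      yy <- row + se[, 2]; xx <- col + se[, 1]
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
      v <- img[cbind(yy[ok], xx[ok])]
      out[row, col] <- if (erode) min(v - se[ok, 3]) else max(v + se[ok, 3])
    }
  }
  out
}

# Grayscale opening with the non-flat ball element (erosion then dilation).
brute_opening <- function(img, radius, scale = 1) {
  se <- ball_se(radius, scale)
  brute_ball_filter(brute_ball_filter(img, se, TRUE), se, FALSE)
}

# Average ranks by explicit counting.
brute_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

brute_spearman <- function(x, y) {
  rx <- brute_rank(x); ry <- brute_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  list(rho = num / den, S = sum((rx - ry)^2))
}

# Rasterize, mapping the "empty mask" error of sliver polygons to an
# all-FALSE mask so oracle comparisons stay total.
rasterize_allow_empty <- function(vertices, shape) {
  tryCatch(rasterize_roi(polygon_roi("total_tract", vertices), shape),
           error = function(e) {
             if (grepl("empty", conditionMessage(e)))
               matrix(FALSE, shape[1], shape[2]) else stop(e)
           })
}

# Star-shaped polygon (sorted angles), guaranteed simple, kept inside the
# image bounds.
random_polygon <- function(shape, n_vertices = sample(3:9, 1)) {
  repeat {
    cx <- runif(1, shape[2] * 0.35, shape[2] * 0.65)
    cy <- runif(1, shape[1] * 0.35, shape[1] * 0.65)
    th <- sort(runif(n_vertices, 0, 2 * pi))
    r <- runif(n_vertices, 1.5, min(shape) * 0.3)
    v <- cbind(cx + r * cos(th), cy + r * sin(th))
    # near-duplicate angles can degenerate into slivers that stop being
    # star-shaped after coordinate rounding; redraw those
    ok <- tryCatch({polygon_roi("total_tract", v); TRUE},
                   error = function(e) FALSE)
    if (ok) return(v)
  }
}

# Effect specification with every factor effect set to 1 (null model).
null_effects <- function(...) {
  one <- c(total_tract = 1, spermatheca = 1)
  effect_spec(cover_effects = list(thermal = one, status = one, time = one),
              intensity_effects = list(thermal = one, status = one,
                                       time = one), ...)
}

# Only the thermal effect on cover, at the given multiplier.
thermal_only_effects <- function(mult) {
  one <- c(total_tract = 1, spermatheca = 1)
  effect_spec(
    cover_effects = list(thermal = c(total_tract = mult, spermatheca = mult),
                         status = one, time = one),
    intensity_effects = list(thermal = one, status = one, time = one))
}

# Tract-cover quasi-binomial main-effects fit from simulated records.
fit_tract_cover <- function(rec, formula = NULL) {
  d <- rec[rec$site == "total_tract", ]
  d$succ <- d$cover_percent
  d$fail <- 100 - d$cover_percent
  if (is.null(formula))
    formula <- cbind(succ, fail) ~ thermal + female_status + time
  occupancy_glm(formula, d, "quasibinomial")
}
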