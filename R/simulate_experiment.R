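#' Factorial design of the sperm-storage experiment
#'
#' The 2 x 2 x 2 design crosses male thermal treatment (control, heat),
#' female mating status (virgin, mated) and time point (30 min, 24 h). The
#' default cell sizes are `(23, 25, 24, 25, 22, 24, 23, 24)` in the order
#' virgin/30min/control, virgin/30min/heat, virgin/24h/control,
#' virgin/24h/heat, mated/30min/control, mated/30min/heat,
#' mated/24h/control, mated/24h/heat (190 females in total).
#'
#' @param sizes integer vector of 8 cell sizes, all >= 1, in the order
#'   above.
#' @return a data frame of class `design_spec` with columns
#'   `female_status`, `time`, `thermal`, `n`.
#' @export
design_spec <- function(sizes = c(23L, 25L, 24L, 25L, 22L, 24L, 23L, 24L)) {
  stopifnot(length(sizes) == 8L, all(sizes >= 1))
  cells <- expand.grid(
    thermal = c("control", "heat"),
    time = c("30min", "24h"),
    female_status = c("virgin", "mated"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("female_status", "time", "thermal")]
  cells$n <- as.integer(sizes)
  class(cells) <- c("design_spec", "data.frame")
  cells
}

#' Generative effect sizes for simulated experiments
#'
#' Encodes the generative model behind the simulated experiment tables:
#' per-site baseline percentage cover and fluorescence intensity at the
#' reference cell (control / virgin / 30 min), multiplicative factor
#' effects on the response scale, beta-binomial overdispersion for cover,
#' Gaussian noise for intensity, and the paternity-assay parameters.
#'
#' Default effects mirror the magnitudes the analysis stage is designed to
#' detect: strong thermal effects at both sites, a temporal decline
#' confined to the total tract, and a competitor effect confined to the
#' spermatheca.
#'
#' @param baseline_cover named proportions in (0, 1) per site.
#' @param baseline_intensity named intensity units per site.
#' @param cover_effects,intensity_effects lists with elements `thermal`,
#'   `status`, `time`, each a named numeric vector of multiplicative
#'   effects per site applied when the factor is at its non-reference
#'   level (heat, mated, 24h).
#' @param cover_overdispersion beta-binomial intraclass correlation in
#'   `[0, 1)`.
#' @param intensity_noise_sd Gaussian noise s.d. per site (intensity
#'   units); draws are truncated at 0.
#' @param paternity_baseline focal-male paternity proportion in the
#'   control arm.
#' @param paternity_effect log-odds shift for the heat arm.
#' @param paternity_overdispersion beta-binomial intraclass correlation of
#'   the paternity proportion.
#' @param brood_mean mean brood size (Poisson).
#' @return a list of class `effect_spec`.
#' @export
effect_spec <- function(
    baseline_cover = c(total_tract = 0.35, spermatheca = 0.45),
    baseline_intensity = c(total_tract = 3000, spermatheca = 4000),
    cover_effects = list(
      thermal = c(total_tract = 0.68, spermatheca = 0.66),
      status = c(total_tract = 1, spermatheca = 0.30),
      time = c(total_tract = 0.28, spermatheca = 1)),
    intensity_effects = list(
      thermal = c(total_tract = 0.79, spermatheca = 0.64),
      status = c(total_tract = 1, spermatheca = 0.42),
      time = c(total_tract = 0.35, spermatheca = 1)),
    cover_overdispersion = 0.05,
    intensity_noise_sd = c(total_tract = 250, spermatheca = 350),
    paternity_baseline = 0.55,
    paternity_effect = -1.5,
    paternity_overdispersion = 0.35,
    brood_mean = 30) {
  stopifnot(all(baseline_cover > 0), all(baseline_cover < 1),
            cover_overdispersion >= 0, cover_overdispersion < 1,
            paternity_overdispersion >= 0, paternity_overdispersion < 1,
            paternity_baseline > 0, paternity_baseline < 1)
  structure(list(baseline_cover = baseline_cover,
                 baseline_intensity = baseline_intensity,
                 cover_effects = cover_effects,
                 intensity_effects = intensity_effects,
                 cover_overdispersion = cover_overdispersion,
                 intensity_noise_sd = intensity_noise_sd,
                 paternity_baseline = paternity_baseline,
                 paternity_effect = paternity_effect,
                 paternity_overdispersion = paternity_overdispersion,
                 brood_mean = brood_mean),
            class = "effect_spec")
}

# Beta-binomial draws with mean prob mu and intraclass correlation rho
# (rho = 0 reduces to plain binomial).
rbetabinom <- function(n, size, mu, rho) {
  if (rho == 0) return(rbinom(n, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

# Normal truncated at 0 via rejection (cheap: truncation mass is tiny at
# the default parameterizations).
rtruncnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

# Expected response for one site given the cell's factor levels.
cell_expectation <- function(base, eff, site, thermal, status, time) {
  mu <- base[[site]]
  mu <- mu * ifelse(thermal == "heat", eff$thermal[[site]], 1)
  mu <- mu * ifelse(status == "mated", eff$status[[site]], 1)
  mu <- mu * ifelse(time == "24h", eff$time[[site]], 1)
  mu
}

#' Simulate one sperm-storage experiment
#'
#' Draws one observation per female per site (total tract, spermatheca):
#' percentage cover beta-binomially with denominator 100 around the cell's
#' expected proportion, and mean intensity from a Gaussian truncated at 0
#' around the cell's expected mean. Factor effects act multiplicatively on
#' the response scale. Median intensity and presence are derived
#' covariates (a noisy fraction of the mean, and cover > 0) included so
#' the descriptive correlation machinery has realistic inputs.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()].
#' @param seed integer seed.
#' @return data frame (class `female_records`) with columns `female_id`,
#'   `thermal`, `female_status`, `time`, `site`, `cover_percent`,
#'   `mean_intensity`, `median_intensity`, `presence`; the generative
#'   truth is attached as `attr(, "truth")`.
#' @export
simulate_experiment <- function(design = design_spec(),
                                effects = effect_spec(), seed = 1L) {
  stopifnot(inherits(design, "design_spec"), inherits(effects, "effect_spec"))
  with_seed(seed, {
    females <- design[rep(seq_len(nrow(design)), design$n), 1:3]
    n_f <- nrow(females)
    females$female_id <- sprintf("F%03d", seq_len(n_f))
    rec <- females[rep(seq_len(n_f), each = 2L), ]
    rec$site <- rep(c("total_tract", "spermatheca"), times = n_f)

    mu_cov <- mapply(cell_expectation,
                     site = rec$site, thermal = rec$thermal,
                     status = rec$female_status, time = rec$time,
                     MoreArgs = list(base = as.list(effects$baseline_cover),
                                     eff = effects$cover_effects))
    if (any(mu_cov <= 0 | mu_cov >= 1))
      stop("expected cover proportion outside (0, 1) after effects")
    mu_int <- mapply(cell_expectation,
                     site = rec$site, thermal = rec$thermal,
                     status = rec$female_status, time = rec$time,
                     MoreArgs = list(
                       base = as.list(effects$baseline_intensity),
                       eff = effects$intensity_effects))

    rec$cover_percent <- rbetabinom(nrow(rec), 100L, mu_cov,
                                    effects$cover_overdispersion)
    rec$mean_intensity <- rtruncnorm0(
      nrow(rec), mu_int, effects$intensity_noise_sd[rec$site])
    rec$median_intensity <- rec$mean_intensity * runif(nrow(rec), 0.80, 0.95)
    rec$presence <- rec$cover_percent > 0

    rec <- rec[, c("female_id", "thermal", "female_status", "time", "site",
                   "cover_percent", "mean_intensity", "median_intensity",
                   "presence")]
    rownames(rec) <- NULL
    rec <- as_female_records(rec)
    attr(rec, "truth") <- effects
    rec
  })
}

# Coerce the design columns to factors with the reference levels first
# (control, virgin, 30min), matching the contrast direction of the
# analysis stage.
as_female_records <- function(df) {
  df$thermal <- factor(df$thermal, levels = c("control", "heat"))
  df$female_status <- factor(df$female_status, levels = c("virgin", "mated"))
  df$time <- factor(df$time, levels = c("30min", "24h"))
  df$site <- factor(df$site, levels = c("total_tract", "spermatheca"))
  class(df) <- c("female_records", "data.frame")
  df
}

#' Simulate a sperm-competition paternity assay
#'
#' For each female, the brood size is Poisson with the configured mean,
#' and the number of offspring sired by the focal (GFP) male is drawn
#' beta-binomially with an arm-specific paternity proportion: the control
#' baseline, shifted by the configured log-odds effect in the heat arm.
#' Offspring counts are conserved: `n_filiform + n_clubbed` equals the
#' drawn brood size.
#'
#' @param n_control,n_heat females per arm (default 19 and 18).
#' @param effects an [effect_spec()].
#' @param seed integer seed.
#' @return data frame (class `paternity_records`) with columns
#'   `female_id`, `male_treatment`, `n_filiform`, `n_clubbed`.
#' @export
simulate_paternity <- function(n_control = 19L, n_heat = 18L,
                               effects = effect_spec(), seed = 1L) {
  stopifnot(n_control >= 1, n_heat >= 1, inherits(effects, "effect_spec"))
  with_seed(seed, {
    arm <- rep(c("control", "heat"), c(n_control, n_heat))
    p <- ifelse(arm == "heat",
                plogis(qlogis(effects$paternity_baseline) +
                         effects$paternity_effect),
                effects$paternity_baseline)
    brood <- rpois(length(arm), effects$brood_mean)
    fil <- rbetabinom(length(arm), brood, p,
                      effects$paternity_overdispersion)
    out <- data.frame(
      female_id = sprintf("P%03d", seq_along(arm)),
      male_treatment = factor(arm, levels = c("control", "heat")),
      n_filiform = fil,
      n_clubbed = brood - fil)
    class(out) <- c("paternity_records", "data.frame")
    out
  })
}
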