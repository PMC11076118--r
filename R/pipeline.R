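#' Pipeline run configuration
#'
#' Assembles (and optionally loads from a YAML file) the full
#' configuration of an end-to-end run: seed, imaging parameters, design
#' and effect specifications, quantification thresholds and fallbacks,
#' and the output directory. Every stochastic run records its seed and
#' configuration in the output manifest.
#'
#' @param seed master integer seed; all per-sample seeds derive from it.
#' @param output_dir directory for CSV/JSON/TIFF outputs.
#' @param design_sizes 8 cell sizes for [design_spec()].
#' @param effects an [effect_spec()].
#' @param imaging named list of overrides for [imaging_params()]
#'   (image geometry, noise model, ...).
#' @param quant a [quant_config()].
#' @param paternity_n `(n_control, n_heat)` for the paternity assay.
#' @param write_images write every simulated channel stack as TIFF
#'   (default `FALSE`; the quantification itself is in-memory either way).
#' @param yaml_path optional YAML file; entries override the defaults
#'   above (schema version `gfpsperm/1`).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, output_dir = tempfile("gfpsperm_run_"),
                       design_sizes = c(23L, 25L, 24L, 25L,
                                        22L, 24L, 23L, 24L),
                       effects = effect_spec(),
                       imaging = list(),
                       quant = quant_config(),
                       paternity_n = c(19L, 18L),
                       write_images = FALSE,
                       yaml_path = NULL) {
  cfg <- list(schema = "gfpsperm/1", seed = as.integer(seed),
              output_dir = output_dir, design_sizes = design_sizes,
              effects = effects, imaging = imaging, quant = quant,
              paternity_n = paternity_n, write_images = write_images)
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    if (!is.null(y$schema) && !identical(y$schema, "gfpsperm/1"))
      stop("unsupported config schema: ", y$schema)
    for (nm in intersect(names(y), c("seed", "design_sizes", "imaging",
                                     "paternity_n", "write_images",
                                     "output_dir")))
      cfg[[nm]] <- y[[nm]]
    if (!is.null(y$effects))
      cfg$effects <- do.call(effect_spec, y$effects)
    if (!is.null(y$quant))
      cfg$quant <- do.call(quant_config, y$quant)
    cfg$seed <- as.integer(cfg$seed)
  }
  class(cfg) <- "run_config"
  cfg
}

# Map one female's target occupancy draws to imaging parameters: the
# sperm-cloud area scales with the target cover at fixed punctum density
# (clouds stay internally confluent), punctum amplitudes scale with the
# target intensity.
imaging_params_for_female <- function(cfg, tract_row, sperm_row, seed,
                                      roi_areas, density = 0.87) {
  base <- cfg$effects
  sigma <- if (!is.null(cfg$imaging$punctum_sigma))
    cfg$imaging$punctum_sigma else 0.9
  r_foot <- sigma * sqrt(2 * log(10))
  r_t <- sqrt(tract_row$cover_percent / 100 *
                roi_areas[["total_tract"]] / pi) - r_foot
  r_t <- min(max(r_t, 0), 26)
  r_s <- sqrt(sperm_row$cover_percent / 100 *
                roi_areas[["spermatheca"]] / pi) - r_foot
  r_s <- min(max(r_s, 0), 6)
  amp_mid <- 1200 * tract_row$mean_intensity /
    base$baseline_intensity[["total_tract"]]
  amp_mid <- min(max(amp_mid, 200), 6000)
  over <- c(list(
    n_puncta = as.integer(round(density * pi * r_t^2)),
    n_puncta_spermatheca = as.integer(round(density * pi * r_s^2)),
    bursa_cloud_radius = max(r_t, 0.5),
    sperm_cloud_radius = max(r_s, 0.5),
    punctum_amplitude_range = c(amp_mid * 0.83, amp_mid * 1.17),
    seed = seed), cfg$imaging)
  do.call(imaging_params, over[!duplicated(names(over))])
}

#' Run the full synthetic pipeline
#'
#' Chains the three stages end to end: simulates the factorial experiment
#' (per-female target occupancy draws), renders a ground-truthed
#' two-channel micrograph for every female, quantifies both sites through
#' the image chain, analyses the measured records with the GLM stage, and
#' analyses a simulated paternity assay. Writes the target and measured
#' record CSVs, a JSON results file, and a manifest (seed, config hash,
#' versions, counts) to the output directory. Per-sample failures are
#' recorded and tolerated up to 10% of samples; beyond that the run
#' errors.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_run`: `records_target`,
#'   `records_measured`, `occupancy`, `paternity`, `manifest`, `failures`.
#' @export
run_full_synthetic <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- child_seeds(config$seed, 2L)
  design <- design_spec(config$design_sizes)

  target <- simulate_experiment(design, config$effects, seeds[1])
  females <- unique(target$female_id)
  sample_seeds <- child_seeds(seeds[1] + 1L, length(females))

  shape <- if (!is.null(config$imaging$image_shape))
    config$imaging$image_shape else c(128L, 128L)
  geom <- default_scene_geometry(shape)
  roi_areas <- list(
    total_tract = sum(rasterize_polygon(geom$tract, shape)),
    spermatheca = sum(rasterize_polygon(geom$spermatheca, shape)))

  quants <- list(); failures <- list()
  for (i in seq_along(females)) {
    id <- females[i]
    tr <- target[target$female_id == id & target$site == "total_tract", ]
    sp <- target[target$female_id == id & target$site == "spermatheca", ]
    res <- tryCatch({
      params <- imaging_params_for_female(config, tr, sp, sample_seeds[i],
                                          roi_areas)
      sim <- simulate_tract_image(params)
      if (isTRUE(config$write_images)) {
        write_channel_stack(sim$stack,
                            file.path(config$output_dir, "images"), id)
        write_roi_json(sim$rois,
                       file.path(config$output_dir, "images",
                                 paste0(id, "_rois.json")))
      }
      quantify_sample(sim$stack, sim$rois, config$quant)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      quants[[id]] <- res
    }
  }
  if (length(failures) > 0.1 * length(females))
    stop("more than 10% of samples failed quantification")

  meta <- unique(as.data.frame(
    target[, c("female_id", "thermal", "female_status", "time")]))
  measured <- records_from_quantification(quants, meta)

  occupancy <- analyze_occupancy(measured)
  paternity <- analyze_paternity(
    simulate_paternity(config$paternity_n[1], config$paternity_n[2],
                       config$effects, seeds[2]))

  write_records_csv(target, file.path(config$output_dir,
                                      "records_target.csv"))
  write_records_csv(measured, file.path(config$output_dir,
                                        "records_measured.csv"))
  jsonlite::write_json(
    list(occupancy_table = occupancy$table,
         paternity = list(term_test = paternity$term_test,
                          contrast = paternity$contrast,
                          dispersion = paternity$dispersion,
                          pseudo_r2 = paternity$pseudo_r2)),
    file.path(config$output_dir, "results.json"),
    dataframe = "rows", digits = NA, auto_unbox = TRUE)

  manifest <- build_manifest(config, n_females = length(females),
                             n_site_records = nrow(measured),
                             failures = failures)
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       digits = NA, auto_unbox = TRUE)

  structure(list(records_target = target, records_measured = measured,
                 occupancy = occupancy, paternity = paternity,
                 manifest = manifest, failures = failures),
            class = "pipeline_run")
}

# Manifest: everything needed to reproduce the run bit-for-bit, plus a
# timestamp (the only field allowed to differ between identical runs).
build_manifest <- function(config, n_females, n_site_records, failures) {
  cfg_yaml <- yaml::as.yaml(strip_config(config))
  tmp <- tempfile(fileext = ".yaml")
  writeLines(cfg_yaml, tmp)
  on.exit(unlink(tmp))
  list(schema = config$schema,
       seed = config$seed,
       config = strip_config(config),
       config_md5 = unname(tools::md5sum(tmp)),
       package_version = as.character(packageVersion("gfpsperm")),
       r_version = R.version.string,
       n_females = n_females,
       n_site_records = n_site_records,
       n_failures = length(failures),
       failures = failures,
       timestamp = format(Sys.time(), tz = "UTC"))
}

# Drop output_dir (location-dependent) from the hashed config view.
strip_config <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  cfg$effects <- unclass(cfg$effects)
  cfg$quant <- unclass(cfg$quant)
  cfg
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Synthetic pipeline run: seed", x$manifest$seed, "\n")
  cat("  ", x$manifest$n_females, "females,", x$manifest$n_site_records,
      "site records,", x$manifest$n_failures, "failures\n\n")
  print(x$occupancy)
  cat("\n")
  print(x$paternity)
  invisible(x)
}

#' Quantify a directory of TIFF channel triples
#'
#' Scans `input_dir` for samples (`<id>_green.tif`, `<id>_red.tif`,
#' `<id>_brightfield.tif`, `<id>_rois.json`), runs [quantify_sample()] on
#' each, and writes one metrics row per sample x site to
#' `metrics.csv` in the output directory plus a JSON-lines provenance
#' log. Samples with missing or unreadable inputs are skipped with a
#' logged reason.
#'
#' @param input_dir directory of channel TIFFs and ROI JSON files.
#' @param config a [run_config()] (quantification settings and output
#'   directory are used).
#' @return data frame of metrics (one row per sample x site), invisibly;
#'   written to `metrics.csv`.
#' @export
run_quantify <- function(input_dir, config = run_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  greens <- sort(list.files(input_dir, pattern = "_green\\.tif$"))
  ids <- sub("_green\\.tif$", "", greens)
  log_path <- file.path(config$output_dir, "quantify_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log_con <- file(log_path, open = "a")
  on.exit(close(log_con))

  rows <- list()
  for (id in ids) {
    res <- tryCatch({
      stack <- read_channel_stack(input_dir, id)
      rois <- read_roi_json(file.path(input_dir,
                                      paste0(id, "_rois.json")))
      quantify_sample(stack, rois, config$quant)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      writeLines(jsonlite::toJSON(
        list(sample = id, status = "skipped",
             reason = conditionMessage(res)), auto_unbox = TRUE), log_con)
      next
    }
    writeLines(jsonlite::toJSON(
      list(sample = id, status = "ok", log = res$log),
      auto_unbox = TRUE, digits = NA), log_con)
    for (site in names(res$metrics)) {
      mt <- res$metrics[[site]]
      rows[[paste(id, site)]] <- data.frame(
        sample = id, site = site,
        mean_intensity = mt$mean_intensity,
        median_intensity = mt$median_intensity,
        percent_cover = mt$percent_cover, presence = mt$presence,
        threshold_value = mt$threshold_value,
        roi_area_px = mt$roi_area_px,
        int_gfp = res$log$int_gfp, int_auto = res$log$int_auto,
        correction_factor = res$log$factor,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(sample = character(0), site = character(0),
                  mean_intensity = numeric(0),
                  median_intensity = numeric(0),
                  percent_cover = numeric(0), presence = logical(0),
                  threshold_value = numeric(0),
                  roi_area_px = integer(0), int_gfp = numeric(0),
                  int_auto = numeric(0), correction_factor = numeric(0))
  if (nrow(out) == 0L)
    warning("no quantifiable samples found in ", input_dir)
  write.csv(out, file.path(config$output_dir, "metrics.csv"),
            row.names = FALSE)
  invisible(out)
}
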