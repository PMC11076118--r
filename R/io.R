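#' Write a channel stack as per-channel 16-bit TIFF files
#'
#' Writes `<sample_id>_brightfield.tif`, `<sample_id>_green.tif` and
#' `<sample_id>_red.tif`. Intensities stay on the 14-bit scale
#' (0..16383) inside a 16-bit container.
#'
#' @param stack a [channel_stack()].
#' @param dir output directory (created if missing).
#' @param sample_id sample identifier used as the filename stem.
#' @return the three file paths, invisibly.
#' @export
write_channel_stack <- function(stack, dir, sample_id) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(sample_id, "_",
                                 c("brightfield", "green", "red"), ".tif"))
  chans <- list(stack$brightfield, stack$green, stack$red)
  for (i in 1:3)
    tiff::writeTIFF(round(chans[[i]]) / 65535, paths[i],
                    bits.per.sample = 16L)
  invisible(paths)
}

#' Read a channel stack from per-channel 16-bit TIFF files
#'
#' @param dir directory containing the three channel files.
#' @param sample_id filename stem used by [write_channel_stack()].
#' @param site_context acquisition context of the sample.
#' @return a [channel_stack()].
#' @export
read_channel_stack <- function(dir, sample_id,
                               site_context = "total_tract") {
  paths <- file.path(dir, paste0(sample_id, "_",
                                 c("brightfield", "green", "red"), ".tif"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing channel file(s): ", paste(basename(missing),
                                            collapse = ", "))
  chans <- lapply(paths, function(p) round(tiff::readTIFF(p) * 65535))
  channel_stack(chans[[1]], chans[[2]], chans[[3]],
                site_context = site_context)
}

#' Flatten quantification results into occupancy records
#'
#' Builds one `female_records` row per sample x site from a list of
#' [quantify_sample()] results and the per-female metadata.
#'
#' @param quants named list of `sample_quantification` objects (names =
#'   female ids).
#' @param meta data frame with columns `female_id`, `thermal`,
#'   `female_status`, `time`, one row per female.
#' @return a `female_records` data frame (as in [simulate_experiment()],
#'   plus `threshold_value` and `correction_factor` provenance columns).
#' @export
records_from_quantification <- function(quants, meta) {
  rows <- lapply(names(quants), function(id) {
    q <- quants[[id]]
    m <- meta[meta$female_id == id, , drop = FALSE]
    do.call(rbind, lapply(names(q$metrics), function(site) {
      mt <- q$metrics[[site]]
      data.frame(female_id = id, thermal = m$thermal,
                 female_status = m$female_status, time = m$time,
                 site = site, cover_percent = mt$percent_cover,
                 mean_intensity = mt$mean_intensity,
                 median_intensity = mt$median_intensity,
                 presence = mt$presence,
                 threshold_value = mt$threshold_value,
                 correction_factor = q$log$factor,
                 stringsAsFactors = FALSE)
    }))
  })
  as_female_records(do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Write occupancy records to CSV
#'
#' @param records a `female_records` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Load an occupancy records CSV
#'
#' Loader for experiment tables, including ones exported from external
#' image analyses. The expected schema is one row per female x site with
#' columns `female_id`, `thermal` (control/heat), `female_status`
#' (virgin/mated), `time` (30min/24h), `site` (total_tract/spermatheca),
#' `cover_percent` (0..100), `mean_intensity`, `median_intensity`
#' (intensity units), `presence` (logical). Extra columns are kept.
#'
#' @param path CSV path.
#' @return a `female_records` data frame.
#' @export
read_records_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("female_id", "thermal", "female_status", "time", "site",
              "cover_percent", "mean_intensity", "median_intensity",
              "presence")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("records CSV lacks column(s): ", paste(missing, collapse = ", "))
  df$presence <- as.logical(df$presence)
  as_female_records(df)
}
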