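#' Full factorial analysis of occupancy records
#'
#' For each of the four response x site combinations (total-tract cover,
#' total-tract intensity, spermathecal cover, spermathecal intensity):
#' fits the appropriate family (logit-link quasi-binomial for percentage
#' cover entered as `cbind(percent, 100 - percent)`, identity-link
#' Gaussian for mean intensity) with all three design factors and their
#' two-way interactions, reduces to the minimum adequate model, and
#' reports per-term likelihood-ratio tests, post-hoc contrasts, Pearson
#' dispersion and explained deviance. Sites are modelled separately;
#' intensities are never compared across sites. Spearman correlations
#' among the occupancy metrics (presence vs cover, median vs mean
#' intensity) are computed per site. No multiple-testing correction is
#' applied.
#'
#' A fitting failure in one response is recorded and the remaining
#' responses are still analysed.
#'
#' @param records a `female_records` data frame (see
#'   [simulate_experiment()] or [records_from_quantification()]).
#' @param alpha interaction-retention threshold for model reduction.
#' @return object of class `occupancy_analysis`: `table` (flat summary,
#'   one row per fixed factor plus a residual row per response), `models`
#'   (named list of reduced fits), `contrasts`, `correlations`, `errors`.
#' @export
analyze_occupancy <- function(records, alpha = 0.05) {
  needed <- c("thermal", "female_status", "time", "site",
              "cover_percent", "mean_intensity")
  stopifnot(all(needed %in% names(records)))
  records <- as_female_records(as.data.frame(records))

  combos <- expand.grid(site = c("total_tract", "spermatheca"),
                        response = c("cover", "intensity"),
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$site, decreasing = TRUE), ]

  models <- list(); contrasts <- list(); errors <- list()
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    site <- combos$site[i]; response <- combos$response[i]
    label <- paste(site, response, sep = "_")
    d <- records[records$site == site, ]
    res <- tryCatch({
      if (response == "cover") {
        d$succ <- d$cover_percent
        d$fail <- 100 - d$cover_percent
        full <- occupancy_glm(
          cbind(succ, fail) ~ (thermal + female_status + time)^2,
          d, "quasibinomial")
      } else {
        full <- occupancy_glm(
          mean_intensity ~ (thermal + female_status + time)^2,
          d, "gaussian")
      }
      fit <- reduce_model(full, alpha)
      tests <- do.call(rbind, lapply(c("thermal", "female_status", "time"),
                                     function(tm) drop1_llrt(fit, tm)))
      list(fit = fit, tests = tests, posthoc = posthoc_contrasts(fit))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[label]] <- conditionMessage(res)
      next
    }
    models[[label]] <- res$fit
    contrasts[[label]] <- res$posthoc
    fam <- if (response == "cover") "GLM Q-bin (logit)" else "GLM Gaus (ID)"
    rows[[label]] <- rbind(
      data.frame(experiment = label, fixed_factor = res$tests$term,
                 df = res$tests$df,
                 statistic_kind = res$tests$statistic_kind,
                 statistic = res$tests$statistic,
                 p_value = res$tests$p_value, family = fam,
                 dispersion = pearson_dispersion(res$fit),
                 pseudo_r2 = pseudo_r2(res$fit),
                 stringsAsFactors = FALSE),
      data.frame(experiment = label, fixed_factor = "residual",
                 df = res$fit$df.residual, statistic_kind = "",
                 statistic = NA_real_, p_value = NA_real_, family = fam,
                 dispersion = NA_real_, pseudo_r2 = NA_real_,
                 stringsAsFactors = FALSE))
  }

  correlations <- lapply(c("total_tract", "spermatheca"), function(site) {
    d <- records[records$site == site, ]
    list(
      presence_vs_cover = try_spearman(as.numeric(d$presence),
                                       d$cover_percent),
      median_vs_mean = try_spearman(d$median_intensity, d$mean_intensity))
  })
  names(correlations) <- c("total_tract", "spermatheca")

  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 models = models, contrasts = contrasts,
                 correlations = correlations, errors = errors),
            class = "occupancy_analysis")
}

try_spearman <- function(x, y) {
  tryCatch(spearman_correlation(x, y), error = function(e) NULL)
}

#' @export
print.occupancy_analysis <- function(x, ...) {
  cat("Occupancy analysis (", length(x$models), "fitted responses )\n\n")
  tab <- x$table
  tab$statistic <- round(tab$statistic, 1)
  tab$p_value <- round(tab$p_value, 3)
  tab$dispersion <- round(tab$dispersion, 2)
  tab$pseudo_r2 <- round(100 * tab$pseudo_r2)
  print(tab, row.names = FALSE)
  if (length(x$errors))
    cat("\nFailed responses:",
        paste(names(x$errors), unlist(x$errors), sep = ": ",
              collapse = "; "), "\n")
  invisible(x)
}

#' Analyse a sperm-competition paternity assay
#'
#' Fits a logit-link quasi-binomial GLM of the paired offspring counts
#' `cbind(n_filiform, n_clubbed)` (focal-male vs competitor paternity) on
#' the male thermal treatment, and reports the likelihood-ratio term
#' test, the post-hoc contrast with percent change in the paternity
#' share, the Pearson dispersion and the explained deviance.
#'
#' @param records a `paternity_records` data frame (see
#'   [simulate_paternity()]).
#' @return object of class `paternity_analysis`: `fit`, `term_test`,
#'   `contrast`, `dispersion`, `pseudo_r2`, `n`.
#' @export
analyze_paternity <- function(records) {
  stopifnot(all(c("male_treatment", "n_filiform", "n_clubbed") %in%
                  names(records)))
  d <- as.data.frame(records)
  d$male_treatment <- factor(d$male_treatment,
                             levels = c("control", "heat"))
  if (any(table(d$male_treatment) == 0))
    stop("both treatment arms must be present")
  brood <- d$n_filiform + d$n_clubbed
  if (all(brood == 0)) stop("all broods are empty")
  d <- d[brood > 0, ]

  fit <- occupancy_glm(cbind(n_filiform, n_clubbed) ~ male_treatment,
                       d, "quasibinomial")
  structure(list(fit = fit,
                 term_test = drop1_llrt(fit, "male_treatment"),
                 contrast = posthoc_contrasts(fit),
                 dispersion = pearson_dispersion(fit),
                 pseudo_r2 = pseudo_r2(fit),
                 n = nrow(d)),
            class = "paternity_analysis")
}

#' @export
print.paternity_analysis <- function(x, ...) {
  cat("Paternity (P2) analysis, n =", x$n, "females\n")
  tt <- x$term_test
  cat(sprintf("  male treatment: chi2(%d) = %.1f, p = %.3f\n",
              tt$df, tt$statistic, tt$p_value))
  ct <- x$contrast
  cat(sprintf("  heat vs control: %+.0f%% paternity share (z = %.1f, p = %.3f)\n",
              ct$percent_change[1], ct$wald_statistic[1], ct$p_value[1]))
  cat(sprintf("  dispersion = %.2f, pseudo-R2 = %.0f%%\n",
              x$dispersion, 100 * x$pseudo_r2))
  invisible(x)
}
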