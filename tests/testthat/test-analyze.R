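test_that("the occupancy analysis table mirrors the reporting structure", {
  rec <- simulate_experiment(seed = 61)
  a <- analyze_occupancy(rec)
  expect_s3_class(a, "occupancy_analysis")
  expect_length(a$models, 4)
  expect_equal(nrow(a$table), 4 * 4)  # 3 fixed factors + residual row each
  expect_setequal(unique(a$table$fixed_factor),
                  c("thermal", "female_status", "time", "residual"))
  cover_rows <- a$table[a$table$experiment == "total_tract_cover" &
                          a$table$fixed_factor != "residual", ]
  expect_true(all(cover_rows$statistic_kind == "chi_squared"))
  int_rows <- a$table[a$table$experiment == "total_tract_intensity" &
                        a$table$fixed_factor != "residual", ]
  expect_true(all(int_rows$statistic_kind == "F"))
  r2 <- a$table$pseudo_r2[!is.na(a$table$pseudo_r2)]
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_output(print(a), "Occupancy analysis")
})

test_that("residual df is n minus the number of parameters", {
  rec <- simulate_experiment(seed = 62)
  a <- analyze_occupancy(rec)
  res <- a$table[a$table$fixed_factor == "residual", ]
  for (i in seq_len(nrow(res))) {
    fit <- a$models[[res$experiment[i]]]
    expect_equal(res$df[i], 190 - length(coef(fit)))
  }
})

test_that("injected effect patterns are detected where injected", {
  rec <- simulate_experiment(seed = 63)  # default effects
  a <- analyze_occupancy(rec)
  tab <- a$table
  p_of <- function(exp, term)
    tab$p_value[tab$experiment == exp & tab$fixed_factor == term]
  # thermal effects at both sites, temporal decline in the tract only,
  # competitor effect in the spermatheca only
  expect_lt(p_of("total_tract_cover", "thermal"), 0.05)
  expect_lt(p_of("total_tract_cover", "time"), 0.001)
  expect_lt(p_of("spermatheca_cover", "thermal"), 0.05)
  expect_lt(p_of("spermatheca_cover", "female_status"), 0.001)
  expect_lt(p_of("spermatheca_intensity", "female_status"), 0.001)
})

test_that("metric correlations are reported per site", {
  rec <- simulate_experiment(seed = 64)
  a <- analyze_occupancy(rec)
  for (site in c("total_tract", "spermatheca")) {
    mm <- a$correlations[[site]]$median_vs_mean
    expect_gt(mm$rho, 0.8)
    expect_equal(mm$n, 190)
  }
})

test_that("paternity analysis reports the full inference chain", {
  pat <- simulate_paternity(seed = 65)
  res <- analyze_paternity(pat)
  expect_s3_class(res, "paternity_analysis")
  expect_equal(res$fit$df.residual, res$n - 2)
  expect_equal(res$term_test$statistic_kind, "chi_squared")
  expect_lt(res$contrast$percent_change, 0)
  expect_gt(res$dispersion, 1)  # the generator is overdispersed
  expect_output(print(res), "Paternity")
})

test_that("identical arms give a null paternity test", {
  pat <- data.frame(
    female_id = sprintf("P%02d", 1:20),
    male_treatment = rep(c("control", "heat"), each = 10),
    n_filiform = rep(c(12, 15, 9, 20, 11), 4),
    n_clubbed = rep(c(8, 15, 21, 10, 19), 4))
  res <- analyze_paternity(pat)
  expect_gt(res$term_test$p_value, 0.9)
  expect_lt(abs(res$contrast$percent_change), 1e-6)
})

test_that("degenerate paternity inputs are rejected", {
  pat <- data.frame(female_id = c("a", "b"),
                    male_treatment = c("control", "heat"),
                    n_filiform = c(0, 0), n_clubbed = c(0, 0))
  expect_error(analyze_paternity(pat), "empty")
  one_arm <- data.frame(female_id = "a", male_treatment = "control",
                        n_filiform = 5, n_clubbed = 5)
  expect_error(analyze_paternity(one_arm), "arms")
})
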