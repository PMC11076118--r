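test_that("the default design reproduces the study cell structure", {
  rec <- simulate_experiment(seed = 1)
  expect_equal(nrow(rec), 380)
  expect_equal(length(unique(rec$female_id)), 190)
  tract <- rec[rec$site == "total_tract", ]
  # virgin/30min/(control,heat), virgin/24h/..., mated/30min/..., mated/24h
  grid <- expand.grid(thermal = c("control", "heat"),
                      time = c("30min", "24h"),
                      female_status = c("virgin", "mated"))
  sizes <- mapply(function(th, ti, st)
    sum(tract$thermal == th & tract$time == ti & tract$female_status == st),
    grid$thermal, grid$time, grid$female_status)
  expect_equal(unname(sizes), c(23, 25, 24, 25, 22, 24, 23, 24))
  expect_true(all(rec$cover_percent >= 0 & rec$cover_percent <= 100))
  expect_true(all(rec$mean_intensity >= 0))
})

test_that("seeds fully determine the simulated records", {
  a <- simulate_experiment(seed = 5)
  b <- simulate_experiment(seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$cover_percent,
                         simulate_experiment(seed = 6)$cover_percent))
})

test_that("null effects give equal cell means up to Monte-Carlo error", {
  big <- design_spec(rep(400L, 8))
  rec <- simulate_experiment(big, null_effects(cover_overdispersion = 0),
                             seed = 2)
  tract <- rec[rec$site == "total_tract", ]
  cells <- aggregate(cover_percent ~ thermal + female_status + time,
                     tract, mean)
  expect_lt(diff(range(cells$cover_percent)), 1.5)
})

test_that("multiplicative effects are injected on the response scale", {
  big <- design_spec(rep(2000L, 8))
  rec <- simulate_experiment(big, thermal_only_effects(0.68), seed = 3)
  tract <- rec[rec$site == "total_tract", ]
  ratio <- mean(tract$cover_percent[tract$thermal == "heat"]) /
    mean(tract$cover_percent[tract$thermal == "control"])
  expect_lt(abs(ratio - 0.68), 0.02)
})

test_that("impossible expected proportions are rejected", {
  bad <- effect_spec(cover_effects = list(
    thermal = c(total_tract = 3, spermatheca = 3),
    status = c(total_tract = 1, spermatheca = 1),
    time = c(total_tract = 1, spermatheca = 1)))
  expect_error(simulate_experiment(effects = bad, seed = 1),
               "outside \\(0, 1\\)")
})

test_that("paternity records conserve brood counts and arm sizes", {
  pat <- simulate_paternity(seed = 4)
  expect_equal(nrow(pat), 37)
  expect_equal(as.vector(table(pat$male_treatment)), c(19, 18))
  expect_true(all(pat$n_filiform >= 0 & pat$n_clubbed >= 0))
  a <- simulate_paternity(seed = 4)
  expect_identical(pat, a)
})

test_that("null paternity effects equalize arms; zero overdispersion is binomial", {
  eff <- effect_spec(paternity_effect = 0, paternity_overdispersion = 0)
  pat <- simulate_paternity(4000, 4000, eff, seed = 9)
  p_arm <- tapply(pat$n_filiform / (pat$n_filiform + pat$n_clubbed),
                  pat$male_treatment, mean)
  expect_lt(abs(p_arm[["control"]] - p_arm[["heat"]]), 0.01)
  # Poisson brood thinned by binomial sampling => filiform count is
  # Poisson with mean (and variance) brood_mean * p
  expect_lt(abs(var(pat$n_filiform) / (30 * 0.55) - 1), 0.1)
})
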