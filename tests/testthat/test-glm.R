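test_that("Gaussian fits equal closed-form OLS on a two-level factor", {
  withr::with_seed(41, {
    d <- data.frame(g = factor(rep(c("a", "b"), each = 12)),
                    y = c(rnorm(12, 10), rnorm(12, 14)))
    fit <- occupancy_glm(y ~ g, d, "gaussian")
    m <- tapply(d$y, d$g, mean)
    expect_equal(unname(coef(fit)),
                 unname(c(m["a"], m["b"] - m["a"])), tolerance = 1e-10)
  })
})

test_that("Gaussian IRLS equals lm on random small designs", {
  withr::with_seed(42, {
    for (i in 1:10) {
      d <- data.frame(a = factor(sample(c("x", "y"), 20, TRUE)),
                      b = factor(sample(c("u", "v"), 20, TRUE)),
                      y = rnorm(20))
      fit <- occupancy_glm(y ~ a + b, d, "gaussian")
      ols <- lm(y ~ a + b, d)
      expect_equal(coef(fit), coef(ols), tolerance = 1e-8)
    }
  })
})

test_that("the two-cell quasi-binomial slope is the log-odds difference", {
  d <- data.frame(g = factor(c("a", "b")), succ = c(90, 10),
                  fail = c(10, 90))
  fit <- occupancy_glm(cbind(succ, fail) ~ g, d, "quasibinomial")
  expect_equal(unname(coef(fit)["gb"]), -2 * log(9), tolerance = 1e-6)
})

test_that("a constant response gives zero non-intercept coefficients", {
  d <- data.frame(g = factor(rep(c("a", "b"), 6)), y = 7)
  fit <- occupancy_glm(y ~ g, d, "gaussian")
  expect_equal(unname(coef(fit)["gb"]), 0)
})

test_that("aliased designs are rejected", {
  d <- data.frame(a = factor(rep(c("x", "y"), 10)), y = rnorm(20))
  d$b <- d$a  # perfectly aliased copy
  expect_error(occupancy_glm(y ~ a + b, d, "gaussian"), "aliased")
})

test_that("Pearson dispersion reduces to known forms", {
  withr::with_seed(43, {
    d <- data.frame(g = factor(rep(c("a", "b"), each = 10)),
                    y = rnorm(20, 5))
    fit <- occupancy_glm(y ~ g, d, "gaussian")
    rss <- sum(residuals(fit)^2)
    expect_equal(pearson_dispersion(fit), rss / 18)
    # a perfect fit has zero dispersion
    d$y2 <- rep(c(1, 2), each = 10)
    expect_equal(pearson_dispersion(occupancy_glm(y2 ~ g, d, "gaussian")), 0)
  })
})

test_that("dispersion recovers beta-binomial variance inflation", {
  # constant denominator 100 and icc rho give phi = 1 + 99 * rho
  rho <- 0.05
  rec <- simulate_experiment(design_spec(rep(25L, 8)),
                             null_effects(cover_overdispersion = rho),
                             seed = 44)
  fit <- fit_tract_cover(rec)
  expect_lt(abs(pearson_dispersion(fit) / (1 + 99 * rho) - 1), 0.15)
})

test_that("drop1 LLRT matches stats::drop1 and classical ANOVA", {
  rec <- simulate_experiment(seed = 45)
  fit <- fit_tract_cover(rec)
  mine <- do.call(rbind, lapply(c("thermal", "female_status", "time"),
                                function(tm) drop1_llrt(fit, tm)))
  ref <- drop1(fit, test = "Chisq")
  expect_equal(mine$statistic, ref[["scaled dev."]][-1], tolerance = 1e-6)
  expect_equal(mine$p_value, ref[["Pr(>Chi)"]][-1], tolerance = 1e-6)

  d <- rec[rec$site == "total_tract", ]
  g <- occupancy_glm(mean_intensity ~ thermal, d, "gaussian")
  a <- anova(aov(mean_intensity ~ thermal, d))
  tt <- drop1_llrt(g, "thermal")
  expect_equal(tt$statistic, a[["F value"]][1], tolerance = 1e-10)
  expect_equal(tt$p_value, a[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(tt$statistic_kind, "F")
})

test_that("a term with exactly zero effect in a noise-free response tests null", {
  d <- expand.grid(a = factor(c("x", "y")), b = factor(c("u", "v")),
                   rep = 1:5)
  d$y <- ifelse(d$b == "v", 3, 1)  # depends only on b
  fit <- occupancy_glm(y ~ a + b, d, "gaussian")
  tt <- drop1_llrt(fit, "a")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
})

test_that("quasi-binomial coefficients are invariant to the dispersion", {
  rec <- simulate_experiment(seed = 46)
  d <- rec[rec$site == "total_tract", ]
  d$succ <- round(d$cover_percent); d$fail <- 100 - d$succ
  qb <- occupancy_glm(cbind(succ, fail) ~ thermal + time, d,
                      "quasibinomial")
  bin <- glm(cbind(succ, fail) ~ thermal + time, binomial(), d)
  expect_equal(coef(qb), coef(bin), tolerance = 1e-7)
  # dispersion scales the standard errors, not the estimates
  se_ratio <- summary(qb)$coefficients[, 2] /
    summary(bin)$coefficients[, 2]
  expect_equal(unname(se_ratio),
               rep(sqrt(pearson_dispersion(qb)), 3), tolerance = 1e-6)
})

test_that("model reduction keeps main effects and prunes null interactions", {
  rec <- simulate_experiment(seed = 47)
  full <- fit_tract_cover(
    rec, cbind(succ, fail) ~ (thermal + female_status + time)^2)
  red <- reduce_model(full)
  labs <- attr(terms(red), "term.labels")
  expect_true(all(c("thermal", "female_status", "time") %in% labs))
  # a model without interactions is returned unchanged
  main <- fit_tract_cover(rec)
  expect_identical(formula(reduce_model(main)), formula(main))
})

test_that("a strong injected interaction is retained", {
  withr::with_seed(48, {
    d <- expand.grid(a = factor(c("x", "y")), b = factor(c("u", "v")),
                     rep = 1:30)
    mu <- with(d, 10 + 3 * (a == "y") + 3 * (b == "v") +
                 8 * (a == "y") * (b == "v"))
    d$y <- rnorm(nrow(d), mu, 1)
    full <- occupancy_glm(y ~ a * b, d, "gaussian")
    red <- reduce_model(full)
    expect_true("a:b" %in% attr(terms(red), "term.labels"))
  })
})

test_that("post-hoc contrasts recover percent change and Wald identities", {
  rec <- simulate_experiment(seed = 49)
  d <- rec[rec$site == "total_tract", ]
  g <- occupancy_glm(mean_intensity ~ thermal, d, "gaussian")
  ph <- posthoc_contrasts(g)
  m <- tapply(d$mean_intensity, d$thermal, mean)
  expect_equal(ph$percent_change,
               100 * (m[["heat"]] - m[["control"]]) / m[["control"]],
               tolerance = 1e-8)
  # squared Wald t equals the drop1 F for a single two-level factor
  expect_equal(ph$wald_statistic^2, drop1_llrt(g, "thermal")$statistic,
               tolerance = 1e-8)
  expect_equal(ph$wald_kind, "t")
})

test_that("explained deviance behaves like a deviance R-squared", {
  withr::with_seed(50, {
    d <- data.frame(g = factor(rep(letters[1:2], each = 15)))
    d$y <- rnorm(30, ifelse(d$g == "b", 3, 0))
    null_fit <- occupancy_glm(y ~ 1, d, "gaussian")
    expect_equal(pseudo_r2(null_fit), 0)
    d$yp <- ifelse(d$g == "b", 3, 1)
    expect_equal(pseudo_r2(occupancy_glm(yp ~ g, d, "gaussian")), 1)
    # non-decreasing in nested models
    d$h <- factor(rep(c("u", "v"), 15))
    r1 <- pseudo_r2(occupancy_glm(y ~ g, d, "gaussian"))
    r2 <- pseudo_r2(occupancy_glm(y ~ g + h, d, "gaussian"))
    expect_gte(r2, r1)
    expect_error(pseudo_r2(occupancy_glm(yp ~ 1,
                                         transform(d, yp = 5),
                                         "gaussian")), "null deviance")
  })
})

test_that("Spearman correlation handles ties like the brute-force ranks", {
  expect_equal(spearman_correlation(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_correlation(1:8, (1:8)^2)$S, 0)
  expect_equal(spearman_correlation(1:8, 8:1)$rho, -1)
  withr::with_seed(51, {
    for (i in 1:25) {
      x <- sample(1:4, 8, TRUE); y <- sample(1:4, 8, TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      got <- spearman_correlation(x, y)
      want <- brute_spearman(x, y)
      expect_equal(got$rho, want$rho, tolerance = 1e-12)
      expect_equal(got$S, want$S, tolerance = 1e-12)
    }
  })
  expect_error(spearman_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("describe_by reports exact means and standard errors", {
  d <- data.frame(g = c("a", "a", "b"), y = c(3, 7, 2))
  out <- describe_by(d, "y", "g")
  expect_equal(out$mean, c(5, 2))
  expect_equal(out$se, c(2, 0))
  expect_equal(out$single_obs, c(FALSE, TRUE))
  expect_equal(out$n, c(2L, 1L))
})
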