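#' Fit a Gaussian or quasi-binomial occupancy GLM
#'
#' Thin, validated wrapper around [stats::glm()] exposing the two model
#' families used for occupancy responses: identity-link Gaussian for
#' continuous intensities and logit-link quasi-binomial for bounded
#' percentage-cover proportions entered as `cbind(success, fail)` with
#' denominator 100 (non-integer values are permitted; quasi-likelihood
#' does not require integer counts). Fitting is by iteratively reweighted
#' least squares to a relative-change tolerance of 1e-8 within 100
#' iterations; for the Gaussian family the fit coincides with ordinary
#' least squares, and the quasi-binomial dispersion is estimated post hoc
#' from Pearson residuals.
#'
#' @param formula model formula; for cover use
#'   `cbind(succ, fail) ~ thermal + female_status + time`.
#' @param data data frame of observations.
#' @param family `"gaussian"` (identity link) or `"quasibinomial"`
#'   (logit link).
#' @return a fitted model of class `occupancy_glm` extending `glm`, with
#'   the data retained for likelihood-ratio refits.
#' @export
occupancy_glm <- function(formula, data,
                          family = c("gaussian", "quasibinomial")) {
  family <- match.arg(family)
  fam <- switch(family,
                gaussian = gaussian(link = "identity"),
                quasibinomial = quasibinomial(link = "logit"))
  fit <- glm(formula, family = fam, data = data,
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop("GLM did not converge within 100 IRLS iterations")
  if (anyNA(coef(fit)))
    stop("aliased terms in the model (rank-deficient design)")
  if (family == "quasibinomial") {
    mu <- fit$fitted.values
    if (any(mu < 1e-10) || any(mu > 1 - 1e-10))
      stop("fitted probabilities of 0 or 1: (quasi-)complete separation")
  }
  fit$family_kind <- family
  fit$records <- data
  class(fit) <- c("occupancy_glm", class(fit))
  fit
}

#' Pearson overdispersion statistic
#'
#' The ratio of the Pearson chi-square to the residual degrees of
#' freedom, `phi = sum(pearson residual^2) / df_residual` — the standard
#' variance-to-mean check used to decide between binomial and
#' quasi-binomial error structures (phi near 1 means no overdispersion).
#' For the Gaussian family this equals the residual sum of squares over
#' its degrees of freedom.
#'
#' @param fit a fitted `glm`.
#' @return single numeric `phi`.
#' @export
pearson_dispersion <- function(fit) {
  df <- fit$df.residual
  if (df == 0) stop("saturated model: zero residual degrees of freedom")
  sum(residuals(fit, type = "pearson")^2) / df
}

refit_without <- function(fit, term) {
  newf <- update(formula(fit), paste(". ~ . -", term))
  occupancy_glm(newf, fit$records, fit$family_kind)
}

#' Single-term likelihood-ratio test
#'
#' Compares the fitted model with the model refitted without one term.
#' For continuous (Gaussian) responses the statistic is
#' `F = (deltaDeviance / deltaDf) / phi` with `phi` the Pearson dispersion
#' of the larger model, referred to an F distribution; for bounded
#' proportions (quasi-binomial) it is the scaled deviance difference
#' `deltaDeviance / phi`, referred to a chi-square distribution.
#'
#' Marginality is respected: when a higher-order interaction containing
#' the term is present in the model, the main effect is tested type-II
#' style — both compared models exclude the interactions that contain the
#' term — with the dispersion still taken from the full fitted model.
#'
#' @param fit an [occupancy_glm()] fit.
#' @param term character name of a term present in `fit`.
#' @return one-row data frame: `term`, `statistic_kind` (`"F"` or
#'   `"chi_squared"`), `statistic`, `df`, `p_value`.
#' @export
drop1_llrt <- function(fit, term) {
  stopifnot(inherits(fit, "occupancy_glm"))
  labels <- attr(terms(fit), "term.labels")
  if (!term %in% labels)
    stop("term '", term, "' not in the model")
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  containing <- labels[vapply(strsplit(labels, ":", fixed = TRUE),
                              function(l) length(l) > length(parts) &&
                                all(parts %in% l), FALSE)]
  base <- fit
  for (tm in containing) base <- refit_without(base, tm)
  reduced <- refit_without(base, term)
  ddf <- reduced$df.residual - base$df.residual
  if (ddf == 0) stop("dropping '", term, "' does not change the model df")
  ddev <- reduced$deviance - base$deviance
  if (ddev < 0 && ddev > -1e-8) ddev <- 0

  if (ddev == 0) {
    stat <- 0; p <- 1
    kind <- if (fit$family_kind == "gaussian") "F" else "chi_squared"
  } else if (fit$family_kind == "gaussian") {
    phi <- pearson_dispersion(fit)
    stat <- (ddev / ddf) / phi
    p <- pf(stat, ddf, fit$df.residual, lower.tail = FALSE)
    kind <- "F"
  } else {
    phi <- pearson_dispersion(fit)
    stat <- ddev / phi
    p <- pchisq(stat, ddf, lower.tail = FALSE)
    kind <- "chi_squared"
  }
  data.frame(term = term, statistic_kind = kind, statistic = stat,
             df = ddf, p_value = p, stringsAsFactors = FALSE)
}

#' Reduce a model to its minimum adequate form
#'
#' Starting from a model with all main effects and two-way interactions
#' (three-way interactions are never entered), iteratively drops the
#' least-significant interaction with `p >= alpha` (one at a time,
#' refitting between drops) until every remaining interaction is
#' significant. Main effects are conceptually part of the design and are
#' never dropped, regardless of p-value.
#'
#' @param fit an [occupancy_glm()] fit.
#' @param alpha retention threshold for interactions (default 0.05).
#' @return the reduced `occupancy_glm` fit.
#' @export
reduce_model <- function(fit, alpha = 0.05) {
  repeat {
    labels <- attr(terms(fit), "term.labels")
    inters <- labels[attr(terms(fit), "order")[seq_along(labels)] == 2]
    if (length(inters) == 0L) return(fit)
    tests <- do.call(rbind, lapply(inters, function(tm) drop1_llrt(fit, tm)))
    worst <- which.max(tests$p_value)
    if (tests$p_value[worst] < alpha) return(fit)
    fit <- refit_without(fit, tests$term[worst])
  }
}

#' Post-hoc treatment contrasts with percent change
#'
#' For each factor in a fitted minimum adequate model, reports the Wald
#' statistic of its non-reference level (`z` for quasi-binomial, `t` for
#' Gaussian) with its p-value, and the percent change of the
#' model-predicted response-scale mean relative to the reference level,
#' with all other factors balanced equally across their levels. Observed
#' group means with standard errors are attached for reporting.
#'
#' @param fit an [occupancy_glm()] fit.
#' @return data frame of class `effect_summary`, one row per factor
#'   contrast: `factor`, `contrast`, `percent_change`, `wald_kind`,
#'   `wald_statistic`, `p_value`, `ref_mean`, `trt_mean`,
#'   `obs_ref_mean`, `obs_ref_se`, `obs_trt_mean`, `obs_trt_se`.
#' @export
posthoc_contrasts <- function(fit) {
  stopifnot(inherits(fit, "occupancy_glm"))
  xl <- fit$xlevels
  if (length(xl) == 0L) stop("model contains no factors")
  grid <- expand.grid(xl, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = TRUE)
  pred <- predict(fit, newdata = grid, type = "response")
  coefs <- summary(fit)$coefficients
  wald_kind <- if (fit$family_kind == "gaussian") "t" else "z"

  obs <- observed_response(fit)
  rows <- lapply(names(xl), function(f) {
    ref <- xl[[f]][1]
    do.call(rbind, lapply(xl[[f]][-1], function(lev) {
      m_ref <- mean(pred[grid[[f]] == ref])
      m_trt <- mean(pred[grid[[f]] == lev])
      cname <- paste0(f, lev)
      stat <- if (cname %in% rownames(coefs)) coefs[cname, 3] else NA_real_
      p <- if (cname %in% rownames(coefs)) coefs[cname, 4] else NA_real_
      o_ref <- obs$y[fit$records[[f]] == ref]
      o_trt <- obs$y[fit$records[[f]] == lev]
      data.frame(factor = f, contrast = paste(lev, "vs", ref),
                 percent_change = 100 * (m_trt - m_ref) / m_ref,
                 wald_kind = wald_kind, wald_statistic = stat, p_value = p,
                 ref_mean = m_ref, trt_mean = m_trt,
                 obs_ref_mean = mean(o_ref),
                 obs_ref_se = sd(o_ref) / sqrt(length(o_ref)),
                 obs_trt_mean = mean(o_trt),
                 obs_trt_se = sd(o_trt) / sqrt(length(o_trt)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_summary", "data.frame")
  out
}

# Observed response on the response scale (proportion for matrix
# responses, raw values otherwise).
observed_response <- function(fit) {
  y <- fit$y
  if (!is.null(fit$prior.weights) && is.numeric(y) &&
      fit$family_kind == "quasibinomial") {
    return(list(y = y))  # glm stores proportions for matrix responses
  }
  list(y = y)
}

#' Explained deviance
#'
#' `pseudo R^2 = 1 - residual deviance / null deviance`: the share of the
#' null deviance captured by the model.
#'
#' @param fit a fitted `glm`.
#' @return single numeric in `[0, 1]` for nested-by-construction models.
#' @export
pseudo_r2 <- function(fit) {
  if (fit$null.deviance == 0)
    stop("null deviance is zero: explained deviance undefined")
  1 - fit$deviance / fit$null.deviance
}
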