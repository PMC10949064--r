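#' Build per-bat records for cohort statistics
#'
#' Joins bat metadata with bout-derived totals into the per-bat table feeding
#' the treatment-contrast models: arousal counts, drinking composite, and
#' mass loss.
#'
#' @param bats Tibble `bat_id`, `treatment`, `initial_mass_g`, `final_mass_g`.
#' @param behaviour_bouts Behavioural bout tibble (after [drop_last_torpor()]).
#' @param drinks_assigned Output of [assign_drinks()]; may be `NULL`.
#' @return Tibble with one row per bat: treatment, masses, `mass_loss_g`,
#'   `n_arousals`, `n_drinks`, `arousals_with_drink`, `arousals_without_drink`.
#' @export
build_bat_records <- function(bats, behaviour_bouts, drinks_assigned = NULL) {
  ar <- behaviour_bouts[behaviour_bouts$kind == "arousal", , drop = FALSE]
  if (is.null(drinks_assigned)) {
    drinks_assigned <- tibble::tibble(bat_id = character(0), time_min = numeric(0),
                                      arousal_start = numeric(0), assigned = logical(0))
  }
  tal <- tally_drinks(ar, drinks_assigned)
  bats |>
    dplyr::mutate(mass_loss_g = .data$initial_mass_g - .data$final_mass_g) |>
    dplyr::left_join(tal, by = "bat_id") |>
    tidyr::replace_na(list(n_arousals = 0L, n_drinks = 0L,
                           arousals_with_drink = 0L, arousals_without_drink = 0L))
}

new_model_fit <- function(response, transform, family, model, extra = list()) {
  structure(c(list(response = response, transform = transform, family = family,
                   model = model), extra),
            class = "torpor_fit")
}

#' @export
print.torpor_fit <- function(x, ...) {
  cat(sprintf("<torpor_fit> %s (%s%s)\n", x$response, x$family,
              if (!is.null(x$transform) && nzchar(x$transform)) paste0(", ", x$transform) else ""))
  print(tidy(x), n = 20)
  invisible(x)
}

#' @export
tidy.torpor_fit <- function(x, ...) x$coefficients

#' @export
glance.torpor_fit <- function(x, ...) {
  m <- x$model
  out <- tibble::tibble(response = x$response, family = x$family,
                        nobs = stats::nobs(m))
  if (inherits(m, "glm")) {
    out$deviance <- m$deviance
    out$df.residual <- m$df.residual
    out$dispersion <- x$dispersion %||% NA_real_
  } else if (inherits(m, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(m))
    out$v_individual <- vc$vcov[vc$grp == "bat_id"][1]
    out$v_residual <- vc$vcov[vc$grp == "Residual"][1]
    out$singular <- lme4::isSingular(m)
  }
  out
}

#' Linear mixed model for bout durations
#'
#' Fits the treatment-contrast model for arousal or torpor bout durations:
#' square-root transformed duration on humidity treatment and initial body
#' mass as fixed effects, with a random intercept per bat, by REML.
#' Censored bouts are excluded. Arousal durations are analysed in hours,
#' torpor durations in days. Coefficient tests use Satterthwaite degrees of
#' freedom. A singular fit (zero between-bat variance) is reported via
#' `glance()`, not an error.
#'
#' @param bouts Bout tibble (one source).
#' @param bat_records Per-bat table with `bat_id`, `treatment`,
#'   `initial_mass_g`.
#' @param response `"arousal_h"` or `"torpor_day"`.
#' @return A `torpor_fit`; `tidy()` gives the coefficient table, `glance()`
#'   the variance components.
#' @export
fit_duration_mixed_model <- function(bouts, bat_records,
                                     response = c("arousal_h", "torpor_day")) {
  response <- match.arg(response)
  kind <- if (response == "arousal_h") "arousal" else "torpor"
  denom <- if (response == "arousal_h") 60 else 1440
  d <- bouts |>
    dplyr::filter(.data$kind == !!kind, !.data$left_censored, !.data$right_censored) |>
    dplyr::transmute(.data$bat_id, y = sqrt(.data$duration_min / denom)) |>
    dplyr::inner_join(dplyr::select(bat_records, "bat_id", "treatment", "initial_mass_g"),
                      by = "bat_id")
  if (dplyr::n_distinct(d$treatment) < 2) abort("need bouts from both treatments.")
  if (min(table(unique(d[c("bat_id", "treatment")])$treatment)) < 2) {
    abort("need at least 2 bats per treatment.")
  }
  d$treatment <- factor(d$treatment, levels = treatments)
  m <- lmerTest::lmer(y ~ treatment + initial_mass_g + (1 | bat_id), data = d,
                      REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
  ct <- as.data.frame(coef(summary(m)))
  coefs <- tibble::tibble(term = rownames(ct), estimate = ct$Estimate,
                          std.error = ct$`Std. Error`, df = ct$df,
                          statistic = ct$`t value`, p.value = ct$`Pr(>|t|)`)
  new_model_fit(response, "sqrt", "gaussian (random intercept per bat)", m,
                list(coefficients = coefs, n_bouts = nrow(d),
                     n_bats = dplyr::n_distinct(d$bat_id)))
}

#' Repeatability of a repeatedly measured trait
#'
#' Estimates the proportion of total variance attributable to consistent
#' among-individual differences, `r = v_individual / (v_individual +
#' v_residual)`, from a random-intercept model on (optionally transformed)
#' values, and tests the individual effect with a likelihood-ratio test:
#' twice the log-likelihood difference (ML fits) between the models with and
#' without the random effect, against chi-square with 1 d.f. (conservative
#' at the boundary).
#'
#' @param measurements Tibble with `bat_id` and `value` (one row per
#'   measurement).
#' @param transform Applied to values before fitting (default `sqrt`; use
#'   `identity` for none).
#' @param estimator `"lmm"` (REML variance components) or `"anova"`
#'   (one-way moment estimator with Searle's coefficient for unbalanced
#'   data; negative between-individual estimates truncate to zero).
#' @param lrt Compute the likelihood-ratio test (default TRUE; skipping it
#'   saves two ML fits in large simulation loops).
#' @return A `repeatability` object: `v_individual`, `v_residual`, `r`,
#'   `lrt_chisq`, `lrt_df`, `lrt_p`, `n_bats`, `n_obs`.
#' @examples
#' m <- tibble::tibble(bat_id = c("A", "A", "B", "B"), value = c(1, 3, 5, 7))
#' repeatability(m, transform = identity, estimator = "anova")$r  # 7/9
#' @export
repeatability <- function(measurements, transform = sqrt,
                          estimator = c("lmm", "anova"), lrt = TRUE) {
  estimator <- match.arg(estimator)
  d <- tibble::tibble(bat_id = as.character(measurements$bat_id),
                      y = transform(measurements$value))
  n_per <- table(d$bat_id)
  if (length(n_per) < 2) abort("repeatability needs at least 2 individuals.")
  if (max(n_per) < 2) abort("repeatability undefined: no individual has repeated measures.")

  if (estimator == "anova") {
    a <- suppressWarnings(anova(lm(y ~ bat_id, data = d)))
    msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
    N <- nrow(d); k <- length(n_per)
    n0 <- (N - sum(n_per^2) / N) / (k - 1)  # Searle's coefficient
    v_i <- max(0, (msb - msw) / n0)
    v_r <- msw
  } else {
    m <- lme4::lmer(y ~ 1 + (1 | bat_id), data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(m))
    v_i <- vc$vcov[vc$grp == "bat_id"][1]
    v_r <- vc$vcov[vc$grp == "Residual"][1]
  }

  chisq <- NA_real_
  if (lrt) {
    m1 <- lme4::lmer(y ~ 1 + (1 | bat_id), data = d, REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    m0 <- lm(y ~ 1, data = d)
    chisq <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
  }
  structure(list(v_individual = v_i, v_residual = v_r,
                 r = v_i / (v_i + v_r),
                 lrt_chisq = chisq, lrt_df = 1L,
                 lrt_p = pchisq(chisq, 1, lower.tail = FALSE),
                 n_bats = length(n_per), n_obs = nrow(d),
                 estimator = estimator),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("<repeatability> r = %.3f (V_I = %.3g, V_Res = %.3g; %s)\n",
              x$r, x$v_individual, x$v_residual, x$estimator))
  cat(sprintf("  LRT chisq = %.2f, d.f. = 1, p = %.3g  [%d bats, %d obs]\n",
              x$lrt_chisq, x$lrt_p, x$n_bats, x$n_obs))
  invisible(x)
}

#' @export
tidy.repeatability <- function(x, ...) {
  tibble::tibble(term = c("bat_id", "residual"),
                 variance = c(x$v_individual, x$v_residual))
}

#' @export
glance.repeatability <- function(x, ...) {
  tibble::tibble(r = x$r, lrt_chisq = x$lrt_chisq, lrt_df = x$lrt_df,
                 lrt_p = x$lrt_p, n_bats = x$n_bats, n_obs = x$n_obs)
}

glm_coef_table <- function(m) {
  ct <- as.data.frame(coef(summary(m)))
  names(ct) <- c("estimate", "std.error", "statistic", "p.value")
  tibble::tibble(term = rownames(ct), estimate = ct$estimate,
                 std.error = ct$std.error, statistic = ct$statistic,
                 p.value = ct$p.value)
}

check_two_groups <- function(d) {
  tab <- table(d$treatment)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("need at least 2 bats in each treatment for a treatment contrast.")
  }
}

#' Poisson GLM for per-bat counts
#'
#' Log-link Poisson regression of a per-bat count (total arousals or total
#' drinks) on humidity treatment, optionally with initial body mass as a
#' covariate. The exponentiated treatment coefficient is the rate ratio; in
#' the treatment-only model it equals the ratio of group mean counts
#' exactly. A Pearson overdispersion statistic is reported.
#'
#' @param bat_records Output of [build_bat_records()].
#' @param response `"arousals"` or `"drinks"`.
#' @param include_mass Include `initial_mass_g` as a covariate (default TRUE).
#' @return A `torpor_fit` with `rate_ratio` and `dispersion`.
#' @export
fit_count_glm <- function(bat_records, response = c("arousals", "drinks"),
                          include_mass = TRUE) {
  response <- match.arg(response)
  col <- if (response == "arousals") "n_arousals" else "n_drinks"
  d <- tibble::tibble(count = bat_records[[col]],
                      treatment = factor(bat_records$treatment, levels = treatments),
                      initial_mass_g = bat_records$initial_mass_g)
  check_two_groups(d)
  if (any(tapply(d$count, d$treatment, function(v) all(v == 0)))) {
    warn("a treatment has all-zero counts; treatment effect is on the boundary (separation).")
  }
  fml <- if (include_mass) count ~ treatment + initial_mass_g else count ~ treatment
  m <- glm(fml, family = poisson(), data = d)
  disp <- sum(resid(m, type = "pearson")^2) / m$df.residual
  rr <- exp(unname(coef(m)["treatmentdry"]))
  new_model_fit(response, NULL, "poisson (log link)", m,
                list(coefficients = glm_coef_table(m), rate_ratio = rr,
                     dispersion = disp))
}

#' Binomial GLM for the proportion of arousals with drinking
#'
#' Logit-link binomial regression of the per-bat composite (arousals with
#' drinking, arousals without) on humidity treatment, optionally with
#' initial body mass. Bats with zero arousals are excluded with a warning.
#' In the treatment-only model the exponentiated treatment coefficient
#' equals the pooled-table odds ratio exactly.
#'
#' @inheritParams fit_count_glm
#' @return A `torpor_fit` with `odds_ratio`.
#' @export
fit_drink_proportion_glm <- function(bat_records, include_mass = TRUE) {
  d <- tibble::tibble(with = bat_records$arousals_with_drink,
                      without = bat_records$arousals_without_drink,
                      treatment = factor(bat_records$treatment, levels = treatments),
                      initial_mass_g = bat_records$initial_mass_g)
  zero <- d$with + d$without == 0
  if (any(zero)) {
    warn(sprintf("%d bat(s) with zero arousals excluded from the drinking-proportion model.",
                 sum(zero)))
    d <- d[!zero, , drop = FALSE]
  }
  check_two_groups(d)
  ok_sep <- tapply(seq_len(nrow(d)), d$treatment, function(i) {
    any(d$with[i] > 0) && any(d$without[i] > 0)
  })
  if (any(!ok_sep)) {
    warn("all arousals in one treatment share the same drinking outcome (separation).")
  }
  fml <- if (include_mass) cbind(with, without) ~ treatment + initial_mass_g
         else cbind(with, without) ~ treatment
  m <- glm(fml, family = binomial(), data = d)
  or <- exp(unname(coef(m)["treatmentdry"]))
  new_model_fit("drink proportion", NULL, "binomial (logit link)", m,
                list(coefficients = glm_coef_table(m), odds_ratio = or))
}

#' Gamma GLM for overwinter mass loss
#'
#' Gamma regression (log link) of total mass loss on initial body mass,
#' humidity treatment, total drinking bouts, and total arousals per bat.
#' Mass loss is right-skewed and strictly positive; bats with non-positive
#' recorded loss are excluded with a warning.
#'
#' @param bat_records Output of [build_bat_records()].
#' @return A `torpor_fit`.
#' @export
fit_mass_loss_glm <- function(bat_records) {
  d <- tibble::tibble(mass_loss = bat_records$initial_mass_g - bat_records$final_mass_g,
                      initial_mass_g = bat_records$initial_mass_g,
                      treatment = factor(bat_records$treatment, levels = treatments),
                      n_drinks = bat_records$n_drinks,
                      n_arousals = bat_records$n_arousals)
  bad <- !is.finite(d$mass_loss) | d$mass_loss <= 0
  if (any(bad)) {
    warn(sprintf("%d bat(s) with non-positive mass loss excluded.", sum(bad)))
    d <- d[!bad, , drop = FALSE]
  }
  check_two_groups(d)
  m <- glm(mass_loss ~ initial_mass_g + treatment + n_drinks + n_arousals,
           family = Gamma(link = "log"), data = d)
  new_model_fit("mass loss (g)", NULL, "gamma (log link)", m,
                list(coefficients = glm_coef_table(m)))
}

#' Cohen's d standardized mean difference
#'
#' Pooled-s.d. standardized difference of group means (sample variances with
#' n - 1 denominators; no small-sample correction), with the conventional
#' magnitude label: negligible below 0.2, small below 0.5, medium below 0.8,
#' large otherwise.
#'
#' @param group_a,group_b Numeric vectors (at least 2 values each).
#' @return Tibble: `d`, `magnitude`, `n_a`, `n_b`.
#' @examples
#' cohens_d(c(0, 2), c(2, 4))  # d = -1.414, large
#' @export
cohens_d <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2) abort("Cohen's d needs at least 2 values per group.")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(d = 0, magnitude = "negligible",
                            n_a = length(a), n_b = length(b)))
    }
    abort("Cohen's d undefined: zero pooled variance with unequal means.")
  }
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  mag <- cut(abs(d), c(-Inf, 0.2, 0.5, 0.8, Inf),
             labels = c("negligible", "small", "medium", "large"), right = FALSE)
  tibble::tibble(d = d, magnitude = as.character(mag),
                 n_a = length(a), n_b = length(b))
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper over the two-sample Welch t-test with Welch-Satterthwaite
#' degrees of freedom; degenerate inputs (both groups constant) short-cut to
#' an exact-equality comparison instead of erroring.
#'
#' @param group_a,group_b Numeric vectors (at least 2 values each).
#' @return Tibble: `statistic`, `df`, `p.value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2) abort("Welch's t needs at least 2 values per group.")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- mean(a) == mean(b)
    return(tibble::tibble(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                          df = length(a) + length(b) - 2,
                          p.value = if (eq) 1 else 0,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
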