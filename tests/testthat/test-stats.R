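fake_records <- function(counts_h, counts_d, mass = NULL,
                         with_h = NULL, wo_h = NULL, with_d = NULL, wo_d = NULL) {
  n <- length(counts_h) + length(counts_d)
  tibble::tibble(
    bat_id = sprintf("b%02d", seq_len(n)),
    treatment = rep(c("humid", "dry"), c(length(counts_h), length(counts_d))),
    initial_mass_g = mass %||% rep(26, n),
    final_mass_g = (mass %||% rep(26, n)) - 5,
    mass_loss_g = 5,
    n_arousals = c(counts_h, counts_d),
    n_drinks = c(counts_h, counts_d),
    arousals_with_drink = c(with_h %||% counts_h, with_d %||% counts_d),
    arousals_without_drink = c(wo_h %||% rep(0, length(counts_h)),
                               wo_d %||% rep(0, length(counts_d))))
}

test_that("repeatability matches the hand-worked balanced ANOVA case", {
  m <- tibble::tibble(bat_id = c("A", "A", "B", "B"), value = c(1, 3, 5, 7))
  # MS_between = 16, MS_within = 2, n = 2: V_I = 7, V_Res = 2, r = 7/9
  r_an <- repeatability(m, transform = identity, estimator = "anova")
  expect_equal(r_an$v_individual, 7, tolerance = 1e-12)
  expect_equal(r_an$v_residual, 2, tolerance = 1e-12)
  expect_equal(r_an$r, 7 / 9, tolerance = 1e-12)
  # REML coincides with the moment estimator on the balanced interior case
  r_lmm <- repeatability(m, transform = identity, estimator = "lmm")
  expect_equal(r_lmm$r, 7 / 9, tolerance = 1e-4)
  expect_equal(r_lmm$lrt_df, 1L)
  expect_gte(r_lmm$lrt_chisq, 0)
})

test_that("repeatability is 1 with zero residual variance, errors when undefined", {
  m <- tibble::tibble(bat_id = rep(c("A", "B", "C"), each = 3),
                      value = rep(c(2, 5, 9), each = 3))
  # LRT refit on zero-residual data triggers benign optimizer warnings
  expect_equal(suppressWarnings(
    repeatability(m, transform = identity, estimator = "anova"))$r, 1)
  expect_error(repeatability(tibble::tibble(bat_id = c("A", "B"), value = 1:2)),
               "repeated measures")
  expect_error(repeatability(tibble::tibble(bat_id = "A", value = c(1, 2))),
               "2 individuals")
})

test_that("r responds to the variance components as the definition requires", {
  # moment estimator: r increases with V_I at fixed V_Res, and hits the edges
  set.seed(4)
  n_bat <- 30
  make <- function(v_i) {
    b <- rnorm(n_bat, 0, sqrt(v_i))
    tibble::tibble(bat_id = rep(sprintf("b%d", 1:n_bat), each = 5),
                   value = rep(b, each = 5) + rnorm(n_bat * 5))
  }
  rs <- vapply(c(0.2, 1, 5), function(v)
    repeatability(make(v), transform = identity, estimator = "anova")$r, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("treatment-only Poisson fit reproduces the mean-count rate ratio exactly", {
  rec <- fake_records(c(10, 12, 14, 12), c(15, 18, 21, 18))
  fit <- fit_count_glm(rec, "arousals", include_mass = FALSE)
  expect_equal(fit$rate_ratio, mean(c(15, 18, 21, 18)) / mean(c(10, 12, 14, 12)),
               tolerance = 1e-8)
  # identical counts in both groups: ratio 1, p near 1
  rec0 <- fake_records(c(10, 12, 14), c(10, 12, 14))
  fit0 <- fit_count_glm(rec0, "arousals", include_mass = FALSE)
  expect_equal(fit0$rate_ratio, 1, tolerance = 1e-8)
  expect_gt(tidy(fit0)$p.value[tidy(fit0)$term == "treatmentdry"], 0.99)
})

test_that("count GLM guards: single-bat groups refused, all-zero flagged", {
  expect_error(fit_count_glm(fake_records(5, c(6, 7)), "arousals"), "at least 2")
  expect_warning(fit_count_glm(fake_records(c(0, 0, 0), c(3, 4, 5)), "arousals",
                               include_mass = FALSE),
                 "all-zero")
})

test_that("treatment-only binomial fit reproduces the pooled odds ratio exactly", {
  rec <- fake_records(c(5, 6), c(7, 8),
                      with_h = c(3, 2), wo_h = c(2, 4),
                      with_d = c(6, 7), wo_d = c(1, 1))
  fit <- fit_drink_proportion_glm(rec, include_mass = FALSE)
  or_pooled <- (13 / 2) / (5 / 6)
  expect_equal(fit$odds_ratio, or_pooled, tolerance = 1e-7)
})

test_that("binomial GLM flags zero-arousal bats and separation", {
  rec <- fake_records(c(5, 6, 0), c(7, 8, 9),
                      with_h = c(3, 2, 0), wo_h = c(2, 4, 0),
                      with_d = c(7, 8, 9), wo_d = c(0, 0, 0))
  expect_warning(expect_warning(fit_drink_proportion_glm(rec, include_mass = FALSE),
                                "zero arousals"),
                 "separation")
})

test_that("Poisson and binomial effects are recovered within 3 s.e.", {
  # rate ratio 1.52 and log-odds difference 1.0, a single seeded replicate
  # (the 200-replicate calibration runs in the acceptance suite)
  set.seed(12)
  n <- 50
  counts_h <- rpois(n, 10)
  counts_d <- rpois(n, 15.2)
  rec <- fake_records(counts_h, counts_d)
  fit <- fit_count_glm(rec, "arousals", include_mass = FALSE)
  co <- tidy(fit)
  est <- co$estimate[co$term == "treatmentdry"]
  se <- co$std.error[co$term == "treatmentdry"]
  expect_lt(abs(est - log(1.52)), 3 * se)

  tot <- rpois(2 * n, 12) + 1
  p <- stats::plogis(c(rep(0, n), rep(1, n)))
  wi <- rbinom(2 * n, tot, p)
  rec2 <- fake_records(rep(1, n), rep(1, n), with_h = wi[1:n], wo_h = (tot - wi)[1:n],
                       with_d = wi[(n + 1):(2 * n)], wo_d = (tot - wi)[(n + 1):(2 * n)])
  fit2 <- fit_drink_proportion_glm(rec2, include_mass = FALSE)
  co2 <- tidy(fit2)
  est2 <- co2$estimate[co2$term == "treatmentdry"]
  se2 <- co2$std.error[co2$term == "treatmentdry"]
  expect_lt(abs(est2 - 1), 3 * se2)
})

test_that("gamma mass-loss model finds the initial-mass slope and nothing else", {
  set.seed(3)
  n <- 40
  mass <- runif(2 * n, 22.4, 29.5)
  mu <- exp(-1 + 0.1 * mass)      # positive dependence on initial mass only
  loss <- rgamma(2 * n, shape = 50, scale = mu / 50)
  rec <- fake_records(rpois(n, 12), rpois(n, 12), mass = mass)
  rec$final_mass_g <- rec$initial_mass_g - loss
  fit <- fit_mass_loss_glm(rec)
  co <- tidy(fit)
  expect_lt(co$p.value[co$term == "initial_mass_g"], 0.001)
  expect_gt(co$estimate[co$term == "initial_mass_g"], 0)
  expect_gt(co$p.value[co$term == "treatmentdry"], 0.01)

  # constant loss: all slope terms at zero (dispersion NaN warnings benign)
  rec$final_mass_g <- rec$initial_mass_g - 5
  co0 <- tidy(suppressWarnings(fit_mass_loss_glm(rec)))
  expect_true(all(abs(co0$estimate[co0$term != "(Intercept)"]) < 1e-6))

  # non-positive losses excluded with a warning
  rec$final_mass_g[1] <- rec$initial_mass_g[1] + 1
  expect_warning(fit_mass_loss_glm(rec), "non-positive")
})

test_that("Cohen's d matches hand calculations and its invariances", {
  expect_equal(cohens_d(c(1, 2), c(1, 2))$d, 0)
  expect_equal(cohens_d(c(1, 2), c(1, 2))$magnitude, "negligible")
  # {0,2} vs {2,4}: pooled variance 2, |d| = 2/sqrt(2)
  res <- cohens_d(c(0, 2), c(2, 4))
  expect_equal(res$d, -2 / sqrt(2), tolerance = 1e-12)
  expect_equal(res$magnitude, "large")
  # antisymmetry and affine invariance
  a <- rnorm(20); b <- rnorm(20, 1)
  expect_equal(cohens_d(a, b)$d, -cohens_d(b, a)$d)
  expect_equal(cohens_d(3 * a + 7, 3 * b + 7)$d, cohens_d(a, b)$d, tolerance = 1e-9)
  expect_error(cohens_d(c(1, 1), c(2, 2)), "zero pooled variance")
})

test_that("Cohen's d estimates a unit standardized shift at large n", {
  set.seed(10)
  d <- cohens_d(rnorm(1e4), rnorm(1e4, 1))$d
  expect_lt(abs(d + 1), 0.05)
})

test_that("Welch's t matches the hand-worked case and handles degenerate input", {
  res <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_equal(welch_t(c(5, 5), c(5, 5))$statistic, 0)
  expect_equal(welch_t(c(5, 5), c(5, 5))$p.value, 1)
  expect_equal(welch_t(c(6, 6), c(5, 5))$p.value, 0)
  res0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$statistic, 0)
})

test_that("Welch's t holds its nominal type-I error", {
  set.seed(6)
  rej <- replicate(400, welch_t(rnorm(8), rnorm(12, sd = 2))$p.value < 0.05)
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("the duration mixed model recovers a known treatment shift", {
  set.seed(21)
  n_bat <- 25
  delta <- 0.6  # shift on the sqrt-hours scale
  mk_bouts <- function() {
    ids <- sprintf("s%02d", 1:(2 * n_bat))
    trt <- rep(c("humid", "dry"), each = n_bat)
    bi <- rnorm(2 * n_bat, 0, 0.3)
    rows <- lapply(1:(2 * n_bat), function(i) {
      mu <- 1.5 + if (trt[i] == "dry") delta else 0
      sq <- pmax(rnorm(12, mu + bi[i], 0.4), 0.05)
      tibble::tibble(bat_id = ids[i], source = "behaviour", kind = "arousal",
                     threshold_c = NA_real_, start_min = (1:12) * 1000,
                     end_min = (1:12) * 1000 + sq^2 * 60,
                     duration_min = sq^2 * 60,
                     left_censored = FALSE, right_censored = FALSE)
    })
    list(bouts = dplyr::bind_rows(rows),
         rec = tibble::tibble(bat_id = ids, treatment = trt,
                              initial_mass_g = runif(2 * n_bat, 22, 30)))
  }
  hits <- replicate(20, {
    d <- mk_bouts()
    co <- tidy(fit_duration_mixed_model(d$bouts, d$rec, "arousal_h"))
    i <- co$term == "treatmentdry"
    abs(co$estimate[i] - delta) < 3 * co$std.error[i]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("mixed-model treatment p-values are null-calibrated under permutation", {
  b <- clean_cohort(seed = 33, n = c(humid = 5, dry = 5), days = 80)
  beh <- drop_last_torpor(detect_bouts_behaviour(b$movements, b$spans))
  rec <- build_bat_records(b$bats, beh, NULL)
  set.seed(14)
  ps <- replicate(60, {
    r2 <- rec
    r2$treatment <- sample(r2$treatment)   # break any true association
    co <- tidy(fit_duration_mixed_model(beh, r2, "arousal_h"))
    co$p.value[co$term == "treatmentdry"]
  })
  expect_lt(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
  expect_gt(mean(ps), 0.25)  # roughly uniform, not clustered near 0
})

test_that("constant durations give a zero treatment effect and zero bat variance", {
  ids <- sprintf("c%d", 1:6)
  bouts <- tibble::tibble(bat_id = rep(ids, each = 4), source = "behaviour",
                          kind = "arousal", threshold_c = NA_real_,
                          start_min = rep(1:4 * 1000, 6),
                          end_min = rep(1:4 * 1000, 6) + 120,
                          duration_min = 120,
                          left_censored = FALSE, right_censored = FALSE)
  rec <- tibble::tibble(bat_id = ids, treatment = rep(c("humid", "dry"), 3),
                        initial_mass_g = 26)
  fit <- suppressWarnings(fit_duration_mixed_model(bouts, rec, "arousal_h"))
  co <- tidy(fit)
  expect_lt(abs(co$estimate[co$term == "treatmentdry"]), 1e-8)
  expect_lt(glance(fit)$v_individual, 1e-8)
})

test_that("per-bat records assemble counts, drinks and mass loss coherently", {
  b <- clean_cohort(seed = 9)
  beh <- drop_last_torpor(detect_bouts_behaviour(b$movements, b$spans))
  dr <- assign_drinks(b$drinks, beh[beh$kind == "arousal", ])
  rec <- build_bat_records(b$bats, beh, dr)
  expect_equal(nrow(rec), 6)
  expect_equal(rec$mass_loss_g, rec$initial_mass_g - rec$final_mass_g)
  expect_equal(rec$arousals_with_drink + rec$arousals_without_drink,
               rec$n_arousals)
  expect_true(all(rec$n_drinks >= rec$arousals_with_drink))
})
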