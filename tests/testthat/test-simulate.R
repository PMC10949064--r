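test_that("config validation enforces the parameter contracts", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_bats_per_treatment = c(humid = 0, dry = 5)), "at least 1")
  expect_error(sim_config(study_days = -1), "strictly positive")
  expect_error(sim_config(sample_interval = 17), "divide the study span")
  expect_error(sim_config(quantization_step = 0), "strictly positive")
  expect_error(sim_config(p_drink_given_arousal = c(humid = 1.2, dry = 0.5)), "\\[0, 1\\]")
  expect_error(sim_config(hsi_mean = c(humid = 150, dry = 2)), "\\[0, 100\\)")
  expect_error(sim_config(torpor_mean_duration = c(humid = 8, wet = 8)),
               "'humid' and 'dry'")
})

test_that("identical seeds give identical bundles; different seeds differ", {
  cfg <- sim_config(seed = 3, n_bats_per_treatment = c(humid = 2, dry = 2),
                    study_days = 20)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$traces, b2$traces)
  expect_identical(b1$movements, b2$movements)
  expect_identical(b1$drinks, b2$drinks)
  expect_identical(b1$bats, b2$bats)
  expect_identical(b1$truth$events, b2$truth$events)
  expect_identical(lapply(b1$masks, `[[`, "pixels"),
                   lapply(b2$masks, `[[`, "pixels"))

  b3 <- simulate_cohort(sim_config(seed = 4, n_bats_per_treatment = c(humid = 2, dry = 2),
                                   study_days = 20))
  expect_false(identical(b1$traces$tsk_c, b3$traces$tsk_c))
})

test_that("adding bats never perturbs existing bats", {
  mk <- function(nh) simulate_cohort(sim_config(
    seed = 9, n_bats_per_treatment = c(humid = nh, dry = 2), study_days = 20))
  small <- mk(2)
  big <- mk(3)
  for (id in unique(small$traces$bat_id)) {
    expect_identical(small$traces$tsk_c[small$traces$bat_id == id],
                     big$traces$tsk_c[big$traces$bat_id == id])
  }
})

test_that("truth intervals tile each bat's span without overlap", {
  b <- clean_cohort(seed = 2)
  span <- 40 * 1440
  for (id in unique(b$truth$events$bat_id)) {
    ev <- dplyr::arrange(dplyr::filter(b$truth$events, bat_id == id), start_min)
    expect_equal(ev$start_min[1], 0)
    expect_equal(ev$end_min[nrow(ev)], span)
    expect_equal(ev$start_min[-1], ev$end_min[-nrow(ev)])
    expect_true(all(ev$end_min > ev$start_min))
    # kinds alternate
    expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  }
})

test_that("every trace value is quantized to the configured step", {
  b <- clean_cohort(seed = 6)
  expect_true(all(abs(b$traces$tsk_c / 0.5 - round(b$traces$tsk_c / 0.5)) < 1e-9))
  bq <- simulate_cohort(sim_config(seed = 6, n_bats_per_treatment = c(humid = 1, dry = 1),
                                   study_days = 10, quantization_step = 0.25))
  expect_true(all(abs(bq$traces$tsk_c / 0.25 - round(bq$traces$tsk_c / 0.25)) < 1e-9))
})

test_that("cohort arousal counts match the renewal-process expectation", {
  b <- clean_cohort(seed = 31, n = c(humid = 10, dry = 10), days = 110)
  counts <- b$truth$events |>
    dplyr::filter(kind == "arousal") |>
    dplyr::count(bat_id) |>
    dplyr::inner_join(b$bats, by = "bat_id")
  for (tr in c("humid", "dry")) {
    tm <- sim_config()$torpor_mean_duration[[tr]]
    am <- sim_config()$arousal_mean_duration[[tr]] / 1440
    expected <- 110 / (tm + am)
    x <- counts$n[counts$treatment == tr]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected), 3 * se + 0.5)
  }
})

test_that("torpor longer than the study yields censored bouts and no arousals", {
  b <- simulate_cohort(sim_config(
    seed = 12, n_bats_per_treatment = c(humid = 3, dry = 3), study_days = 20,
    torpor_mean_duration = c(humid = 200, dry = 200),
    artifact_rates = list(shed_prob = 0, failure_prob = 0)))
  n_ar <- b$truth$events |>
    dplyr::filter(kind == "arousal") |>
    dplyr::count(bat_id)
  solo <- setdiff(unique(b$bats$bat_id), n_ar$bat_id)
  expect_gt(length(solo), 0)  # some bats never complete an arousal
  for (id in solo) {
    ev <- dplyr::filter(b$truth$events, bat_id == id)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$kind, "torpor")
    expect_true(ev$right_censored)
  }
})

test_that("a pure-torpor trace sits within one quantization step of the torpid plateau", {
  cfg <- sim_config(seed = 1, study_days = 10)
  ev <- tibble::tibble(bat_id = "x", kind = "torpor", start_min = 0,
                       end_min = 10 * 1440, left_censored = TRUE,
                       right_censored = TRUE)
  tr <- simulate_tsk_trace(ev, cfg, seed = 42)
  expect_true(all(abs(tr$tsk_c - 9) <= 0.5))
  expect_error(simulate_tsk_trace(ev[c(1, 1), ], cfg, seed = 1), "tile")
})

test_that("detector-measured arousal duration matches the closed-form ramp crossings", {
  # rewarm T(t) = 30 - 21 exp(-t/21); cooling T(t) = 9 + 21 exp(-t/42)
  # crossing 20 C: up at 21*log(21/10) = 15.58 min after onset,
  # down at 42*log(21/10) = 31.16 min after offset
  cfg <- sim_config(seed = 1, study_days = 14)
  ev <- tibble::tibble(
    bat_id = "x", kind = c("torpor", "arousal", "torpor"),
    start_min = c(0, 5000, 5134), end_min = c(5000, 5134, 14 * 1440),
    left_censored = c(TRUE, FALSE, FALSE),
    right_censored = c(FALSE, FALSE, TRUE))
  expected <- 134 + 42 * log(21 / 10) - 21 * log(21 / 10)
  durs <- sapply(1:20, function(s) {
    tr <- simulate_tsk_trace(ev, cfg, seed = s)
    b <- detect_bouts_tsk(tr, 20)
    b$duration_min[b$kind == "arousal"]
  })
  expect_true(all(abs(durs - expected) <= 30))  # within 2 sample intervals
})

test_that("the 20-degree detector recovers truth exactly on artifact-free traces", {
  b <- clean_cohort(seed = 8, n = c(humid = 4, dry = 4), days = 60)
  det <- detect_bouts_tsk(b$traces, 20)
  truth_counts <- b$truth$events |>
    dplyr::filter(kind == "arousal") |>
    dplyr::count(bat_id)
  det_counts <- det |>
    dplyr::filter(kind == "arousal") |>
    dplyr::count(bat_id)
  cmp <- dplyr::full_join(truth_counts, det_counts, by = "bat_id",
                          suffix = c("_true", "_det"))
  expect_equal(cmp$n_true, cmp$n_det)
  # mean durations within 2 sample intervals of truth
  md_det <- mean(det$duration_min[det$kind == "arousal" &
                                    !det$left_censored & !det$right_censored])
  tru <- dplyr::filter(b$truth$events, kind == "arousal", !right_censored)
  expect_lt(abs(md_det - mean(tru$end_min - tru$start_min)), 30)
})

test_that("artifact injection obeys the bookkeeping contracts", {
  cfg0 <- sim_config(seed = 1, artifact_rates = list(
    heating_per_100d = 0, shallow_heating_per_100d = 0,
    subthreshold_per_100d = 0, shed_prob = 0, failure_prob = 0))
  ev <- tibble::tibble(bat_id = "x", kind = c("torpor", "arousal", "torpor"),
                       start_min = c(0, 20000, 20150),
                       end_min = c(20000, 20150, 40 * 1440),
                       left_censored = c(TRUE, FALSE, FALSE),
                       right_censored = c(FALSE, FALSE, TRUE))
  tr <- simulate_tsk_trace(ev, sim_config(seed = 1, study_days = 40), seed = 2)
  log <- tibble::tibble(bat_id = "x", start_min = 20000, end_min = 20150)

  # all-zero rates: inputs unchanged
  out0 <- inject_artifacts(tr, log, cfg0, seed = 3)
  expect_identical(out0$trace, tr)
  expect_identical(out0$movements, log)
  expect_equal(nrow(out0$artifacts), 0)

  # heavy rates: count differences equal the applied artifact tallies
  cfg1 <- sim_config(seed = 1, artifact_rates = list(
    heating_per_100d = 25, shallow_heating_per_100d = 10,
    subthreshold_per_100d = 25, shed_prob = 0, failure_prob = 0))
  spans <- tibble::tibble(bat_id = "x", start_min = 0, end_min = 40 * 1440)
  for (s in 1:5) {
    out <- inject_artifacts(tr, log, cfg1, seed = s)
    applied <- out$artifacts[out$artifacts$applied, ]
    k <- sum(applied$type == "heating")
    m <- sum(applied$type == "subthreshold")
    n_tsk <- sum(detect_bouts_tsk(out$trace, 20)$kind == "arousal")
    n_beh <- sum(detect_bouts_behaviour(out$movements, spans)$kind == "arousal")
    expect_equal(n_tsk - n_beh, k - m)
    expect_true(all(applied$peak_c[applied$type == "heating"] <= 23.2))
    expect_true(all(applied$peak_c[applied$type != "heating"] >= 11.3 &
                      applied$peak_c[applied$type != "heating"] <= 18.6))
  }
})

test_that("single constructed artifacts shift one detector by exactly one bout", {
  # clean bat with one true arousal
  tsk <- c(rep(8, 20), rep(25, 6), rep(8, 20))
  tr <- make_trace(tsk)
  log <- tibble::tibble(bat_id = "b1", start_min = 300, end_min = 390)
  spans <- tibble::tibble(bat_id = "b1", start_min = 0, end_min = 46 * 15)
  base_tsk <- sum(detect_bouts_tsk(tr, 20)$kind == "arousal")
  base_beh <- sum(detect_bouts_behaviour(log, spans)$kind == "arousal")
  expect_equal(base_tsk, base_beh)

  # heating artifact: two warm samples, no movement
  tr2 <- tr; tr2$tsk_c[5:6] <- 22.5
  expect_equal(sum(detect_bouts_tsk(tr2, 20)$kind == "arousal"), base_tsk + 1)

  # sub-threshold movement: motion with only a shallow T_sk bump
  tr3 <- tr; tr3$tsk_c[40:41] <- 15
  log3 <- dplyr::bind_rows(log, tibble::tibble(bat_id = "b1", start_min = 585,
                                               end_min = 615))
  expect_equal(sum(detect_bouts_tsk(tr3, 20)$kind == "arousal"), base_tsk)
  expect_equal(sum(detect_bouts_behaviour(log3, spans)$kind == "arousal"),
               base_beh + 1)
})

test_that("clean-data concordance: both detectors agree per bat", {
  b <- clean_cohort(seed = 21, n = c(humid = 3, dry = 3), days = 50)
  tsk_counts <- detect_bouts_tsk(b$traces, 20) |>
    dplyr::filter(kind == "arousal") |>
    dplyr::count(bat_id)
  beh_counts <- detect_bouts_behaviour(b$movements, b$spans) |>
    dplyr::filter(kind == "arousal") |>
    dplyr::count(bat_id)
  cmp <- dplyr::full_join(tsk_counts, beh_counts, by = "bat_id")
  expect_equal(cmp$n.x, cmp$n.y)
})

test_that("huddle masks are single 4-connected regions with calibrated area", {
  cfg <- sim_config(seed = 2, n_photos = c(humid = 5, dry = 5))
  res <- simulate_huddle_masks(cfg, seed = 10)
  expect_length(res$masks, 10)
  for (m in res$masks) {
    px <- m$pixels
    expect_true(all(px %in% c(0L, 1L)))
    expect_equal(dim(px), c(238, 352))
    # each foreground row is one contiguous run, and the rows are contiguous:
    # sufficient for 4-connectivity of the filled ellipse
    rows <- which(rowSums(px) > 0)
    expect_equal(rows, seq(min(rows), max(rows)))
    for (r in rows) {
      cols <- which(px[r, ] == 1)
      expect_equal(cols, seq(min(cols), max(cols)))
    }
  }
  expect_equal(res$truth$true_pct,
               vapply(res$masks, function(m) 100 * sum(m$pixels) / length(m$pixels),
                      numeric(1)))
})

test_that("mask area fractions are centred on the configured treatment mean", {
  cfg <- sim_config(seed = 3, n_photos = c(humid = 1000, dry = 2))
  res <- simulate_huddle_masks(cfg, seed = 99)
  frac <- res$truth$true_pct[res$truth$treatment == "humid"]
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 2.14), 3 * se + 0.02)  # + rasterization allowance
})

test_that("requested zero area gives a valid all-background mask", {
  m <- torportools:::ellipse_mask(352, 238, 0)
  expect_equal(sum(m), 0)
  expect_equal(dim(m), c(238, 352))
})

test_that("shed and failed loggers truncate trace validity but not behaviour", {
  b <- simulate_cohort(sim_config(
    seed = 17, n_bats_per_treatment = c(humid = 6, dry = 6), study_days = 30,
    artifact_rates = list(heating_per_100d = 0, shallow_heating_per_100d = 0,
                          subthreshold_per_100d = 0, shed_prob = 0.5,
                          failure_prob = 0.2)))
  loss <- b$truth$logger_loss
  expect_true(any(loss$logger_failed) || any(!is.na(loss$shed_min)))
  for (i in seq_len(nrow(loss))) {
    tr <- b$traces[b$traces$bat_id == loss$bat_id[i], ]
    if (loss$logger_failed[i]) {
      expect_true(all(!tr$valid))
    } else if (!is.na(loss$shed_min[i])) {
      expect_true(all(!tr$valid[tr$time_min >= loss$shed_min[i]]))
      expect_true(all(tr$valid[tr$time_min < loss$shed_min[i]]))
    }
  }
  # movement logs still cover every true arousal
  beh <- detect_bouts_behaviour(b$movements, b$spans)
  expect_equal(sum(beh$kind == "arousal"),
               sum(b$truth$events$kind == "arousal"))
})

test_that("cohort round-trips through the plain-text fixture layout", {
  b <- clean_cohort(seed = 4, n = c(humid = 2, dry = 2), days = 20)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expect_true(all(file.exists(file.path(dir, c("traces.csv", "movements.csv",
                                               "drinks.csv", "bats.csv",
                                               "truth.json")))))
  rt <- read_cohort(dir)
  expect_equal(nrow(rt$traces), nrow(b$traces))
  expect_equal(rt$traces$tsk_c, b$traces$tsk_c)
  expect_equal(rt$bats$initial_mass_g, b$bats$initial_mass_g)
  expect_length(rt$masks, length(b$masks))
  expect_identical(rt$masks[[1]]$pixels, b$masks[[1]]$pixels)
})

test_that("cascade mode keeps tiling valid and synchronizes onsets within treatment", {
  b <- simulate_cohort(sim_config(
    seed = 23, n_bats_per_treatment = c(humid = 4, dry = 4), study_days = 60,
    cascade_sync = TRUE, cascade_jitter_sd = 20,
    artifact_rates = list(shed_prob = 0, failure_prob = 0)))
  span <- 60 * 1440
  ons <- b$truth$events |>
    dplyr::filter(kind == "arousal") |>
    dplyr::mutate(treatment = ifelse(grepl("^H", bat_id), "humid", "dry"))
  for (id in unique(b$truth$events$bat_id)) {
    ev <- dplyr::arrange(dplyr::filter(b$truth$events, bat_id == id), start_min)
    expect_equal(ev$start_min[1], 0)
    expect_equal(ev$end_min[nrow(ev)], span)
    expect_equal(ev$start_min[-1], ev$end_min[-nrow(ev)])
  }
  # onsets cluster: for each humid bat pair, most onsets have a near partner
  h <- split(ons$start_min[ons$treatment == "humid"],
             ons$bat_id[ons$treatment == "humid"])
  if (length(h) >= 2) {
    near <- mean(vapply(h[[1]], function(t) min(abs(h[[2]] - t)) < 120, logical(1)))
    expect_gt(near, 0.5)
  }
})
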