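#' Simulate a hibernating cohort
#'
#' Generates a complete synthetic hibernation experiment: per-bat
#' skin-temperature (T_sk) traces on a regular logger grid, behavioural
#' movement logs, drinking events, huddle masks, body-mass records, and the
#' ground truth behind all of them. The statistical structure mirrors the
#' assumptions of the downstream analysis: alternating multi-day torpor bouts
#' and brief arousals (shifted-gamma durations with per-bat multipliers),
#' exponential-approach rewarming/cooling between a torpid plateau near
#' ambient and a normothermic plateau near 30 degrees C, drinking during a
#' treatment-dependent fraction of arousals, treatment-dependent huddle area,
#' and mass loss increasing with initial mass. Optional artifacts (huddle
#' heating, sub-threshold movement, shed and failed loggers) reproduce the
#' known failure modes of skin-mounted dataloggers.
#'
#' Identical configs (including the seed) give bit-identical bundles. Each
#' bat draws from its own substream, so enlarging the roster never changes
#' existing animals.
#'
#' @param config A [sim_config()] object.
#' @return A `cohort_bundle`: list with `config`, `bats`, `traces`,
#'   `movements`, `spans`, `drinks`, `masks`, `artifacts` and `truth`
#'   (ground-truth events, drink assignments, mask area fractions, logger
#'   losses).
#' @examples
#' cfg <- sim_config(seed = 42, n_bats_per_treatment = c(humid = 2, dry = 2),
#'                   study_days = 30)
#' bundle <- simulate_cohort(cfg)
#' dplyr::count(bundle$truth$events, bat_id, kind)
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  span_min <- cfg$study_days * 1440
  n <- cfg$n_bats_per_treatment
  roster <- tibble::tibble(
    bat_id = c(sprintf("H%02d", seq_len(n[["humid"]])),
               sprintf("D%02d", seq_len(n[["dry"]]))),
    treatment = rep(treatments, times = c(n[["humid"]], n[["dry"]]))
  )
  n_bats <- nrow(roster)

  # cohort-level seeds first (fixed count), then one independent stream per
  # treatment with 6 slots per bat, so enlarging one treatment's roster
  # never renumbers the other's substreams
  seeds0 <- derive_seeds(cfg$seed, 4L)
  mask_seed <- seeds0[1L]
  cascade_seed <- seeds0[2L]
  stream <- list(humid = derive_seeds(seeds0[3L], 6L * n[["humid"]]),
                 dry = derive_seeds(seeds0[4L], 6L * n[["dry"]]))
  bat_seed <- function(i, slot) {
    tr <- roster$treatment[i]
    j <- sum(roster$treatment[seq_len(i)] == tr)  # index within treatment
    stream[[tr]][(j - 1L) * 6L + slot]
  }

  latent <- NULL
  if (cfg$cascade_sync) {
    latent <- with_seed(cascade_seed, lapply(treatments, function(tr) {
      cycle <- cfg$torpor_mean_duration[[tr]] * 1440 + cfg$arousal_mean_duration[[tr]]
      onsets <- cumsum(rgamma(ceiling(cfg$study_days * 1440 / cycle * 3) + 5,
                              shape = cfg$torpor_shape,
                              scale = cycle / cfg$torpor_shape))
      onsets[onsets < span_min]
    }))
    names(latent) <- treatments
  }

  events_l <- vector("list", n_bats)
  traces_l <- vector("list", n_bats)
  moves_l <- vector("list", n_bats)
  drinks_l <- vector("list", n_bats)
  truth_drinks_l <- vector("list", n_bats)
  art_l <- vector("list", n_bats)
  shed_l <- vector("list", n_bats)
  mass_l <- vector("list", n_bats)

  for (i in seq_len(n_bats)) {
    id <- roster$bat_id[i]
    tr <- roster$treatment[i]

    ev <- with_seed(bat_seed(i, 1L),
                    sim_bat_events(cfg, tr, span_min,
                                   latent_onsets = latent[[tr]]))
    ev$bat_id <- id
    ev <- ev[, c("bat_id", setdiff(names(ev), "bat_id"))]
    events_l[[i]] <- ev

    moves_l[[i]] <- with_seed(bat_seed(i, 1L) + 1L, sim_movements(ev, id))

    trace <- simulate_tsk_trace(ev, cfg, seed = bat_seed(i, 2L), treatment = tr)

    dr <- with_seed(bat_seed(i, 4L), sim_drinks(ev, cfg, tr, id))
    drinks_l[[i]] <- dr[, c("bat_id", "time_min")]
    truth_drinks_l[[i]] <- dr

    mass_l[[i]] <- with_seed(bat_seed(i, 5L), {
      im <- runif(1, cfg$initial_mass_range[1], cfg$initial_mass_range[2])
      mu <- cfg$massloss_intercept + cfg$massloss_slope_on_initial_mass * im
      mu <- max(mu, 0.5)
      shp <- 1 / cfg$massloss_cv^2
      loss <- rgamma(1, shape = shp, scale = mu / shp)
      tibble::tibble(bat_id = id, treatment = tr,
                     initial_mass_g = round(im, 1),
                     final_mass_g = round(im - loss, 1))
    })

    # logger losses + in-trace artifacts share the bat's artifact substream
    shed <- with_seed(bat_seed(i, 3L), {
      fail <- runif(1) < cfg$artifact_rates$failure_prob
      shed_at <- if (!fail && runif(1) < cfg$artifact_rates$shed_prob) {
        runif(1, 0.25, 0.95) * span_min
      } else {
        NA_real_
      }
      tibble::tibble(bat_id = id, logger_failed = fail, shed_min = shed_at)
    })
    shed_l[[i]] <- shed
    if (shed$logger_failed) {
      trace$valid <- FALSE
    } else if (!is.na(shed$shed_min)) {
      trace$valid <- trace$valid & trace$time_min < shed$shed_min
    }

    inj <- inject_artifacts(trace, moves_l[[i]], cfg, seed = bat_seed(i, 3L) + 1L)
    traces_l[[i]] <- inj$trace
    moves_l[[i]] <- inj$movements
    art_l[[i]] <- inj$artifacts
  }

  masks <- simulate_huddle_masks(cfg, seed = mask_seed)

  truth_events <- dplyr::bind_rows(events_l)
  bundle <- list(
    config = cfg,
    bats = dplyr::bind_rows(mass_l),
    traces = dplyr::bind_rows(traces_l),
    movements = dplyr::bind_rows(moves_l),
    spans = tibble::tibble(bat_id = roster$bat_id, start_min = 0,
                           end_min = span_min),
    drinks = dplyr::bind_rows(drinks_l),
    masks = masks$masks,
    artifacts = dplyr::bind_rows(art_l),
    truth = list(
      events = truth_events,
      drinks = dplyr::bind_rows(truth_drinks_l),
      mask_fractions = masks$truth,
      logger_loss = dplyr::bind_rows(shed_l)
    )
  )
  structure(bundle, class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf("  %d bats, %g days, %d trace samples, %d movement intervals\n",
              nrow(x$bats), x$config$study_days, nrow(x$traces), nrow(x$movements)))
  cat(sprintf("  %d drink events, %d huddle masks, %d true arousals\n",
              nrow(x$drinks), length(x$masks),
              sum(x$truth$events$kind == "arousal")))
  invisible(x)
}

# Alternating torpor/arousal renewal sequence tiling [0, span_min) exactly.
# Durations are shifted gammas; per-bat log-normal multipliers (mean-corrected)
# induce consistent individual differences.
sim_bat_events <- function(cfg, treatment, span_min, latent_onsets = NULL) {
  mult_t <- exp(rnorm(1, -cfg$bat_sd_torpor^2 / 2, cfg$bat_sd_torpor))
  mult_a <- exp(rnorm(1, -cfg$bat_sd_arousal^2 / 2, cfg$bat_sd_arousal))
  t_min <- cfg$torpor_min_duration * 1440
  t_extra <- (cfg$torpor_mean_duration[[treatment]] - cfg$torpor_min_duration) * 1440
  a_min <- cfg$arousal_min_duration
  a_extra <- cfg$arousal_mean_duration[[treatment]] - cfg$arousal_min_duration

  draw_torpor <- function() t_min + rgamma(1, cfg$torpor_shape,
                                           scale = t_extra * mult_t / cfg$torpor_shape)
  draw_arousal <- function() a_min + rgamma(1, cfg$arousal_shape,
                                            scale = a_extra * mult_a / cfg$arousal_shape)

  if (!is.null(latent_onsets)) {
    onsets <- sort(latent_onsets + rnorm(length(latent_onsets), 0, cfg$cascade_jitter_sd))
    onsets <- onsets[onsets > t_min & onsets < span_min]
    kind <- character(0); s <- numeric(0); e <- numeric(0)
    cur <- 0
    for (on in onsets) {
      if (on - cur < t_min) next
      dur <- draw_arousal()
      if (on + dur > span_min) dur <- span_min - on
      kind <- c(kind, "torpor", "arousal")
      s <- c(s, cur, on); e <- c(e, on, on + dur)
      cur <- on + dur
    }
    if (cur < span_min) { kind <- c(kind, "torpor"); s <- c(s, cur); e <- c(e, span_min) }
  } else {
    kind <- character(0); s <- numeric(0); e <- numeric(0)
    cur <- 0
    k <- "torpor"
    while (cur < span_min) {
      dur <- if (k == "torpor") draw_torpor() else draw_arousal()
      end <- min(cur + dur, span_min)
      kind <- c(kind, k); s <- c(s, cur); e <- c(e, end)
      cur <- end
      k <- if (k == "torpor") "arousal" else "torpor"
    }
  }
  tibble::tibble(
    kind = kind, start_min = s, end_min = e,
    left_censored = s == 0,
    right_censored = e >= span_min
  )
}

# Movement intervals for each true arousal: one to three bouts of motion
# separated by stillness gaps well under the 90-min termination window, so a
# behavioural detector recovers the arousal interval exactly.
sim_movements <- function(events, bat_id) {
  ar <- events[events$kind == "arousal", , drop = FALSE]
  if (nrow(ar) == 0) {
    return(tibble::tibble(bat_id = character(0), start_min = numeric(0),
                          end_min = numeric(0)))
  }
  out <- vector("list", nrow(ar))
  for (j in seq_len(nrow(ar))) {
    s <- ar$start_min[j]; e <- ar$end_min[j]
    dur <- e - s
    n_sub <- if (dur > 120) sample(1:3, 1, prob = c(0.5, 0.3, 0.2)) else 1L
    if (n_sub == 1L) {
      out[[j]] <- tibble::tibble(bat_id = bat_id, start_min = s, end_min = e)
    } else {
      # place n_sub - 1 stillness gaps (10-60 min each) inside the interval
      gaps <- runif(n_sub - 1L, 10, min(60, dur / (2 * n_sub)))
      inner <- sort(runif(n_sub - 1L, s + dur * 0.2, e - dur * 0.2))
      starts <- c(s, inner)
      ends <- c(inner - gaps, e)
      ends <- pmax(ends, starts + 1)
      out[[j]] <- tibble::tibble(bat_id = bat_id, start_min = starts, end_min = ends)
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start_min)
}

sim_drinks <- function(events, cfg, treatment, bat_id) {
  ar <- events[events$kind == "arousal" & !events$right_censored, , drop = FALSE]
  empty <- tibble::tibble(bat_id = character(0), time_min = numeric(0),
                          arousal_start = numeric(0))
  if (nrow(ar) == 0) return(empty)
  p <- cfg$p_drink_given_arousal[[treatment]]
  lam <- cfg$drink_extra_mean[[treatment]]
  out <- vector("list", nrow(ar))
  for (j in seq_len(nrow(ar))) {
    if (runif(1) < p) {
      k <- 1L + rpois(1, lam)
      out[[j]] <- tibble::tibble(
        bat_id = bat_id,
        time_min = sort(runif(k, ar$start_min[j] + 1, ar$end_min[j] - 1)),
        arousal_start = ar$start_min[j]
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Render one bat's skin-temperature trace from its true event sequence
#'
#' Builds the piecewise T_sk trajectory implied by a tiling sequence of torpor
#' and arousal intervals: a torpid plateau at `ambient_temp +
#' torpid_tsk_offset`, exponential-approach rewarming at `rewarm_rate`
#' (initial slope, degrees C/min) toward the normothermic plateau at arousal
#' onset, a jittered plateau for the rest of the arousal, and
#' exponential-approach cooling at `cool_rate` back to the torpid baseline
#' after the arousal ends. The trajectory is sampled every `sample_interval`
#' minutes and quantized to `quantization_step`.
#'
#' @param bat_truth Tibble of events with columns `kind` ("torpor"/"arousal"),
#'   `start_min`, `end_min`, tiling the span without gaps, and optionally
#'   `bat_id`.
#' @param config A [sim_config()].
#' @param seed Integer seed for the plateau jitter and baseline noise.
#' @param treatment Optional treatment label copied into the output.
#' @return Tibble with `bat_id`, `treatment`, `time_min`, `tsk_c`, `valid`.
#' @export
simulate_tsk_trace <- function(bat_truth, config, seed, treatment = NA_character_) {
  cfg <- validate_sim_config(unclass(config))
  ev <- dplyr::arrange(bat_truth, .data$start_min)
  if (nrow(ev) == 0) abort("`bat_truth` must contain at least one event.")
  if (any(abs(ev$start_min[-1] - ev$end_min[-nrow(ev)]) > 1e-6)) {
    abort("truth events must tile the span without gaps or overlap.")
  }
  span_min <- ev$end_min[nrow(ev)]
  times <- seq(0, span_min - cfg$sample_interval, by = cfg$sample_interval)
  t_torpid <- cfg$ambient_temp + cfg$torpid_tsk_offset
  t_norm <- cfg$normothermic_tsk_mean
  k_r <- cfg$rewarm_rate / (t_norm - t_torpid)
  k_c <- cfg$cool_rate / (t_norm - t_torpid)

  tsk <- with_seed(seed, {
    base <- t_torpid + rnorm(length(times), 0, 0.1)
    out <- base
    prev_arousal_end <- -Inf
    for (j in seq_len(nrow(ev))) {
      idx <- which(times >= ev$start_min[j] & times < ev$end_min[j])
      if (length(idx) == 0) next
      tt <- times[idx]
      if (ev$kind[j] == "arousal") {
        ramp <- t_norm - (t_norm - t_torpid) * exp(-k_r * (tt - ev$start_min[j]))
        out[idx] <- ramp + runif(length(idx), -cfg$plateau_jitter, cfg$plateau_jitter)
        prev_arousal_end <- ev$end_min[j]
      } else if (is.finite(prev_arousal_end) && prev_arousal_end <= ev$start_min[j]) {
        decay <- t_torpid + (t_norm - t_torpid) * exp(-k_c * (tt - ev$start_min[j]))
        cooling <- decay > t_torpid + 0.25
        out[idx] <- ifelse(cooling, decay, base[idx])
      }
    }
    out
  })
  tibble::tibble(
    bat_id = if ("bat_id" %in% names(ev)) ev$bat_id[1] else "bat",
    treatment = treatment,
    time_min = times,
    tsk_c = round(tsk / cfg$quantization_step) * cfg$quantization_step,
    valid = TRUE
  )
}

#' Inject datalogger and behaviour artifacts into a bat's record
#'
#' Adds the two artifact classes that make threshold and behavioural
#' detectors disagree: *heating artifacts* (T_sk pushed above 20 degrees C
#' for at least two samples by warm huddle-mates, peak at most 23.2 degrees
#' C, with no associated movement) and *sub-threshold movements* (motion
#' intervals whose T_sk response peaks between 11.3 and 18.6 degrees C).
#' Counts are Poisson with the configured per-100-day rates. Candidate sites
#' are torpid stretches well clear of true arousals; an artifact that cannot
#' be placed without touching one is skipped and logged.
#'
#' @param trace Single-bat T_sk tibble (`time_min`, `tsk_c`, `valid`).
#' @param log Single-bat movement tibble (`start_min`, `end_min`).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with modified `trace`, `movements`, and an `artifacts` tibble
#'   (`bat_id`, `type`, `start_min`, `end_min`, `peak_c`, `applied`).
#' @export
inject_artifacts <- function(trace, log, config, seed) {
  cfg <- validate_sim_config(unclass(config))
  bat <- trace$bat_id[1] %||% "bat"
  empty <- tibble::tibble(bat_id = character(0), type = character(0),
                          start_min = numeric(0), end_min = numeric(0),
                          peak_c = numeric(0), applied = logical(0))
  rate_h <- cfg$artifact_rates$heating_per_100d
  rate_sh <- cfg$artifact_rates$shallow_heating_per_100d
  rate_s <- cfg$artifact_rates$subthreshold_per_100d
  if (rate_h == 0 && rate_sh == 0 && rate_s == 0) {
    return(list(trace = trace, movements = log, artifacts = empty))
  }
  days <- (max(trace$time_min) + cfg$sample_interval) / 1440
  step <- cfg$quantization_step
  margin <- 120  # min clearance from any warm sample or movement

  with_seed(seed, {
    n_h <- rpois(1, rate_h * days / 100)
    n_sh <- rpois(1, rate_sh * days / 100)
    n_s <- rpois(1, rate_s * days / 100)
    types <- rep(c("heating", "shallow_heating", "subthreshold"),
                 times = c(n_h, n_sh, n_s))
    recs <- list()
    for (k in seq_along(types)) {
      type <- types[k]
      len <- sample(2:4, 1)                       # samples at peak
      peak <- if (type == "heating") {
        round(runif(1, 20.5 + step, 23.2) / step) * step
      } else {
        round(runif(1, 11.5, 18.5) / step) * step
      }
      # allowed: valid, torpid, far from warm samples and movements
      warm <- trace$tsk_c > cfg$ambient_temp + cfg$torpid_tsk_offset + 2
      near_warm <- near_any(trace$time_min, trace$time_min[warm], margin)
      near_move <- near_any(trace$time_min, c(log$start_min, log$end_min), margin) |
        in_any_interval(trace$time_min, log)
      ok <- trace$valid & !near_warm & !near_move
      # also require the whole bump (plus margin) to fit in an ok stretch
      need <- len + ceiling(margin / cfg$sample_interval)
      run_ok <- stats::filter(as.numeric(ok), rep(1, need), sides = 1)
      starts <- which(!is.na(run_ok) & run_ok == need) - need + 1L
      if (length(starts) == 0) {
        recs[[k]] <- tibble::tibble(bat_id = bat, type = type,
                                    start_min = NA_real_, end_min = NA_real_,
                                    peak_c = peak, applied = FALSE)
        next
      }
      i0 <- starts[sample.int(length(starts), 1)]
      idx <- i0:(i0 + len - 1L)
      t0 <- trace$time_min[i0]
      t1 <- trace$time_min[i0 + len - 1L] + cfg$sample_interval
      trace$tsk_c[idx] <- pmax(trace$tsk_c[idx], peak)
      if (type == "subthreshold") {
        log <- dplyr::arrange(
          dplyr::bind_rows(log, tibble::tibble(bat_id = bat, start_min = t0,
                                               end_min = t1)),
          .data$start_min)
      }
      recs[[k]] <- tibble::tibble(bat_id = bat, type = type, start_min = t0,
                                  end_min = t1, peak_c = peak, applied = TRUE)
    }
    arts <- if (length(recs)) dplyr::bind_rows(recs) else empty
    list(trace = trace, movements = log, artifacts = arts)
  })
}

near_any <- function(x, pts, margin) {
  if (length(pts) == 0) return(rep(FALSE, length(x)))
  p <- sort(pts)
  i <- findInterval(x, p)
  d_lo <- ifelse(i >= 1, x - p[pmax(i, 1)], Inf)
  d_hi <- ifelse(i < length(p), p[pmin(i + 1, length(p))] - x, Inf)
  pmin(d_lo, d_hi) <= margin
}

in_any_interval <- function(x, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(x)))
  o <- order(intervals$start_min)
  s <- intervals$start_min[o]; e <- intervals$end_min[o]
  i <- findInterval(x, s)
  i >= 1 & x < e[pmax(i, 1)]
}

#' Simulate binary huddle masks
#'
#' Draws, for each treatment, `n_photos` binary masks of `mask_dim` pixels
#' containing a single filled, axis-aligned elliptical huddle whose area
#' fraction is normal about the treatment's `hsi_mean` (s.d. `hsi_sd`,
#' truncated to stay positive and inside the frame). The realized pixel
#' fraction of every mask is recorded as ground truth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `masks` (list of `huddle_mask` objects: `image_id`,
#'   `treatment`, `capture_time`, integer 0/1 `pixels` matrix) and `truth`
#'   (tibble `image_id`, `treatment`, `requested_pct`, `true_pct`).
#' @export
simulate_huddle_masks <- function(config, seed) {
  cfg <- validate_sim_config(unclass(config))
  w <- cfg$mask_dim[1]; h <- cfg$mask_dim[2]
  with_seed(seed, {
    masks <- list(); rows <- list(); k <- 0L
    for (tr in treatments) {
      mu <- cfg$hsi_mean[[tr]]; sdv <- cfg$hsi_sd[[tr]]
      for (j in seq_len(cfg$n_photos[[tr]])) {
        k <- k + 1L
        frac <- -1
        while (frac <= 0.01 || frac >= 40) frac <- rnorm(1, mu, sdv)
        m <- ellipse_mask(w, h, frac)
        id <- sprintf("%s_photo_%02d", tr, j)
        masks[[k]] <- structure(
          list(image_id = id, treatment = tr,
               capture_time = round(runif(1, 1, cfg$study_days), 2) * 1440,
               pixels = m, observer = "synthetic"),
          class = "huddle_mask")
        rows[[k]] <- tibble::tibble(image_id = id, treatment = tr,
                                    requested_pct = frac,
                                    true_pct = 100 * sum(m) / length(m))
      }
    }
    list(masks = masks, truth = dplyr::bind_rows(rows))
  })
}

# Filled axis-aligned ellipse by pixel-centre inclusion; rows are y, cols x.
ellipse_mask <- function(w, h, frac_pct) {
  area <- frac_pct / 100 * w * h
  if (area < 0.5) return(matrix(0L, nrow = h, ncol = w))
  aspect <- runif(1, 1.2, 2.2)
  a <- sqrt(area * aspect / pi)       # semi-axis along x
  b <- area / (pi * a)                # semi-axis along y
  a <- min(a, w / 2 - 1); b <- min(b, h / 2 - 1)
  cx <- runif(1, a + 1, w - a)
  cy <- runif(1, b + 1, h - b)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  matrix(as.integer(inside), nrow = h)
}

#' Write / read a cohort bundle as plain-text fixtures
#'
#' Serializes a bundle to the on-disk layout consumed by the pipeline:
#' `traces.csv`, `movements.csv`, `drinks.csv`, `bats.csv`, `spans.csv`,
#' `masks/*.png` and `truth.json`.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$traces, file.path(dir, "traces.csv"))
  readr::write_csv(bundle$movements, file.path(dir, "movements.csv"))
  readr::write_csv(bundle$drinks, file.path(dir, "drinks.csv"))
  readr::write_csv(bundle$bats, file.path(dir, "bats.csv"))
  readr::write_csv(bundle$spans, file.path(dir, "spans.csv"))
  if (length(bundle$masks)) {
    mdir <- file.path(dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (m in bundle$masks) {
      png::writePNG(m$pixels + 0, file.path(mdir, paste0(m$image_id, ".png")))
    }
    readr::write_csv(
      tibble::tibble(
        image_id = vapply(bundle$masks, `[[`, "", "image_id"),
        treatment = vapply(bundle$masks, `[[`, "", "treatment"),
        capture_time = vapply(bundle$masks, `[[`, 0, "capture_time")),
      file.path(dir, "masks.csv"))
  }
  jsonlite::write_json(
    list(events = bundle$truth$events, drinks = bundle$truth$drinks,
         mask_fractions = bundle$truth$mask_fractions,
         logger_loss = bundle$truth$logger_loss),
    file.path(dir, "truth.json"), digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @param col_types Ignored; column types are fixed by the layout.
#' @export
read_cohort <- function(dir, col_types = NULL) {
  read1 <- function(f, types) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort(sprintf("missing cohort file '%s'", p))
    readr::read_csv(p, col_types = types, progress = FALSE)
  }
  traces <- read1("traces.csv", "ccddl")
  movements <- read1("movements.csv", "cdd")
  drinks <- read1("drinks.csv", "cd")
  bats <- read1("bats.csv", "ccdd")
  spans <- read1("spans.csv", "cdd")
  masks <- list()
  mfile <- file.path(dir, "masks.csv")
  if (file.exists(mfile)) {
    mtab <- readr::read_csv(mfile, col_types = "ccd", progress = FALSE)
    masks <- lapply(seq_len(nrow(mtab)), function(i) {
      px <- png::readPNG(file.path(dir, "masks", paste0(mtab$image_id[i], ".png")))
      if (length(dim(px)) == 3) px <- px[, , 1]
      structure(list(image_id = mtab$image_id[i], treatment = mtab$treatment[i],
                     capture_time = mtab$capture_time[i],
                     pixels = matrix(as.integer(px > 0.5), nrow = nrow(px)),
                     observer = "file"),
                class = "huddle_mask")
    })
  }
  structure(list(config = NULL, bats = bats, traces = traces,
                 movements = movements, spans = spans, drinks = drinks,
                 masks = masks, artifacts = NULL, truth = NULL),
            class = "cohort_bundle")
}
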