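# Shared fixture builders and the independent brute-force bout oracle.

make_trace <- function(tsk, bat_id = "b1", cadence = 15, valid = TRUE) {
  tibble::tibble(bat_id = bat_id,
                 time_min = seq(0, by = cadence, length.out = length(tsk)),
                 tsk_c = tsk,
                 valid = rep_len(valid, length(tsk)))
}

# Random quantized trace: iid draws from the 0.5-degree grid spanning the
# torpid-to-normothermic range, with occasional invalid samples.
random_trace <- function(n = NULL, p_invalid = 0.1, bat_id = "b1") {
  if (is.null(n)) n <- sample(4:60, 1)
  tsk <- sample(seq(5, 35, by = 0.5), n, replace = TRUE)
  valid <- runif(n) > p_invalid
  make_trace(tsk, bat_id = bat_id, valid = valid)
}

# Brute-force oracle for the two-reading threshold rule.  Deliberately a
# different algorithm from the package's rle walk: it labels every sample by
# stepping through the series one sample at a time, flipping state whenever
# the current and next sample agree on the opposite side of the threshold,
# then reads bouts off the label changes.  Operates per maximal valid run.
oracle_bouts_tsk <- function(trace, threshold) {
  trace <- trace[order(trace$time_min), ]
  cadence <- if (nrow(trace) > 1) diff(trace$time_min)[1] else 15
  v <- trace$valid & is.finite(trace$tsk_c)
  out <- list()
  i <- 1
  n <- nrow(trace)
  while (i <= n) {
    if (!v[i]) { i <- i + 1; next }
    j <- i
    while (j < n && v[j + 1]) j <- j + 1
    out[[length(out) + 1]] <- oracle_scan_run(trace$time_min[i:j],
                                              trace$tsk_c[i:j],
                                              threshold, cadence)
    i <- j + 1
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  res$bat_id <- trace$bat_id[1]
  res
}

oracle_scan_run <- function(times, tsk, threshold, cadence) {
  n <- length(tsk)
  above <- tsk > threshold
  # initial state: side of the first two consecutive agreeing samples
  init <- above[1]
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      if (above[i] == above[i + 1]) { init <- above[i]; break }
    }
  }
  lab <- logical(n)
  state <- init
  for (i in seq_len(n)) {
    if (above[i] != state && i < n && above[i + 1] == above[i]) {
      state <- above[i]
    }
    lab[i] <- state
  }
  changes <- which(diff(lab) != 0) + 1L
  starts <- c(1L, changes)
  ends <- c(changes, n + 1L)
  data.frame(
    kind = ifelse(lab[starts], "arousal", "torpor"),
    start_min = times[starts],
    end_min = c(times[changes], times[n] + cadence),
    left_censored = seq_along(starts) == 1L,
    right_censored = seq_along(starts) == length(starts),
    stringsAsFactors = FALSE
  )
}

bouts_equal <- function(b, o) {
  if (is.null(o)) return(nrow(b) == 0)
  b <- b[order(b$start_min), ]
  o <- o[order(o$start_min), ]
  nrow(b) == nrow(o) &&
    all(b$kind == o$kind) &&
    all(abs(b$start_min - o$start_min) < 1e-9) &&
    all(abs(b$end_min - o$end_min) < 1e-9) &&
    all(b$left_censored == o$left_censored) &&
    all(b$right_censored == o$right_censored)
}

# small clean cohort used across tests
clean_cohort <- function(seed = 1, n = c(humid = 3, dry = 3), days = 40, ...) {
  simulate_cohort(sim_config(
    seed = seed, n_bats_per_treatment = n, study_days = days,
    artifact_rates = list(heating_per_100d = 0, shallow_heating_per_100d = 0,
                          subthreshold_per_100d = 0, shed_prob = 0,
                          failure_prob = 0),
    ...))
}
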