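#' Detect torpor bouts and arousals from a skin-temperature trace
#'
#' Segments each bat's T_sk series with the two-reading threshold rule: the
#' bat is scored normothermic from the first sample of a run of at least two
#' consecutive valid samples strictly above `threshold`, and torpid from the
#' first sample of a run of at least two consecutive valid samples at or
#' below it. Single-sample excursions never flip the state. Samples before
#' the first qualifying run belong to a censored bout of the initial state's
#' kind. Bouts never span invalid gaps; bouts abutting the trace edges or an
#' invalid gap are flagged censored on that side.
#'
#' @param trace Tibble with `bat_id`, `time_min` (regular cadence, strictly
#'   increasing within bat), `tsk_c`, `valid`; multiple bats allowed.
#' @param threshold T_sk threshold, degrees C.
#' @return Tibble of bouts: `bat_id`, `source` (`"tsk_threshold"`), `kind`
#'   (`"torpor"`/`"arousal"`), `threshold_c`, `start_min`, `end_min`,
#'   `duration_min`, `left_censored`, `right_censored`. Intervals are
#'   half-open `[start, end)`.
#' @examples
#' tr <- tibble::tibble(bat_id = "b1", time_min = seq(0, 75, 15),
#'                      tsk_c = c(8, 8, 25, 25, 8, 8), valid = TRUE)
#' detect_bouts_tsk(tr, threshold = 20)
#' @export
detect_bouts_tsk <- function(trace, threshold) {
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  needed <- c("bat_id", "time_min", "tsk_c", "valid")
  if (!all(needed %in% names(trace))) {
    abort("`trace` needs columns bat_id, time_min, tsk_c, valid.")
  }
  ids <- trace$bat_id
  acc <- list()
  for (ix in split(seq_along(ids), ids)) {
    acc[[length(acc) + 1L]] <-
      detect_tsk_one(ids[ix[1]], trace$time_min[ix], trace$tsk_c[ix],
                     trace$valid[ix], threshold)
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (length(acc) == 0) {
    warn("no valid samples anywhere; returning empty bout table.")
    return(tibble::tibble(bat_id = character(0), source = character(0),
                          kind = character(0), threshold_c = numeric(0),
                          start_min = numeric(0), end_min = numeric(0),
                          duration_min = numeric(0),
                          left_censored = logical(0), right_censored = logical(0)))
  }
  pull <- function(f) do.call(c, lapply(acc, `[[`, f))
  s <- pull("start"); e <- pull("end")
  tibble::tibble(
    bat_id = pull("bat_id"), source = "tsk_threshold",
    kind = ifelse(pull("state"), "arousal", "torpor"),
    threshold_c = threshold, start_min = s, end_min = e,
    duration_min = e - s,
    left_censored = pull("lc"), right_censored = pull("rc"))
}

detect_tsk_one <- function(id, tm, ts, vv, threshold) {
  o <- order(tm)
  tm <- tm[o]; ts <- ts[o]; vv <- vv[o]
  dt <- diff(tm)
  if (length(dt) > 0 && any(abs(dt - dt[1]) > 1e-6)) {
    abort(sprintf("trace for bat '%s' is not on a regular cadence.", id))
  }
  cadence <- if (length(dt)) dt[1] else 15
  v <- vv & is.finite(ts)
  if (!any(v)) return(NULL)
  # maximal runs of valid samples
  rv <- rle(v)
  ends <- cumsum(rv$lengths)
  starts <- ends - rv$lengths + 1L
  state <- logical(0); s <- numeric(0); e <- numeric(0)
  lc <- logical(0); rc <- logical(0)
  for (j in which(rv$values)) {
    idx <- starts[j]:ends[j]
    b <- scan_valid_run(tm[idx], ts[idx], threshold, cadence)
    state <- c(state, b$state); s <- c(s, b$start); e <- c(e, b$end)
    lc <- c(lc, b$lc); rc <- c(rc, b$rc)
  }
  list(bat_id = rep(id, length(s)), state = state, start = s, end = e,
       lc = lc, rc = rc)
}

# State machine over one gap-free run of valid samples.
scan_valid_run <- function(times, tsk, threshold, cadence) {
  n <- length(times)
  above <- tsk > threshold
  r <- rle(above)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  qualifying <- r$lengths >= 2L
  first_q <- which(qualifying)[1]
  init <- if (is.na(first_q)) above[1] else r$values[first_q]
  # flips: qualifying runs whose value differs from the running state; since
  # qualifying runs alternate in value relative to the last flip, these are
  # exactly the qualifying runs after dropping consecutive duplicates of the
  # current state
  state <- init
  flips <- integer(0); flip_state <- logical(0)
  for (j in which(qualifying)) {
    if (r$values[j] != state) {
      state <- r$values[j]
      flips <- c(flips, run_start[j])
      flip_state <- c(flip_state, state)
    }
  }
  k <- length(flips) + 1L
  list(state = c(init, flip_state),
       start = times[c(1L, flips)],
       end = c(times[flips], times[n] + cadence),
       lc = seq_len(k) == 1L,
       rc = seq_len(k) == k)
}

#' Detect arousals from behavioural movement logs
#'
#' Implements the movement-based arousal definition: any observed movement
#' marks an arousal; an arousal ends once the bat has been motionless for
#' longer than the termination window (`merge_gap`, default 90 min), and
#' movement after that window starts a new arousal. Movement intervals whose
#' stillness gap is shorter than `merge_gap` are merged into one arousal.
#' Complement intervals within the observation span are torpor bouts; bouts
#' touching the span edges are censored.
#'
#' @param log Tibble of motion intervals: `bat_id`, `start_min`, `end_min`.
#' @param spans Tibble of observation spans: `bat_id`, `start_min`,
#'   `end_min`. Bats present here but absent from `log` yield a single
#'   censored torpor bout.
#' @param merge_gap Stillness gap (min) below which consecutive movements
#'   merge into one arousal; a gap of at least `merge_gap` terminates it.
#' @param end_rule `"last_movement"` (default): the arousal ends at the end
#'   of the last merged movement. `"movement_plus_gap"`: the termination
#'   window itself is included in the arousal.
#' @return Bout tibble in the same layout as [detect_bouts_tsk()], with
#'   `source = "behaviour"` and `threshold_c = NA`.
#' @examples
#' log <- tibble::tibble(bat_id = "b1", start_min = c(0, 70), end_min = c(10, 80))
#' spans <- tibble::tibble(bat_id = "b1", start_min = 0, end_min = 1000)
#' detect_bouts_behaviour(log, spans)  # gap 60 < 90: one arousal [0, 80)
#' @export
detect_bouts_behaviour <- function(log, spans, merge_gap = 90,
                                   end_rule = c("last_movement", "movement_plus_gap")) {
  end_rule <- match.arg(end_rule)
  if (merge_gap <= 0) abort("`merge_gap` must be strictly positive.")
  bats <- unique(spans$bat_id)
  out <- lapply(bats, function(id) {
    sp <- spans[spans$bat_id == id, , drop = FALSE][1, ]
    lg <- log[log$bat_id == id, , drop = FALSE]
    detect_behaviour_one(lg, sp$start_min, sp$end_min, merge_gap, end_rule, id)
  })
  dplyr::bind_rows(out)
}

detect_behaviour_one <- function(lg, span_start, span_end, merge_gap, end_rule, id) {
  mk <- function(kind, s, e, lc, rc) {
    tibble::tibble(bat_id = id, source = "behaviour", kind = kind,
                   threshold_c = NA_real_, start_min = s, end_min = e,
                   duration_min = e - s, left_censored = lc, right_censored = rc)
  }
  if (nrow(lg) == 0) {
    return(mk("torpor", span_start, span_end, TRUE, TRUE))
  }
  lg <- lg[order(lg$start_min), , drop = FALSE]
  if (any(lg$start_min < span_start | lg$end_min > span_end)) {
    abort(sprintf("movements outside the observation span for bat '%s'.", id))
  }
  # merge movements separated by stillness < merge_gap
  s <- lg$start_min[1]; e <- lg$end_min[1]
  ars <- list()
  for (i in seq_len(nrow(lg))[-1]) {
    if (lg$start_min[i] - e < merge_gap) {
      e <- max(e, lg$end_min[i])
    } else {
      ars[[length(ars) + 1L]] <- c(s, e)
      s <- lg$start_min[i]; e <- lg$end_min[i]
    }
  }
  ars[[length(ars) + 1L]] <- c(s, e)
  a <- do.call(rbind, ars)
  if (end_rule == "movement_plus_gap") {
    a[, 2] <- pmin(a[, 2] + merge_gap, span_end)
    # re-merge if extension caused contact
    keep <- list(); s <- a[1, 1]; e <- a[1, 2]
    for (i in seq_len(nrow(a))[-1]) {
      if (a[i, 1] <= e) e <- max(e, a[i, 2]) else { keep[[length(keep) + 1L]] <- c(s, e); s <- a[i, 1]; e <- a[i, 2] }
    }
    keep[[length(keep) + 1L]] <- c(s, e)
    a <- do.call(rbind, keep)
  }
  arousal_intervals_to_bouts(a, span_start, span_end, id)
}

# Tile the observation span with arousal intervals (matrix of start, end
# rows) and their complementary torpor bouts.
arousal_intervals_to_bouts <- function(a, span_start, span_end, id) {
  mk <- function(kind, s, e, lc, rc) {
    tibble::tibble(bat_id = id, source = "behaviour", kind = kind,
                   threshold_c = NA_real_, start_min = s, end_min = e,
                   duration_min = e - s, left_censored = lc, right_censored = rc)
  }
  rows <- list()
  cur <- span_start
  for (i in seq_len(nrow(a))) {
    if (a[i, 1] > cur) {
      rows[[length(rows) + 1L]] <-
        mk("torpor", cur, a[i, 1], cur == span_start, FALSE)
    }
    rows[[length(rows) + 1L]] <-
      mk("arousal", a[i, 1], a[i, 2],
         a[i, 1] <= span_start, a[i, 2] >= span_end)
    cur <- a[i, 2]
  }
  if (cur < span_end) {
    rows[[length(rows) + 1L]] <- mk("torpor", cur, span_end, FALSE, TRUE)
  }
  dplyr::bind_rows(rows)
}

#' Reconcile behavioural arousals against the skin-temperature record
#'
#' Optional pass (off by default in the pipeline) resolving the two
#' known disagreement modes between detectors using the T_sk record as
#' arbiter: two consecutive behavioural arousals are **merged** when T_sk
#' never falls to or below the threshold between them (the animal stayed
#' normothermic through the stillness), and one behavioural arousal is
#' **split** when the threshold detector finds two or more complete
#' descents and re-ascents inside it.
#'
#' @param bouts Behavioural bout tibble for the cohort.
#' @param traces T_sk tibble covering the same bats.
#' @param spans Observation spans (`bat_id`, `start_min`, `end_min`).
#' @param threshold T_sk threshold, degrees C (default 20).
#' @return A reconciled behavioural bout tibble.
#' @export
reconcile_bouts <- function(bouts, traces, spans, threshold = 20) {
  out <- lapply(unique(spans$bat_id), function(id) {
    sp <- spans[spans$bat_id == id, , drop = FALSE][1, ]
    b <- bouts[bouts$bat_id == id, , drop = FALSE]
    ar <- b[b$kind == "arousal", , drop = FALSE]
    if (nrow(ar) == 0) return(b)
    tr <- traces[traces$bat_id == id, , drop = FALSE]
    tsk_ar <- detect_bouts_tsk(tr, threshold)
    tsk_ar <- tsk_ar[tsk_ar$kind == "arousal", , drop = FALSE]
    a <- cbind(sort(ar$start_min), ar$end_min[order(ar$start_min)])
    # split: behavioural arousal containing >= 2 complete threshold arousals
    pieces <- list()
    for (i in seq_len(nrow(a))) {
      inside <- tsk_ar[tsk_ar$start_min >= a[i, 1] & tsk_ar$end_min <= a[i, 2] &
                         !tsk_ar$left_censored & !tsk_ar$right_censored, ,
                       drop = FALSE]
      if (nrow(inside) >= 2) {
        o <- order(inside$start_min)
        cuts <- (inside$end_min[o][-nrow(inside)] + inside$start_min[o][-1]) / 2
        edges <- c(a[i, 1], cuts, a[i, 2])
        for (j in seq_len(length(edges) - 1)) {
          pieces[[length(pieces) + 1L]] <- c(edges[j], edges[j + 1])
        }
      } else {
        pieces[[length(pieces) + 1L]] <- a[i, ]
      }
    }
    a <- do.call(rbind, pieces)
    # merge: T_sk never at/below threshold on valid samples between two arousals
    keep <- list()
    s <- a[1, 1]; e <- a[1, 2]
    for (i in seq_len(nrow(a))[-1]) {
      gap <- tr$valid & tr$time_min >= e & tr$time_min < a[i, 1]
      stayed_warm <- sum(gap) > 0 && all(tr$tsk_c[gap] > threshold)
      if (stayed_warm) {
        e <- a[i, 2]
      } else {
        keep[[length(keep) + 1L]] <- c(s, e)
        s <- a[i, 1]; e <- a[i, 2]
      }
    }
    keep[[length(keep) + 1L]] <- c(s, e)
    arousal_intervals_to_bouts(do.call(rbind, keep), sp$start_min, sp$end_min, id)
  })
  dplyr::bind_rows(out)
}

#' Drop the final torpor bout of each bat
#'
#' Records end with animals removed from hibernation while still torpid, so
#' the last (truncated) torpor bout per bat is omitted from analyses. The
#' final bout is removed if and only if it is a torpor bout; afterwards a
#' bat's arousal count may exceed its torpor count by one.
#'
#' @param bouts Bout tibble (any source); may contain several bats.
#' @return The bout tibble without each bat's trailing torpor bout.
#' @export
drop_last_torpor <- function(bouts) {
  if (nrow(bouts) == 0) return(bouts)
  bouts |>
    dplyr::group_by(.data$bat_id, .data$source) |>
    dplyr::arrange(.data$start_min, .by_group = TRUE) |>
    dplyr::filter(!(dplyr::row_number() == dplyr::n() & .data$kind == "torpor")) |>
    dplyr::ungroup()
}

#' Assign drinking events to behavioural arousals
#'
#' Each drink is assigned to the unique arousal whose half-open interval
#' contains its timestamp. Drinks falling outside every arousal (e.g. during
#' torpor or outside the observation span) are flagged unassigned and
#' excluded from tallies, with a warning.
#'
#' @param drinks Tibble with `bat_id`, `time_min`.
#' @param arousals Bout tibble filtered to behavioural arousals (rows of other
#'   kinds are ignored).
#' @return The `drinks` tibble with `arousal_start` (NA when unassigned) and
#'   `assigned`.
#' @seealso [tally_drinks()] for the per-bat composite counts.
#' @export
assign_drinks <- function(drinks, arousals) {
  ar <- arousals[arousals$kind == "arousal", , drop = FALSE]
  if (nrow(drinks) == 0) {
    return(dplyr::mutate(drinks, arousal_start = numeric(0), assigned = logical(0)))
  }
  res <- drinks
  res$arousal_start <- NA_real_
  for (id in unique(res$bat_id)) {
    ai <- ar[ar$bat_id == id, , drop = FALSE]
    di <- which(res$bat_id == id)
    if (nrow(ai) == 0) next
    o <- order(ai$start_min)
    s <- ai$start_min[o]; e <- ai$end_min[o]
    pos <- findInterval(res$time_min[di], s)
    hit <- pos >= 1 & res$time_min[di] < e[pmax(pos, 1)]
    res$arousal_start[di[hit]] <- s[pos[hit]]
  }
  res$assigned <- !is.na(res$arousal_start)
  if (any(!res$assigned)) {
    warn(sprintf("%d drink event(s) fell outside every arousal and were excluded.",
                 sum(!res$assigned)))
  }
  res
}

#' Per-bat drinking tallies
#'
#' Builds the per-bat composite used by the drinking analyses: total drinks,
#' number of arousals containing at least one drink, and arousals without.
#'
#' @param arousals Behavioural bout tibble (only `kind == "arousal"` rows are
#'   used; censored arousals count like any other since drinking needs no
#'   complete bout).
#' @param drinks_assigned Output of [assign_drinks()].
#' @return Tibble: `bat_id`, `n_arousals`, `n_drinks`,
#'   `arousals_with_drink`, `arousals_without_drink`, `prop_drink`.
#' @export
tally_drinks <- function(arousals, drinks_assigned) {
  ar <- arousals[arousals$kind == "arousal", , drop = FALSE]
  base <- ar |>
    dplyr::count(.data$bat_id, name = "n_arousals")
  dr <- drinks_assigned[drinks_assigned$assigned, , drop = FALSE]
  per <- dr |>
    dplyr::group_by(.data$bat_id) |>
    dplyr::summarise(n_drinks = dplyr::n(),
                     arousals_with_drink = dplyr::n_distinct(.data$arousal_start),
                     .groups = "drop")
  base |>
    dplyr::left_join(per, by = "bat_id") |>
    tidyr::replace_na(list(n_drinks = 0L, arousals_with_drink = 0L)) |>
    dplyr::mutate(arousals_without_drink = .data$n_arousals - .data$arousals_with_drink,
                  prop_drink = ifelse(.data$n_arousals > 0,
                                      .data$arousals_with_drink / .data$n_arousals, NA_real_))
}

#' Per-bat bout summaries
#'
#' @param bouts Bout tibble.
#' @param censored Include censored bouts in duration summaries? Default
#'   `FALSE` (censored bouts are truncated, so their durations are biased).
#' @return Tibble with one row per bat x source x kind: bout count, mean /
#'   s.d. duration (minutes).
#' @export
summarize_bouts <- function(bouts, censored = FALSE) {
  b <- bouts
  if (!censored) b <- b[!b$left_censored & !b$right_censored, , drop = FALSE]
  b |>
    dplyr::group_by(.data$bat_id, .data$source, .data$kind) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_duration_min = mean(.data$duration_min),
                     sd_duration_min = sd(.data$duration_min),
                     .groups = "drop")
}
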