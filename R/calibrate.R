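#' Sweep candidate skin-temperature thresholds over a cohort
#'
#' Runs [detect_bouts_tsk()] at every threshold on the grid and collects, per
#' threshold, the total arousal count over the cohort and the uncensored
#' arousal durations (censored bouts are truncated and excluded from the
#' duration sets, but still counted).
#'
#' @param traces T_sk tibble for the whole cohort.
#' @param grid Numeric threshold grid, degrees C (default 13 to 27 by 1).
#' @return A `sweep_table`: list with `counts` (tibble `threshold_c`,
#'   `n_arousals`), `durations` (tibble `threshold_c`, `bat_id`,
#'   `duration_min`), and `grid`.
#' @export
sweep_thresholds <- function(traces, grid = 13:27) {
  if (length(grid) == 0) abort("`grid` must contain at least one threshold.")
  if (nrow(traces) == 0) abort("`traces` is empty.")
  grid <- sort(unique(grid))
  counts <- vector("list", length(grid))
  durs <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    b <- detect_bouts_tsk(traces, grid[i])
    ar <- b[b$kind == "arousal", , drop = FALSE]
    counts[[i]] <- tibble::tibble(threshold_c = grid[i], n_arousals = nrow(ar))
    keep <- !ar$left_censored & !ar$right_censored
    durs[[i]] <- tibble::tibble(threshold_c = grid[i],
                                bat_id = ar$bat_id[keep],
                                duration_min = ar$duration_min[keep])
  }
  structure(list(counts = dplyr::bind_rows(counts),
                 durations = dplyr::bind_rows(durs),
                 grid = grid),
            class = "sweep_table")
}

#' @export
print.sweep_table <- function(x, ...) {
  cat("<sweep_table> thresholds", min(x$grid), "to", max(x$grid), "degrees C\n")
  print(x$counts, n = length(x$grid))
  invisible(x)
}

#' Continuous two-segment (breakpoint) regression
#'
#' Fits `y ~ x` with a single breakpoint `psi`: a continuous piecewise-linear
#' model `y = b0 + b1 x + b2 (x - psi)_+`, with `psi` chosen by grid search
#' at 0.1 degree resolution over the interior of the `x` range, minimizing
#' the residual sum of squares. Candidates leaving fewer than 3 points on
#' either side are excluded. The breakpoint is retained (`has_breakpoint`)
#' when the two-segment fit improves on a single straight line by an F-test
#' at `alpha` (2 extra parameters: the slope change and the break position).
#' Separate per-segment regressions (left segment: points with `x <=
#' floor(psi)`) report each slope with its F statistic and p-value.
#'
#' @param x,y Numeric vectors (at least 5 points).
#' @param resolution Breakpoint grid resolution (default 0.1).
#' @param alpha Significance level of the existence F-test.
#' @return A `breakpoint_fit`: list with `psi`, `has_breakpoint`, `rss`,
#'   `rss_linear`, `f_stat`, `p_value`, `left_slope`, `right_slope`,
#'   `left_f`, `left_p`, `right_f`, `right_p`, `n`.
#' @examples
#' x <- 13:27
#' y <- ifelse(x < 17.4, 112 - 3 * (x - 13), 112 - 3 * (17.4 - 13))
#' fit_breakpoint(x, y)$psi
#' @export
fit_breakpoint <- function(x, y, resolution = 0.1, alpha = 0.05) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) abort("breakpoint regression needs at least 5 points.")
  cand <- seq(ceiling(min(x) / resolution) * resolution,
              floor(max(x) / resolution) * resolution, by = resolution)
  cand <- round(cand, 6)
  keep <- vapply(cand, function(p) sum(x <= p) >= 3 && sum(x > p) >= 3, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) abort("no admissible breakpoint candidate (need 3 points per segment).")
  rss <- vapply(cand, function(p) {
    h <- pmax(x - p, 0)
    sum(resid(lm.fit2(cbind(1, x, h), y))^2)
  }, numeric(1))
  best <- which.min(rss)
  psi <- cand[best]
  rss2 <- rss[best]
  fit0 <- lm.fit2(cbind(1, x), y)
  rss0 <- sum(resid(fit0)^2)
  df2 <- n - 4
  if (rss2 < 1e-10 * max(rss0, 1)) {
    has_bp <- rss0 > 1e-8 * max(sum(y^2), 1)
    f_stat <- if (has_bp) Inf else 0
    p_val <- if (has_bp) 0 else 1
  } else {
    f_stat <- ((rss0 - rss2) / 2) / (rss2 / df2)
    p_val <- pf(f_stat, 2, df2, lower.tail = FALSE)
    has_bp <- is.finite(f_stat) && p_val < alpha
  }
  seg <- function(xs, ys) {
    if (length(xs) < 3) return(list(slope = NA_real_, f = NA_real_, p = NA_real_))
    m <- lm(ys ~ xs)
    a <- suppressWarnings(anova(m))  # perfect segment fits are legitimate here
    list(slope = unname(coef(m)[2]), f = a$`F value`[1], p = a$`Pr(>F)`[1])
  }
  left <- seg(x[x <= floor(psi)], y[x <= floor(psi)])
  right <- seg(x[x > floor(psi)], y[x > floor(psi)])
  structure(list(psi = psi, has_breakpoint = has_bp, rss = rss2,
                 rss_linear = rss0, f_stat = f_stat, p_value = p_val,
                 left_slope = left$slope, left_f = left$f, left_p = left$p,
                 right_slope = right$slope, right_f = right$f, right_p = right$p,
                 n = n, grid_range = range(x)),
            class = "breakpoint_fit")
}

# least squares via QR without model.frame overhead
lm.fit2 <- function(X, y) stats::lm.fit(X, y)

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("<breakpoint_fit> psi = %.1f degrees C (%s; F = %.2f, p = %.3g)\n",
              x$psi, if (x$has_breakpoint) "retained" else "not supported",
              x$f_stat, x$p_value))
  cat(sprintf("  left slope %.3f (F = %.2f, p = %.3g); right slope %.3f (F = %.2f, p = %.3g)\n",
              x$left_slope, x$left_f, x$left_p,
              x$right_slope, x$right_f, x$right_p))
  invisible(x)
}

#' Compare per-threshold arousal durations against a behavioural reference
#'
#' Many-to-one (Dunnett-type) comparison of the transformed arousal durations
#' at each swept threshold against the behavioural reference set. Durations
#' are square-root transformed by default; when every observation carries a
#' `bat_id`, the repeated-measures structure is respected by subtracting
#' per-bat means of the transformed values (within-bat centering) before the
#' comparisons, and the pooled-error degrees of freedom are reduced
#' accordingly. Family-wise adjusted p-values come from the exact many-to-one
#' multivariate-t distribution with the unbalanced correlation structure,
#' integrated by a seeded quasi-Monte-Carlo routine (deterministic);
#' `method = "bonferroni"` is the conservative fallback. A Brown-Forsythe
#' variance-homogeneity check across groups is reported and, on failure,
#' raised as a warning only.
#'
#' @param sweep A `sweep_table`.
#' @param behaviour_durations Reference durations: tibble with `bat_id` and
#'   `duration_min`, or a bare numeric vector (in which case centering is
#'   skipped).
#' @param transform Transformation applied to durations (default `sqrt`).
#' @param method `"mvt"` or `"bonferroni"`.
#' @param alpha Level used by the homogeneity warning and downstream
#'   selection.
#' @return A `dunnett_result`: tibble `threshold_c`, `n`, `mean_diff`
#'   (transformed scale), `statistic`, `p_adj`, with attributes `df`,
#'   `n_reference`, `levene_f`, `levene_p`, `method`, `alpha`.
#' @export
compare_durations <- function(sweep, behaviour_durations, transform = sqrt,
                              method = c("mvt", "bonferroni"), alpha = 0.05) {
  method <- match.arg(method)
  if (is.numeric(behaviour_durations)) {
    ref <- tibble::tibble(bat_id = NA_character_, duration_min = behaviour_durations)
    center <- FALSE
    inform("reference durations carry no bat_id; within-bat centering skipped.")
  } else {
    ref <- tibble::tibble(bat_id = behaviour_durations$bat_id,
                          duration_min = behaviour_durations$duration_min)
    center <- TRUE
  }
  if (nrow(ref) == 0) abort("behavioural reference set is empty.")
  grp_n <- table(sweep$durations$threshold_c)
  if (any(grp_n < 2)) abort("every threshold needs at least 2 uncensored durations.")

  all_df <- dplyr::bind_rows(
    dplyr::mutate(ref, group = "reference"),
    tibble::tibble(bat_id = sweep$durations$bat_id,
                   duration_min = sweep$durations$duration_min,
                   group = as.character(sweep$durations$threshold_c))
  )
  all_df$z <- transform(all_df$duration_min)

  # Brown-Forsythe on the transformed (uncentered) values
  devs <- all_df |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(adev = abs(.data$z - median(.data$z))) |>
    dplyr::ungroup()
  lev <- anova(lm(adev ~ group, data = devs))
  lev_f <- lev$`F value`[1]; lev_p <- lev$`Pr(>F)`[1]
  if (is.finite(lev_p) && lev_p < alpha) {
    warn(sprintf("variance-homogeneity check failed (Brown-Forsythe p = %.3g).", lev_p))
  }

  n_bat_param <- 0L
  if (center) {
    all_df <- all_df |>
      dplyr::group_by(.data$bat_id) |>
      dplyr::mutate(z = .data$z - mean(.data$z)) |>
      dplyr::ungroup()
    n_bat_param <- dplyr::n_distinct(all_df$bat_id) - 1L
  }

  gs <- split(all_df$z, all_df$group)
  ref_z <- gs[["reference"]]
  thr_names <- setdiff(names(gs), "reference")
  thr_levels <- thr_names[order(as.numeric(thr_names))]
  k <- length(thr_levels)
  n0 <- length(ref_z)
  ni <- vapply(gs[thr_levels], length, integer(1))
  sse <- sum(vapply(gs, function(v) sum((v - mean(v))^2), numeric(1)))
  df_err <- sum(lengths(gs)) - (k + 1L) - n_bat_param
  if (df_err < 1) abort("not enough residual degrees of freedom.")
  sp2 <- sse / df_err
  mean_diff <- vapply(gs[thr_levels], mean, numeric(1)) - mean(ref_z)
  tstat <- mean_diff / sqrt(sp2 * (1 / ni + 1 / n0))

  if (method == "bonferroni") {
    p_adj <- pmin(1, 2 * pt(abs(tstat), df_err, lower.tail = FALSE) * k)
  } else {
    lam <- sqrt(ni / (ni + n0))
    corr <- outer(lam, lam)
    diag(corr) <- 1
    p_adj <- vapply(abs(tstat), function(q) {
      pr <- with_seed(20240307L,
                      mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                                    df = as.integer(df_err), corr = corr))
      max(0, min(1, 1 - as.numeric(pr)))
    }, numeric(1))
  }

  out <- tibble::tibble(threshold_c = as.numeric(thr_levels), n = as.integer(ni),
                        mean_diff = unname(mean_diff),
                        statistic = unname(tstat), p_adj = unname(p_adj))
  structure(out, class = c("dunnett_result", class(out)),
            df = df_err, n_reference = n0, levene_f = lev_f, levene_p = lev_p,
            method = method, alpha = alpha)
}

#' Select the operating skin-temperature threshold
#'
#' Combines both calibration analyses: the frequency-valid thresholds are the
#' grid values at or above `ceiling(psi)` (i.e. strictly above the
#' breakpoint, where threshold choice no longer affects arousal counts; when
#' no breakpoint is supported the whole grid qualifies), and the
#' duration-valid thresholds are those whose many-to-one comparison against
#' the behavioural reference is non-significant. The selected threshold is
#' the minimum of the intersection: the most sensitive threshold (lowest,
#' catching shallow rewarming) that is reliable for both arousal frequency
#' and duration.
#'
#' @param fit A `breakpoint_fit`.
#' @param dunnett A `dunnett_result`.
#' @param grid The threshold grid both were computed on.
#' @param alpha Significance level for the duration comparisons.
#' @return Selected threshold (degrees C), with attributes
#'   `frequency_valid` and `duration_valid`.
#' @export
select_threshold <- function(fit, dunnett, grid, alpha = 0.05) {
  grid <- sort(unique(grid))
  freq_valid <- if (isTRUE(fit$has_breakpoint)) grid[grid >= ceiling(fit$psi)] else grid
  dur_valid <- dunnett$threshold_c[dunnett$p_adj > alpha]
  sel <- intersect(freq_valid, dur_valid)
  if (length(sel) == 0) {
    abort(paste0(
      "no threshold satisfies both criteria.\n",
      sprintf("  breakpoint psi = %.1f -> frequency-valid {%s}\n",
              fit$psi, paste(freq_valid, collapse = ", ")),
      sprintf("  duration-valid (p_adj > %g): {%s}", alpha,
              paste(dur_valid, collapse = ", "))))
  }
  structure(min(sel), frequency_valid = freq_valid, duration_valid = sort(dur_valid))
}

#' Full threshold calibration
#'
#' Convenience wrapper running the complete calibration: threshold sweep,
#' breakpoint regression on the count-vs-threshold curve, many-to-one
#' duration comparison against the behavioural reference, and threshold
#' selection.
#'
#' @param traces Cohort T_sk tibble.
#' @param behaviour_bouts Behavioural bout tibble ([detect_bouts_behaviour()]).
#' @param grid Threshold grid.
#' @param alpha Significance level.
#' @param method Dunnett adjustment passed to [compare_durations()].
#' @return A `calibration` list: `sweep`, `breakpoint`, `dunnett`,
#'   `selected` (NA with a `selection_error` attribute if no threshold
#'   qualifies).
#' @export
calibrate_threshold <- function(traces, behaviour_bouts, grid = 13:27,
                                alpha = 0.05, method = "mvt") {
  sweep <- sweep_thresholds(traces, grid)
  bp <- fit_breakpoint(sweep$counts$threshold_c, sweep$counts$n_arousals,
                       alpha = alpha)
  ref <- behaviour_bouts |>
    dplyr::filter(.data$kind == "arousal",
                  !.data$left_censored, !.data$right_censored) |>
    dplyr::select("bat_id", "duration_min")
  dn <- compare_durations(sweep, ref, method = method, alpha = alpha)
  sel <- tryCatch(select_threshold(bp, dn, grid, alpha = alpha),
                  error = function(e) structure(NA_real_, selection_error = conditionMessage(e)))
  structure(list(sweep = sweep, breakpoint = bp, dunnett = dn, selected = sel),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration>\n")
  print(x$breakpoint)
  sel <- x$selected
  if (is.na(sel)) {
    cat("  no valid threshold:", attr(sel, "selection_error"), "\n")
  } else {
    cat(sprintf("  selected threshold: %g degrees C\n", as.numeric(sel)))
  }
  invisible(x)
}
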