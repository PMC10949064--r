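#' Run the hibernation analysis pipeline end to end
#'
#' Orchestrates the stages `simulate -> detect -> calibrate -> stats ->
#' huddle -> report` from a single config, writing every artifact plus a
#' deterministic run manifest to `out_dir`. Re-running with an identical
#' config and seed reproduces identical output checksums. Stages are gated
#' by the presence of their config section (e.g. no `huddle` section, no
#' huddle outputs); a failing stage names its offending input and leaves
#' completed stage outputs intact.
#'
#' Config layout (YAML or JSON file, or an equivalent nested list):
#' \preformatted{
#' seed: 1
#' simulation: {study_days: 110, n_bats_per_treatment: {humid: 10, dry: 9}}
#' # or: fixtures: path/to/cohort-dir   (written by write_cohort())
#' detection:   {threshold: 20, merge_gap: 90}
#' calibration: {grid_min: 13, grid_max: 27, alpha: 0.05}
#' stats: {}
#' huddle: {}
#' }
#'
#' @param config Path to a YAML/JSON config file, or a list.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, or `"all"`.
#' @param seed Optional root-seed override.
#' @param verbose Log stage boundaries with row counts.
#' @return A `run_manifest` (invisibly): config hash, seed, stage list,
#'   output checksums, timestamps.
#' @export
run_pipeline <- function(config, out_dir, stages = "all", seed = NULL,
                         verbose = FALSE) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  all_stages <- c("simulate", "detect", "calibrate", "stats", "huddle", "report")
  if (identical(stages, "all")) stages <- all_stages
  stages <- intersect(all_stages, stages)
  # gate on config sections
  if (is.null(cfg$simulation)) stages <- setdiff(stages, "simulate")
  if (is.null(cfg$huddle)) stages <- setdiff(stages, "huddle")
  if (is.null(cfg$calibration)) stages <- setdiff(stages, "calibrate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  cohort_dir <- cfg$fixtures %||% file.path(out_dir, "cohort")

  if ("simulate" %in% stages) {
    sc <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulation))
    bundle <- simulate_cohort(sc)
    write_cohort(bundle, cohort_dir)
    say("simulate: %d bats, %d trace rows -> %s", nrow(bundle$bats),
        nrow(bundle$traces), cohort_dir)
  }

  needs_cohort <- any(c("detect", "calibrate", "stats", "huddle") %in% stages)
  bundle <- NULL
  if (needs_cohort) {
    bundle <- tryCatch(read_cohort(cohort_dir), error = function(e) {
      abort(sprintf("detect stage: cannot load cohort from '%s': %s",
                    cohort_dir, conditionMessage(e)))
    })
    check_cohort_files(bundle, cohort_dir)
  }

  det <- cfg$detection %||% list()
  threshold <- det$threshold %||% 20
  merge_gap <- det$merge_gap %||% 90

  bouts_beh <- NULL
  if (any(c("detect", "calibrate", "stats") %in% stages)) {
    bouts_beh <- detect_bouts_behaviour(bundle$movements, bundle$spans,
                                        merge_gap = merge_gap)
  }

  if ("detect" %in% stages) {
    bouts_tsk <- detect_bouts_tsk(bundle$traces, threshold)
    bouts <- dplyr::bind_rows(bouts_tsk, bouts_beh)
    readr::write_csv(bouts, file.path(out_dir, "bouts.csv"))
    dr <- assign_drinks(bundle$drinks,
                        bouts_beh[bouts_beh$kind == "arousal", , drop = FALSE])
    readr::write_csv(dr, file.path(out_dir, "drinks_assigned.csv"))
    say("detect: %d T_sk bouts, %d behavioural bouts at %g degrees C",
        nrow(bouts_tsk), nrow(bouts_beh), threshold)
  }

  if ("calibrate" %in% stages) {
    cal_cfg <- cfg$calibration %||% list()
    grid <- seq(cal_cfg$grid_min %||% 13, cal_cfg$grid_max %||% 27)
    cal <- calibrate_threshold(bundle$traces, bouts_beh, grid = grid,
                               alpha = cal_cfg$alpha %||% 0.05)
    sw <- cal$sweep$counts |>
      dplyr::left_join(
        cal$sweep$durations |>
          dplyr::group_by(.data$threshold_c) |>
          dplyr::summarise(mean_duration_h = mean(.data$duration_min) / 60,
                           .groups = "drop"),
        by = "threshold_c")
    readr::write_csv(sw, file.path(out_dir, "sweep.csv"))
    jsonlite::write_json(
      list(psi = cal$breakpoint$psi,
           has_breakpoint = cal$breakpoint$has_breakpoint,
           breakpoint_f = cal$breakpoint$f_stat,
           breakpoint_p = cal$breakpoint$p_value,
           left_slope = cal$breakpoint$left_slope,
           right_slope = cal$breakpoint$right_slope,
           dunnett = as.data.frame(cal$dunnett),
           selected_threshold = as.numeric(cal$selected)),
      file.path(out_dir, "calibration_report.json"), auto_unbox = TRUE,
      digits = NA, na = "null")
    say("calibrate: psi = %.1f, selected %g", cal$breakpoint$psi,
        as.numeric(cal$selected))
  }

  if ("stats" %in% stages) {
    beh <- drop_last_torpor(bouts_beh)
    dr <- assign_drinks(bundle$drinks,
                        beh[beh$kind == "arousal", , drop = FALSE])
    rec <- build_bat_records(bundle$bats, beh, dr)
    readr::write_csv(rec, file.path(out_dir, "bat_records.csv"))
    stats_out <- cohort_stats(beh, rec)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    say("stats: %d bat records", nrow(rec))
  }

  if ("huddle" %in% stages) {
    if (length(bundle$masks) == 0) {
      abort(sprintf("huddle stage: no masks under '%s'.", cohort_dir))
    }
    hsi <- compute_hsi(bundle$masks)
    readr::write_csv(hsi, file.path(out_dir, "hsi.csv"))
    cmp <- compare_hsi(hsi)
    jsonlite::write_json(
      list(n_images = nrow(hsi),
           mean_hsi = as.list(tapply(hsi$hsi, hsi$treatment, mean)),
           coefficients = as.data.frame(tidy(cmp)),
           dispersion = cmp$dispersion, ratio = cmp$ratio,
           cohens_d = as.data.frame(cmp$effect_size)),
      file.path(out_dir, "huddle_report.json"), auto_unbox = TRUE,
      digits = NA, na = "null")
    say("huddle: %d images", nrow(hsi))
  }

  if ("report" %in% stages) {
    make_report(out_dir)
    say("report written")
  }

  manifest <- build_manifest(cfg, out_dir)
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

# per-bat summaries and all group statistics for the stats stage
cohort_stats <- function(beh_bouts, rec) {
  out <- list()
  out$per_treatment <- beh_bouts |>
    dplyr::filter(!.data$left_censored, !.data$right_censored) |>
    dplyr::inner_join(dplyr::select(rec, "bat_id", "treatment"), by = "bat_id") |>
    dplyr::group_by(.data$treatment, .data$kind) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_duration_min = mean(.data$duration_min),
                     sem_duration_min = sd(.data$duration_min) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    as.data.frame()

  dur_models <- list()
  for (resp in c("arousal_h", "torpor_day")) {
    dur_models[[resp]] <- tryCatch({
      f <- fit_duration_mixed_model(beh_bouts, rec, resp)
      list(coefficients = as.data.frame(tidy(f)),
           glance = as.data.frame(glance(f)))
    }, error = function(e) list(note = conditionMessage(e)))
  }
  out$duration_models <- dur_models

  rep_in <- beh_bouts |>
    dplyr::filter(!.data$left_censored, !.data$right_censored)
  out$repeatability <- lapply(
    c(arousal = "arousal", torpor = "torpor"),
    function(k) {
      d <- rep_in[rep_in$kind == k, , drop = FALSE]
      tryCatch({
        r <- repeatability(tibble::tibble(bat_id = d$bat_id, value = d$duration_min))
        as.data.frame(glance(r))
      }, error = function(e) list(note = conditionMessage(e)))
    })

  out$arousal_count_glm <- as.data.frame(tidy(fit_count_glm(rec, "arousals")))
  out$drink_count_glm <- as.data.frame(tidy(fit_count_glm(rec, "drinks")))
  if (sum(rec$arousals_with_drink) == 0) {
    out$drink_proportion <- list(note = "no drinking events recorded",
                                 proportions = 0)
  } else {
    out$drink_proportion <- as.data.frame(tidy(fit_drink_proportion_glm(rec)))
  }
  out$mass_loss_glm <- as.data.frame(tidy(fit_mass_loss_glm(rec)))
  out$initial_mass_welch <- as.data.frame(
    welch_t(rec$initial_mass_g[rec$treatment == "humid"],
            rec$initial_mass_g[rec$treatment == "dry"]))
  out$effect_sizes <- dplyr::bind_rows(
    arousals = cohens_d(rec$n_arousals[rec$treatment == "humid"],
                        rec$n_arousals[rec$treatment == "dry"]),
    drinks = cohens_d(rec$n_drinks[rec$treatment == "humid"],
                      rec$n_drinks[rec$treatment == "dry"]),
    prop_drink = tryCatch(
      cohens_d(rec$prop_drink[rec$treatment == "humid"],
               rec$prop_drink[rec$treatment == "dry"]),
      error = function(e) tibble::tibble(d = NA_real_, magnitude = NA_character_,
                                         n_a = NA_integer_, n_b = NA_integer_)),
    .id = "contrast") |>
    as.data.frame()
  out
}

#' Compose the run report
#'
#' Collects the calibration, statistics and huddle artifacts of a pipeline
#' run into one document (`report.json` plus a human-readable `report.md`):
#' sweep curve, breakpoint, selected threshold, per-treatment bout
#' summaries, model tables, effect sizes, and HSI summary.
#'
#' @param out_dir Directory holding the stage outputs.
#' @return The report list, invisibly.
#' @export
make_report <- function(out_dir) {
  need <- file.path(out_dir, "stats_report.json")
  if (!file.exists(need)) abort(sprintf("report stage: missing '%s'.", need))
  rep <- list(package_version = as.character(utils::packageVersion("torportools")))
  cal_p <- file.path(out_dir, "calibration_report.json")
  if (file.exists(cal_p)) {
    rep$calibration <- jsonlite::read_json(cal_p, simplifyVector = TRUE)
    rep$sweep <- as.data.frame(readr::read_csv(file.path(out_dir, "sweep.csv"),
                                               col_types = "did", progress = FALSE))
  }
  rep$stats <- jsonlite::read_json(need, simplifyVector = TRUE)
  hud_p <- file.path(out_dir, "huddle_report.json")
  if (file.exists(hud_p)) rep$huddle <- jsonlite::read_json(hud_p, simplifyVector = TRUE)
  jsonlite::write_json(rep, file.path(out_dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  writeLines(render_report_md(rep), file.path(out_dir, "report.md"))
  invisible(rep)
}

render_report_md <- function(rep) {
  md <- c("# Hibernation pipeline report", "")
  if (!is.null(rep$calibration)) {
    md <- c(md,
            sprintf("- Breakpoint in count vs threshold: psi = %.1f C (retained: %s)",
                    rep$calibration$psi, rep$calibration$has_breakpoint),
            sprintf("- Selected T_sk threshold: %s C",
                    format(rep$calibration$selected_threshold)), "")
  }
  pt <- rep$stats$per_treatment
  if (!is.null(pt)) {
    md <- c(md, "## Uncensored bout summaries (behavioural)",
            "", "| treatment | kind | n | mean duration (min) |",
            "|---|---|---|---|",
            sprintf("| %s | %s | %d | %.1f |", pt$treatment, pt$kind, pt$n,
                    pt$mean_duration_min), "")
  }
  es <- rep$stats$effect_sizes
  if (!is.null(es)) {
    md <- c(md, "## Treatment effect sizes (Cohen's d, humid - dry)", "",
            "| contrast | d | magnitude |", "|---|---|---|",
            sprintf("| %s | %s | %s |", es$contrast,
                    formatC(es$d, digits = 3, format = "f"), es$magnitude), "")
  }
  if (!is.null(rep$stats$drink_proportion$note)) {
    md <- c(md, sprintf("- Drinking: %s (proportion 0).",
                        rep$stats$drink_proportion$note), "")
  }
  if (!is.null(rep$huddle)) {
    md <- c(md, "## Huddle size index",
            sprintf("- mean HSI humid %.3f%%, dry %.3f%% (ratio %.3f; Cohen's d %.2f)",
                    rep$huddle$mean_hsi$humid, rep$huddle$mean_hsi$dry,
                    rep$huddle$ratio, rep$huddle$cohens_d$d), "")
  }
  md
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found.", config))
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    abort("`config` must be a file path or a list.")
  }
}

check_cohort_files <- function(bundle, dir) {
  checks <- list(
    traces.csv = c("bat_id", "time_min", "tsk_c", "valid"),
    movements.csv = c("bat_id", "start_min", "end_min"),
    bats.csv = c("bat_id", "treatment", "initial_mass_g", "final_mass_g"))
  tabs <- list(traces.csv = bundle$traces, movements.csv = bundle$movements,
               bats.csv = bundle$bats)
  for (f in names(checks)) {
    if (!all(checks[[f]] %in% names(tabs[[f]]))) {
      abort(sprintf("detect stage: '%s' is corrupt or malformed (missing columns).",
                    file.path(dir, f)))
    }
  }
  invisible(TRUE)
}

build_manifest <- function(cfg, out_dir) {
  # seed is hashed as part of the config
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_hash <- unname(tools::md5sum(tmp))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  sums <- unname(tools::md5sum(file.path(out_dir, files)))
  structure(list(config_hash = cfg_hash, seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("torportools")),
                 files = files, checksums = sums,
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "config", substr(x$config_hash, 1, 8), "\n")
  cat("  ", length(x$files), "artifacts in manifest\n")
  invisible(x)
}
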