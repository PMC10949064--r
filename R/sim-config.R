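#' Configuration for the synthetic hibernation-cohort generator
#'
#' Builds and validates the parameter set that drives [simulate_cohort()].
#' Defaults reproduce the study conditions the package targets: two humidity
#' treatments (`humid`, `dry`) of hibernating bats held at 8 degrees C for
#' 110 days, skin temperature (T_sk) logged every 15 min with 0.5 degree C
#' quantization, multi-day torpor bouts interrupted by brief normothermic
#' arousals, drinking during a treatment-dependent fraction of arousals,
#' huddle masks with treatment-dependent area, and mass loss increasing with
#' initial body mass.
#'
#' Per-treatment parameters are named numeric vectors with exactly the labels
#' `humid` and `dry`.
#'
#' @param seed Integer root seed. All randomness in the generator flows from
#'   this via per-bat substreams, so adding a bat never perturbs the others.
#' @param n_bats_per_treatment Bats per treatment (default `c(humid = 10, dry = 9)`).
#' @param study_days Length of the hibernation record, days.
#' @param ambient_temp Ambient temperature, degrees C.
#' @param sample_interval Datalogger cadence, minutes.
#' @param quantization_step Datalogger resolution, degrees C.
#' @param torpor_mean_duration Mean torpor bout duration per treatment, days.
#' @param arousal_mean_duration Mean arousal duration per treatment, minutes.
#' @param torpor_min_duration,arousal_min_duration Lower bounds (days, minutes)
#'   of the shifted-gamma duration laws; keep every event long enough to be
#'   physically expressible at the logger cadence.
#' @param torpor_shape,arousal_shape Gamma shape parameters controlling
#'   duration dispersion.
#' @param bat_sd_arousal,bat_sd_torpor Between-bat log-normal s.d. of the
#'   per-bat duration multiplier (drives repeatability); multipliers are
#'   mean-corrected so cohort means stay at the configured values.
#' @param torpid_tsk_offset Torpid T_sk above ambient, degrees C.
#' @param normothermic_tsk_mean Normothermic plateau T_sk, degrees C.
#' @param plateau_jitter Half-width of uniform plateau jitter, degrees C
#'   (applied before quantization).
#' @param rewarm_rate,cool_rate Initial rewarming / cooling rates, degrees C
#'   per minute (exponential approach to the plateau / torpid baseline).
#' @param p_drink_given_arousal Probability an arousal includes drinking,
#'   per treatment.
#' @param drink_extra_mean Mean extra dish visits (beyond the first) per
#'   drinking arousal, per treatment.
#' @param hsi_mean,hsi_sd Huddle-size index mean and s.d. per treatment,
#'   percent of image area.
#' @param n_photos Huddle photos per treatment.
#' @param mask_dim Huddle mask dimensions, pixels `c(width, height)`.
#' @param initial_mass_range Uniform range of initial body mass, g.
#' @param massloss_slope_on_initial_mass Slope of mass loss on initial mass, g/g.
#' @param massloss_intercept Intercept of the mass-loss relation, g.
#' @param massloss_cv Coefficient of variation of the multiplicative gamma
#'   noise on mass loss.
#' @param artifact_rates Named list: `heating_per_100d` (huddle-heating bumps
#'   above 20 degrees C), `shallow_heating_per_100d` (movement-free heat
#'   bumps peaking below 18.6 degrees C, the shallow events that inflate
#'   low-threshold arousal counts) and `subthreshold_per_100d` (movement
#'   with only a shallow T_sk response) — all expected events per bat per
#'   100 days — plus `shed_prob` (probability a logger is shed mid-study)
#'   and `failure_prob` (probability a logger records nothing).
#' @param cascade_sync If `TRUE`, arousal onsets within a treatment follow a
#'   shared latent schedule with per-bat jitter (arousal cascades); off by
#'   default.
#' @param cascade_jitter_sd Per-bat onset jitter when `cascade_sync = TRUE`, minutes.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_bats_per_treatment = c(humid = 3, dry = 3),
#'                   study_days = 40)
#' cfg$torpor_mean_duration
#' @export
sim_config <- function(seed = 1L,
                       n_bats_per_treatment = c(humid = 10, dry = 9),
                       study_days = 110,
                       ambient_temp = 8,
                       sample_interval = 15,
                       quantization_step = 0.5,
                       torpor_mean_duration = c(humid = 8.3, dry = 7.9),
                       arousal_mean_duration = c(humid = 134, dry = 106),
                       torpor_min_duration = 0.5,
                       arousal_min_duration = 60,
                       torpor_shape = 4,
                       arousal_shape = 1.3,
                       bat_sd_arousal = 0.12,
                       bat_sd_torpor = 0.10,
                       torpid_tsk_offset = 1,
                       normothermic_tsk_mean = 30,
                       plateau_jitter = 0.5,
                       rewarm_rate = 1,
                       cool_rate = 0.5,
                       p_drink_given_arousal = c(humid = 0.5, dry = 0.85),
                       drink_extra_mean = c(humid = 0.3, dry = 0.7),
                       hsi_mean = c(humid = 2.14, dry = 1.81),
                       hsi_sd = c(humid = 0.11, dry = 0.19),
                       n_photos = c(humid = 24, dry = 27),
                       mask_dim = c(352, 238),
                       initial_mass_range = c(22.4, 29.5),
                       massloss_slope_on_initial_mass = 0.93,
                       massloss_intercept = -17.8,
                       massloss_cv = 0.12,
                       artifact_rates = list(heating_per_100d = 1.3,
                                             shallow_heating_per_100d = 4.6,
                                             subthreshold_per_100d = 1.1,
                                             shed_prob = 0.3,
                                             failure_prob = 0.1),
                       cascade_sync = FALSE,
                       cascade_jitter_sd = 30) {
  cfg <- list(
    seed = as.integer(seed),
    n_bats_per_treatment = n_bats_per_treatment,
    study_days = study_days,
    ambient_temp = ambient_temp,
    sample_interval = sample_interval,
    quantization_step = quantization_step,
    torpor_mean_duration = torpor_mean_duration,
    arousal_mean_duration = arousal_mean_duration,
    torpor_min_duration = torpor_min_duration,
    arousal_min_duration = arousal_min_duration,
    torpor_shape = torpor_shape,
    arousal_shape = arousal_shape,
    bat_sd_arousal = bat_sd_arousal,
    bat_sd_torpor = bat_sd_torpor,
    torpid_tsk_offset = torpid_tsk_offset,
    normothermic_tsk_mean = normothermic_tsk_mean,
    plateau_jitter = plateau_jitter,
    rewarm_rate = rewarm_rate,
    cool_rate = cool_rate,
    p_drink_given_arousal = p_drink_given_arousal,
    drink_extra_mean = drink_extra_mean,
    hsi_mean = hsi_mean,
    hsi_sd = hsi_sd,
    n_photos = n_photos,
    mask_dim = mask_dim,
    initial_mass_range = initial_mass_range,
    massloss_slope_on_initial_mass = massloss_slope_on_initial_mass,
    massloss_intercept = massloss_intercept,
    massloss_cv = massloss_cv,
    artifact_rates = artifact_rates,
    cascade_sync = isTRUE(cascade_sync),
    cascade_jitter_sd = cascade_jitter_sd
  )
  validate_sim_config(cfg)
}

treatments <- c("humid", "dry")

check_treatment_map <- function(x, name) {
  if (is.list(x)) x <- unlist(x)  # YAML/JSON configs give named lists
  if (!is.numeric(x) || length(x) != 2L || is.null(names(x)) ||
      !setequal(names(x), treatments)) {
    abort(sprintf("`%s` must be a numeric vector with exactly the names 'humid' and 'dry'.", name))
  }
  x[treatments]
}

validate_sim_config <- function(cfg) {
  for (nm in c("n_bats_per_treatment", "torpor_mean_duration",
               "arousal_mean_duration", "p_drink_given_arousal",
               "drink_extra_mean", "hsi_mean", "hsi_sd", "n_photos")) {
    cfg[[nm]] <- check_treatment_map(cfg[[nm]], nm)
  }
  if (any(cfg$n_bats_per_treatment < 1)) {
    abort("`n_bats_per_treatment` must be at least 1 per treatment.")
  }
  if (cfg$study_days <= 0) abort("`study_days` must be strictly positive.")
  if (cfg$sample_interval <= 0 || cfg$quantization_step <= 0) {
    abort("`sample_interval` and `quantization_step` must be strictly positive.")
  }
  span_min <- cfg$study_days * 1440
  if (abs(span_min / cfg$sample_interval - round(span_min / cfg$sample_interval)) > 1e-9) {
    abort("`sample_interval` must divide the study span.")
  }
  pos <- c("torpor_min_duration", "arousal_min_duration", "torpor_shape",
           "arousal_shape", "rewarm_rate", "cool_rate",
           "normothermic_tsk_mean", "massloss_cv")
  for (nm in pos) {
    if (cfg[[nm]] <= 0) abort(sprintf("`%s` must be strictly positive.", nm))
  }
  if (any(cfg$torpor_mean_duration <= cfg$torpor_min_duration)) {
    abort("`torpor_mean_duration` must exceed `torpor_min_duration`.")
  }
  if (any(cfg$arousal_mean_duration <= cfg$arousal_min_duration)) {
    abort("`arousal_mean_duration` must exceed `arousal_min_duration`.")
  }
  if (any(cfg$p_drink_given_arousal < 0 | cfg$p_drink_given_arousal > 1)) {
    abort("`p_drink_given_arousal` must lie in [0, 1].")
  }
  if (any(cfg$hsi_mean < 0 | cfg$hsi_mean >= 100)) {
    abort("`hsi_mean` must lie in [0, 100).")
  }
  ar <- cfg$artifact_rates
  needed <- c("heating_per_100d", "shallow_heating_per_100d",
              "subthreshold_per_100d", "shed_prob", "failure_prob")
  missing <- setdiff(needed, names(ar))
  for (nm in missing) ar[[nm]] <- 0
  if (any(unlist(ar[needed]) < 0)) abort("artifact rates must be non-negative.")
  if (ar$shed_prob > 1 || ar$failure_prob > 1) {
    abort("`shed_prob` and `failure_prob` are probabilities in [0, 1].")
  }
  cfg$artifact_rates <- ar[needed]
  if (diff(cfg$initial_mass_range) < 0) abort("`initial_mass_range` must be increasing.")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d + %d bats (humid + dry) | %g days @ %g min cadence\n",
              x$seed, x$n_bats_per_treatment[["humid"]],
              x$n_bats_per_treatment[["dry"]], x$study_days, x$sample_interval))
  cat(sprintf("  torpor %g/%g d, arousal %g/%g min (humid/dry)\n",
              x$torpor_mean_duration[["humid"]], x$torpor_mean_duration[["dry"]],
              x$arousal_mean_duration[["humid"]], x$arousal_mean_duration[["dry"]]))
  cat(sprintf("  artifacts: heating %g, sub-threshold %g per 100 d; shed %g, failure %g\n",
              x$artifact_rates$heating_per_100d, x$artifact_rates$subthreshold_per_100d,
              x$artifact_rates$shed_prob, x$artifact_rates$failure_prob))
  invisible(x)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seeds derived from a root seed.  Drawing n + 1
# seeds reproduces the first n, so extending a roster never perturbs
# existing bats.
derive_seeds <- function(root_seed, n) {
  with_seed(root_seed,
            vapply(seq_len(n), function(i) sample.int(.Machine$integer.max - 1L, 1L),
                   integer(1)))
}
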