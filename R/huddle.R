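#' Huddle-size index from a binary mask
#'
#' The huddle-size index (HSI) is the percentage of total image area, in
#' pixels, occupied by the huddle: `100 * foreground / total`, exact integer
#' arithmetic. Smaller values mean a more compact huddle.
#'
#' @param mask A `huddle_mask` (see [simulate_huddle_masks()]), a plain 0/1
#'   matrix, or a list of either; a matrix may use any single non-zero value
#'   as foreground.
#' @return Tibble: `image_id`, `treatment`, `hsi` (percent). For a bare
#'   matrix `image_id` is `NA`.
#' @examples
#' m <- matrix(0L, 238, 352); m[1:40, 1:42] <- 1L
#' compute_hsi(m)$hsi  # 100 * 1680 / 83776
#' @export
compute_hsi <- function(mask) {
  if (is.list(mask) && !inherits(mask, "huddle_mask")) {
    return(dplyr::bind_rows(lapply(mask, compute_hsi)))
  }
  if (inherits(mask, "huddle_mask")) {
    px <- mask$pixels
    id <- mask$image_id
    tr <- mask$treatment
  } else if (is.matrix(mask)) {
    px <- mask
    id <- NA_character_
    tr <- NA_character_
  } else {
    abort("`mask` must be a huddle_mask, a matrix, or a list of them.")
  }
  if (length(px) == 0) abort("empty image.")
  vals <- unique(as.vector(px))
  fg <- setdiff(vals, 0)
  if (length(fg) > 1) {
    abort(sprintf("mask is multi-valued (%d distinct non-zero values); expected a binary mask.",
                  length(fg)))
  }
  tibble::tibble(image_id = id, treatment = tr,
                 hsi = 100 * sum(px != 0) / length(px))
}

#' Randomize and blind a set of huddle photos
#'
#' Produces a seeded random presentation order with uninformative labels
#' (`img_001`, ...) so scoring is blind to study date and treatment, plus a
#' key mapping blind labels back to the originals. The key is the only link
#' between blind label and identity; presentation entries carry no treatment
#' or date information.
#'
#' @param masks List of `huddle_mask` objects.
#' @param seed Integer seed.
#' @return List with `presentation` (list of masks in blind order, ids
#'   replaced, treatment/capture time stripped) and `key` (tibble
#'   `blind_id`, `image_id`, `position`).
#' @export
randomize_blind <- function(masks, seed) {
  if (length(masks) == 0) abort("need at least one mask.")
  ord <- with_seed(seed, sample.int(length(masks)))
  blind <- sprintf("img_%03d", seq_along(masks))
  pres <- lapply(seq_along(ord), function(i) {
    m <- masks[[ord[i]]]
    structure(list(image_id = blind[i], treatment = NA_character_,
                   capture_time = NA_real_, pixels = m$pixels,
                   observer = m$observer),
              class = "huddle_mask")
  })
  key <- tibble::tibble(
    blind_id = blind,
    image_id = vapply(masks[ord], `[[`, "", "image_id"),
    position = seq_along(ord))
  list(presentation = pres, key = key)
}

#' Dual-observer agreement on huddle-size estimates
#'
#' Pearson correlation between two observers' HSI values on the same images,
#' plus a Welch comparison of the observer means (a systematic offset check).
#'
#' @param hsi_a,hsi_b Paired numeric vectors, length at least 3.
#' @return Tibble: `pearson_r`, `r_p`, `welch_t`, `df`, `p.value`, `n`.
#' @export
observer_agreement <- function(hsi_a, hsi_b) {
  if (length(hsi_a) != length(hsi_b)) abort("observer vectors must be paired (equal length).")
  if (length(hsi_a) < 3) abort("need at least 3 paired images.")
  if (sd(hsi_a) == 0 || sd(hsi_b) == 0) {
    abort("correlation undefined: an observer's values have zero variance.")
  }
  ct <- cor.test(hsi_a, hsi_b, method = "pearson")
  wt <- welch_t(hsi_a, hsi_b)
  tibble::tibble(pearson_r = unname(ct$estimate), r_p = ct$p.value,
                 welch_t = wt$statistic, df = wt$df, p.value = wt$p.value,
                 n = length(hsi_a))
}

#' Compare the huddle-size index between treatments
#'
#' Quasi-Poisson (log link) regression of HSI on treatment — variance
#' proportional to the mean, dispersion estimated, so non-integer
#' percentages are valid responses — plus Cohen's d for the magnitude of
#' the contrast. In this treatment-only model the exponentiated coefficient
#' equals the ratio of group mean HSI exactly.
#'
#' @param hsi_values Tibble with `treatment` and `hsi` (e.g. from
#'   [compute_hsi()]).
#' @return A `torpor_fit` with `dispersion`, `ratio` (dry/humid mean ratio)
#'   and `effect_size` (Cohen's d tibble).
#' @export
compare_hsi <- function(hsi_values) {
  d <- tibble::tibble(hsi = hsi_values$hsi,
                      treatment = factor(hsi_values$treatment, levels = treatments))
  tab <- table(d$treatment)
  if (length(tab) < 2 || any(tab < 2)) abort("need at least 2 images per treatment.")
  if (any(tapply(d$hsi, d$treatment, function(v) all(v == 0)))) {
    warn("a treatment has all-zero HSI values (separation on the log scale).")
  }
  m <- glm(hsi ~ treatment, family = quasipoisson(), data = d)
  disp <- summary(m)$dispersion
  es <- cohens_d(d$hsi[d$treatment == "humid"], d$hsi[d$treatment == "dry"])
  new_model_fit("HSI (%)", NULL, "quasi-Poisson (log link)", m,
                list(coefficients = glm_coef_table(m), dispersion = disp,
                     ratio = exp(unname(coef(m)["treatmentdry"])),
                     effect_size = es))
}
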