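#' Default assay directionality map
#'
#' Orientation signs applied to per-assay z-scores before averaging so that
#' higher oriented scores always mean more resilient. Chronic stress lowers
#' body weight, sucrose consumption, elevated-plus-maze open-arm time,
#' open-field center time and object/social discrimination (orientation +1)
#' and raises forced-swim immobility and locomotor distance (orientation -1).
#' The table is an explicit config, never inferred from data; pass an edited
#' copy to [composite_scores()] to include/exclude assays (locomotion is a
#' frequent exclusion candidate since it doubles as a confound screen).
#'
#' @return Tibble with columns `assay`, `orientation` (+1 or -1).
#' @export
default_assay_directions <- function() {
  tibble(
    assay = c("body_weight_change", "sucrose_consumption",
              "forced_swim_immobility", "epm_open_arm_time",
              "oft_center_time", "locomotion", "novel_object_di",
              "social_interaction_di"),
    orientation = c(1, 1, -1, 1, 1, -1, 1, 1)
  )
}

#' z-score against the control mean, scaled by the experimental-group SD
#'
#' The composite-score building block: `(x - mu_ctrl) / sigma_exp`. The
#' denominator is the standard deviation of the animal's own experimental
#' group (not the control SD) — this standardizes how far an experimental
#' value deviates from the control mean relative to the variability within
#' its group.
#'
#' @param x Measured value(s).
#' @param mu_ctrl Control-group mean.
#' @param sigma_exp Experimental-group standard deviation; must be > 0.
#' @param assay,group Optional labels used in the degenerate-scale error.
#' @return `(x - mu_ctrl) / sigma_exp`.
#' @export
zscore <- function(x, mu_ctrl, sigma_exp, assay = NULL, group = NULL) {
  if (any(!is.finite(sigma_exp)) || any(sigma_exp <= 0)) {
    where <- paste(c(assay, group), collapse = " / ")
    stop_degenerate(paste0(
      "sigma_exp must be > 0",
      if (nzchar(where)) paste0(" (", where, ")") else ""
    ))
  }
  (x - mu_ctrl) / sigma_exp
}

#' Build the per-assay control reference for z-scoring
#'
#' Within one sex, computes the control mean (no-stress / no-stimulation
#' animals only) per assay and the sample SD (n - 1 denominator) of every
#' group per assay. The group's own SD is the default z-score denominator;
#' `sigma_source = "control"` substitutes the conventional control-SD variant.
#'
#' @param measurements Behavior table (see [simulate_behavior()] for the
#'   schema); a `group` column is derived from `stress`/`frequency_hz` if
#'   absent.
#' @param sex `"male"` or `"female"`.
#' @param sigma_source `"experimental"` (default) or `"control"`.
#' @return Tibble with columns `assay`, `group`, `mu_ctrl`, `sigma_exp`,
#'   `n_ctrl`, `n_exp`.
#' @export
build_reference <- function(measurements, sex,
                            sigma_source = c("experimental", "control")) {
  sigma_source <- match.arg(sigma_source)
  meas <- prep_measurements(measurements, sex)
  ctrl <- filter(meas, .data$group == "control")
  if (nrow(ctrl) == 0) stop_config("no control (no-stress/no-stim) animals found")

  ctrl_stats <- ctrl |>
    group_by(.data$assay) |>
    summarise(mu_ctrl = mean(.data$value), sd_ctrl = sd(.data$value),
              n_ctrl = n(), .groups = "drop")
  if (any(ctrl_stats$n_ctrl < 2)) {
    stop_config("need >= 2 control animals per assay")
  }

  ref <- meas |>
    group_by(.data$assay, .data$group) |>
    summarise(sigma_own = sd(.data$value), n_exp = n(), .groups = "drop") |>
    left_join(ctrl_stats, by = "assay")
  if (any(ref$n_exp < 2)) {
    bad <- ref[ref$n_exp < 2, ]
    stop_config(paste0("groups with a single animal (SD undefined): ",
                       paste(unique(bad$group), collapse = ", ")))
  }
  ref$sigma_exp <- if (sigma_source == "control") ref$sd_ctrl else ref$sigma_own
  degen <- !is.finite(ref$sigma_exp) | ref$sigma_exp <= 0
  if (any(degen)) {
    bad <- ref[degen, ]
    stop_degenerate(paste0("zero/degenerate SD for ",
                           paste(bad$assay, bad$group, sep = "/",
                                 collapse = ", ")))
  }
  select(ref, "assay", "group", "mu_ctrl", "sigma_exp", "n_ctrl", "n_exp")
}

prep_measurements <- function(measurements, sex = NULL) {
  meas <- as_tibble(measurements)
  need <- c("animal_id", "sex", "assay", "value")
  if (!all(need %in% names(meas))) {
    stop_config(paste0("behavior table needs columns: ",
                       paste(need, collapse = ", ")))
  }
  if (!"group" %in% names(meas)) {
    if (!all(c("stress", "frequency_hz") %in% names(meas))) {
      stop_config("behavior table needs `group` or `stress` + `frequency_hz`")
    }
    meas$group <- condition_label(meas$stress, as.character(meas$frequency_hz))
  }
  if (!is.null(sex)) meas <- filter(meas, .data$sex == !!sex)
  if (anyDuplicated(meas[c("animal_id", "assay")])) {
    stop_config("(animal_id, assay) pairs must be unique")
  }
  if (any(!is.finite(meas$value))) stop_config("assay values must be finite")
  meas
}

#' Per-animal composite stress-susceptibility score
#'
#' z-scores every measurement against the sex-matched control reference,
#' orients each assay so that higher = more resilient, and averages the
#' oriented z-scores per animal (equal assay weights, mean over the assays
#' actually present). Negative composites signify heightened stress
#' susceptibility. Animals with no scorable assay are dropped with a warning.
#'
#' @param measurements Behavior table (one row per animal x assay).
#' @param sex Which sex to score (computed within sex).
#' @param directions Directionality table (`assay`, `orientation`); default
#'   [default_assay_directions()]. Assays absent from the table are an error.
#' @param reference Optionally a precomputed [build_reference()] table.
#' @param sigma_source Passed to [build_reference()].
#' @return Tibble with one row per animal: `animal_id`, `group`, `composite`
#'   (mean oriented z), `n_assays_used`, and a nested `per_assay` list-column
#'   of the oriented z-scores.
#' @export
composite_scores <- function(measurements, sex,
                             directions = default_assay_directions(),
                             reference = NULL,
                             sigma_source = c("experimental", "control")) {
  meas <- prep_measurements(measurements, sex)
  if (is.null(reference)) {
    reference <- build_reference(measurements, sex, sigma_source)
  }
  missing_dir <- setdiff(unique(meas$assay), directions$assay)
  if (length(missing_dir)) {
    stop_config(paste0("no orientation for assay(s): ",
                       paste(missing_dir, collapse = ", ")))
  }

  scored <- meas |>
    left_join(reference, by = c("assay", "group")) |>
    left_join(directions, by = "assay")
  unmatched <- is.na(scored$mu_ctrl)
  if (any(unmatched)) {
    warn(paste0(sum(unmatched), " measurement(s) without a reference entry ",
                "were dropped"))
    scored <- scored[!unmatched, ]
  }
  scored$z <- zscore(scored$value, scored$mu_ctrl, scored$sigma_exp)
  scored$oriented_z <- scored$orientation * scored$z

  out <- scored |>
    group_by(.data$animal_id, .data$group) |>
    summarise(
      composite = mean(.data$oriented_z),
      n_assays_used = n(),
      per_assay = list(setNames(.data$oriented_z, .data$assay)),
      .groups = "drop"
    )

  all_animals <- unique(meas$animal_id)
  dropped <- setdiff(all_animals, out$animal_id)
  if (length(dropped)) {
    warn(paste0("animals with zero scorable assays excluded: ",
                paste(dropped, collapse = ", ")))
  }
  attr(out, "excluded_animals") <- dropped
  out
}

#' Group summary of composite scores
#'
#' @param scores Output of [composite_scores()].
#' @return Tibble with `group`, `mean_composite`, `sem`, `n`.
#' @export
summarise_composites <- function(scores) {
  scores |>
    group_by(.data$group) |>
    summarise(mean_composite = mean(.data$composite),
              sem = sd(.data$composite) / sqrt(n()),
              n = n(), .groups = "drop")
}
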