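#' Assays scored per sex
#'
#' The behavioral battery comprises body-weight change, sucrose consumption,
#' forced-swim immobility, elevated-plus-maze open-arm time, open-field center
#' time and locomotion for both sexes; males additionally get a novel-object
#' discrimination index and females a social-interaction discrimination index
#' (females receive the extra social assay because standard stress assays are
#' more variable in females).
#'
#' @param sex `"male"` or `"female"`.
#' @return Character vector of assay names.
#' @export
assays_for_sex <- function(sex) {
  core <- c(
    "body_weight_change", "sucrose_consumption", "forced_swim_immobility",
    "epm_open_arm_time", "oft_center_time", "locomotion"
  )
  extra <- switch(sex,
    male = "novel_object_di",
    female = "social_interaction_di",
    stop_config(paste0("unknown sex: ", sex))
  )
  c(core, extra)
}

# nominal raw-scale control means per assay (the published analyses are fully
# z-scored, so these only anchor the raw scale; z-scores are invariant to them)
assay_baselines <- c(
  body_weight_change = 5, sucrose_consumption = 70, forced_swim_immobility = 90,
  epm_open_arm_time = 60, oft_center_time = 120, locomotion = 45,
  novel_object_di = 0.3, social_interaction_di = 0.3
)

default_behavior_effects <- function() {
  list(
    male = list(
      stress = c(all = -4),
      stress_10hz = c(all = -1),
      stress_20hz = c(all = -3),
      stress_40hz = c(all = -3)
    ),
    female = list(
      stress = c(all = -1),
      stress_10hz = c(all = -1),
      stress_20hz = c(all = -1),
      stress_40hz = c(all = 0)
    )
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators: the group design
#' (stress crossed with flicker frequency), per-assay behavioral shifts in
#' control-SD units, negative-binomial count parameters with a planted
#' stress-responsive gene set and per-frequency reversal fractions, and
#' morphology parameters (star skeletons and class-conditional spine
#' geometry). A fixed `seed` makes every generator bit-reproducible.
#'
#' @param seed Integer RNG seed.
#' @param n_per_group Animals per group per sex (behavioral arm); >= 2.
#' @param groups Data frame with columns `stress` (logical) and `frequency_hz`
#'   (`"none"`, `"10"`, `"20"` or `"40"`). Default: unstressed control plus
#'   stress alone and stress with 10/20/40 Hz flicker.
#' @param sexes Subset of `c("male", "female")`.
#' @param behavior_effects Named list per sex; each element is a named list
#'   mapping condition label (see [condition_label()]) to a named numeric
#'   vector of per-assay shifts in control-SD units on the oriented scale
#'   (negative = more stress-susceptible). The name `all` applies one shift to
#'   every assay. Defaults plant the published group separations: a -4 SD
#'   stress effect in males (-1 in females) and the strongest rescue by 10 Hz
#'   flicker in males and 40 Hz in females.
#' @param n_genes Number of genes (>= 100 for count generation).
#' @param nb_mean Per-gene baseline mean counts (scalar or length `n_genes`).
#' @param nb_dispersion Negative-binomial dispersion alpha >= 0 (scalar or
#'   per-gene); 0 gives Poisson counts.
#' @param frac_stress_de Fraction of coding genes planted as stress-responsive.
#' @param planted_lfc Magnitude of the planted log2 fold change.
#' @param reversal_fraction Named numeric, frequency (`"10"`, `"20"`, `"40"`)
#'   to fraction of planted stress genes whose shift is cancelled in the
#'   matching stress+flicker group.
#' @param reversal_strength Fraction of the planted shift removed in reversed
#'   genes (1 = full return to the control mean).
#' @param frac_noncoding Fraction of genes labelled non-coding (never planted).
#' @param n_samples_per_group RNA-seq samples per sex x condition (default 3,
#'   the pooled-pair layout of the study; samples are independent draws).
#' @param cell_types Cell types to simulate counts for.
#' @param morph_params List: `soma_radius` (um), `n_processes`,
#'   `process_length` (um), `nodes_per_process`, `kink_sd` (radians of
#'   direction jitter per internode; 0 = straight rays).
#' @param spine_mix Named proportions over
#'   `c("long_thin", "filopodia", "stubby", "mushroom")`, summing to 1.
#' @param n_spines Spines per generated population.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(seed = 20250712L,
                       n_per_group = 8L,
                       groups = NULL,
                       sexes = c("male", "female"),
                       behavior_effects = default_behavior_effects(),
                       n_genes = 2000L,
                       nb_mean = 500,
                       nb_dispersion = 0.1,
                       frac_stress_de = 0.15,
                       planted_lfc = 2,
                       reversal_fraction = c("10" = 0.30, "20" = 0.30, "40" = 0.30),
                       reversal_strength = 1,
                       frac_noncoding = 0.1,
                       n_samples_per_group = 3L,
                       cell_types = c("neuron", "astrocyte", "microglia"),
                       morph_params = list(),
                       spine_mix = c(long_thin = 0.25, filopodia = 0.25,
                                     stubby = 0.25, mushroom = 0.25),
                       n_spines = 400L) {
  if (is.null(groups)) {
    groups <- tibble(
      stress = c(FALSE, TRUE, TRUE, TRUE, TRUE),
      frequency_hz = c("none", "none", "10", "20", "40")
    )
  }
  groups <- as_tibble(groups)
  groups$frequency_hz <- as.character(groups$frequency_hz)

  if (!is_count(seed)) stop_config("`seed` must be a single integer")
  if (!is_count(n_per_group, min = 2L)) {
    stop_config("`n_per_group` must be an integer >= 2")
  }
  if (!all(c("stress", "frequency_hz") %in% names(groups))) {
    stop_config("`groups` needs columns `stress` and `frequency_hz`")
  }
  if (!all(groups$frequency_hz %in% c("none", "10", "20", "40"))) {
    stop_config("`frequency_hz` must be one of none/10/20/40")
  }
  if (!any(!groups$stress & groups$frequency_hz == "none")) {
    stop_config("`groups` must include the no-stress/no-stimulation control")
  }
  sexes <- match.arg(sexes, c("male", "female"), several.ok = TRUE)

  labels <- condition_label(groups$stress, groups$frequency_hz)
  for (sx in names(behavior_effects)) {
    eff <- behavior_effects[[sx]]
    if (!sx %in% c("male", "female")) {
      stop_config(paste0("behavior_effects: unknown sex `", sx, "`"))
    }
    # effects for conditions not in `groups` are inert and simply dropped
    behavior_effects[[sx]] <- eff <- eff[intersect(names(eff), labels)]
    for (grp in names(eff)) {
      bad <- setdiff(names(eff[[grp]]), c("all", assays_for_sex(sx)))
      if (length(bad)) {
        stop_config(paste0("behavior_effects: unknown assay(s) ",
                           paste(bad, collapse = ", "), " for ", sx, "/", grp))
      }
    }
  }

  if (!is_count(n_genes, min = 1L)) stop_config("`n_genes` must be a positive integer")
  if (!is.numeric(nb_mean) || any(nb_mean <= 0) ||
      !length(nb_mean) %in% c(1L, n_genes)) {
    stop_config("`nb_mean` must be positive, scalar or length n_genes")
  }
  if (!is.numeric(nb_dispersion) || any(nb_dispersion < 0) ||
      !length(nb_dispersion) %in% c(1L, n_genes)) {
    stop_config("`nb_dispersion` must be >= 0, scalar or length n_genes")
  }
  for (frac in list(frac_stress_de, frac_noncoding, reversal_strength)) {
    if (!is_number(frac) || frac < 0 || frac > 1) {
      stop_config("fractions must be single numbers in [0, 1]")
    }
  }
  if (length(reversal_fraction)) {
    if (is.null(names(reversal_fraction)) ||
        !all(nzchar(names(reversal_fraction)))) {
      stop_config("`reversal_fraction` must be named by frequency")
    }
    if (any(reversal_fraction < 0 | reversal_fraction > 1)) {
      stop_config("`reversal_fraction` values must be in [0, 1]")
    }
  }
  if (!is_number(planted_lfc)) stop_config("`planted_lfc` must be a number")
  if (!is_count(n_samples_per_group, min = 2L)) {
    stop_config("`n_samples_per_group` must be an integer >= 2")
  }
  cell_types <- match.arg(cell_types,
                          c("neuron", "astrocyte", "microglia"),
                          several.ok = TRUE)

  mp_default <- list(soma_radius = 5, n_processes = 5, process_length = 15,
                     nodes_per_process = 10L, kink_sd = 0.15)
  bad_mp <- setdiff(names(morph_params), names(mp_default))
  if (length(bad_mp)) {
    stop_config(paste0("morph_params: unknown field(s) ",
                       paste(bad_mp, collapse = ", ")))
  }
  mp <- utils::modifyList(mp_default, morph_params)
  if (mp$n_processes < 0 || mp$process_length <= 0 || mp$soma_radius <= 0) {
    stop_config("morph_params: process count >= 0, lengths/radius > 0")
  }

  classes <- c("long_thin", "filopodia", "stubby", "mushroom")
  if (!setequal(names(spine_mix), classes)) {
    stop_config("`spine_mix` must be named by the four spine classes")
  }
  spine_mix <- spine_mix[classes]
  if (any(spine_mix < 0) || abs(sum(spine_mix) - 1) > 1e-9) {
    stop_config("`spine_mix` proportions must be >= 0 and sum to 1 (1e-9)")
  }
  if (!is_count(n_spines)) stop_config("`n_spines` must be a non-negative integer")

  structure(
    list(
      seed = as.integer(seed), n_per_group = as.integer(n_per_group),
      groups = groups, sexes = sexes, behavior_effects = behavior_effects,
      n_genes = as.integer(n_genes), nb_mean = nb_mean,
      nb_dispersion = nb_dispersion, frac_stress_de = frac_stress_de,
      planted_lfc = planted_lfc, reversal_fraction = reversal_fraction,
      reversal_strength = reversal_strength, frac_noncoding = frac_noncoding,
      n_samples_per_group = as.integer(n_samples_per_group),
      cell_types = cell_types, morph_params = mp, spine_mix = spine_mix,
      n_spines = as.integer(n_spines)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " n_per_group:", x$n_per_group,
      " sexes:", paste(x$sexes, collapse = "/"), "\n")
  cat("  groups:", paste(condition_label(x$groups$stress, x$groups$frequency_hz),
                         collapse = ", "), "\n")
  cat("  counts:", x$n_genes, "genes,", x$n_samples_per_group,
      "samples/group, frac_stress_de", x$frac_stress_de,
      ", planted_lfc", x$planted_lfc, "\n")
  if (length(x$reversal_fraction)) {
    cat("  reversal:", paste(names(x$reversal_fraction), "Hz:",
                             x$reversal_fraction, collapse = "; "), "\n")
  }
  invisible(x)
}
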