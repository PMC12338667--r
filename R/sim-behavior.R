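with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

effect_for <- function(effects, sex, group, assay) {
  eff <- effects[[sex]][[group]]
  if (is.null(eff)) return(0)
  if (assay %in% names(eff)) return(unname(eff[[assay]]))
  if ("all" %in% names(eff)) return(unname(eff[["all"]]))
  0
}

#' Generate a synthetic behavioral assay table
#'
#' One row per animal x assay. Control animals are drawn from a unit-SD
#' Gaussian around a nominal per-assay baseline; every other group is shifted
#' by the configured effect, expressed in control-SD units on the oriented
#' scale (a negative effect means more stress-susceptible regardless of the
#' assay's native direction, so the raw shift is effect x orientation).
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `animal_id`, `sex`, `stress`, `frequency_hz`,
#'   `group`, `assay`, `value`.
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  directions <- default_assay_directions()
  dir_map <- setNames(directions$orientation, directions$assay)
  n <- config$n_per_group

  with_seed(config$seed, {
    blocks <- list()
    for (sex in config$sexes) {
      assays <- assays_for_sex(sex)
      for (g in seq_len(nrow(config$groups))) {
        stress <- config$groups$stress[g]
        freq <- config$groups$frequency_hz[g]
        group <- condition_label(stress, freq)
        ids <- sprintf("%s_%s_%02d", sex, group, seq_len(n))
        for (assay in assays) {
          eff <- effect_for(config$behavior_effects, sex, group, assay)
          shift <- eff * dir_map[[assay]]
          vals <- assay_baselines[[assay]] + shift + rnorm(n)
          blocks[[length(blocks) + 1L]] <- tibble(
            animal_id = ids, sex = sex, stress = stress, frequency_hz = freq,
            group = group, assay = assay, value = vals
          )
        }
      }
    }
    bind_rows(blocks)
  })
}
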