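as_deg_set <- function(x, contrast = NULL) {
  x <- as_tibble(x)
  if (!"gene_id" %in% names(x)) stop_config("DEG set needs a `gene_id` column")
  if (!"sign" %in% names(x)) {
    if (!"log2fc" %in% names(x)) {
      stop_config("DEG set needs `sign` or `log2fc`")
    }
    x$sign <- as.integer(sign(x$log2fc))
  }
  if (any(x$sign == 0)) stop_config("DEG signs must be nonzero")
  if (anyDuplicated(x$gene_id)) stop_config("duplicate genes in DEG set")
  attr(x, "contrast") <- contrast %||% attr(x, "contrast")
  x
}

#' Identify modifiable markers for a stress/flicker contrast pair
#'
#' A gene is a modifiable marker when it is a DEG in both the stress contrast
#' and the flicker contrast with opposite-signed fold changes — upregulated by
#' stress and downregulated by flicker, or vice versa. Two percentages are
#' reported: `percent_modifiable`, the share of flicker-contrast DEGs that are
#' modifiable (modifiable / flicker DEGs x 100), and
#' `percent_of_stress_degs`, the share of stress-contrast DEGs whose change is
#' reversed by flicker — the quantity that estimates a planted reversal
#' fraction. Genes significant in both contrasts with the same sign count as
#' non-modifiable (they stay in the denominators).
#'
#' @param stress_degs DEG table for the stress-vs-control contrast
#'   (`gene_id` plus `sign` or `log2fc`; see [call_degs()]).
#' @param flicker_degs DEG table for a flicker-vs-no-stim contrast; must be
#'   nonempty (an empty flicker set makes the percentage undefined, which is
#'   an error rather than 0).
#' @return One-row tibble of class `reversal_result`: `contrast`,
#'   `n_flicker_degs`, `n_stress_degs`, `n_modifiable`, `percent_modifiable`,
#'   `percent_modifiable_rounded`, `percent_of_stress_degs`, and a
#'   `modifiable_genes` list-column.
#' @export
classify_modifiable <- function(stress_degs, flicker_degs) {
  s <- as_deg_set(stress_degs)
  f <- as_deg_set(flicker_degs)
  if (nrow(f) == 0) {
    stop_degenerate("empty flicker DEG set: percent modifiable is undefined")
  }
  joined <- dplyr::inner_join(
    select(s, "gene_id", stress_sign = "sign"),
    select(f, "gene_id", flicker_sign = "sign"),
    by = "gene_id"
  )
  modifiable <- joined$gene_id[joined$stress_sign * joined$flicker_sign < 0]
  pct <- 100 * length(modifiable) / nrow(f)
  out <- tibble(
    contrast = attr(f, "contrast") %||% "flicker",
    n_flicker_degs = nrow(f),
    n_stress_degs = nrow(s),
    n_modifiable = length(modifiable),
    percent_modifiable = pct,
    percent_modifiable_rounded = round(pct),
    percent_of_stress_degs =
      if (nrow(s)) 100 * length(modifiable) / nrow(s) else NA_real_,
    modifiable_genes = list(modifiable)
  )
  class(out) <- c("reversal_result", class(out))
  out
}

#' Overlap summary of two DEG sets
#'
#' Exact set algebra on gene identifiers (Venn counts).
#'
#' @param set_a,set_b DEG tables (`gene_id` column) or character vectors.
#' @return One-row tibble: `n_a`, `n_b`, `shared`, `unique_a`, `unique_b`,
#'   `union`, plus a `shared_genes` list-column.
#' @export
overlap_sets <- function(set_a, set_b) {
  ga <- if (is.character(set_a)) unique(set_a) else as_deg_set(set_a)$gene_id
  gb <- if (is.character(set_b)) unique(set_b) else as_deg_set(set_b)$gene_id
  shared <- intersect(ga, gb)
  tibble(
    n_a = length(ga), n_b = length(gb), shared = length(shared),
    unique_a = length(setdiff(ga, gb)), unique_b = length(setdiff(gb, ga)),
    union = length(union(ga, gb)), shared_genes = list(shared)
  )
}

#' Up/down direction fractions of a DEG set
#'
#' @param degs DEG table (`gene_id` plus `sign` or `log2fc`); must be
#'   nonempty.
#' @return One-row tibble: `n`, `n_up`, `n_down`, `percent_up`,
#'   `percent_down` (exact rationals; they sum to 100).
#' @export
direction_fractions <- function(degs) {
  d <- as_deg_set(degs)
  if (nrow(d) == 0) stop_degenerate("empty DEG set has no direction fractions")
  n_up <- sum(d$sign > 0)
  tibble(
    n = nrow(d), n_up = n_up, n_down = nrow(d) - n_up,
    percent_up = 100 * n_up / nrow(d),
    percent_down = 100 * (nrow(d) - n_up) / nrow(d)
  )
}
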