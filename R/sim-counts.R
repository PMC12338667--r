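#' Generate synthetic negative-binomial count data with planted structure
#'
#' Draws raw counts for every sex x condition x cell type combination in the
#' configuration (`n_samples_per_group` independent samples each). A fraction
#' `frac_stress_de` of coding genes carries a +/-`planted_lfc` log2 shift in
#' all stressed groups; of those, `reversal_fraction[f]` have the shift
#' cancelled (scaled by `reversal_strength`) in the stress + f Hz flicker
#' group, emulating genes whose stress response is reversed by flicker.
#' Counts are NB(mean x size factor, dispersion alpha); alpha = 0 gives
#' Poisson draws. Per-sample true size factors are log-normal around 1.
#'
#' @param config A [sim_config()] with `n_genes >= 100`.
#' @param cell_types Cell types to generate (default from config).
#' @param sexes Sexes to generate (default from config).
#' @return A [count_dataset()] with an extra element `truth`: a tibble
#'   (`gene_id`, `biotype`, `stress_de`, `planted_lfc` signed, and one logical
#'   `reversed_<f>hz` column per configured frequency).
#' @export
simulate_counts <- function(config, cell_types = config$cell_types,
                            sexes = config$sexes) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 100) stop_config("count generation needs n_genes >= 100")
  stress_freqs <- unique(config$groups$frequency_hz[config$groups$stress])
  bad <- setdiff(names(config$reversal_fraction), stress_freqs)
  if (length(bad)) {
    stop_config(paste0("reversal_fraction given for frequencies absent from ",
                       "the stressed groups: ", paste(bad, collapse = ", ")))
  }

  n <- config$n_genes
  gene_ids <- sprintf("gene_%05d", seq_len(n))
  base_mean <- rep_len(config$nb_mean, n)
  alpha <- rep_len(config$nb_dispersion, n)

  with_seed(config$seed + 1L, {
    n_nc <- round(config$frac_noncoding * n)
    noncoding <- sample(n, n_nc)
    biotype <- rep("protein_coding", n)
    biotype[noncoding] <- sample(c("lncRNA", "miRNA", "processed_pseudogene"),
                                 n_nc, replace = TRUE)

    coding <- setdiff(seq_len(n), noncoding)
    n_de <- round(config$frac_stress_de * length(coding))
    de_idx <- sort(sample(coding, n_de))
    sign_de <- sample(c(-1, 1), n_de, replace = TRUE)

    lfc <- numeric(n)
    lfc[de_idx] <- sign_de * config$planted_lfc

    truth <- tibble(gene_id = gene_ids, biotype = biotype,
                    stress_de = seq_len(n) %in% de_idx, planted_lfc = lfc)
    reversed <- list()
    for (f in names(config$reversal_fraction)) {
      n_rev <- round(config$reversal_fraction[[f]] * n_de)
      rev_idx <- sort(sample(de_idx, n_rev))
      reversed[[f]] <- rev_idx
      truth[[paste0("reversed_", f, "hz")]] <- seq_len(n) %in% rev_idx
    }

    samples <- tidyr::expand_grid(
      cell_type = cell_types, sex = sexes,
      config$groups,
      rep = seq_len(config$n_samples_per_group)
    )
    samples$group <- condition_label(samples$stress, samples$frequency_hz)
    samples$sample_id <- sprintf("%s_%s_%s_s%d", samples$cell_type,
                                 samples$sex, samples$group, samples$rep)
    samples$true_size_factor <- exp(rnorm(nrow(samples), 0, 0.15))

    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(gene_ids, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      lfc_s <- numeric(n)
      if (samples$stress[s]) {
        lfc_s <- lfc
        f <- samples$frequency_hz[s]
        if (f %in% names(reversed) && length(reversed[[f]])) {
          lfc_s[reversed[[f]]] <- lfc[reversed[[f]]] * (1 - config$reversal_strength)
        }
      }
      mu <- base_mean * 2^lfc_s * samples$true_size_factor[s]
      pois <- alpha == 0
      y <- integer(n)
      if (any(pois)) y[pois] <- rpois(sum(pois), mu[pois])
      if (any(!pois)) {
        y[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / alpha[!pois])
      }
      counts[, s] <- y
    }

    out <- count_dataset(counts,
                         samples[c("sample_id", "sex", "cell_type", "stress",
                                   "frequency_hz", "true_size_factor")],
                         tibble(gene_id = gene_ids, biotype = biotype))
    out$truth <- truth
    out
  })
}
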