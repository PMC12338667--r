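#' Filter genes by raw-count abundance and biotype
#'
#' Applies the pipeline's two pre-filters: a gene is excluded when fewer than
#' 50 raw counts are observed in at least 75% of samples (the 75% boundary is
#' inclusive: exactly 3 of 4 low samples excludes), and when its biotype is
#' not protein-coding. A filter report (genes before/after, removed per rule)
#' is attached as the `"filter_report"` attribute.
#'
#' @param dataset A [count_dataset()] with >= 2 samples.
#' @param min_count Raw-count threshold (default 50).
#' @param min_frac_low Fraction of low samples at which a gene is dropped
#'   (default 0.75, inclusive).
#' @param coding_only Drop non-protein-coding biotypes (default TRUE).
#' @return The filtered `count_dataset`.
#' @export
filter_genes <- function(dataset, min_count = 50, min_frac_low = 0.75,
                         coding_only = TRUE) {
  stopifnot(inherits(dataset, "count_dataset"))
  if (ncol(dataset$counts) < 2) stop_config("need >= 2 samples to filter")
  frac_low <- rowMeans(dataset$counts < min_count)
  low_fail <- frac_low >= min_frac_low
  bio_fail <- if (coding_only) dataset$genes$biotype != "protein_coding" else
    rep(FALSE, nrow(dataset$counts))
  keep <- !low_fail & !bio_fail
  if (!any(keep)) stop_degenerate("all genes removed by filtering")
  out <- count_dataset(dataset$counts[keep, , drop = FALSE],
                       dataset$samples[setdiff(names(dataset$samples), "group")],
                       dataset$genes[keep, ])
  if (!is.null(dataset$truth)) out$truth <- dataset$truth[keep, ]
  attr(out, "filter_report") <- list(
    n_before = nrow(dataset$counts), n_after = sum(keep),
    n_low_count = sum(low_fail), n_noncoding = sum(bio_fail & !low_fail),
    min_count = min_count, min_frac_low = min_frac_low
  )
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes of the ratio of
#' the sample's count to the gene's geometric mean across samples, taken over
#' genes with all-positive counts; factors are then rescaled to geometric mean
#' 1 (the rescaling cancels in any contrast, it only fixes the reporting
#' scale). With `pseudo_reference = TRUE`, zero-containing genes participate
#' via a positive-part geometric mean — the fallback when no gene is positive
#' everywhere.
#'
#' @param dataset A [count_dataset()] or a counts matrix.
#' @param pseudo_reference Use all genes with a positive-sample geometric mean
#'   instead of requiring all-positive genes.
#' @return Named numeric vector of size factors (one per sample).
#' @export
size_factors <- function(dataset, pseudo_reference = FALSE) {
  counts <- if (inherits(dataset, "count_dataset")) dataset$counts else
    as.matrix(dataset)
  if (pseudo_reference) {
    logg <- log(counts)
    logg[!is.finite(logg)] <- NA
    geo <- exp(rowMeans(logg, na.rm = TRUE))
    use <- is.finite(geo) & geo > 0
  } else {
    use <- rowSums(counts > 0) == ncol(counts)
    if (!any(use)) {
      stop_degenerate(paste0(
        "no gene has positive counts in every sample; ",
        "re-run with pseudo_reference = TRUE"))
    }
    geo <- exp(rowMeans(log(pmax(counts, 1e-300))))
  }
  ratios <- counts[use, , drop = FALSE] / geo[use]
  sf <- apply(ratios, 2, median)
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

# Profile NB group means with fixed dispersion: for each gene solve
# sum_i (y_i - q s_i) / (1 + alpha q s_i) = 0 for q > 0 (Newton, vectorized
# across genes). With alpha = 0 this is the weighted mean sum(y)/sum(s).
nb_group_mean <- function(y, sf, alpha) {
  q <- pmax(rowSums(y) / sum(sf), 1e-8)
  for (it in 1:50) {
    f <- numeric(length(q))
    fp <- numeric(length(q))
    for (j in seq_along(sf)) {
      denom <- 1 + alpha * q * sf[j]
      f <- f + (y[, j] - q * sf[j]) / denom
      fp <- fp - sf[j] * (1 + alpha * y[, j]) / denom^2
    }
    step <- f / fp
    step[!is.finite(step)] <- 0
    q_new <- q - step
    q_new <- ifelse(q_new <= 0, q / 2, q_new)
    moved <- max(abs(q_new - q) / pmax(q, 1e-8))
    q <- q_new
    if (moved < 1e-10) break
  }
  pmax(q, 1e-12)
}

#' Per-gene negative-binomial Wald test for a two-level contrast
#'
#' Fits, per gene, an NB model with log link and log size-factor offsets for
#' one two-level factor (`Stress`: stressed vs unstressed at matched
#' frequency; `Frequency`: one flicker frequency vs no-stim within stressed
#' animals). The dispersion is a per-gene method-of-moments estimate on
#' normalized counts, pooled within groups and floored at 1e-8 — no
#' empirical-Bayes shrinkage, no outlier handling, no independent filtering.
#' The Wald statistic log2FC / SE is referred to a Student t distribution
#' with residual degrees of freedom (N - 2): with the dispersion estimated
#' from so few residual df, the plug-in normal reference is markedly
#' anticonservative at n = 3/group, and the t reference restores nominal
#' type-I control while converging to the normal as n grows.
#' Benjamini-Hochberg adjusted p-values are reported alongside, but DEG
#' calling uses the unadjusted p (see [call_degs()]).
#'
#' @param dataset A filtered [count_dataset()]; analyze one cell type and sex
#'   at a time (use [subset_samples()]).
#' @param variable `"stress"` or `"frequency"`.
#' @param level Test level: for `"stress"` ignored (stressed vs unstressed);
#'   for `"frequency"` the flicker frequency, e.g. `"10"`.
#' @param reference Reference level: for `"frequency"` default `"none"`
#'   (stressed, unstimulated).
#' @param factors Optional size factors; computed by [size_factors()] if NULL.
#' @return Tibble of class `de_result`: `gene_id`, `mean_norm_count`,
#'   `log2fc` (level vs reference), `se_log2fc`, `wald_stat`, `p_value`,
#'   `p_adj`, `is_deg`, plus attributes recording the contrast.
#' @export
nb_wald_test <- function(dataset, variable = c("stress", "frequency"),
                         level = NULL, reference = NULL, factors = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  variable <- match.arg(variable)
  smp <- dataset$samples
  if (length(unique(smp$cell_type)) > 1) {
    warn("multiple cell types in one model; analyses are usually per cell type")
  }

  if (variable == "stress") {
    # stress no-stim vs no-stress no-stim (unstimulated animals only)
    in_ref <- !smp$stress & smp$frequency_hz == "none"
    in_lvl <- smp$stress & smp$frequency_hz == "none"
    label <- "stress_vs_control"
  } else {
    if (is.null(level)) stop_config("`level` (frequency) is required")
    level <- as.character(level)
    reference <- as.character(reference %||% "none")
    if (identical(level, reference)) {
      stop_config("`level` must differ from `reference`")
    }
    in_ref <- smp$stress & smp$frequency_hz == reference
    in_lvl <- smp$stress & smp$frequency_hz == level
    label <- paste0("flicker_", level, "hz_vs_", reference)
  }
  if (sum(in_ref) < 2 || sum(in_lvl) < 2) {
    stop_config("need >= 2 samples in each level of the contrast")
  }

  used <- in_ref | in_lvl
  counts <- dataset$counts[, used, drop = FALSE]
  grp <- in_lvl[used]
  if (is.null(factors)) {
    factors <- size_factors(counts)
  } else {
    factors <- factors[colnames(counts)]
  }

  nonzero <- rowSums(counts) > 0
  y <- counts[nonzero, , drop = FALSE]
  sf <- unname(factors)
  z <- sweep(y, 2, sf, "/")

  # method-of-moments dispersion on normalized counts, pooled within groups:
  # Var(y/s) = mu/s + alpha mu^2, so alpha_g = (v_g - m_g mean(1/s)) / m_g^2
  alpha_hat <- rep(0, nrow(y))
  wsum <- 0
  for (g in list(which(!grp), which(grp))) {
    zg <- z[, g, drop = FALSE]
    m <- rowMeans(zg)
    v <- apply(zg, 1, var)
    a <- (v - m * mean(1 / sf[g])) / m^2
    a[!is.finite(a)] <- 0
    w <- length(g) - 1L
    alpha_hat <- alpha_hat + w * pmax(a, 0)
    wsum <- wsum + w
  }
  alpha_hat <- pmax(alpha_hat / wsum, 1e-8)

  q_ref <- nb_group_mean(y[, !grp, drop = FALSE], sf[!grp], alpha_hat)
  q_lvl <- nb_group_mean(y[, grp, drop = FALSE], sf[grp], alpha_hat)

  info <- function(q, s) {
    i <- numeric(length(q))
    for (j in seq_along(s)) {
      mu <- q * s[j]
      i <- i + mu / (1 + alpha_hat * mu)
    }
    i
  }
  var_beta <- unname(1 / info(q_ref, sf[!grp]) + 1 / info(q_lvl, sf[grp]))
  beta <- unname(log(q_lvl / q_ref))
  log2fc <- beta / log(2)
  se_log2fc <- sqrt(var_beta) / log(2)
  wald <- beta / sqrt(var_beta)
  df_resid <- ncol(y) - 2L
  p <- 2 * pt(-abs(wald), df = df_resid)

  res <- tibble(
    gene_id = rownames(y),
    mean_norm_count = rowMeans(z),
    log2fc = log2fc,
    se_log2fc = se_log2fc,
    wald_stat = wald,
    p_value = p,
    p_adj = p.adjust(p, method = "BH")
  )
  res$is_deg <- abs(res$log2fc) >= 1 & res$p_value < 0.05
  attr(res, "contrast") <- label
  attr(res, "n_samples") <- c(reference = sum(!grp), level = sum(grp))
  class(res) <- c("de_result", class(res))
  res
}

#' Call differentially expressed genes
#'
#' A pure function of the result table: a gene is a DEG when
#' |log2FC| >= `lfc_threshold` (inclusive) and unadjusted p < `p_threshold`.
#'
#' @param results A [nb_wald_test()] table (needs `gene_id`, `log2fc`,
#'   `p_value`).
#' @param lfc_threshold Minimum |log2FC| (default 1, inclusive).
#' @param p_threshold Unadjusted-p cutoff (default 0.05, exclusive).
#' @return Tibble of class `deg_set`: `gene_id`, `log2fc`, `sign` (+1/-1),
#'   with `n_up`/`n_down` attributes and the contrast label carried over.
#' @export
call_degs <- function(results, lfc_threshold = 1, p_threshold = 0.05) {
  need <- c("gene_id", "log2fc", "p_value")
  if (!all(need %in% names(results))) {
    stop_config(paste0("`results` needs columns: ", paste(need, collapse = ", ")))
  }
  hits <- filter(as_tibble(results),
                 abs(.data$log2fc) >= lfc_threshold,
                 .data$p_value < p_threshold)
  out <- tibble(gene_id = hits$gene_id, log2fc = hits$log2fc,
                sign = as.integer(sign(hits$log2fc)))
  attr(out, "contrast") <- attr(results, "contrast")
  attr(out, "n_up") <- sum(out$sign > 0)
  attr(out, "n_down") <- sum(out$sign < 0)
  class(out) <- c("deg_set", class(out))
  out
}
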