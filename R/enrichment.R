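#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: term, description, then member genes.
#' Identifiers are matched exactly after whitespace stripping; no symbol
#' aliasing is attempted.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (term -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- trimws(strsplit(l, "\t", fixed = TRUE)[[1]])
    genes <- unique(parts[-(1:2)])
    genes[nzchar(genes)]
  })
  names(sets) <- vapply(lines, function(l) {
    trimws(strsplit(l, "\t", fixed = TRUE)[[1]][1])
  }, character(1))
  if (any(!lengths(sets))) stop_config("GMT contains an empty gene set")
  if (anyDuplicated(names(sets))) stop_config("duplicate term names in GMT")
  sets
}

#' Hypergeometric over-representation test of a DEG list against gene sets
#'
#' One-sided (upper tail) hypergeometric test per term, the Fisher's-exact
#' over-representation mode: with `N` background genes, `K` of them in the
#' term, `n` DEGs and `k` DEGs in the term, `p = P(X >= k)`. The background
#' must be the post-filter gene universe the DEGs were called from;
#' Benjamini-Hochberg FDR across terms is applied when `adjust = TRUE`
#' (the convention used for flicker-vs-stress contrasts; stress-vs-control
#' enrichments are customarily left unadjusted for inclusiveness).
#'
#' @param degs DEG table (`gene_id`) or character vector of genes; must be a
#'   subset of `background` (identifier mismatches are an error, not silently
#'   dropped).
#' @param sets Named list of gene sets (e.g. [read_gmt()]); set members absent
#'   from the background are ignored.
#' @param background Character vector: the filtered gene universe.
#' @param adjust Apply BH FDR across terms.
#' @return Tibble sorted by p: `term`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `p_value`, and `fdr` when `adjust = TRUE`.
#' @export
fisher_overrepresentation <- function(degs, sets, background, adjust = TRUE) {
  genes <- if (is.character(degs)) unique(trimws(degs)) else
    unique(trimws(as_deg_set(degs)$gene_id))
  background <- unique(trimws(background))
  missing <- setdiff(genes, background)
  if (length(missing)) {
    stop_config(paste0("DEG(s) absent from the background universe: ",
                       paste(utils::head(missing, 10), collapse = ", "),
                       if (length(missing) > 10) " ..." else ""))
  }
  if (is.null(names(sets)) || !all(nzchar(names(sets)))) {
    stop_config("gene sets must be named")
  }
  N <- length(background)
  n <- length(genes)
  rows <- purrr::imap(sets, function(members, term) {
    members <- intersect(unique(trimws(members)), background)
    K <- length(members)
    k <- length(intersect(genes, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    tibble(term = term, k = k, K = K, n = n, N = N,
           odds_ratio = or, p_value = p)
  })
  out <- arrange(bind_rows(rows), .data$p_value)
  if (adjust) out$fdr <- p.adjust(out$p_value, method = "BH")
  out
}

#' Single-sample rank-walk enrichment scores
#'
#' A simplified per-sample enrichment score in the spirit of gene-set
#' variation analysis: within each sample, genes are ranked by expression
#' (descending); walking down the ranking, set members add `1 / n_set` and
#' non-members subtract `1 / (N - n_set)`; the score is the maximum deviation
#' of the walk, signed (positive when set genes concentrate at the top).
#' Being rank-based, scores are invariant to any monotone transform of a
#' sample's expression values and lie in [-1, 1]. This is deliberately not
#' the full kernel-CDF pipeline of the published GSVA package.
#'
#' @param expr Normalized expression matrix (genes x samples, rownames gene
#'   ids) or a [count_dataset()] (normalized by [size_factors()] internally).
#' @param sets Named list of gene sets; sets with < 2 genes present in `expr`
#'   are skipped with a warning. Missing member genes are dropped (warned).
#' @param ties Tie-break for equal expression (default `"first"`, i.e. input
#'   order; ties are rare on continuous data).
#' @return Tibble: `sample_id`, `term`, `score`, `n_genes_used`.
#' @export
gsva_scores <- function(expr, sets, ties = "first") {
  if (inherits(expr, "count_dataset")) {
    sf <- size_factors(expr)
    expr <- sweep(expr$counts, 2, sf, "/")
  }
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop_config("need >= 2 samples for enrichment scoring")
  if (is.null(rownames(expr))) stop_config("`expr` needs gene-id rownames")
  genes <- rownames(expr)
  N <- length(genes)

  rows <- list()
  for (term in names(sets)) {
    members <- unique(trimws(sets[[term]]))
    present <- intersect(members, genes)
    if (length(present) < length(members)) {
      warn(paste0(term, ": ", length(members) - length(present),
                  " set gene(s) absent from expression matrix"))
    }
    if (length(present) < 2) {
      warn(paste0(term, ": fewer than 2 matched genes, skipped"))
      next
    }
    in_set <- genes %in% present
    n_set <- sum(in_set)
    for (s in seq_len(ncol(expr))) {
      ord <- order(expr[, s], decreasing = TRUE,
                   method = if (ties == "first") "radix" else "auto")
      steps <- ifelse(in_set[ord], 1 / n_set, -1 / (N - n_set))
      walk <- cumsum(steps)
      peak <- max(walk)
      trough <- min(walk)
      score <- if (peak >= -trough) peak else trough
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = colnames(expr)[s] %||% as.character(s),
        term = term, score = score, n_genes_used = n_set
      )
    }
  }
  if (!length(rows)) {
    return(tibble(sample_id = character(), term = character(),
                  score = numeric(), n_genes_used = integer()))
  }
  bind_rows(rows)
}
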