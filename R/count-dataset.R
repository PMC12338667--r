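#' Construct a count dataset
#'
#' The container for cell-type bulk RNA-seq input: a genes x samples matrix of
#' raw counts plus sample metadata and gene annotation. Analyses run
#' separately per cell type (and sex), so `samples` carries `cell_type`,
#' `sex`, `stress` and `frequency_hz`.
#'
#' @param counts Integer matrix, genes x samples, non-negative; rownames are
#'   gene ids, colnames sample ids.
#' @param samples Data frame with columns `sample_id`, `sex`, `cell_type`,
#'   `stress` (logical), `frequency_hz`; one row per column of `counts`.
#' @param genes Data frame with columns `gene_id`, `biotype`; one row per row
#'   of `counts`.
#' @return An object of class `count_dataset`.
#' @export
count_dataset <- function(counts, samples, genes) {
  counts <- as.matrix(counts)
  samples <- as_tibble(samples)
  genes <- as_tibble(genes)
  if (!is.numeric(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop_config("`counts` must be non-negative integers")
  }
  if (anyDuplicated(genes$gene_id)) stop_config("gene ids must be unique")
  if (anyDuplicated(samples$sample_id)) stop_config("sample ids must be unique")
  need <- c("sample_id", "sex", "cell_type", "stress", "frequency_hz")
  if (!all(need %in% names(samples))) {
    stop_config(paste0("`samples` needs columns: ", paste(need, collapse = ", ")))
  }
  if (!all(c("gene_id", "biotype") %in% names(genes))) {
    stop_config("`genes` needs columns gene_id, biotype")
  }
  if (nrow(genes) != nrow(counts) || nrow(samples) != ncol(counts)) {
    stop_config("counts dimensions must match genes/samples tables")
  }
  if (anyNA(samples[need])) stop_config("sample metadata must be complete")
  rownames(counts) <- genes$gene_id
  colnames(counts) <- samples$sample_id
  samples$group <- condition_label(samples$stress, samples$frequency_hz)
  structure(list(counts = counts, samples = samples, genes = genes),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("<count_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  cell types:", paste(unique(x$samples$cell_type), collapse = ", "), "\n")
  cat("  groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a count dataset by sample
#'
#' @param dataset A [count_dataset()].
#' @param ... Filter expressions evaluated in the sample-metadata table, e.g.
#'   `cell_type == "neuron"`, `sex == "male"`.
#' @return A `count_dataset` restricted to the matching samples.
#' @export
subset_samples <- function(dataset, ...) {
  stopifnot(inherits(dataset, "count_dataset"))
  keep <- filter(dataset$samples, ...)
  out <- count_dataset(dataset$counts[, keep$sample_id, drop = FALSE],
                       keep[setdiff(names(keep), "group")], dataset$genes)
  out$truth <- dataset$truth
  out
}

#' Read a count dataset from TSV files
#'
#' @param counts_tsv Genes x samples TSV with a leading `gene_id` column.
#' @param samples_tsv Sample metadata TSV (`sample_id`, `sex`, `cell_type`,
#'   `stress`, `frequency_hz`).
#' @param genes_tsv Gene annotation TSV (`gene_id`, `biotype`).
#' @return A [count_dataset()].
#' @export
read_count_dataset <- function(counts_tsv, samples_tsv, genes_tsv) {
  cts <- readr::read_tsv(counts_tsv, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_tsv, show_col_types = FALSE,
                             col_types = readr::cols(frequency_hz = "c"))
  genes <- readr::read_tsv(genes_tsv, show_col_types = FALSE)
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$gene_id
  genes <- genes[match(rownames(m), genes$gene_id), ]
  samples <- samples[match(colnames(m), samples$sample_id), ]
  count_dataset(m, samples, genes)
}

#' Write a count dataset to TSV files
#'
#' @param dataset A [count_dataset()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_count_dataset <- function(dataset, dir, prefix = "counts") {
  stopifnot(inherits(dataset, "count_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".tsv", "_samples.tsv", "_genes.tsv")))
  readr::write_tsv(
    bind_cols(tibble(gene_id = rownames(dataset$counts)),
              as_tibble(dataset$counts)),
    paths[1]
  )
  readr::write_tsv(dataset$samples, paths[2])
  readr::write_tsv(dataset$genes, paths[3])
  invisible(paths)
}
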