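tiny_dataset <- function(counts, biotype = NULL, stress = NULL,
                         frequency_hz = NULL) {
  counts <- as.matrix(counts)
  ns <- ncol(counts)
  rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("s%02d", seq_len(ns))
  count_dataset(
    counts,
    tibble::tibble(
      sample_id = colnames(counts), sex = "male", cell_type = "neuron",
      stress = if (is.null(stress)) rep(c(FALSE, TRUE), each = ns / 2) else stress,
      frequency_hz = if (is.null(frequency_hz)) rep("none", ns) else frequency_hz
    ),
    tibble::tibble(
      gene_id = rownames(counts),
      biotype = if (is.null(biotype)) rep("protein_coding", nrow(counts)) else biotype
    )
  )
}

test_that("gene filters apply the low-count and biotype rules at the boundary", {
  m <- rbind(c(49, 49, 49, 100),   # 75% below 50 -> excluded (inclusive)
             c(50, 50, 0, 0),      # 50% below -> retained
             c(1000, 1000, 1000, 1000),
             c(1000, 1000, 1000, 1000))
  ds <- tiny_dataset(m, biotype = c("protein_coding", "protein_coding",
                                    "lncRNA", "protein_coding"))
  f <- filter_genes(ds)
  expect_setequal(rownames(f$counts), c("g002", "g004"))
  rep <- attr(f, "filter_report")
  expect_equal(rep$n_before, 4L)
  expect_equal(rep$n_after, 2L)
  expect_equal(rep$n_low_count, 1L)
  expect_equal(rep$n_noncoding, 1L)
  expect_error(filter_genes(tiny_dataset(matrix(1, 2, 4))),
               class = "flickerstress_degenerate_error")
})

test_that("size factors follow the median-of-ratios closed forms", {
  set.seed(1)
  base <- matrix(rpois(300, 200), 100, 3)
  m <- cbind(base, 2 * base[, 1])  # sample 4 = exact doubling of sample 1
  sf <- size_factors(m)
  expect_equal(unname(sf[4] / sf[1]), 2, tolerance = 1e-12)

  ident <- matrix(rep(rpois(50, 100), 4), ncol = 4)
  expect_equal(unname(size_factors(ident)), rep(1, 4), tolerance = 1e-12)

  # a single all-positive gene: factors are that gene's (centered) ratios
  m2 <- rbind(c(10, 20, 40), matrix(c(0, 5, 5, 5, 0, 5, 5, 5, 0), 3, 3))
  sf2 <- size_factors(m2)
  expected <- c(10, 20, 40) / exp(mean(log(c(10, 20, 40))))
  expect_equal(unname(sf2), unname(expected), tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)),
               class = "flickerstress_degenerate_error")
  expect_silent(size_factors(matrix(c(0, 1, 1, 0), 2, 2),
                             pseudo_reference = TRUE))
})

test_that("identical counts across groups give log2fc 0 and p ~ 1", {
  ds <- tiny_dataset(matrix(100L, 50, 6))
  res <- nb_wald_test(ds, "stress")
  expect_equal(res$log2fc, rep(0, 50), tolerance = 1e-10)
  expect_true(all(res$p_value > 0.99))
  expect_false(any(res$is_deg))
})

test_that("null simulation keeps type-I error within the accepted band", {
  cfg <- sim_config(seed = 71, n_genes = 2000, frac_stress_de = 0,
                    nb_mean = 200, nb_dispersion = 0.1, frac_noncoding = 0,
                    reversal_fraction = numeric(0))
  f <- filter_genes(simulate_counts(cfg, cell_types = "neuron", sexes = "male"))
  res <- nb_wald_test(f, "stress")
  expect_gte(mean(res$p_value < 0.05), 0.03)
  expect_lte(mean(res$p_value < 0.05), 0.08)
})

test_that("planted fold changes are recovered by the NB fit", {
  cfg <- sim_config(seed = 72, n_genes = 2000, nb_mean = 500,
                    frac_stress_de = 0.15, planted_lfc = 2)
  f <- filter_genes(simulate_counts(cfg, cell_types = "neuron", sexes = "male"))
  res <- nb_wald_test(f, "stress")
  m <- dplyr::inner_join(res, f$truth, by = "gene_id")
  planted <- dplyr::filter(m, stress_de)
  expect_lt(median(abs(planted$log2fc - planted$planted_lfc)), 0.3)
  expect_equal(median(planted$log2fc[planted$planted_lfc > 0]), 2,
               tolerance = 0.3 / 2)
  expect_equal(median(planted$log2fc[planted$planted_lfc < 0]), -2,
               tolerance = 0.3 / 2)
})

test_that("column scaling moves the size factor, not the fold changes", {
  cfg <- sim_config(seed = 73, n_genes = 300, frac_noncoding = 0)
  f <- filter_genes(simulate_counts(cfg, cell_types = "neuron", sexes = "male"))
  res0 <- nb_wald_test(f, "stress")
  scaled <- f$counts
  scaled[, 2] <- 3L * scaled[, 2]
  sf0 <- size_factors(f$counts)
  sf1 <- size_factors(scaled)
  expect_equal(unname(sf1[2] / sf1[1]), unname(3 * sf0[2] / sf0[1]),
               tolerance = 1e-9)
  ds1 <- count_dataset(scaled, f$samples[setdiff(names(f$samples), "group")],
                       f$genes)
  res1 <- nb_wald_test(ds1, "stress")
  expect_equal(res1$log2fc, res0$log2fc, tolerance = 0.02)
})

test_that("gene order permutation permutes results identically", {
  cfg <- sim_config(seed = 74, n_genes = 200, frac_noncoding = 0)
  f <- filter_genes(simulate_counts(cfg, cell_types = "neuron", sexes = "male"))
  res0 <- nb_wald_test(f, "stress")
  perm <- sample(nrow(f$counts))
  dsp <- count_dataset(f$counts[perm, ],
                       f$samples[setdiff(names(f$samples), "group")],
                       f$genes[perm, ])
  resp <- nb_wald_test(dsp, "stress")
  reordered <- resp[match(res0$gene_id, resp$gene_id), ]
  expect_equal(reordered$log2fc, res0$log2fc)
  expect_equal(reordered$p_value, res0$p_value)
})

test_that("DEG calling applies inclusive |log2FC| and exclusive p thresholds", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(1.0, 0.99, -3, 2),
    p_value = c(0.049, 1e-10, 0.051, 0.2)
  )
  degs <- call_degs(res)
  expect_equal(degs$gene_id, "a")
  expect_equal(degs$sign, 1L)
  # re-thresholding the same table is idempotent
  expect_identical(call_degs(res)$gene_id, degs$gene_id)
})

test_that("fold changes agree with an independent DESeq2 fit", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(seed = 42, n_genes = 400, nb_mean = 300,
                    frac_stress_de = 0.2, planted_lfc = 1.5, frac_noncoding = 0)
  f <- filter_genes(simulate_counts(cfg, cell_types = "neuron", sexes = "male"))
  use <- f$samples$frequency_hz == "none"
  cond <- factor(ifelse(f$samples$stress[use], "stress", "ctrl"),
                 levels = c("ctrl", "stress"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    f$counts[, use], data.frame(condition = cond), ~condition
  )
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  ref <- DESeq2::results(dds)
  mine <- nb_wald_test(f, "stress")
  expect_identical(rownames(ref), mine$gene_id)
  expect_gt(cor(mine$log2fc, ref$log2FoldChange), 0.999)
  expect_lt(max(abs(mine$log2fc - ref$log2FoldChange)), 0.05)
  sf_mine <- size_factors(f$counts[, use])
  sf_ref <- DESeq2::sizeFactors(dds)
  sf_ref <- sf_ref / exp(mean(log(sf_ref)))
  expect_lt(max(abs(sf_mine - sf_ref) / sf_ref), 0.02)
})

test_that("contrast preconditions are enforced", {
  ds <- tiny_dataset(matrix(100L, 20, 6))
  expect_error(nb_wald_test(ds, "frequency", level = "none"),
               class = "flickerstress_config_error")
  expect_error(nb_wald_test(ds, "frequency", level = "10"),
               class = "flickerstress_config_error")  # no such samples
})
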