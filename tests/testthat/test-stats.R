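long_df <- function(groups) {
  tibble::tibble(value = unlist(groups),
                 group = rep(names(groups), lengths(groups)))
}

test_that("one-way ANOVA matches the hand variance decomposition", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  orc <- oracle_anova_f(groups)
  res <- one_way_anova(long_df(groups), value, group)
  expect_equal(res$statistic, orc$f, tolerance = 1e-12)
  expect_equal(res$df, c(orc$df1, orc$df2))
  expect_equal(res$p_value, pf(orc$f, orc$df1, orc$df2, lower.tail = FALSE))

  # two groups: F equals the squared pooled t statistic
  g2 <- list(a = c(1.2, 3.4, 2.2, 0.8), b = c(2.5, 4.1, 3.3))
  f2 <- one_way_anova(long_df(g2), value, group)
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(f2$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(f2$p_value, tt$p.value, tolerance = 1e-12)

  expect_error(
    suppressWarnings(one_way_anova(long_df(list(a = c(1, 1), b = c(1, 1))),
                                   value, group)),
    class = "flickerstress_degenerate_error"
  )
  expect_error(one_way_anova(long_df(list(a = c(1, 2))), value, group),
               class = "flickerstress_config_error")
})

test_that("two-way ANOVA matches the balanced textbook decomposition", {
  set.seed(15)
  d <- tidyr::expand_grid(a = factor(c("a1", "a2", "a3")),
                          b = factor(c("b1", "b2")), rep = 1:4)
  d$value <- rnorm(nrow(d)) + as.integer(d$a) + 2 * (d$b == "b2") +
    0.5 * (d$a == "a2" & d$b == "b2")
  orc <- oracle_two_way(d)
  res <- two_way_anova(d, value, a, b)
  expect_equal(res$statistic, orc$f_ab, tolerance = 1e-10)
  terms <- res$terms
  expect_equal(terms$f_statistic[terms$term == "a (factor 1)"], orc$f_a,
               tolerance = 1e-10)
  expect_equal(terms$f_statistic[terms$term == "b (factor 2)"], orc$f_b,
               tolerance = 1e-10)

  # duplicating the data changes F through the residual df, not the SS ratio
  d2 <- dplyr::bind_rows(d, d)
  res2 <- two_way_anova(d2, value, a, b)
  expect_false(isTRUE(all.equal(res2$statistic, res$statistic)))
  expect_equal(res2$df[2], 2 * nrow(d) - 6)

  # empty design cell errors with the cell named
  d3 <- dplyr::filter(d, !(a == "a1" & b == "b1"))
  expect_error(two_way_anova(d3, value, a, b), "a1 x b1")
})

test_that("Kruskal-Wallis matches the rank-formula oracle", {
  groups <- list(a = c(1, 2), b = c(3, 4))
  res <- kruskal_wallis(long_df(groups), value, group)
  expect_equal(res$statistic, oracle_kruskal_h(groups), tolerance = 1e-12)
  expect_equal(res$df, 1)

  # with ties
  gt <- list(a = c(1, 2, 2), b = c(2, 3, 4), c = c(4, 4, 5))
  rt <- kruskal_wallis(long_df(gt), value, group)
  expect_equal(rt$statistic, oracle_kruskal_h(gt), tolerance = 1e-12)

  # rank invariance under a constant shift
  shifted <- lapply(gt, function(x) x + 100)
  expect_equal(kruskal_wallis(long_df(shifted), value, group)$statistic,
               rt$statistic)

  expect_error(kruskal_wallis(long_df(list(a = c(2, 2), b = c(2, 2))),
                              value, group),
               class = "flickerstress_degenerate_error")
})

test_that("omnibus null rejection rates sit near the nominal level", {
  set.seed(16)
  reps <- 400
  rej <- replicate(reps, {
    d <- long_df(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
    c(one_way_anova(d, value, group)$p_value < 0.05,
      kruskal_wallis(d, value, group)$p_value < 0.05)
  })
  # 3 sigma around 0.05 at 400 replicates
  half <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej[1, ]) - 0.05), half)
  expect_lt(abs(mean(rej[2, ]) - 0.05), half)
})

test_that("post-hoc procedures implement their adjustment contracts", {
  set.seed(17)
  d <- long_df(list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2),
                    d = rnorm(8), e = rnorm(8)))
  bon <- posthoc_pairwise(d, value, group, "bonferroni_t")
  lsd <- posthoc_pairwise(d, value, group, "fisher_lsd")
  m <- nrow(bon)
  expect_equal(m, choose(5, 2))
  expect_equal(bon$p_adjusted, pmin(1, bon$p_value * m))
  expect_equal(lsd$p_adjusted, lsd$p_value)   # LSD is deliberately unadjusted
  expect_equal(bon$p_value, lsd$p_value)      # same pooled-MSE t tests

  # two groups: bonferroni_t equals the plain pooled t-test
  d2 <- long_df(list(a = rnorm(6), b = rnorm(6, 0.5)))
  b2 <- posthoc_pairwise(d2, value, group, "bonferroni_t")
  tt <- t.test(value ~ group, data = d2, var.equal = TRUE)
  expect_equal(b2$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(b2$p_adjusted, b2$p_value)

  dn <- posthoc_pairwise(d, value, group, "dunn")
  expect_true(all(dn$p_adjusted >= dn$p_value - 1e-15))
  # identical groups: Dunn adjusted p-values saturate at 1
  same <- long_df(list(a = c(1, 5, 3, 9, 7), b = c(5, 3, 9, 7, 1),
                       c = c(3, 9, 7, 1, 5)))
  dn_same <- posthoc_pairwise(same, value, group, "dunn")
  expect_true(all(dn_same$p_adjusted == 1))

  expect_error(posthoc_pairwise(d, value, group, "tukey"))
})

test_that("Dunn z-statistics follow the tie-corrected rank formula", {
  d <- long_df(list(a = c(1, 2, 2, 5), b = c(2, 6, 7, 8), c = c(3, 3, 9, 10)))
  dn <- posthoc_pairwise(d, value, group, "dunn")
  r <- rank(d$value)
  N <- length(r)
  ties <- table(r)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, d$group, mean)
  z_ab <- (mr[["a"]] - mr[["b"]]) / sqrt(s2 * (1 / 4 + 1 / 4))
  row <- dn[dn$group1 == "a" & dn$group2 == "b", ]
  expect_equal(row$statistic, z_ab, tolerance = 1e-12)
  expect_equal(row$p_value, 2 * pnorm(-abs(z_ab)), tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand step-up on an uneven vector
  p <- c(0.003, 0.04, 0.7, 0.012)
  expect_equal(bh_fdr(p), c(0.012, 0.04 * 4 / 3, 0.7, 0.024))
  expect_error(bh_fdr(c(0.1, 1.2)), class = "flickerstress_config_error")
})
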