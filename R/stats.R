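new_test_result <- function(test, statistic, df, p_value, terms = NULL,
                            posthoc = NULL) {
  structure(
    list(test = test, statistic = statistic, df = df, p_value = p_value,
         terms = terms, posthoc = posthoc),
    class = "stress_test_result"
  )
}

#' @export
print.stress_test_result <- function(x, ...) {
  cat("<", x$test, ">  statistic = ", format(x$statistic, digits = 5),
      ", df = (", paste(x$df, collapse = ", "), "), p = ",
      format.pval(x$p_value, digits = 4), "\n", sep = "")
  if (!is.null(x$terms)) print(x$terms)
  if (!is.null(x$posthoc)) {
    cat("post hoc (", attr(x$posthoc, "method") %||% "", "):\n", sep = "")
    print(x$posthoc)
  }
  invisible(x)
}

prep_groups <- function(data, value, group) {
  df <- as_tibble(data)
  v <- rlang::eval_tidy(rlang::enquo(value), df)
  g <- rlang::eval_tidy(rlang::enquo(group), df)
  if (is.null(v) || is.null(g)) stop_config("`value`/`group` columns not found")
  keep <- is.finite(v) & !is.na(g)
  tibble(value = v[keep], group = factor(g[keep]))
}

#' One-way ANOVA
#'
#' Classical fixed-effects F test: F = MS_between / MS_within with
#' (k - 1, N - k) degrees of freedom.
#'
#' @param data Long-format data frame.
#' @param value,group Column names (unquoted) of the response and the group.
#' @return A `stress_test_result` (statistic F, df, p).
#' @export
one_way_anova <- function(data, value, group) {
  d <- prep_groups(data, {{ value }}, {{ group }})
  k <- nlevels(d$group)
  if (k < 2) stop_config("need >= 2 groups")
  ns <- table(d$group)
  if (any(ns < 2)) stop_config("need n >= 2 per group")
  fit <- stats::lm(value ~ group, data = d)
  an <- stats::anova(fit)
  if (an["Residuals", "Sum Sq"] <= 1e-300) {
    stop_degenerate("zero within-group variance in every group")
  }
  new_test_result("one_way_anova",
                  statistic = an["group", "F value"],
                  df = c(an["group", "Df"], an["Residuals", "Df"]),
                  p_value = an["group", "Pr(>F)"])
}

#' Two-way ANOVA with interaction (Type II sums of squares)
#'
#' Fits `value ~ a * b` and reports Type II sums of squares (identical to
#' Type I/III on balanced designs); the interaction F and p are first-class
#' results, matching the convention of testing spine class x experimental
#' group (or stress x flicker) interactions.
#'
#' @param data Long-format data frame.
#' @param value,a,b Column names (unquoted): response and the two factors.
#' @return A `stress_test_result`; `statistic`/`p_value` are the
#'   interaction's, and `$terms` holds the full Type II table as a tibble.
#' @export
two_way_anova <- function(data, value, a, b) {
  df <- as_tibble(data)
  v <- rlang::eval_tidy(rlang::enquo(value), df)
  fa <- factor(rlang::eval_tidy(rlang::enquo(a), df))
  fb <- factor(rlang::eval_tidy(rlang::enquo(b), df))
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    stop_config("each factor needs >= 2 levels")
  }
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop_config(paste0("empty design cell: ", rownames(cells)[idx[1]], " x ",
                       colnames(cells)[idx[2]]))
  }
  d <- tibble(value = v, a = fa, b = fb)
  fit <- stats::lm(value ~ a * b, data = d)
  tab <- if (requireNamespace("car", quietly = TRUE)) {
    as.data.frame(car::Anova(fit, type = 2))
  } else {
    type2_anova(d)
  }
  terms <- tibble(
    term = sub("^a$", "a (factor 1)",
               sub("^b$", "b (factor 2)", rownames(tab))),
    sum_sq = tab[["Sum Sq"]], df = tab[["Df"]],
    f_statistic = tab[["F value"]], p_value = tab[["Pr(>F)"]]
  )
  inter <- match("a:b", rownames(tab))
  new_test_result("two_way_anova",
                  statistic = tab[inter, "F value"],
                  df = c(tab[inter, "Df"], tab["Residuals", "Df"]),
                  p_value = tab[inter, "Pr(>F)"],
                  terms = terms)
}

# Type II decomposition by model comparison (fallback when car is absent)
type2_anova <- function(d) {
  full <- stats::lm(value ~ a * b, data = d)
  add <- stats::lm(value ~ a + b, data = d)
  no_a <- stats::lm(value ~ b, data = d)
  no_b <- stats::lm(value ~ a, data = d)
  rss <- function(m) sum(stats::residuals(m)^2)
  df_res <- stats::df.residual(full)
  ms_res <- rss(full) / df_res
  ss <- c(a = rss(no_a) - rss(add), b = rss(no_b) - rss(add),
          `a:b` = rss(add) - rss(full), Residuals = rss(full))
  dfs <- c(nlevels(d$a) - 1, nlevels(d$b) - 1,
           (nlevels(d$a) - 1) * (nlevels(d$b) - 1), df_res)
  fv <- c((ss[1:3] / dfs[1:3]) / ms_res, NA)
  pv <- c(pf(fv[1:3], dfs[1:3], df_res, lower.tail = FALSE), NA)
  out <- data.frame(`Sum Sq` = ss, Df = dfs, `F value` = fv, `Pr(>F)` = pv,
                    check.names = FALSE)
  rownames(out) <- c("a", "b", "a:b", "Residuals")
  out
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction, df = k - 1, chi-square p-value — the
#' omnibus test used for non-normally distributed outcomes.
#'
#' @inheritParams one_way_anova
#' @return A `stress_test_result` (statistic H).
#' @export
kruskal_wallis <- function(data, value, group) {
  d <- prep_groups(data, {{ value }}, {{ group }})
  if (nlevels(d$group) < 2) stop_config("need >= 2 groups")
  if (nrow(d) < 3) stop_config("need total N >= 3")
  if (length(unique(d$value)) == 1) {
    stop_degenerate("all observations tied: H undefined")
  }
  kt <- stats::kruskal.test(d$value, d$group)
  new_test_result("kruskal_wallis",
                  statistic = unname(kt$statistic),
                  df = unname(kt$parameter),
                  p_value = kt$p.value)
}

#' Pairwise post-hoc comparisons
#'
#' The three procedures used after the omnibus tests: `bonferroni_t`
#' (pooled-variance t per pair, p x m capped at 1), `dunn` (rank-based z with
#' tie correction after a Kruskal-Wallis, Bonferroni-adjusted by default) and
#' `fisher_lsd` (pooled-MSE t tests, deliberately unadjusted).
#'
#' @inheritParams one_way_anova
#' @param method One of `"bonferroni_t"`, `"dunn"`, `"fisher_lsd"`.
#' @param dunn_adjust Adjustment for Dunn's p (default `"bonferroni"`; any
#'   [stats::p.adjust()] method).
#' @return Tibble: `group1`, `group2`, `estimate` (mean or mean-rank
#'   difference), `statistic`, `p_value`, `p_adjusted`, with the method in
#'   the `"method"` attribute.
#' @export
posthoc_pairwise <- function(data, value, group,
                             method = c("bonferroni_t", "dunn", "fisher_lsd"),
                             dunn_adjust = "bonferroni") {
  method <- match.arg(method)
  d <- prep_groups(data, {{ value }}, {{ group }})
  lev <- levels(d$group)
  if (length(lev) < 2) stop_config("need >= 2 groups")
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)

  if (method %in% c("bonferroni_t", "fisher_lsd")) {
    ns <- table(d$group)
    means <- tapply(d$value, d$group, mean)
    ss <- tapply(d$value, d$group, function(x) sum((x - mean(x))^2))
    df_res <- nrow(d) - length(lev)
    mse <- sum(ss) / df_res
    if (mse <= 0) stop_degenerate("zero pooled within-group variance")
    rows <- lapply(seq_len(m), function(i) {
      g1 <- pairs[1, i]; g2 <- pairs[2, i]
      est <- means[[g1]] - means[[g2]]
      se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
      tstat <- est / se
      p <- 2 * pt(-abs(tstat), df_res)
      tibble(group1 = g1, group2 = g2, estimate = est, statistic = tstat,
             p_value = p)
    })
    out <- bind_rows(rows)
    out$p_adjusted <- if (method == "bonferroni_t") {
      pmin(1, out$p_value * m)
    } else {
      out$p_value
    }
  } else {
    r <- rank(d$value)
    N <- nrow(d)
    ns <- table(d$group)
    mean_ranks <- tapply(r, d$group, mean)
    tie_tab <- table(r)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
    s2 <- N * (N + 1) / 12 - tie_corr
    rows <- lapply(seq_len(m), function(i) {
      g1 <- pairs[1, i]; g2 <- pairs[2, i]
      est <- mean_ranks[[g1]] - mean_ranks[[g2]]
      se <- sqrt(s2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
      zstat <- est / se
      tibble(group1 = g1, group2 = g2, estimate = est, statistic = zstat,
             p_value = 2 * pnorm(-abs(zstat)))
    })
    out <- bind_rows(rows)
    out$p_adjusted <- p.adjust(out$p_value, method = dunn_adjust)
  }
  attr(out, "method") <- method
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment; validates the input range (a convenience wrapper kept
#' on the module surface because both the DE and enrichment stages report it).
#'
#' @param pvalues Numeric vector in [0, 1] (NA allowed).
#' @return Adjusted p-values, same length/order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues)) stop_config("`pvalues` must be numeric")
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop_config("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
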