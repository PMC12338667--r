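#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a hypothesis-test result
#'
#' @param x A `stress_test_result` (from [one_way_anova()],
#'   [two_way_anova()] or [kruskal_wallis()]).
#' @param ... Unused.
#' @return For a two-way ANOVA, the per-term Type II table; otherwise a
#'   one-row tibble with `term`, `statistic`, `df1`, `df2`, `p_value`.
#' @method tidy stress_test_result
#' @export
tidy.stress_test_result <- function(x, ...) {
  if (!is.null(x$terms)) return(x$terms)
  tibble(term = x$test, statistic = x$statistic,
         df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p_value = x$p_value)
}

#' One-row summary of a hypothesis-test result
#'
#' @inheritParams tidy.stress_test_result
#' @return One-row tibble: `test`, `statistic`, `df1`, `df2`, `p_value`.
#' @method glance stress_test_result
#' @export
glance.stress_test_result <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic,
         df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p_value = x$p_value)
}

#' One-row summary of a differential-expression result table
#'
#' @param x A [nb_wald_test()] result.
#' @param ... Unused.
#' @return One-row tibble: `contrast`, `n_genes`, `n_deg`, `n_up`, `n_down`,
#'   `percent_up`.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  deg <- x[x$is_deg, ]
  tibble(
    contrast = attr(x, "contrast") %||% NA_character_,
    n_genes = nrow(x), n_deg = nrow(deg),
    n_up = sum(deg$log2fc > 0), n_down = sum(deg$log2fc < 0),
    percent_up = if (nrow(deg)) 100 * mean(deg$log2fc > 0) else NA_real_
  )
}
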