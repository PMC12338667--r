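#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select group_by summarise ungroup left_join
#'   arrange bind_rows bind_cols across n
#' @importFrom stats rnorm rnbinom rpois runif sd var median p.adjust pnorm pf
#'   pchisq pt phyper setNames aggregate
NULL

stop_config <- function(msg) {
  abort(msg, class = "flickerstress_config_error")
}

stop_degenerate <- function(msg) {
  abort(msg, class = "flickerstress_degenerate_error")
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Group label for a (stress, frequency) condition
#'
#' Conditions are labelled `control`, `stress`, `stress_10hz`, `stress_20hz`,
#' `stress_40hz` (and `flicker_<f>hz` for unstressed stimulated groups).
#'
#' @param stress Logical vector.
#' @param frequency_hz Vector with values in `"none"`, `"10"`, `"20"`, `"40"`.
#' @return Character vector of condition labels.
#' @export
condition_label <- function(stress, frequency_hz) {
  frequency_hz <- as.character(frequency_hz)
  base <- ifelse(stress, "stress", "control")
  suffix <- ifelse(frequency_hz == "none", "", paste0("_", frequency_hz, "hz"))
  out <- paste0(base, suffix)
  out[!stress & frequency_hz != "none"] <-
    paste0("flicker_", frequency_hz[!stress & frequency_hz != "none"], "hz")
  out
}
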