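rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a star/tree skeleton in SWC form
#'
#' Builds a soma root (structure type 1) at the origin with
#' `morph_params$n_processes` processes, each a chain of
#' `morph_params$nodes_per_process` nodes of total path length
#' `morph_params$process_length` micrometres. Process directions are random
#' unit vectors; `kink_sd > 0` jitters the direction at every internode
#' (random kinks), `kink_sd = 0` gives straight rays.
#'
#' @param config A [sim_config()].
#' @param cell Integer used to decorrelate multiple cells from one config.
#' @return A skeleton tibble (see [read_swc()]).
#' @export
simulate_skeleton <- function(config, cell = 1L) {
  stopifnot(inherits(config, "sim_config"))
  mp <- config$morph_params
  with_seed(config$seed + 2L + 1000L * (cell - 1L), {
    rows <- list(tibble(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                        radius = mp$soma_radius, parent = -1L))
    nid <- 1L
    step_len <- mp$process_length / mp$nodes_per_process
    for (p in seq_len(mp$n_processes)) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pos <- c(0, 0, 0)
      parent <- 1L
      for (k in seq_len(mp$nodes_per_process)) {
        if (mp$kink_sd > 0 && k > 1) {
          dir <- dir + rnorm(3, 0, mp$kink_sd)
          dir <- dir / sqrt(sum(dir^2))
        }
        pos <- pos + dir * step_len
        nid <- nid + 1L
        rows[[length(rows) + 1L]] <- tibble(
          id = nid, type = 3L, x = pos[1], y = pos[2], z = pos[3],
          radius = 0.5, parent = parent
        )
        parent <- nid
      }
    }
    validate_skeleton(bind_rows(rows))
  })
}

spine_class_samplers <- list(
  mushroom = function(n) {
    head <- rtnorm(n, 0.85, 0.08, 0.65, 1.20)
    ratio <- rtnorm(n, 2.00, 0.25, 1.30, 3.00)
    tibble(length_um = rtnorm(n, 1.0, 0.20, 0.5, 1.8),
           head_diameter_um = head, neck_width_um = head / ratio)
  },
  filopodia = function(n) {
    neck <- rtnorm(n, 0.20, 0.04, 0.10, 0.35)
    tibble(length_um = rtnorm(n, 2.8, 0.40, 2.05, 4.0),
           head_diameter_um = neck * rtnorm(n, 0.95, 0.05, 0.80, 1.08),
           neck_width_um = neck)
  },
  stubby = function(n) {
    neck <- rtnorm(n, 0.45, 0.08, 0.30, 0.70)
    tibble(length_um = neck * rtnorm(n, 0.70, 0.10, 0.40, 0.95),
           head_diameter_um = neck * rtnorm(n, 1.00, 0.04, 0.90, 1.08),
           neck_width_um = neck)
  },
  long_thin = function(n) {
    tibble(length_um = rtnorm(n, 1.4, 0.25, 0.80, 1.95),
           head_diameter_um = rtnorm(n, 0.40, 0.08, 0.20, 0.58),
           neck_width_um = rtnorm(n, 0.15, 0.03, 0.08, 0.30))
  }
)

#' Generate a synthetic spine population
#'
#' Draws `n_spines` spines with class labels multinomial on
#' `config$spine_mix`, then (length, head diameter, neck width) triples from
#' class-conditional truncated normals centred inside the default
#' classifier's decision regions, so the planted class is recoverable.
#'
#' @param config A [sim_config()].
#' @param cell_id,segment_id Identifier columns for the output table.
#' @return Tibble: `cell_id`, `segment_id`, `spine_id`, `length_um`,
#'   `head_diameter_um`, `neck_width_um`, `true_class`.
#' @export
simulate_spines <- function(config, cell_id = "cell_01",
                            segment_id = "seg_01") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_spines
  empty <- tibble(cell_id = character(), segment_id = character(),
                  spine_id = character(), length_um = numeric(),
                  head_diameter_um = numeric(), neck_width_um = numeric(),
                  true_class = character())
  if (n == 0) return(empty)
  with_seed(config$seed + 3L, {
    cls <- sample(names(config$spine_mix), n, replace = TRUE,
                  prob = config$spine_mix)
    out <- bind_rows(lapply(names(spine_class_samplers), function(k) {
      nk <- sum(cls == k)
      if (nk == 0) return(NULL)
      g <- spine_class_samplers[[k]](nk)
      g$true_class <- k
      g
    }))
    out <- out[order(stats::runif(nrow(out))), ]
    bind_cols(
      tibble(cell_id = cell_id, segment_id = segment_id,
             spine_id = sprintf("spine_%04d", seq_len(n))),
      out
    )
  })
}
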