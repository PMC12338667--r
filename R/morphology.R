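#' Sholl crossings at given radii
#'
#' Counts, for each radius, how many times the skeleton's edges cross the
#' sphere of that radius centred on the soma (the root node). Each
#' parent-child segment is intersected with the sphere exactly, by solving
#' the quadratic |P0 + t (P1 - P0)|^2 = r^2 for t: roots in (0, 1] count, so
#' a node lying exactly on the sphere is counted once (on its incoming edge),
#' and a tangent touch (double root) counts once.
#'
#' @param skeleton Skeleton tibble (see [read_swc()]).
#' @param radii Strictly increasing positive radii in micrometres. Default:
#'   5 um steps to the maximal radial extent, always including 10 and 20 um
#'   (the two distances conventionally reported for microglial branching).
#' @return Tibble of class `sholl_profile`: `radius_um`, `crossings`.
#' @export
sholl_crossings <- function(skeleton, radii = NULL) {
  skel <- validate_skeleton(skeleton)
  root <- skel[skel$parent == -1, ]
  origin <- c(root$x, root$y, root$z)
  edges <- skeleton_edges(skel)

  if (is.null(radii)) {
    rmax <- if (nrow(edges)) {
      max(sqrt((skel$x - origin[1])^2 + (skel$y - origin[2])^2 +
                 (skel$z - origin[3])^2))
    } else 20
    radii <- sort(unique(c(seq(5, max(rmax, 20), by = 5), 10, 20)))
  }
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    stop_config("`radii` must be strictly increasing and > 0")
  }
  if (nrow(edges) == 0) {
    out <- tibble(radius_um = radii, crossings = 0L)
    class(out) <- c("sholl_profile", class(out))
    return(out)
  }

  p0 <- cbind(edges$x0 - origin[1], edges$y0 - origin[2], edges$z0 - origin[3])
  v <- cbind(edges$x1 - edges$x0, edges$y1 - edges$y0, edges$z1 - edges$z0)
  a <- rowSums(v^2)
  b <- 2 * rowSums(p0 * v)
  c0 <- rowSums(p0^2)

  crossings <- vapply(radii, function(r) {
    cc <- c0 - r^2
    disc <- b^2 - 4 * a * cc
    n <- integer(length(a))
    # degenerate zero-length edges: on-sphere counts once via parent node rule
    zl <- a == 0
    pos <- !zl & disc > 0
    if (any(pos)) {
      sq <- sqrt(disc[pos])
      t1 <- (-b[pos] - sq) / (2 * a[pos])
      t2 <- (-b[pos] + sq) / (2 * a[pos])
      n[pos] <- (t1 > 0 & t1 <= 1) + (t2 > 0 & t2 <= 1)
    }
    tang <- !zl & disc == 0
    if (any(tang)) {
      t0 <- -b[tang] / (2 * a[tang])
      n[tang] <- as.integer(t0 > 0 & t0 <= 1)
    }
    sum(n)
  }, integer(1))

  out <- tibble(radius_um = radii, crossings = crossings)
  class(out) <- c("sholl_profile", class(out))
  out
}

#' Total arborization length
#'
#' Sum of Euclidean parent-child distances over all non-root edges, the
#' skeleton's total branching length in micrometres.
#'
#' @param skeleton Skeleton tibble.
#' @return Length in micrometres (0 for a soma-only skeleton).
#' @export
arborization_length <- function(skeleton) {
  edges <- skeleton_edges(skeleton)
  if (nrow(edges) == 0) return(0)
  sum(sqrt((edges$x1 - edges$x0)^2 + (edges$y1 - edges$y0)^2 +
             (edges$z1 - edges$z0)^2))
}

#' Convex hull volume of a skeleton
#'
#' Hull of all node coordinates (no resampling), a proxy for the cell's
#' volumetric territory.
#'
#' @param skeleton Skeleton tibble.
#' @return See [convex_hull_volume()].
#' @export
skeleton_hull <- function(skeleton) {
  skel <- validate_skeleton(skeleton)
  convex_hull_volume(as.matrix(skel[, c("x", "y", "z")]))
}

#' Default spine classification rule table
#'
#' The four-class scheme (long thin, filopodia, stubby, mushroom) keyed on
#' spine length, head diameter and neck width. Thresholds follow common
#' literature conventions and are fully configurable; precedence order is
#' mushroom, filopodia, stubby, long thin.
#'
#' @return Named list of thresholds: `mushroom_head_um` (0.6),
#'   `head_neck_ratio` (1.1), `filopodia_length_um` (2.0),
#'   `stubby_length_neck_ratio` (1.0).
#' @export
default_spine_rules <- function() {
  list(mushroom_head_um = 0.6, head_neck_ratio = 1.1,
       filopodia_length_um = 2.0, stubby_length_neck_ratio = 1.0)
}

#' Classify dendritic spines from geometry triples
#'
#' Precedence-ordered rules on (length, head diameter, neck width), all in
#' micrometres: (1) mushroom if head >= `mushroom_head_um` and head/neck >=
#' `head_neck_ratio`; (2) filopodia if length >= `filopodia_length_um` and
#' head/neck < `head_neck_ratio`; (3) stubby if length/neck <=
#' `stubby_length_neck_ratio`; (4) long thin otherwise. Mushroom and stubby
#' are the mature/stable classes, long thin and filopodia the
#' immature/dynamic ones.
#'
#' @param spines Data frame with columns `length_um`, `head_diameter_um`,
#'   `neck_width_um` (all > 0).
#' @param rules Threshold list (see [default_spine_rules()]).
#' @return The input tibble with a `class` column (factor over the four
#'   classes) and a `mature` logical.
#' @export
classify_spines <- function(spines, rules = default_spine_rules()) {
  sp <- as_tibble(spines)
  need <- c("length_um", "head_diameter_um", "neck_width_um")
  if (!all(need %in% names(sp))) {
    stop_config(paste0("spine table needs columns: ",
                       paste(need, collapse = ", ")))
  }
  if (nrow(sp)) {
    m <- as.matrix(sp[need])
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop_config("spine measures must be finite and > 0")
    }
  }
  ratio <- sp$head_diameter_um / sp$neck_width_um
  cls <- rep("long_thin", nrow(sp))
  stub <- sp$length_um / sp$neck_width_um <= rules$stubby_length_neck_ratio
  cls[stub] <- "stubby"
  filo <- sp$length_um >= rules$filopodia_length_um &
    ratio < rules$head_neck_ratio
  cls[filo] <- "filopodia"
  mush <- sp$head_diameter_um >= rules$mushroom_head_um &
    ratio >= rules$head_neck_ratio
  cls[mush] <- "mushroom"
  sp$class <- factor(cls, levels = c("long_thin", "filopodia", "stubby",
                                     "mushroom"))
  sp$mature <- sp$class %in% c("stubby", "mushroom")
  sp
}

#' Spine class counts and mature/immature ratio
#'
#' @param classified Output of [classify_spines()].
#' @return One-row tibble: per-class counts, `n`, `prop_mature`,
#'   `mature_immature_ratio`.
#' @export
spine_class_summary <- function(classified) {
  counts <- table(classified$class)
  n_mature <- sum(counts[c("stubby", "mushroom")])
  n_imm <- sum(counts[c("long_thin", "filopodia")])
  tibble(
    n_long_thin = as.integer(counts[["long_thin"]]),
    n_filopodia = as.integer(counts[["filopodia"]]),
    n_stubby = as.integer(counts[["stubby"]]),
    n_mushroom = as.integer(counts[["mushroom"]]),
    n = nrow(classified),
    prop_mature = if (nrow(classified)) n_mature / nrow(classified) else NA_real_,
    mature_immature_ratio = if (n_imm > 0) n_mature / n_imm else Inf
  )
}

#' Spine density
#'
#' Number of spines per micron of dendritic segment.
#'
#' @param spine_count Non-negative integer.
#' @param segment_length_um Segment length in micrometres, > 0.
#' @return Spines per micrometre.
#' @export
spine_density <- function(spine_count, segment_length_um) {
  if (!is_count(spine_count)) stop_config("`spine_count` must be an integer >= 0")
  if (!is_number(segment_length_um) || segment_length_um <= 0) {
    stop_config("`segment_length_um` must be > 0")
  }
  spine_count / segment_length_um
}
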