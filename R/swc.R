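#' Read an SWC skeleton
#'
#' Standard 7-column SWC (id, structure type, x, y, z, radius, parent id;
#' `#` comments allowed), coordinates in micrometres. Validates that there is
#' exactly one root (parent -1, soma type 1 expected) and that parent links
#' form a tree.
#'
#' @param path SWC file path.
#' @return Tibble of class `skeleton`: `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`.
#' @export
read_swc <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  validate_skeleton(as_tibble(raw))
}

#' Write an SWC skeleton
#'
#' @param skeleton A skeleton tibble (see [read_swc()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(skeleton, path) {
  skeleton <- validate_skeleton(skeleton)
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   skeleton$id, skeleton$type, skeleton$x, skeleton$y,
                   skeleton$z, skeleton$radius, skeleton$parent)
  writeLines(c("# SWC skeleton (um)", lines), path)
  invisible(path)
}

validate_skeleton <- function(skeleton) {
  skel <- as_tibble(skeleton)
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(skel))) {
    stop_config(paste0("skeleton needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(skel$id)) stop_config("duplicate SWC node ids")
  if (any(!is.finite(as.matrix(skel[c("x", "y", "z")])))) {
    stop_config("SWC coordinates must be finite")
  }
  roots <- skel$id[skel$parent == -1]
  if (length(roots) != 1) {
    stop_config(paste0("skeleton must have exactly one root, found ",
                       length(roots)))
  }
  nonroot <- skel$parent != -1
  if (!all(skel$parent[nonroot] %in% skel$id)) {
    bad <- skel$id[nonroot][!skel$parent[nonroot] %in% skel$id]
    stop_config(paste0("node(s) with missing parent: ",
                       paste(bad, collapse = ", ")))
  }
  # cycle check: every node must reach the root
  parent_of <- setNames(skel$parent, skel$id)
  for (nd in skel$id) {
    seen <- 0L
    cur <- nd
    while (parent_of[[as.character(cur)]] != -1) {
      cur <- parent_of[[as.character(cur)]]
      seen <- seen + 1L
      if (seen > nrow(skel)) stop_config("parent links contain a cycle")
    }
  }
  class(skel) <- unique(c("skeleton", class(skel)))
  skel
}

skeleton_edges <- function(skeleton) {
  skel <- validate_skeleton(skeleton)
  child <- skel[skel$parent != -1, ]
  if (nrow(child) == 0) {
    return(tibble(x0 = numeric(), y0 = numeric(), z0 = numeric(),
                  x1 = numeric(), y1 = numeric(), z1 = numeric()))
  }
  pidx <- match(child$parent, skel$id)
  tibble(x0 = skel$x[pidx], y0 = skel$y[pidx], z0 = skel$z[pidx],
         x1 = child$x, y1 = child$y, z1 = child$z)
}
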