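# Incremental 3D convex hull. Points are an n x 3 matrix; returns a list of
# triangular faces (vertex index triples, outward-oriented) or NULL when the
# point set is degenerate (rank < 3 within tolerance).
hull3d_faces <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(NULL)
  scale <- max(abs(pts - matrix(colMeans(pts), n, 3, byrow = TRUE)))
  if (scale == 0) return(NULL)
  eps <- 1e-10 * scale

  # initial simplex: two extreme points, then farthest from their line, then
  # farthest from that plane
  i1 <- which.max(pts[, 1])
  i2 <- which.min(pts[, 1])
  if (max(pts[, 1]) - min(pts[, 1]) < eps) {
    rng <- apply(pts, 2, function(v) diff(range(v)))
    ax <- which.max(rng)
    i1 <- which.max(pts[, ax]); i2 <- which.min(pts[, ax])
  }
  if (i1 == i2) return(NULL)
  v12 <- pts[i2, ] - pts[i1, ]
  d_line <- vapply(seq_len(n), function(i) {
    w <- pts[i, ] - pts[i1, ]
    cr <- c(v12[2] * w[3] - v12[3] * w[2],
            v12[3] * w[1] - v12[1] * w[3],
            v12[1] * w[2] - v12[2] * w[1])
    sqrt(sum(cr^2))
  }, numeric(1))
  i3 <- which.max(d_line)
  if (d_line[i3] < eps * sqrt(sum(v12^2))) return(NULL)
  nrm <- tri_normal(pts[i1, ], pts[i2, ], pts[i3, ])
  d_plane <- as.numeric((pts - matrix(pts[i1, ], n, 3, byrow = TRUE)) %*% nrm)
  i4 <- which.max(abs(d_plane))
  if (abs(d_plane[i4]) < eps) return(NULL)

  simplex <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[simplex, ])
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(faces, orient_out, pts = pts, interior = interior)

  for (p in setdiff(seq_len(n), simplex)) {
    dists <- vapply(faces, function(f) {
      sum(tri_normal(pts[f[1], ], pts[f[2], ], pts[f[3], ]) *
            (pts[p, ] - pts[f[1], ]))
    }, numeric(1))
    visible <- dists > eps
    if (!any(visible)) next
    vis_faces <- faces[visible]
    faces <- faces[!visible]
    # horizon = edges of the visible region that appear exactly once
    edges <- do.call(rbind, lapply(vis_faces, function(f) {
      rbind(sort(c(f[1], f[2])), sort(c(f[2], f[3])), sort(c(f[1], f[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    new_faces <- lapply(seq_len(nrow(horizon)), function(e) {
      orient_out(c(horizon[e, 1], horizon[e, 2], p), pts, interior)
    })
    faces <- c(faces, new_faces)
  }
  faces
}

tri_normal <- function(a, b, c) {
  u <- b - a; v <- c - a
  nrm <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  len <- sqrt(sum(nrm^2))
  if (len == 0) return(c(0, 0, 0))
  nrm / len
}

orient_out <- function(f, pts, interior) {
  nrm <- tri_normal(pts[f[1], ], pts[f[2], ], pts[f[3], ])
  if (sum(nrm * (interior - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
}

#' 3D convex hull volume
#'
#' Computes the volume of the convex hull of a 3D point set (incremental hull
#' construction; volume by signed tetrahedra against an interior point).
#' Collinear/coplanar point sets are not an error: they return volume 0 with
#' `degenerate = TRUE`.
#'
#' @param points n x 3 numeric matrix (or data frame with columns x, y, z) of
#'   coordinates in micrometres; n >= 1.
#' @return One-row tibble of class `hull_result`: `volume_um3`, `n_points`,
#'   `n_hull_vertices`, `degenerate`, with a `hull_vertices` list-column of
#'   point indices on the hull.
#' @export
convex_hull_volume <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 1 || anyNA(points) || any(!is.finite(points))) {
    stop_config("`points` must be a nonempty n x 3 matrix of finite coordinates")
  }
  faces <- hull3d_faces(points)
  if (is.null(faces)) {
    out <- tibble(volume_um3 = 0, n_points = nrow(points),
                  n_hull_vertices = NA_integer_, degenerate = TRUE,
                  hull_vertices = list(integer()))
    class(out) <- c("hull_result", class(out))
    return(out)
  }
  verts <- sort(unique(unlist(faces)))
  interior <- colMeans(points[verts, , drop = FALSE])
  vol <- sum(vapply(faces, function(f) {
    a <- points[f[1], ] - interior
    b <- points[f[2], ] - interior
    c_ <- points[f[3], ] - interior
    (a[1] * (b[2] * c_[3] - b[3] * c_[2]) -
       a[2] * (b[1] * c_[3] - b[3] * c_[1]) +
       a[3] * (b[1] * c_[2] - b[2] * c_[1])) / 6
  }, numeric(1)))
  out <- tibble(volume_um3 = abs(vol), n_points = nrow(points),
                n_hull_vertices = length(verts), degenerate = FALSE,
                hull_vertices = list(verts))
  class(out) <- c("hull_result", class(out))
  out
}
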