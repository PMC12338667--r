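# Independent oracles used by unit and acceptance tests. Each is a direct,
# brute-force computation, kept deliberately separate from the package's
# algorithms.

# Sholl crossings by dense sampling: each edge is sampled at n_samples points
# and strict sign changes of (distance - r) are counted.
oracle_sholl <- function(skeleton, radii, n_samples = 1e4) {
  root <- skeleton[skeleton$parent == -1, ]
  origin <- c(root$x, root$y, root$z)
  child <- skeleton[skeleton$parent != -1, ]
  tt <- seq(0, 1, length.out = n_samples + 1)
  counts <- setNames(integer(length(radii)), radii)
  if (nrow(child) == 0) return(unname(counts))
  pidx <- match(child$parent, skeleton$id)
  for (e in seq_len(nrow(child))) {
    p0 <- c(skeleton$x[pidx[e]], skeleton$y[pidx[e]], skeleton$z[pidx[e]]) - origin
    p1 <- c(child$x[e], child$y[e], child$z[e]) - origin
    d <- sqrt((p0[1] + tt * (p1[1] - p0[1]))^2 +
                (p0[2] + tt * (p1[2] - p0[2]))^2 +
                (p0[3] + tt * (p1[3] - p0[3]))^2)
    for (i in seq_along(radii)) {
      s <- d - radii[i]
      counts[i] <- counts[i] + sum(s[-1] * s[-length(s)] < 0)
    }
  }
  unname(counts)
}

# Convex-hull volume by exhaustive facet enumeration: a point triple is a
# facet iff every point lies on one side of its plane; the volume is the fan
# of absolute tetrahedra from the point centroid over the facets. Assumes
# points in general position (no 4 coplanar points on a face).
oracle_hull_volume <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  eps <- 1e-9 * max(abs(sweep(pts, 2, ctr)))
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c_ <- pts[k, ]
    nrm <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
             (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
             (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    if (sum(nrm^2) == 0) next
    d <- as.numeric(sweep(pts, 2, a) %*% nrm)
    if (all(d <= eps) || all(d >= -eps)) {
      u <- a - ctr; v <- b - ctr; w <- c_ - ctr
      vol <- vol + abs(u[1] * (v[2] * w[3] - v[3] * w[2]) -
                         u[2] * (v[1] * w[3] - v[3] * w[1]) +
                         u[3] * (v[1] * w[2] - v[2] * w[1])) / 6
    }
  }
  vol
}

# Upper-tail hypergeometric probability by explicit summation.
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  }, numeric(1)))
}

# One-way ANOVA F by direct variance decomposition.
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups)
  N <- length(all_v)
  list(f = (ssb / (k - 1)) / (ssw / (N - k)), df1 = k - 1, df2 = N - k)
}

# Kruskal-Wallis H by the rank formula with tie correction.
oracle_kruskal_h <- function(groups) {
  all_v <- unlist(groups)
  r <- rank(all_v)
  N <- length(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(g) {
      length(groups[[g]]) * (mean(r[idx == g]) - (N + 1) / 2)^2
    }, numeric(1)))
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Balanced two-way ANOVA by the textbook cell-mean decomposition.
oracle_two_way <- function(d) {
  stopifnot(length(unique(table(d$a, d$b))) == 1)
  r <- unique(table(d$a, d$b))
  grand <- mean(d$value)
  am <- tapply(d$value, d$a, mean)
  bm <- tapply(d$value, d$b, mean)
  cm <- tapply(d$value, list(d$a, d$b), mean)
  na <- nlevels(d$a); nb <- nlevels(d$b)
  ssa <- nb * r * sum((am - grand)^2)
  ssb <- na * r * sum((bm - grand)^2)
  ssab <- r * sum((sweep(sweep(cm, 1, am), 2, bm) + grand)^2)
  sse <- sum((d$value - cm[cbind(as.integer(d$a), as.integer(d$b))])^2)
  dfe <- nrow(d) - na * nb
  list(
    f_a = (ssa / (na - 1)) / (sse / dfe),
    f_b = (ssb / (nb - 1)) / (sse / dfe),
    f_ab = (ssab / ((na - 1) * (nb - 1))) / (sse / dfe),
    ss = c(a = ssa, b = ssb, ab = ssab, e = sse)
  )
}

# Random general-position tree skeleton for geometry property tests.
random_tree <- function(n_nodes, scale = 12) {
  parent <- c(-1L, vapply(2:n_nodes, function(i) sample.int(i - 1L, 1),
                          integer(1)))
  tibble::tibble(
    id = seq_len(n_nodes), type = c(1L, rep(3L, n_nodes - 1L)),
    x = c(0, rnorm(n_nodes - 1, 0, scale)),
    y = c(0, rnorm(n_nodes - 1, 0, scale)),
    z = c(0, rnorm(n_nodes - 1, 0, scale)),
    radius = 0.5, parent = parent
  )
}
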