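# Independent oracles used across the suite. Deliberately brute-force and
# separate from the package's implementations.

# O(n^2) neighbour counts in a point-centred cube (Chebyshev radius `half`)
brute_neighbors_centered <- function(cloud, half = 2) {
  n <- nrow(cloud)
  vapply(seq_len(n), function(i) {
    sum(abs(cloud$x - cloud$x[i]) <= half &
          abs(cloud$y - cloud$y[i]) <= half &
          abs(cloud$z - cloud$z[i]) <= half) - 1L
  }, 0L)
}

# O(n^2) neighbour counts in the anchored-lattice block containing each point
brute_neighbors_lattice <- function(cloud, block = 4) {
  bx <- floor(cloud$x / block)
  by <- floor(cloud$y / block)
  bz <- floor(cloud$z / block)
  vapply(seq_len(nrow(cloud)), function(i) {
    sum(bx == bx[i] & by == by[i] & bz == bz[i]) - 1L
  }, 0L)
}

# brute-force block mean with coverage rule, matrix in, matrix out
brute_block_mean <- function(v, f, min_frac) {
  nr <- nrow(v) %/% f
  nc <- ncol(v) %/% f
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      blk <- v[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
      ok <- is.finite(blk)
      if (mean(ok) >= min_frac && any(ok)) out[i, j] <- mean(blk[ok])
    }
  }
  out
}

# ray-casting point-in-polygon (closed: boundary points count as inside)
brute_pip <- function(px, py, poly) {
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    inside <- FALSE
    for (k in seq_len(n)) {
      a <- poly[k, ]; b <- poly[if (k == n) 1 else k + 1, ]
      # boundary check
      cross <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
      if (abs(cross) < 1e-9 &&
          x >= min(a[1], b[1]) - 1e-9 && x <= max(a[1], b[1]) + 1e-9 &&
          y >= min(a[2], b[2]) - 1e-9 && y <= max(a[2], b[2]) + 1e-9) {
        return(TRUE)
      }
      if ((a[2] > y) != (b[2] > y)) {
        xint <- a[1] + (y - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, NA)
}

# exact two-sided Wilcoxon p by enumerating every group assignment of the
# pooled sample (tie-free samples only)
enum_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# direct O(n^2)-style separable Gaussian blur with edge replication,
# re-implementing the terrain filter recipe independently
brute_gauss_blur <- function(m, sigma) {
  w <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-w, w), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      idx <- (i - w):(i + w)
      idx <- pmin(pmax(idx, 1L), n)  # edge replication
      out[i] <- sum(k * v[idx])
    }
    out
  }
  m2 <- apply(m, 2, blur1)
  t(apply(m2, 1, blur1))
}

# one small classified scene shared across test files (expensive pieces
# computed once per test run)
.scene_cache <- new.env(parent = emptyenv())

small_scene <- function() {
  if (is.null(.scene_cache$sc)) {
    cfg <- scene_config(extent_length = 200, extent_width = 100,
                        outlier_count = 12, seed = 7)
    sc <- generate_scene(cfg)
    fl <- remove_outliers(sc$cloud)
    classified <- classify_ground(fl$kept)
    dtm <- build_dtm(classified, extent = c(0, 200, 0, 100))
    .scene_cache$sc <- list(
      cfg = cfg, scene = sc, filtered = fl, classified = classified,
      dtm = dtm
    )
  }
  .scene_cache$sc
}
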