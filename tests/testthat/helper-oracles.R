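# Shared fixtures and independent oracles used across tests. Oracles are
# deliberately naive (exhaustive / closed form) and share no code with the
# package implementations they check.

make_disk <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad + 1
  cx <- (n + 1) / 2
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  m <- matrix(0L, n, n)
  m[(i - cx)^2 + (j - cx)^2 <= r^2] <- 1L
  m
}

make_square <- function(s, pad = 10, theta = 0) {
  n <- ceiling(s * 1.6) + 2 * pad
  cx <- (n + 1) / 2
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  u <- cos(theta) * (i - cx) + sin(theta) * (j - cx)
  v <- -sin(theta) * (i - cx) + cos(theta) * (j - cx)
  m <- matrix(0L, n, n)
  m[abs(u) <= s / 2 & abs(v) <= s / 2] <- 1L
  m
}

# exhaustive nearest-source distance, O(N * sources)
brute_force_distance <- function(mask, pixel_size_um = 1) {
  src <- which(mask == 1, arr.ind = TRUE)
  stopifnot(nrow(src) > 0)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- sqrt(min((src[, 1] - i)^2 + (src[, 2] - j)^2))
    }
  }
  out * pixel_size_um
}

# exhaustive box occupancy count: loop over grid cells, test point inclusion
brute_force_box_count <- function(points, eps, offset = 0) {
  p <- points + offset
  xr <- range(p[, 1]); yr <- range(p[, 2])
  cells <- 0L
  for (cx in seq(floor(xr[1] / eps), floor(xr[2] / eps))) {
    for (cy in seq(floor(yr[1] / eps), floor(yr[2] / eps))) {
      hit <- any(p[, 1] >= cx * eps & p[, 1] < (cx + 1) * eps &
                 p[, 2] >= cy * eps & p[, 2] < (cy + 1) * eps)
      if (hit) cells <- cells + 1L
    }
  }
  cells
}

brute_force_fd <- function(points, box_sizes, n_offsets = 4) {
  counts <- vapply(box_sizes, function(e) {
    mean(vapply(seq_len(n_offsets), function(o)
      brute_force_box_count(points, e, offset = (o - 1) / n_offsets * e),
      numeric(1)))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(box_sizes))
  -unname(stats::coef(fit)[2])
}

# Koch-curve prefractal, densely sampled; total length chosen so the
# smallest segment matches the 2 px box floor of the default dyadic grid
koch_prefractal <- function(iterations = 4, length_px = 162, step = 0.3) {
  pts <- matrix(c(0, 0, length_px, 0), 2, 2, byrow = TRUE)
  rot <- matrix(c(cos(-pi / 3), -sin(-pi / 3),
                  sin(-pi / 3), cos(-pi / 3)), 2, 2)
  for (it in seq_len(iterations)) {
    out <- vector("list", nrow(pts) - 1)
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]; d <- (b - a) / 3
      out[[i]] <- rbind(a, a + d, a + d + as.vector(rot %*% d), a + 2 * d)
    }
    pts <- rbind(do.call(rbind, out), pts[nrow(pts), ])
  }
  dense <- lapply(seq_len(nrow(pts) - 1), function(i) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    L <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(L / step) + 1))
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  })
  unique(do.call(rbind, dense))
}

# fuzzy c-means objective with memberships profiled out (optimal U given V);
# for use with a generic optimizer as an independent minimizer
fcm_reduced_objective <- function(v, x, m = 2) {
  d2 <- outer(x, v, function(a, b) (a - b)^2)
  per_point <- apply(d2, 1, function(d) {
    if (any(d < .Machine$double.eps)) return(0)
    sum(d^(-1 / (m - 1)))^(-(m - 1))
  })
  sum(per_point)
}
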