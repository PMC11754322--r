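# Independent reference implementations used to cross-check the package's
# geometry code.  These are deliberately written with different algorithms
# (gift wrapping instead of Andrew's monotone chain via chull, plain
# recursion instead of an explicit stack, root finding on the arc-length
# parametrization instead of per-segment circle intersection).

# O(n^2) gift-wrapping hull + shoelace area
oracle_hull_area <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- order(xy[, 1], xy[, 2])[1]
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p) next
      cr <- cross(xy[p, ], xy[q, ], xy[r, ])
      further <- sum((xy[r, ] - xy[p, ])^2) > sum((xy[q, ] - xy[p, ])^2)
      if (q == p || cr < 0 || (cr == 0 && further)) q <- r
    }
    p <- q
    if (p == start || length(hull) > n) break
  }
  hx <- xy[hull, 1]; hy <- xy[hull, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# plain recursive RDP returning the keep mask
oracle_rdp_keep <- function(xy, eps) {
  n <- nrow(xy)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  pd <- function(p, a, b) {
    d <- b - a
    len <- sqrt(sum(d^2))
    if (len == 0) return(sqrt(sum((p - a)^2)))
    abs(d[2] * (p[1] - a[1]) - d[1] * (p[2] - a[2])) / len
  }
  rec <- function(lo, hi) {
    if (hi - lo < 2) return(invisible())
    idx <- (lo + 1):(hi - 1)
    d <- vapply(idx, function(i) pd(xy[i, ], xy[lo, ], xy[hi, ]), numeric(1))
    i <- idx[which.max(d)]
    if (max(d) > eps) {
      keep[i] <<- TRUE
      rec(lo, i)
      rec(i, hi)
    }
  }
  rec(1, n)
  keep
}

# arc-length-parametrized constant-step walker: root finding on
# |P(s) - q| = step along the cumulative arc length
oracle_rediscretize <- function(xy, step) {
  seg <- diff(xy)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  point_at <- function(s) {
    if (s >= total) return(xy[nrow(xy), ])
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    t <- (s - cum[i]) / seglen[i]
    xy[i, ] + t * seg[i, ]
  }
  out <- xy[1, , drop = FALSE]
  q <- xy[1, ]
  s <- 0
  ds <- step / 64
  repeat {
    f <- function(ss) sqrt(sum((point_at(ss) - q)^2)) - step
    found <- FALSE
    s_prev <- s
    while (s_prev < total - 1e-12) {
      s_next <- min(s_prev + ds, total)
      if (f(s_next) >= 0) {
        root <- stats::uniroot(f, c(s_prev, s_next), tol = 1e-13)$root
        q <- point_at(root)
        out <- rbind(out, q)
        s <- root
        found <- TRUE
        break
      }
      s_prev <- s_next
    }
    if (!found) break
  }
  unname(out)
}

# per-sample bin scan: half-open cells anchored at the lower-left corner
oracle_bins <- function(xy, bounds, s) {
  nx <- ceiling((bounds[3] - bounds[1]) / s - 1e-9)
  ny <- ceiling((bounds[4] - bounds[2]) / s - 1e-9)
  ids <- numeric(nrow(xy))
  for (k in seq_len(nrow(xy))) {
    i <- min(max(floor((xy[k, 1] - bounds[1]) / s), 0), nx - 1)
    j <- min(max(floor((xy[k, 2] - bounds[2]) / s), 0), ny - 1)
    ids[k] <- i + nx * j
  }
  entries <- ids[1]
  for (k in seq_along(ids)[-1])
    if (ids[k] != ids[k - 1]) entries <- c(entries, ids[k])
  list(id = ids, entries = entries)
}

# seeded random open polyline for geometry property checks
random_polyline <- function(n, seed, scale = 1) {
  set.seed(seed)
  cbind(cumsum(rnorm(n, sd = scale)), cumsum(rnorm(n, sd = scale)))
}

# two columns with an exact empirical correlation r (orthonormal basis trick)
make_pair_with_cor <- function(n, r, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, rnorm(n), rnorm(n))))[, 2:3]
  z1 <- q[, 1]; z2 <- q[, 2]
  x1 <- z1
  x2 <- r * z1 + sqrt(1 - r^2) * z2
  cbind(a = x1, b = x2)
}

# block-structured cohort: `sizes` variables per block, within-block
# correlation via a shared latent factor, independent across blocks
make_block_matrix <- function(n, sizes, within = 0.95, seed = 1) {
  set.seed(seed)
  cols <- list()
  nm <- character(0)
  for (b in seq_along(sizes)) {
    f <- rnorm(n)
    for (j in seq_len(sizes[b])) {
      cols[[length(cols) + 1]] <-
        within * f + sqrt(1 - within^2) * rnorm(n)
      nm <- c(nm, sprintf("b%d_v%d", b, j))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}
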