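# Independent oracle implementations used to cross-check package kernels.
# These are deliberately written differently from the package code paths.

# exact two-sided Mann-Whitney p by full enumeration of group assignments
enumerate_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  mu <- na * nb / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# density clustering oracle: iterative label propagation on the core-point
# graph; borders join the nearest core point within range
bf_density_cluster <- function(dmat, eps, min_samples) {
  n <- nrow(dmat)
  nb <- dmat <= eps
  core <- rowSums(nb) >= min_samples
  labels <- ifelse(core, seq_len(n), 0L)
  repeat {
    changed <- FALSE
    for (i in which(core)) {
      friends <- which(nb[i, ] & core)
      m <- min(labels[friends])
      if (m < labels[i]) { labels[i] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  # relabel cores in order of smallest member index
  u <- unique(labels[core])
  u <- u[order(u)]
  labels[core] <- match(labels[core], u)
  for (i in which(!core)) {
    cand <- which(nb[i, ] & core)
    labels[i] <- if (length(cand))
      labels[cand[order(dmat[i, cand], cand)][1]] else 0L
  }
  labels
}

# convex hull area by triangle fan from the hull centroid
fan_hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  cx <- mean(hx); cy <- mean(hy)
  k <- length(hx)
  s <- 0
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    s <- s + abs((hx[i] - cx) * (hy[j] - cy) - (hx[j] - cx) * (hy[i] - cy)) / 2
  }
  s
}

# circumradius of a triangle from its side lengths (R = abc / 4K)
circumradius_sides <- function(a, b, c) {
  s <- (a + b + c) / 2
  K <- sqrt(max(s * (s - a) * (s - b) * (s - c), 0))
  if (K == 0) return(Inf)
  a * b * c / (4 * K)
}

# histogram entropy by direct loop
loop_entropy <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0)
  counts <- integer(n_bins)
  for (v in x) {
    b <- floor((v - lo) / (hi - lo) * n_bins) + 1
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (cn in counts) if (cn > 0) {
    p <- cn / length(x)
    h <- h - p * log(p)
  }
  h
}
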