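# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# triple-loop topological overlap
tom_oracle <- function(adj) {
  a <- adj
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# definitional BH step-up: q_(i) = min over j >= i of p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# naive O(n^3) average-linkage agglomeration; returns sorted merge heights
average_linkage_heights_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# linear-interpolation quantile of a sorted sample (type-7 definition,
# written out by hand)
quantile_oracle <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# random valid symmetric adjacency in [0,1)
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n, 0, 0.95), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# small planted-module dataset shared by several tests
planted_dataset <- function(seed, n_samples = 26, sizes = c(30, 45, 55, 70, 80),
                            wmc = 0.5, n_background = 500, ...) {
  generate_dataset(simulation_config(
    n_samples = n_samples, module_sizes = sizes, within_module_cor = wmc,
    n_background = n_background, seed = seed, ...))
}
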