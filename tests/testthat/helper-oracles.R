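# Independent oracles: naive reimplementations of the definitions, kept
# deliberately separate from the package's code paths.

# kernel weights by direct enumeration over the full integer support
oracle_kernel_weights <- function(shape, h) {
  m <- c(gaussian = 5, square = 3, triangle = 6)[[shape]]
  r <- floor(m * h)
  j <- as.numeric(-r:r)
  raw <- switch(shape,
    gaussian = exp(-j^2 / (2 * h^2)),
    square   = rep(1, length(j)),
    triangle = 1 - abs(j) / (6 * h))
  list(offsets = j, w = raw / sum(raw), r = r)
}

# per-query naive summation of Eq-style estimate, one kernel at a time
oracle_eval <- function(x, h, shape, queries, epsilon = 0, G) {
  if (length(h) == 1L) h <- rep(h, length(x))
  f <- vapply(queries, function(q) {
    s <- 0
    for (i in seq_along(x)) {
      ok <- oracle_kernel_weights(shape, h[i])
      d <- q - x[i]
      if (abs(d) <= ok$r) s <- s + ok$w[d + ok$r + 1L]
    }
    s / length(x)
  }, numeric(1))
  (1 - epsilon) * f + epsilon / G
}

# brute-force KNN rules by full O(n^2) distance enumeration
brute_knn1 <- function(x, k, h_min = 1) {
  vapply(seq_along(x), function(i) {
    max(sort(abs(x[-i] - x[i]))[k], h_min)
  }, numeric(1))
}

# Directional-coverage statement of the KNN2 rule: a direction holding at
# least one point but none of the k nearest (ties at rank k count as
# covered) pulls the bandwidth out to its nearest point. Equals the paper's
# all-on-one-side override whenever positions are distinct; duplicates of
# x_i (distance 0) lie on neither side and never provide coverage.
brute_knn2 <- function(x, k, h_min = 1) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d <- abs(x[-i] - x[i])
    side <- sign(x[-i] - x[i])
    kth <- sort(d)[k]
    h <- kth
    lnz <- if (any(side < 0)) min(d[side < 0]) else Inf
    rnz <- if (any(side > 0)) min(d[side > 0]) else Inf
    if (is.finite(lnz) && lnz > kth) h <- max(h, lnz)
    if (is.finite(rnz) && rnz > kth) h <- max(h, rnz)
    max(h, h_min)
  }, numeric(1))
}

# triple-scan strict-maxima oracle on a dense value vector
oracle_maxima <- function(values) {
  which(vapply(seq_along(values), function(b) {
    b > 1 && b < length(values) &&
      values[b] > values[b - 1] && values[b] > values[b + 1]
  }, logical(1)))
}

# adversarial two-dense-clusters-with-a-gap instance (the "zero problem"
# configuration): all k nearest neighbors of cluster points stay in-cluster
rand_gap_instance <- function(k) {
  c1 <- sort(sample(1:60, k + 3, replace = TRUE)) + 100
  gap <- sample(500:2000, 1)
  c2 <- sort(sample(1:60, k + 3, replace = TRUE)) + 100 + 60 + gap
  sort(c(c1, c2))
}

# the stated synthetic world for the tuning-protocol criteria: 2e4 reads,
# 50 point sources over uniform background on a 1 Mb chromosome
acceptance_sim_config <- function(seed) {
  sim_config(
    G = 1e6, n_reads = 2e4, fragment_length = 150,
    sources = data.frame(center = seq(2e4, 98e4, length.out = 50),
                         weight = rep(0.7 / 50, 50), spread = 50),
    background_weight = 0.3, seed = seed)
}

acceptance_positions <- function(seed) {
  cfg <- acceptance_sim_config(seed)
  preprocess(simulate_reads(cfg)$reads, cfg$fragment_length,
             chrom_info(cfg$chrom, cfg$G))
}

# small heterogeneous dataset for fast tests
small_sim_positions <- function(seed, G = 1e5, n = 2000) {
  cfg <- sim_config(G = G, n_reads = n, fragment_length = 150,
                    sources = data.frame(center = c(0.2, 0.5, 0.8) * G,
                                         weight = c(0.25, 0.3, 0.25),
                                         spread = c(30, 50, 80)),
                    background_weight = 0.2, seed = seed)
  preprocess(simulate_reads(cfg)$reads, 150, chrom_info(cfg$chrom, G))
}
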