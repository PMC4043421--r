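# Synthetic single-end read generator with known ground truth.
#
# The generative model is a mixture of point-source binding events plus
# uniform background: a fragment center is drawn from a source (normal
# around the source center, modeling binding-site plus fragmentation noise)
# or uniformly from the chromosome; the read is assigned a strand by a fair
# coin and its 5' start is displaced from the fragment center by half the
# fragment length, away from the center on the strand's upstream side --
# the geometry that the half-fragment shift in preprocess() inverts.

#' Simulation configuration
#'
#' @param G Chromosome length in bp.
#' @param n_reads Number of reads to generate.
#' @param fragment_length Mean fragment length `L` in bp (`>= 0`).
#' @param sources data.frame with columns `center` (bp, in `[1, G]`),
#'   `weight` (sampling probability) and `spread` (sd of fragment-center
#'   noise in bp; 0 gives a point mass).
#' @param background_weight Probability that a read is uniform background;
#'   must sum to 1 with the source weights.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param chrom Chromosome name for the generated reads.
#' @return A `sim_config` object.
#' @export
sim_config <- function(G, n_reads, fragment_length, sources = NULL,
                       background_weight = 1, seed = 1, chrom = "chrS") {
  if (is.null(sources)) {
    sources <- data.frame(center = numeric(0), weight = numeric(0),
                          spread = numeric(0))
  }
  stopifnot(is.data.frame(sources),
            all(c("center", "weight", "spread") %in% names(sources)))
  w <- c(background_weight, sources$weight)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stopf("background_weight plus source weights must be non-negative and sum to 1")
  }
  if (nrow(sources) > 0 && any(sources$center < 1 | sources$center > G)) {
    stopf("source centers must lie in [1, G]")
  }
  if (fragment_length < 0) stopf("fragment_length must be >= 0")
  structure(list(G = as.numeric(G), n_reads = as.integer(n_reads),
                 fragment_length = fragment_length, sources = sources,
                 background_weight = background_weight,
                 seed = as.integer(seed), chrom = chrom),
            class = "sim_config")
}

#' Simulate mapped single-end reads
#'
#' @param config A [sim_config()].
#' @return List with `reads` (data.frame `chrom`, `pos5`, `strand`),
#'   `centers` (the true fragment centers, for diagnostics) and `config`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_reads
  s <- floor(config$fragment_length / 2 + 0.5)
  out <- with_seed(config$seed, {
    comp <- sample.int(nrow(config$sources) + 1L, n, replace = TRUE,
                       prob = c(config$background_weight, config$sources$weight)) - 1L
    center <- numeric(n)
    bg <- comp == 0L
    center[bg] <- sample.int(config$G, sum(bg), replace = TRUE)
    for (j in seq_len(nrow(config$sources))) {
      sel <- comp == j
      center[sel] <- round(config$sources$center[j] +
                             stats::rnorm(sum(sel), 0, config$sources$spread[j]))
    }
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    pos5 <- center + ifelse(strand == "+", -s, s)
    list(center = center, strand = strand,
         pos5 = pmin(pmax(pos5, 1), config$G))
  })
  list(reads = data.frame(chrom = config$chrom, pos5 = out$pos5,
                          strand = out$strand),
       centers = out$center, config = config)
}

#' Ground-truth mixture density
#'
#' The per-base probability of a fragment center: uniform background plus
#' per-source normals discretized to integer positions and renormalized to
#' the chromosome, so the density sums to 1 over `[1, G]`.
#'
#' @param config A [sim_config()].
#' @param positions Integer positions at which to evaluate.
#' @return Numeric vector of probabilities.
#' @export
true_density <- function(config, positions) {
  stopifnot(inherits(config, "sim_config"))
  p <- rep(config$background_weight / config$G, length(positions))
  for (j in seq_len(nrow(config$sources))) {
    ctr <- config$sources$center[j]
    sd <- config$sources$spread[j]
    w <- config$sources$weight[j]
    if (sd == 0) {
      p <- p + w * as.numeric(positions == round(ctr))
    } else {
      total <- stats::pnorm(config$G + 0.5, ctr, sd) - stats::pnorm(0.5, ctr, sd)
      p <- p + w * (stats::pnorm(positions + 0.5, ctr, sd) -
                      stats::pnorm(positions - 0.5, ctr, sd)) / total
    }
  }
  p
}
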