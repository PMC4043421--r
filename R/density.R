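# Kernel density estimation over integer base-pair positions.
#
# The estimate is f(x) = (1/n) * sum_i K(x - x_i, h_i), where K is a
# discretely-normalized truncated kernel. Each kernel contributes exactly
# mass 1/n, so the estimate is a probability distribution over the integers
# (minus whatever mass overhangs the chromosome ends; overhanging kernels
# are neither renormalized nor reflected).

#' Uniform-mixture parameters
#'
#' The blended estimate is `f_eps(x) = (1 - eps) f(x) + eps / G`, assigning a
#' baseline probability `eps / G` everywhere on a chromosome of length `G`.
#' This resolves the "zero problem" of held-out points falling outside every
#' kernel support.
#'
#' @param epsilon Mixture weight in `[0, 1]`.
#' @param G Chromosome length in bp (the uniform density is `1/G` on `[1, G]`).
#' @return A `mixture_params` object.
#' @export
mixture_params <- function(epsilon, G) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0 || epsilon > 1) {
    stopf("epsilon must be a single value in [0, 1]")
  }
  if (!is_count(G) || G < 1) stopf("G must be a positive integer")
  structure(list(epsilon = epsilon, G = as.numeric(G)), class = "mixture_params")
}

# Kernel cache keyed by bandwidth, one kernel_spec per cache.
kernel_cache <- function(spec) {
  env <- new.env(parent = emptyenv())
  function(h) {
    key <- format(h, digits = 17)
    k <- env[[key]]
    if (is.null(k)) {
      k <- build_kernel(spec, h)
      env[[key]] <- k
    }
    k
  }
}

new_kde_track <- function(chrom_info, kind, n_train, s_bar, epsilon = 0, ...) {
  structure(
    c(list(chrom = chrom_info$name, G = chrom_info$length, kind = kind,
           n_train = n_train, s_bar = s_bar, epsilon = epsilon), list(...)),
    class = "kde_track"
  )
}

#' @export
print.kde_track <- function(x, ...) {
  extent <- switch(x$kind,
    dense = sprintf("[%g, %g]", x$start, x$end),
    pconst = sprintf("%d pieces", nrow(x$pieces)),
    plinear = sprintf("%d breakpoints", nrow(x$breaks)))
  cat(sprintf(
    "<kde_track> %s (G = %g): %s representation, %s, n = %d, mean support %.1f bp, epsilon = %g\n",
    x$chrom, x$G, x$kind, extent, x$n_train, x$s_bar, x$epsilon))
  invisible(x)
}

check_bandwidths <- function(X, bandwidths) {
  if (length(bandwidths) == 1L) bandwidths <- rep(as.numeric(bandwidths), X$n)
  if (length(bandwidths) != X$n) {
    stopf("bandwidth vector length %d does not match n = %d",
          length(bandwidths), X$n)
  }
  bandwidths
}

# Shared dense accumulator: kernels added in ascending x_i order, float64
# accumulation (error budget 1e-6, no compensated summation).
dense_accumulate <- function(X, bandwidths, spec, chrom_info) {
  x <- X$positions
  n <- X$n
  get_kernel <- kernel_cache(spec)
  r <- vapply(bandwidths, function(h) get_kernel(h)$r, integer(1))
  start <- max(1, min(x - r))
  end <- min(chrom_info$length, max(x + r))
  values <- numeric(end - start + 1L)
  for (i in seq_len(n)) {
    kern <- get_kernel(bandwidths[i])
    lo <- x[i] - kern$r
    hi <- x[i] + kern$r
    w <- kernel_full_weights(kern) / n
    clip_lo <- max(lo, start)
    clip_hi <- min(hi, end)
    idx <- (clip_lo - start + 1L):(clip_hi - start + 1L)
    values[idx] <- values[idx] + w[(clip_lo - lo + 1L):(clip_hi - lo + 1L)]
  }
  list(start = start, end = end, values = values, s_bar = mean(2 * r + 1))
}

#' Fixed-bandwidth kernel density estimate
#'
#' Evaluates `f(x) = (1/n) sum_i K(x - x_i, h)` at every integer position in
#' the union of kernel supports (clipped to `[1, G]`); the implicit value
#' outside the evaluated range is 0.
#'
#' @param X A [position_array()].
#' @param h Constant bandwidth in bp.
#' @param spec A [kernel_spec()].
#' @param chrom_info A [chrom_info()].
#' @return A dense `kde_track`.
#' @export
fixed_kde <- function(X, h, spec, chrom_info) {
  X <- as_position_array(X)
  adaptive_kde(X, rep(as.numeric(h), X$n), spec, chrom_info)
}

#' Adaptive-bandwidth (sample-point) kernel density estimate
#'
#' Evaluates `f(x) = (1/n) sum_i K(x - x_i, h_i)` with one bandwidth per data
#' point, e.g. from [knn1_bandwidths()] or [knn2_bandwidths()]. With a
#' constant bandwidth vector the result equals [fixed_kde()] exactly.
#'
#' @param X A [position_array()].
#' @param bandwidths Numeric vector of per-point bandwidths (length `n`), or
#'   a single value.
#' @param spec A [kernel_spec()].
#' @param chrom_info A [chrom_info()].
#' @return A dense `kde_track`.
#' @export
adaptive_kde <- function(X, bandwidths, spec, chrom_info) {
  X <- as_position_array(X)
  stopifnot(inherits(chrom_info, "chrom_info"))
  bandwidths <- check_bandwidths(X, bandwidths)
  acc <- dense_accumulate(X, bandwidths, spec, chrom_info)
  new_kde_track(chrom_info, "dense", X$n, acc$s_bar,
                start = acc$start, end = acc$end, values = acc$values)
}

#' Blend a density track with the uniform background
#'
#' Every per-base value `v` becomes `(1 - eps) v + eps / G`; the implicit
#' value outside the evaluated range becomes `eps / G`.
#'
#' @param track A `kde_track`.
#' @param params A [mixture_params()]; its `G` must match the track's.
#' @return The blended `kde_track`.
#' @export
blend_uniform <- function(track, params) {
  stopifnot(inherits(track, "kde_track"), inherits(params, "mixture_params"))
  if (params$G != track$G) stopf("mixture G (%g) != track G (%g)", params$G, track$G)
  if (track$epsilon != 0) stopf("track is already blended (epsilon = %g)", track$epsilon)
  e <- params$epsilon
  u <- e / params$G
  if (track$kind == "dense") {
    track$values <- (1 - e) * track$values + u
  } else if (track$kind == "pconst") {
    track$pieces$value <- (1 - e) * track$pieces$value + u
  } else {
    track$breaks$value <- (1 - e) * track$breaks$value + u
  }
  track$epsilon <- e
  track
}

#' Evaluate the blended estimate at query positions
#'
#' Computes `f_eps(q)` for each query without materializing a
#' whole-chromosome track: queries are sorted once and, for each data point,
#' the covered query range is located by binary search (integer support test
#' `|q - x_i| <= r_i`). The result is identical to reading a dense track at
#' the same positions.
#'
#' @param X A [position_array()] of training positions.
#' @param bandwidths Per-point bandwidths (length `n`) or a single value.
#' @param spec A [kernel_spec()].
#' @param params A [mixture_params()] supplying `epsilon` and `G`.
#' @param queries Integer positions in `[1, G]`.
#' @return Numeric vector of probability masses, one per query, in input order.
#' @export
evaluate_at <- function(X, bandwidths, spec, params, queries) {
  X <- as_position_array(X)
  stopifnot(inherits(params, "mixture_params"))
  if (length(queries) == 0L) return(numeric(0))
  if (any(queries < 1 | queries > params$G)) {
    stopf("queries must lie within [1, G = %g]", params$G)
  }
  bandwidths <- check_bandwidths(X, bandwidths)
  if (any(bandwidths < H_MIN_KERNEL)) {
    stopf("bandwidths below minimum admissible %g", H_MIN_KERNEL)
  }
  ord <- order(queries)
  qs <- as.numeric(queries[ord])
  code <- shape_code(spec$shape)
  uh <- unique(bandwidths)
  ur <- as.integer(floor(spec$support_multiplier * uh))
  ut <- vapply(seq_along(uh), function(i) kernel_total_cpp(code, uh[i], ur[i]),
               numeric(1))
  idx <- match(bandwidths, uh)
  f <- kde_eval_sorted_cpp(X$positions, bandwidths, code, ut[idx], ur[idx], qs)
  e <- params$epsilon
  blended <- (1 - e) * f + e / params$G
  out <- numeric(length(blended))
  out[ord] <- blended
  out
}

#' Exact piecewise-constant square-kernel estimate
#'
#' The square-kernel estimate is piecewise constant with at most `2n + 1`
#' pieces: each data point contributes one rise and one fall. The
#' representation is built by an event sweep in `O(n log n)` time,
#' independent of the chromosome length, and matches dense evaluation
#' pointwise.
#'
#' @inheritParams adaptive_kde
#' @param spec Must be the square [kernel_spec()].
#' @return A `kde_track` with a `pieces` data frame (1-based inclusive
#'   `start`, `end`, `value`); the implicit value between/outside pieces is 0.
#' @export
piecewise_constant_kde <- function(X, bandwidths, spec, chrom_info) {
  X <- as_position_array(X)
  stopifnot(inherits(spec, "kernel_spec"), inherits(chrom_info, "chrom_info"))
  if (spec$shape != "square") stopf("piecewise_constant_kde requires the square kernel")
  bandwidths <- check_bandwidths(X, bandwidths)
  get_kernel <- kernel_cache(spec)
  x <- X$positions
  n <- X$n
  kerns <- lapply(bandwidths, get_kernel)
  r <- vapply(kerns, `[[`, integer(1), "r")
  height <- vapply(kerns, function(k) k$half[1L], numeric(1)) / n
  # rise at x_i - r_i, fall just after x_i + r_i
  pos <- c(x - r, x + r + 1)
  delta <- c(height, -height)
  ord <- order(pos)
  pos <- pos[ord]
  delta <- delta[ord]
  agg <- rowsum(delta, group = pos, reorder = TRUE)
  bnd <- as.numeric(rownames(agg))
  level <- cumsum(agg[, 1L])
  starts <- bnd[-length(bnd)]
  ends <- bnd[-1L] - 1
  vals <- level[-length(level)]
  keep <- vals > 0 & ends >= 1 & starts <= chrom_info$length
  pieces <- data.frame(start = pmax(starts[keep], 1),
                       end = pmin(ends[keep], chrom_info$length),
                       value = vals[keep])
  new_kde_track(chrom_info, "pconst", n, mean(2 * r + 1), pieces = pieces)
}

#' Exact piecewise-linear triangle-kernel estimate
#'
#' The triangle-kernel estimate is piecewise linear with `O(n)` breakpoints:
#' each kernel is linear between its apex, its support edges, and the first
#' offsets outside the support. The stored breakpoints are the union of
#' these knots; linear interpolation between them reproduces dense
#' evaluation exactly at every integer.
#'
#' @inheritParams adaptive_kde
#' @param spec Must be the triangle [kernel_spec()].
#' @return A `kde_track` with a `breaks` data frame (`pos`, `value`); the
#'   implicit value outside the breakpoint range is 0.
#' @export
piecewise_linear_kde <- function(X, bandwidths, spec, chrom_info) {
  X <- as_position_array(X)
  stopifnot(inherits(spec, "kernel_spec"), inherits(chrom_info, "chrom_info"))
  if (spec$shape != "triangle") stopf("piecewise_linear_kde requires the triangle kernel")
  bandwidths <- check_bandwidths(X, bandwidths)
  get_kernel <- kernel_cache(spec)
  x <- X$positions
  r <- vapply(bandwidths, function(h) get_kernel(h)$r, integer(1))
  knots <- sort(unique(pmin(pmax(
    c(x - r - 1, x - r, x, x + r, x + r + 1), 1), chrom_info$length)))
  vals <- evaluate_at(X, bandwidths, spec,
                      mixture_params(0, chrom_info$length), knots)
  keep <- prune_colinear_knots(knots, vals)
  new_kde_track(chrom_info, "plinear", X$n, mean(2 * r + 1),
                breaks = data.frame(pos = knots[keep], value = vals[keep]))
}

# Drop knots that linear interpolation of their kept neighbors reproduces
# (colinear chains, e.g. long zero runs between disjoint kernels), plus
# leading/trailing knots of all-zero segments: the implicit outside value is
# already 0. Keeps the representation at its canonical minimal set (a lone
# kernel with integer 6h reduces to apex plus the two support-edge zeros).
prune_colinear_knots <- function(pos, val) {
  m <- length(pos)
  keep <- rep(TRUE, m)
  if (m >= 2L && val[1L] == 0 && val[2L] == 0) keep[1L] <- FALSE
  if (m >= 2L && val[m] == 0 && val[m - 1L] == 0) keep[m] <- FALSE
  prev <- if (keep[1L]) 1L else 2L
  for (i in seq(2L, length.out = max(m - 2L, 0L))) {
    if (i <= prev) next
    interp <- val[prev] + (val[i + 1L] - val[prev]) *
      (pos[i] - pos[prev]) / (pos[i + 1L] - pos[prev])
    if (abs(val[i] - interp) <= 1e-15 * max(val[i], interp, 1e-300)) {
      keep[i] <- FALSE
    } else {
      prev <- i
    }
  }
  keep
}

#' Read per-base values off any track representation
#'
#' @param track A `kde_track`.
#' @param at Integer positions in `[1, G]`.
#' @return Values at `at`, honoring the track's blending (positions outside
#'   the represented support get `epsilon / G`).
#' @export
evaluate_track <- function(track, at) {
  stopifnot(inherits(track, "kde_track"))
  if (any(at < 1 | at > track$G)) stopf("positions must lie within [1, G]")
  base <- track$epsilon / track$G
  out <- rep(base, length(at))
  if (track$kind == "dense") {
    inside <- at >= track$start & at <= track$end
    out[inside] <- track$values[at[inside] - track$start + 1L]
  } else if (track$kind == "pconst") {
    p <- track$pieces
    idx <- findInterval(at, p$start)
    hit <- idx >= 1L
    hit[hit] <- at[hit] <= p$end[idx[hit]]
    out[hit] <- p$value[idx[hit]]
  } else {
    b <- track$breaks
    inside <- at >= b$pos[1L] & at <= b$pos[nrow(b)]
    if (any(inside)) {
      out[inside] <- stats::approx(b$pos, b$value, xout = at[inside],
                                   method = "linear", ties = "ordered")$y
    }
  }
  out
}
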