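# Held-out likelihood protocol: split the shifted read positions 50/25/25
# into training (builds the estimate), tuning (sets h or k) and test
# (final comparison) sets, and score parameter grids by the mean natural-log
# probability of the held-out points. The exponential of that score is the
# geometric-mean probability reported for test data.

#' Estimator configuration
#'
#' Bundles everything needed to evaluate a density estimate built from a
#' training set: fixed bandwidth `h`, or a nearest-neighbor rule plus `k`,
#' the kernel shape, the uniform-mixture weight and the chromosome length.
#'
#' @param kind `"fixed"` or `"adaptive"`.
#' @param spec A [kernel_spec()].
#' @param G Chromosome length in bp.
#' @param h Bandwidth (fixed case).
#' @param k Nearest-neighbor count (adaptive case).
#' @param rule `"knn2"` (default; positive density everywhere) or `"knn1"`.
#' @param epsilon Uniform-mixture weight, default 0.1.
#' @return A `kde_config` object.
#' @export
kde_config <- function(kind = c("fixed", "adaptive"), spec, G, h = NULL, k = NULL,
                       rule = c("knn2", "knn1"), epsilon = 0.1) {
  kind <- match.arg(kind)
  rule <- match.arg(rule)
  stopifnot(inherits(spec, "kernel_spec"))
  if (kind == "fixed" && is.null(h)) stopf("fixed configuration requires h")
  if (kind == "adaptive" && is.null(k)) stopf("adaptive configuration requires k")
  structure(list(kind = kind, spec = spec, G = as.numeric(G), h = h, k = k,
                 rule = rule, epsilon = epsilon), class = "kde_config")
}

config_bandwidths <- function(config, train) {
  if (config$kind == "fixed") {
    rep(as.numeric(config$h), train$n)
  } else {
    switch(config$rule,
           knn1 = knn1_bandwidths(train, config$k),
           knn2 = knn2_bandwidths(train, config$k))
  }
}

#' Random 50/25/25 split specification
#'
#' @param seed Integer seed making the split reproducible.
#' @param fractions Train/tune/test fractions; must be positive and sum to 1.
#' @return A `split_spec` object.
#' @export
split_spec <- function(seed, fractions = c(train = 0.5, tune = 0.25, test = 0.25)) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-12) {
    stopf("fractions must be three positive values summing to 1")
  }
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split positions into training, tuning and test sets
#'
#' Points are assigned by a seeded uniform permutation followed by a
#' proportional cut: the tuning and test sets get `round(n * fraction)`
#' points each and the remainder goes to training. Each part is re-sorted.
#'
#' @param X A [position_array()].
#' @param spec A [split_spec()].
#' @return List of three [position_array()]s: `train`, `tune`, `test`.
#' @export
split_positions <- function(X, spec) {
  X <- as_position_array(X)
  stopifnot(inherits(spec, "split_spec"))
  n <- X$n
  n_tune <- round(n * spec$fractions[[2L]])
  n_test <- round(n * spec$fractions[[3L]])
  n_train <- n - n_tune - n_test
  if (min(n_train, n_tune, n_test) < 1L) {
    stopf("n = %d too small to give each split part at least one point", n)
  }
  perm <- with_seed(spec$seed, sample.int(n))
  pos <- X$positions[perm]
  list(
    train = position_array(pos[seq_len(n_train)], X$chrom),
    tune = position_array(pos[n_train + seq_len(n_tune)], X$chrom),
    test = position_array(pos[n_train + n_tune + seq_len(n_test)], X$chrom)
  )
}

#' Mean log probability of held-out points
#'
#' `(1/m) sum_j ln f_eps(y_j)` with the estimate built from the training
#' positions under `config`. If any held-out point has zero probability
#' (possible only with `epsilon = 0`), the result is `-Inf`: a single
#' uncovered point collapses the joint probability of the whole set.
#'
#' @param train Training [position_array()].
#' @param config A [kde_config()].
#' @param eval_points Held-out [position_array()] (or numeric positions).
#' @return Mean natural-log probability (may be `-Inf`).
#' @export
mean_log_probability <- function(train, config, eval_points) {
  train <- as_position_array(train)
  stopifnot(inherits(config, "kde_config"))
  eval_points <- as_position_array(eval_points)
  bw <- config_bandwidths(config, train)
  p <- evaluate_at(train, bw, config$spec,
                   mixture_params(config$epsilon, config$G),
                   eval_points$positions)
  mean(log(p))
}

new_tuning_result <- function(param_name, grid, scores, epsilon) {
  finite <- is.finite(scores)
  if (!any(finite)) {
    stopf(paste0("all grid points scored -Inf; some held-out points are outside ",
                 "every kernel support -- set epsilon > 0"))
  }
  best <- grid[finite][which.max(scores[finite])]  # ties -> smaller value (grid sorted)
  structure(list(param_name = param_name,
                 grid = data.frame(param = grid, mean_log_prob = scores),
                 best = best, epsilon = epsilon),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %s grid of %d values, epsilon = %g, best %s = %g (mean log prob %.6g)\n",
              x$param_name, nrow(x$grid), x$epsilon, x$param_name, x$best,
              max(x$grid$mean_log_prob[is.finite(x$grid$mean_log_prob)])))
  invisible(x)
}

#' Default bandwidth grid: half-integer powers of two, 4 to 32768 bp
#' @return Numeric vector `2^(j/2)` for `j = 4..30`.
#' @export
default_h_grid <- function() 2^(seq(4L, 30L) / 2)

#' Default nearest-neighbor grid
#' @return Integer vector `1:32`.
#' @export
default_k_grid <- function() 1:32

#' Tune a fixed bandwidth on held-out data
#'
#' Scores every bandwidth in the grid by the mean log probability of the
#' tuning points under the training-set estimate and returns the argmax
#' (ties broken toward smaller `h`, favoring emphasis of true signal
#' regions).
#'
#' @param train,tune Training and tuning [position_array()]s.
#' @param h_grid Bandwidth grid (sorted internally), e.g. [default_h_grid()].
#' @param spec A [kernel_spec()].
#' @param epsilon Uniform-mixture weight.
#' @param G Chromosome length.
#' @return A `tuning_result`.
#' @export
tune_fixed_bandwidth <- function(train, tune, h_grid = default_h_grid(), spec,
                                 epsilon = 0.1, G) {
  if (length(h_grid) == 0L) stopf("empty bandwidth grid")
  h_grid <- sort(h_grid)
  scores <- vapply(h_grid, function(h) {
    cfg <- kde_config("fixed", spec, G, h = h, epsilon = epsilon)
    mean_log_probability(train, cfg, tune)
  }, numeric(1))
  new_tuning_result("h", h_grid, scores, epsilon)
}

#' Tune the nearest-neighbor count k on held-out data
#'
#' @inheritParams tune_fixed_bandwidth
#' @param k_grid Grid of `k` values, e.g. [default_k_grid()]; entries with
#'   `k >= n_train` are skipped with a warning.
#' @param rule `"knn2"` or `"knn1"`.
#' @return A `tuning_result` (ties broken toward smaller `k`).
#' @export
tune_adaptive_k <- function(train, tune, k_grid = default_k_grid(),
                            rule = c("knn2", "knn1"), spec, epsilon = 0.1, G) {
  rule <- match.arg(rule)
  if (length(k_grid) == 0L) stopf("empty k grid")
  k_grid <- sort(k_grid)
  train <- as_position_array(train)
  usable <- k_grid < train$n
  if (!all(usable)) {
    warning(sprintf("skipping k >= n_train (%d): %s", train$n,
                    paste(k_grid[!usable], collapse = ", ")))
    k_grid <- k_grid[usable]
    if (length(k_grid) == 0L) stopf("no usable k values in grid")
  }
  scores <- vapply(k_grid, function(k) {
    cfg <- kde_config("adaptive", spec, G, k = k, rule = rule, epsilon = epsilon)
    mean_log_probability(train, cfg, tune)
  }, numeric(1))
  new_tuning_result("k", k_grid, scores, epsilon)
}

#' Geometric-mean probability of test points
#'
#' @param train Training [position_array()].
#' @param test Test [position_array()].
#' @param config Chosen [kde_config()].
#' @return `exp` of the mean log probability.
#' @export
evaluate_test <- function(train, test, config) {
  exp(mean_log_probability(train, config, test))
}
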