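ci1k <- chrom_info("chr1", 1000)

test_that("single-point square estimate is a normalized plateau", {
  tr <- fixed_kde(position_array(50), 1, kernel_spec("square"), ci1k)
  expect_equal(evaluate_track(tr, 47:53), rep(1 / 7, 7))
  expect_identical(evaluate_track(tr, c(46, 54)), c(0, 0))
  expect_equal(sum(tr$values), 1, tolerance = 1e-12)
})

test_that("duplicated points give the same track as a single point", {
  for (shape in c("gaussian", "square", "triangle")) {
    t1 <- fixed_kde(position_array(50), 2, kernel_spec(shape), ci1k)
    t2 <- fixed_kde(position_array(c(50, 50)), 2, kernel_spec(shape), ci1k)
    expect_equal(t1$values, t2$values, tolerance = 1e-15)
  }
})

test_that("adaptive with constant bandwidths equals fixed bit-for-bit", {
  set.seed(421)
  X <- position_array(sort(sample.int(1000, 30)))
  for (shape in c("gaussian", "square", "triangle")) {
    tf <- fixed_kde(X, 4, kernel_spec(shape), ci1k)
    ta <- adaptive_kde(X, rep(4, 30), kernel_spec(shape), ci1k)
    expect_identical(tf$values, ta$values)
    expect_identical(tf$start, ta$start)
  }
})

test_that("two-plateau adaptive square example", {
  ci <- chrom_info("chr1", 3000)
  X <- position_array(c(1, 1001))
  tr <- adaptive_kde(X, c(2, 500), kernel_spec("square"), ci)
  # h=2 -> r=6 -> width 13 plateau of (1/2)(1/13); h=500 -> r=1500 -> width
  # 3001 clipped at both chromosome ends here, value (1/2)(1/3001)
  expect_equal(evaluate_track(tr, 1:7), rep(0.5 / 13, 7) + 0.5 / 3001)
  expect_equal(evaluate_track(tr, 8), 0.5 / 3001)
  expect_equal(evaluate_track(tr, 2500), 0.5 / 3001)
  pc <- piecewise_constant_kde(X, c(2, 500), kernel_spec("square"), ci)
  expect_equal(evaluate_track(pc, c(1, 5, 8, 100, 2501, 2502)),
               evaluate_track(tr, c(1, 5, 8, 100, 2501, 2502)))
})

test_that("fixed and adaptive KDE match the naive summation oracle", {
  set.seed(422)
  for (rep in 1:15) {
    shape <- sample(c("gaussian", "square", "triangle"), 1)
    n <- sample(3:40, 1)
    x <- sort(sample.int(2000, n, replace = TRUE))
    X <- position_array(x)
    q <- sample.int(2000, 50)
    h <- runif(1, 0.6, 30)
    got <- evaluate_at(X, h, kernel_spec(shape), mixture_params(0, 2000), q)
    expect_equal(got, oracle_eval(x, h, shape, q, 0, 2000), tolerance = 1e-10)
    H <- pmax(knn2_bandwidths(X, min(3, n - 1)), 1)
    got_a <- evaluate_at(X, H, kernel_spec(shape), mixture_params(0, 2000), q)
    expect_equal(got_a, oracle_eval(x, H, shape, q, 0, 2000), tolerance = 1e-10)
  }
})

test_that("uniform blending is the stated affine map", {
  tr <- fixed_kde(position_array(500), 2, kernel_spec("triangle"), ci1k)
  t0 <- blend_uniform(tr, mixture_params(0, 1000))
  expect_equal(t0$values, tr$values)
  t1 <- blend_uniform(tr, mixture_params(1, 1000))
  expect_true(all(t1$values == 0.001))
  expect_equal(evaluate_track(t1, 1), 0.001)  # off-support baseline
  # worked arithmetic: v = 0.01, eps = 0.1, G = 1000
  tr$values[1] <- 0.01
  tb <- blend_uniform(tr, mixture_params(0.1, 1000))
  expect_equal(tb$values[1], 0.0091)
  expect_error(blend_uniform(tb, mixture_params(0.1, 1000)), "already blended")
  expect_error(mixture_params(1.2, 1000), "\\[0, 1\\]")
  expect_error(mixture_params(-0.1, 1000), "\\[0, 1\\]")
})

test_that("evaluate_at equals dense-track lookup bitwise and handles epsilon", {
  set.seed(423)
  X <- position_array(sort(sample.int(900, 40)) + 50)
  q <- sample.int(1000, 500, replace = TRUE)
  for (shape in c("gaussian", "square", "triangle")) {
    tr <- fixed_kde(X, 16, kernel_spec(shape), ci1k)
    expect_identical(
      evaluate_at(X, 16, kernel_spec(shape), mixture_params(0, 1000), q),
      evaluate_track(tr, q))
  }
  # far from all points: 0 with eps = 0, eps/G otherwise
  Xone <- position_array(5)
  p0 <- evaluate_at(Xone, 1, kernel_spec("square"), mixture_params(0, 1e6), 5e5)
  expect_identical(p0, 0)
  p1 <- evaluate_at(Xone, 1, kernel_spec("square"), mixture_params(0.1, 1e6), 5e5)
  expect_equal(p1, 1e-7)
  expect_error(evaluate_at(Xone, 1, kernel_spec("square"),
                           mixture_params(0, 1e6), 0), "within")
})

test_that("piecewise-constant square representation matches dense pointwise", {
  set.seed(424)
  for (rep in 1:10) {
    n <- sample(2:50, 1)
    x <- sort(sample.int(3000, n, replace = TRUE))
    X <- position_array(x)
    H <- knn2_bandwidths(X, min(2, n - 1))
    ci <- chrom_info("chr1", 5000)
    pc <- piecewise_constant_kde(X, H, kernel_spec("square"), ci)
    expect_lte(nrow(pc$pieces), 2 * n + 1)
    dense <- adaptive_kde(X, H, kernel_spec("square"), ci)
    at <- dense$start:dense$end
    expect_equal(evaluate_track(pc, at), dense$values, tolerance = 1e-10)
  }
  expect_error(piecewise_constant_kde(position_array(5), 1,
                                      kernel_spec("gaussian"), ci1k), "square")
})

test_that("single-point piecewise examples", {
  pc <- piecewise_constant_kde(position_array(50), 1, kernel_spec("square"), ci1k)
  expect_equal(pc$pieces$start, 47)
  expect_equal(pc$pieces$end, 53)
  expect_equal(pc$pieces$value, 1 / 7)
  pl <- piecewise_linear_kde(position_array(50), 1, kernel_spec("triangle"), ci1k)
  b <- pl$breaks
  expect_equal(b$value[b$pos == 44], 0)
  expect_equal(b$value[b$pos == 50], 1 / 6)
  expect_equal(b$value[b$pos == 56], 0)
  # two disjoint triangles just superpose
  pl2 <- piecewise_linear_kde(position_array(c(50, 500)), c(1, 1),
                              kernel_spec("triangle"), ci1k)
  expect_equal(nrow(pl2$breaks), 6)
  expect_equal(evaluate_track(pl2, c(50, 500)), c(1 / 12, 1 / 12))
})

test_that("piecewise-linear triangle representation matches dense pointwise", {
  set.seed(425)
  for (rep in 1:10) {
    n <- sample(2:40, 1)
    x <- sort(sample.int(2500, n, replace = TRUE))
    X <- position_array(x)
    H <- knn2_bandwidths(X, min(3, n - 1))
    ci <- chrom_info("chr1", 4000)
    pl <- piecewise_linear_kde(X, H, kernel_spec("triangle"), ci)
    dense <- adaptive_kde(X, H, kernel_spec("triangle"), ci)
    at <- dense$start:dense$end
    expect_equal(evaluate_track(pl, at), dense$values, tolerance = 1e-9)
  }
  expect_error(piecewise_linear_kde(position_array(5), 1,
                                    kernel_spec("square"), ci1k), "triangle")
})

test_that("mass is conserved for interior kernels and after blending", {
  set.seed(426)
  # points confined to a 1e4 window in the middle of a 1 Mb chromosome so
  # every kernel support (r <= 6 * max pair distance) stays inside [1, G]
  ci <- chrom_info("chr1", 1e6)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    x <- sort(sample(495000:505000, n, replace = TRUE))
    X <- position_array(x)
    shape <- sample(c("gaussian", "square", "triangle"), 1)
    H <- knn2_bandwidths(X, min(4, n - 1))
    tr <- adaptive_kde(X, H, kernel_spec(shape), ci)
    expect_lt(abs(sum(tr$values) - 1), 1e-6)
    tb <- blend_uniform(tr, mixture_params(0.1, 1e6))
    inside <- sum(tb$values)
    outside <- (1e6 - length(tb$values)) * 0.1 / 1e6
    expect_lt(abs(inside + outside - 1), 1e-6)
  }
})

test_that("KNN2 density is positive everywhere between the extreme points", {
  set.seed(427)
  for (rep in 1:30) {
    k <- sample(2:5, 1)
    x <- rand_gap_instance(k)
    X <- position_array(x)
    H <- knn2_bandwidths(X, k)
    for (shape in c("gaussian", "square", "triangle")) {
      tr <- adaptive_kde(X, H, kernel_spec(shape), chrom_info("chr1", max(x) + 500))
      inner <- evaluate_track(tr, x[1]:x[length(x)])
      expect_gt(min(inner), 0)
    }
  }
})

test_that("piecewise-constant construction is independent of chromosome size", {
  set.seed(428)
  x <- sort(sample.int(10000, 100))
  X <- position_array(x)
  big <- chrom_info("chr1", 2e9 - 1)
  elapsed <- system.time(
    pc <- piecewise_constant_kde(X, 16, kernel_spec("square"), big))[["elapsed"]]
  expect_lte(nrow(pc$pieces), 201)
  expect_lt(elapsed, 5)  # generous: must not scale with G = 2e9
})

test_that("length mismatches and empty inputs are rejected", {
  X <- position_array(c(10, 20))
  expect_error(adaptive_kde(X, c(1, 2, 3), kernel_spec("square"), ci1k),
               "does not match")
  expect_error(position_array(numeric(0)), "at least one")
})
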