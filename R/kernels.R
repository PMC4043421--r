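#' Kernel shape specifications
#'
#' The estimator supports three kernel shapes, each truncated to a finite
#' support expressed in units of the bandwidth `h`: Gaussian (|x| <= 5h),
#' square / Parzen window (|x| <= 3h) and triangle / hat (|x| <= 6h). The
#' bandwidth is interpreted so that the standard deviation of the kernel,
#' viewed as a distribution, is approximately `h` for every shape, which makes
#' tuning curves for different shapes directly comparable.
#'
#' @param shape One of `"gaussian"`, `"square"`, `"triangle"`.
#' @return A `kernel_spec` object with fields `shape` and `support_multiplier`.
#' @examples
#' kernel_spec("gaussian")$support_multiplier  # 5
#' @export
kernel_spec <- function(shape = c("gaussian", "square", "triangle")) {
  shape <- match.arg(shape)
  m <- switch(shape, gaussian = 5, square = 3, triangle = 6)
  structure(list(shape = shape, support_multiplier = m), class = "kernel_spec")
}

# Smallest admissible bandwidth: keeps the support radius >= 1 for all shapes.
H_MIN_KERNEL <- 0.5

# integer codes shared with the C++ kernels
shape_code <- function(shape) match(shape, c("gaussian", "square", "triangle"))

#' Build a discrete, sum-to-one kernel
#'
#' Kernels are normalized *discretely*: the weights at the integer offsets
#' `j = -r, ..., r` (with `r = floor(m * h)`) sum to exactly one, so that a
#' density built from them is a proper probability distribution over integer
#' base-pair positions. Unnormalized weights are `exp(-j^2 / (2 h^2))`
#' (gaussian), `1` (square) and `1 - |j| / (6 h)` (triangle).
#'
#' @param spec A [kernel_spec()].
#' @param h Bandwidth in bp; must be `>= 0.5` and finite.
#' @return A `discrete_kernel` with fields `shape`, `h`, `r` (support radius)
#'   and `half` (weights at offsets `0..r`; the kernel is symmetric).
#' @examples
#' k <- build_kernel(kernel_spec("square"), 1)
#' kernel_weight(k, 0)  # 1/7
#' @export
build_kernel <- function(spec, h) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h)) {
    stopf("bandwidth h must be a single finite number")
  }
  if (h < H_MIN_KERNEL) {
    stopf("bandwidth h = %g below minimum admissible %g", h, H_MIN_KERNEL)
  }
  r <- floor(spec$support_multiplier * h)
  j <- as.numeric(0:r)  # double: j*j overflows integer range for large supports
  raw <- switch(spec$shape,
    gaussian = exp(-(j * j) / (2 * h * h)),
    square   = rep(1, r + 1L),
    triangle = 1 - j / (6 * h)
  )
  # normalizer computed by the shared C++ routine so that table-based (dense)
  # and direct (query) evaluation divide by the identical double
  total <- kernel_total_cpp(shape_code(spec$shape), h, as.integer(r))
  structure(
    list(shape = spec$shape, h = h, r = as.integer(r), half = raw / total),
    class = "discrete_kernel"
  )
}

#' Kernel weight at an integer offset
#'
#' @param kernel A [build_kernel()] result.
#' @param offset Integer offset(s) from the kernel center; offsets beyond the
#'   support radius return exactly 0.
#' @return Probability mass at each offset.
#' @export
kernel_weight <- function(kernel, offset) {
  stopifnot(inherits(kernel, "discrete_kernel"))
  a <- abs(offset)
  w <- numeric(length(a))
  inside <- a <= kernel$r
  w[inside] <- kernel$half[a[inside] + 1L]
  w
}

# Full weight vector at offsets -r..r, used by the dense accumulator.
kernel_full_weights <- function(kernel) {
  if (kernel$r == 0L) return(kernel$half)
  c(rev(kernel$half[-1L]), kernel$half)
}

#' @export
print.discrete_kernel <- function(x, ...) {
  cat(sprintf("<discrete_kernel> %s, h = %g, support +-%d bp, %d offsets\n",
              x$shape, x$h, x$r, 2L * x$r + 1L))
  invisible(x)
}
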