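#' Sorted read-position container
#'
#' Holds the sorted 1-based integer positions `x_1 <= ... <= x_n` on one
#' chromosome that serve as data points for density estimation (typically
#' deduplicated, half-fragment-shifted read starts; see [preprocess()]).
#'
#' @param positions Numeric vector of 1-based integer positions; sorted
#'   internally.
#' @param chrom Chromosome name.
#' @return A `position_array` with fields `chrom`, `positions`, `n`.
#' @export
position_array <- function(positions, chrom = "chr1") {
  if (length(positions) < 1L) stopf("position_array requires at least one position")
  if (any(!is.finite(positions))) stopf("positions must be finite")
  if (any(positions < 1)) stopf("positions must be >= 1 (1-based coordinates)")
  if (any(positions != round(positions))) stopf("positions must be integers")
  structure(
    list(chrom = chrom, positions = as.numeric(sort(positions)),
         n = length(positions)),
    class = "position_array"
  )
}

#' @export
print.position_array <- function(x, ...) {
  cat(sprintf("<position_array> %s: n = %d, range [%g, %g]\n",
              x$chrom, x$n, x$positions[1L], x$positions[x$n]))
  invisible(x)
}

#' Chromosome name and length
#'
#' @param name Chromosome name.
#' @param length Chromosome length `G` in bp; the uniform background density
#'   is `1/G` on `[1, G]`.
#' @return A `chrom_info` object.
#' @export
chrom_info <- function(name, length) {
  if (!is_count(length) || length < 1) stopf("chromosome length must be a positive integer")
  structure(list(name = name, length = as.numeric(length)), class = "chrom_info")
}

as_position_array <- function(X, chrom = "chr1") {
  if (inherits(X, "position_array")) X else position_array(X, chrom)
}
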