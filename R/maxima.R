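# Strict local maxima of a density track: positions b with
# f(b) > f(b - 1) and f(b) > f(b + 1). Plateaus produce no maxima (the
# inequality is strict), so an isolated square kernel -- a flat plateau --
# has zero strict maxima while an isolated gaussian or triangle kernel has
# exactly one. Blending with the uniform background is an increasing affine
# map of the values and cannot change the set of maxima.

new_local_maxima <- function(positions, heights) {
  structure(list(positions = positions, heights = heights,
                 count = length(positions)), class = "local_maxima")
}

#' @export
print.local_maxima <- function(x, ...) {
  cat(sprintf("<local_maxima> NLM = %d%s\n", x$count,
              if (x$count > 0) sprintf(", heights in [%.4g, %.4g]",
                                       min(x$heights), max(x$heights)) else ""))
  invisible(x)
}

#' Strict local maxima of a density track
#'
#' Dense tracks are scanned directly; piecewise representations are scanned
#' analytically (a constant piece can host a strict maximum only if it is a
#' single base flanked by lower values; a linear piece only at breakpoints).
#' Endpoints of the evaluated range are excluded since they lack a
#' two-sided neighborhood.
#'
#' @param track A `kde_track`.
#' @return A `local_maxima` object with `positions` (1-based bp), `heights`
#'   and `count` (the NLM statistic).
#' @export
strict_local_maxima <- function(track) {
  stopifnot(inherits(track, "kde_track"))
  if (track$kind == "dense") {
    v <- track$values
    m <- length(v)
    if (m < 3L) return(new_local_maxima(numeric(0), numeric(0)))
    mid <- 2:(m - 1L)
    is_max <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]
    pos <- (track$start:track$end)[mid][is_max]
    return(new_local_maxima(pos, v[mid][is_max]))
  }
  cand <- if (track$kind == "pconst") {
    p <- track$pieces
    p$start[p$start == p$end]          # only single-base pieces can qualify
  } else {
    track$breaks$pos                   # linear pieces peak only at breakpoints
  }
  cand <- cand[cand - 1 >= 1 & cand + 1 <= track$G]
  if (length(cand) == 0L) return(new_local_maxima(numeric(0), numeric(0)))
  fb <- evaluate_track(track, cand)
  fl <- evaluate_track(track, cand - 1)
  fr <- evaluate_track(track, cand + 1)
  keep <- fb > fl & fb > fr
  new_local_maxima(cand[keep], fb[keep])
}

#' Histogram of local-maxima heights
#'
#' Bins are left-closed right-open, with the last bin closed on both sides.
#'
#' @param maxima A `local_maxima` object.
#' @param bin_edges Ascending bin edges (length `nbins + 1`).
#' @return Integer vector of counts per bin.
#' @export
height_histogram <- function(maxima, bin_edges) {
  stopifnot(inherits(maxima, "local_maxima"))
  if (is.unsorted(bin_edges, strictly = TRUE)) stopf("bin edges must be strictly ascending")
  nb <- length(bin_edges) - 1L
  if (maxima$count == 0L) return(integer(nb))
  idx <- findInterval(maxima$heights, bin_edges, rightmost.closed = TRUE)
  tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
}

#' Export local maxima as BED plus an exact-value TSV sidecar
#'
#' BED intervals are 0-based half-open single bases; the BED score column is
#' the height scaled to 0-1000 per the BED convention, with exact heights in
#' the TSV.
#'
#' @param maxima A `local_maxima` object.
#' @param chrom Chromosome name.
#' @param bed_path,tsv_path Output paths.
#' @export
write_maxima_bed <- function(maxima, chrom, bed_path, tsv_path) {
  stopifnot(inherits(maxima, "local_maxima"))
  score <- if (maxima$count > 0 && max(maxima$heights) > 0) {
    as.integer(round(1000 * maxima$heights / max(maxima$heights)))
  } else integer(0)
  bed <- data.frame(chrom = rep(chrom, maxima$count),
                    start = maxima$positions - 1,
                    end = maxima$positions,
                    name = sprintf("nlm_%d", seq_len(maxima$count)),
                    score = score)
  utils::write.table(bed, bed_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(chrom = rep(chrom, maxima$count),
               pos = maxima$positions, height = fmt_val(maxima$heights)),
    tsv_path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(bed_path)
}
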