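# Reading mapped reads, preprocessing them into density-estimation points,
# and writing browser tracks.
#
# Reads are held as a plain data.frame with columns:
#   chrom  - chromosome name
#   pos5   - 1-based 5'-most genomic coordinate of the read on its strand
#   strand - "+" or "-"
# For a minus-strand BAM alignment the 5' end is the alignment end
# (rightmost aligned base), converted to 1-based.

validate_reads <- function(reads) {
  if (!is.data.frame(reads) || !all(c("chrom", "pos5", "strand") %in% names(reads))) {
    stopf("reads must be a data.frame with columns chrom, pos5, strand")
  }
  if (!all(reads$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (any(reads$pos5 < 1)) stopf("pos5 must be >= 1")
  invisible(reads)
}

#' Load mapped single-end reads for one chromosome
#'
#' @param source Path to a read file.
#' @param format `"bam"` (mapped alignments; index optional) or `"bed"` (a
#'   minimal 3-column whitespace text: chrom, 1-based 5' position, strand).
#' @param chrom Chromosome to load; an error is raised if it is absent from
#'   the file (usually a misnamed chromosome).
#' @return data.frame with columns `chrom`, `pos5`, `strand`; one row per
#'   mapped read on `chrom`.
#' @export
load_reads <- function(source, format = c("bam", "bed"), chrom) {
  format <- match.arg(format)
  if (!file.exists(source)) stopf("read file not found: %s", source)
  if (format == "bam") {
    aln <- GenomicAlignments::readGAlignments(source)
    if (!chrom %in% GenomeInfoDb::seqlevels(aln)) {
      stopf("chromosome '%s' not found in BAM header of %s", chrom, source)
    }
    aln <- aln[as.character(GenomeInfoDb::seqnames(aln)) == chrom]
    if (length(aln) == 0L) stopf("no mapped reads on chromosome '%s' in %s", chrom, source)
    minus <- as.character(BiocGenerics::strand(aln)) == "-"
    pos5 <- ifelse(minus, BiocGenerics::end(aln), BiocGenerics::start(aln))
    reads <- data.frame(chrom = chrom, pos5 = as.numeric(pos5),
                        strand = ifelse(minus, "-", "+"))
  } else {
    tab <- utils::read.table(source, header = FALSE,
                             col.names = c("chrom", "pos5", "strand"),
                             colClasses = c("character", "numeric", "character"))
    if (!chrom %in% tab$chrom) stopf("chromosome '%s' not found in %s", chrom, source)
    reads <- tab[tab$chrom == chrom, , drop = FALSE]
    rownames(reads) <- NULL
  }
  validate_reads(reads)
}

#' Write reads in the minimal 3-column text format
#'
#' @param reads data.frame with columns `chrom`, `pos5`, `strand`.
#' @param path Output path.
#' @export
write_reads <- function(reads, path) {
  validate_reads(reads)
  utils::write.table(reads[, c("chrom", "pos5", "strand")], path,
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Preprocess mapped reads into density-estimation points
#'
#' Collapses duplicate reads (identical chromosome, 5' position and strand --
#' the standard ChIP-seq dedup, applied before shifting), then shifts plus-
#' and minus-strand read starts toward each other by half the mean fragment
#' length (`round(L/2)`, ties up) so both strands point at the underlying
#' binding event, clamps to `[1, G]` and sorts. Distinct reads whose shifted
#' positions coincide are retained.
#'
#' @param reads data.frame of reads on a single chromosome.
#' @param fragment_length Mean sequenced-fragment length `L` in bp (`>= 0`);
#'   this is an input parameter, not estimated here.
#' @param chrom_info A [chrom_info()] supplying the chromosome length.
#' @return A [position_array()] of shifted read starts.
#' @export
preprocess <- function(reads, fragment_length, chrom_info) {
  validate_reads(reads)
  stopifnot(inherits(chrom_info, "chrom_info"))
  if (nrow(reads) == 0L) stopf("no reads to preprocess")
  if (length(unique(reads$chrom)) != 1L) stopf("reads must all be on one chromosome")
  if (!is.numeric(fragment_length) || fragment_length < 0) {
    stopf("fragment_length must be >= 0")
  }
  reads <- reads[!duplicated(reads[, c("pos5", "strand")]), , drop = FALSE]
  shift <- floor(fragment_length / 2 + 0.5)
  pos <- reads$pos5 + ifelse(reads$strand == "+", shift, -shift)
  pos <- pmin(pmax(pos, 1), chrom_info$length)
  position_array(pos, chrom = reads$chrom[1L])
}

fmt_val <- function(v) sprintf("%.12g", v)

#' Write a density track as bedGraph
#'
#' Intervals are 0-based half-open per the bedGraph convention; adjacent
#' equal-value intervals are merged and zero-valued intervals omitted.
#' Values are written with 13 significant digits so they round-trip.
#'
#' @param track A dense or piecewise-constant `kde_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "kde_track"))
  if (track$kind == "plinear") {
    stopf("bedGraph requires a piecewise-constant or dense track")
  }
  if (track$kind == "dense") {
    runs <- rle(track$values)
    ends1 <- track$start - 1 + cumsum(runs$lengths)   # 1-based inclusive ends
    starts1 <- ends1 - runs$lengths + 1
    vals <- runs$values
  } else {
    p <- track$pieces
    starts1 <- p$start; ends1 <- p$end; vals <- p$value
    # merge adjacent pieces that touch with equal value
    if (length(vals) > 1L) {
      same <- c(FALSE, vals[-1L] == vals[-length(vals)] &
                       starts1[-1L] == ends1[-length(ends1)] + 1)
      grp <- cumsum(!same)
      starts1 <- tapply(starts1, grp, min)
      ends1 <- tapply(ends1, grp, max)
      vals <- vals[!same]
    }
  }
  keep <- vals != 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s_density"', track$chrom), con)
  if (any(keep)) {
    writeLines(paste(track$chrom, fmt_val(starts1[keep] - 1),
                     fmt_val(ends1[keep]), fmt_val(vals[keep]),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a dense track as fixedStep WIG (step 1)
#'
#' Dense export for estimates that are not piecewise-simple (e.g. Gaussian
#' kernels): one value per base over the track's evaluated range.
#'
#' @param track A dense `kde_track`.
#' @param path Output path.
#' @export
write_wig_dense <- function(track, path) {
  stopifnot(inherits(track, "kde_track"))
  if (track$kind != "dense" || length(track$values) == 0L) {
    stopf("fixedStep WIG export requires a dense track with a nonempty range")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fixedStep chrom=%s start=%d step=1", track$chrom,
                     as.integer(track$start)), con)
  writeLines(fmt_val(track$values), con)
  invisible(path)
}

# Minimal reader for the two formats written above, for the CLI's
# track-input path. Returns a kde_track (pconst for bedGraph, dense for WIG).
read_track_file <- function(path, G = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stopf("empty track file: %s", path)
  if (startsWith(lines[1L], "track type=bedGraph")) {
    if (length(lines) == 1L) stopf("bedGraph %s has no data lines", path)
    f <- utils::read.table(text = lines[-1L],
                           col.names = c("chrom", "start0", "end", "value"))
    if (is.null(G)) G <- max(f$end)
    ci <- chrom_info(f$chrom[1L], G)
    new_kde_track(ci, "pconst", NA_integer_, NA_real_,
                  pieces = data.frame(start = f$start0 + 1, end = f$end,
                                      value = f$value))
  } else if (startsWith(lines[1L], "fixedStep")) {
    hdr <- strsplit(lines[1L], "\\s+")[[1L]]
    kv <- strsplit(grep("=", hdr, value = TRUE), "=")
    kv <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    start <- as.numeric(kv[["start"]])
    vals <- as.numeric(lines[-1L])
    if (is.null(G)) G <- start + length(vals) - 1
    ci <- chrom_info(kv[["chrom"]], G)
    new_kde_track(ci, "dense", NA_integer_, NA_real_,
                  start = start, end = start + length(vals) - 1, values = vals)
  } else {
    stopf("unrecognized track format in %s", path)
  }
}
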