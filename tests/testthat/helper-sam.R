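# Build a tiny BAM fixture at test time from SAM text (deliverables stay
# text-only; Rsamtools converts in the temp dir).
sam_from_reads <- function(reads, chrom_len, read_len = 36) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", reads$chrom[1], chrom_len))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  # SAM POS is the 1-based leftmost coordinate: pos5 for +, pos5 - len + 1 for -
  pos <- ifelse(reads$strand == "-", reads$pos5 - read_len + 1, reads$pos5)
  body <- sprintf("r%04d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                  seq_len(nrow(reads)), flag, reads$chrom, pos, read_len)
  c(hdr, body)
}

write_bam_fixture <- function(reads, chrom_len, dir = NULL, read_len = 36) {
  if (is.null(dir)) {
    dir <- tempfile("bamfix")
    dir.create(dir)
  }
  sam <- file.path(dir, "fixture.sam")
  writeLines(sam_from_reads(reads, chrom_len, read_len), sam)
  Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE,
                   indexDestination = FALSE)
}
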