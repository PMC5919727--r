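#' Write alignments to a SAM file
#'
#' @param aln alignment tibble (`qname`, `flag`, `rname`, `pos`, `cigar`,
#'   `NM`, `MD`, `seq`).
#' @param path output path (plain-text SAM).
#' @param sq named integer vector of reference (contig) lengths for the
#'   `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, sq) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  recs <- vapply(seq_len(nrow(aln)), function(i) {
    mapped <- bitwAnd(aln$flag[i], 0x4L) == 0L
    fields <- c(aln$qname[i], aln$flag[i],
                if (mapped) aln$rname[i] else "*",
                if (mapped) aln$pos[i] else 0L,
                if (mapped) 60L else 0L,
                if (mapped) aln$cigar[i] else "*",
                "*", 0L, 0L, aln$seq[i], "*")
    if (mapped) {
      fields <- c(fields, sprintf("NM:i:%d", aln$NM[i]),
                  sprintf("MD:Z:%s", aln$MD[i]))
    }
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a SAM file of tag alignments
#'
#' Reads a plain-text SAM through `Rsamtools` (converting to BAM in a
#' temporary directory) and returns the alignment tibble used throughout
#' the divergence module.
#'
#' @param path SAM file path.
#' @return tibble `qname`, `flag`, `rname`, `pos`, `cigar`, `NM`, `MD`,
#'   `seq`.
#' @export
read_sam <- function(path) {
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
                               tag = c("NM", "MD"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble::tibble(qname = x$qname,
                 flag = as.integer(x$flag),
                 rname = as.character(x$rname),
                 pos = x$pos,
                 cigar = x$cigar,
                 NM = if (is.null(x$tag$NM)) NA_integer_ else as.integer(x$tag$NM),
                 MD = if (is.null(x$tag$MD)) NA_character_ else as.character(x$tag$MD),
                 seq = as.character(x$seq))
}
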