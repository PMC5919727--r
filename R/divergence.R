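#' Exhaustive ungapped alignment of tags against a small genome
#'
#' Test-scale aligner: scans both strands of every contig for the best
#' full-length ungapped placement of each tag with at most `max_mismatch`
#' substitutions (ambiguity codes such as `N` match anything and never
#' count as mismatches). Ties are broken toward the plus strand, then the
#' first contig, then the lowest position. Tags with no acceptable
#' placement are reported unmapped.
#'
#' @param tags named [Biostrings::DNAStringSet] of tag sequences.
#' @param genome named [Biostrings::DNAStringSet] of contigs.
#' @param max_mismatch maximum substitutions allowed (default 8).
#' @return alignment tibble: `qname`, `flag` (0 plus / 16 minus / 4
#'   unmapped), `rname`, `pos` (1-based), `cigar`, `NM`, `MD`, `seq` (the
#'   tag as aligned, reverse-complemented on the minus strand).
#' @export
naive_align <- function(tags, genome, max_mismatch = 8) {
  stopifnot(methods::is(tags, "DNAStringSet"), methods::is(genome, "DNAStringSet"))
  out <- vector("list", length(tags))
  for (i in seq_along(tags)) {
    tag <- tags[[i]]
    best <- NULL
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else Biostrings::reverseComplement(tag)
      for (ct in seq_along(genome)) {
        subj <- genome[[ct]]
        if (length(pat) > length(subj)) next
        hits <- Biostrings::matchPattern(pat, subj,
                                         max.mismatch = max_mismatch,
                                         with.indels = FALSE, fixed = FALSE)
        if (length(hits) == 0L) next
        nm <- Biostrings::neditStartingAt(pat, subj,
                                          starting.at = Biostrings::start(hits),
                                          with.indels = FALSE, fixed = FALSE)
        for (h in order(nm)) {
          cand <- list(strand = strand, rname = names(genome)[ct],
                       pos = Biostrings::start(hits)[h], nm = nm[h],
                       ref = as.character(Biostrings::subseq(
                         subj, Biostrings::start(hits)[h],
                         Biostrings::end(hits)[h])),
                       seq = as.character(pat))
          if (is.null(best) || cand$nm < best$nm) best <- cand
          break  # hits already best-first within this contig/strand
        }
      }
    }
    if (is.null(best)) {
      out[[i]] <- tibble::tibble(qname = names(tags)[i], flag = 4L,
                                 rname = NA_character_, pos = NA_integer_,
                                 cigar = NA_character_, NM = NA_integer_,
                                 MD = NA_character_, seq = as.character(tag))
    } else {
      out[[i]] <- tibble::tibble(qname = names(tags)[i],
                                 flag = if (best$strand == "+") 0L else 16L,
                                 rname = best$rname, pos = best$pos,
                                 cigar = paste0(length(tag), "M"),
                                 NM = as.integer(best$nm),
                                 MD = md_string(best$seq, best$ref),
                                 seq = best$seq)
    }
  }
  do.call(rbind, out)
}

# MD tag for an ungapped alignment: runs of matches interleaved with the
# reference base at each mismatch; N on either side counts as a match
md_string <- function(read, ref) {
  r <- strsplit(read, "")[[1]]; f <- strsplit(ref, "")[[1]]
  mism <- r != f & r != "N" & f != "N"
  md <- character(0); run <- 0L
  for (i in seq_along(r)) {
    if (mism[i]) {
      md <- c(md, as.character(run), f[i]); run <- 0L
    } else run <- run + 1L
  }
  paste(c(md, as.character(run)), collapse = "")
}

# parse an MD tag of an ungapped alignment into 1-based mismatch offsets
# along the alignment, with the reference base at each
parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1]]
  pos <- integer(0); base <- character(0); at <- 0L
  for (tk in toks) {
    if (grepl("^\\d+$", tk)) {
      at <- at + as.integer(tk)
    } else if (startsWith(tk, "^")) {
      stop("parse_md: deletion in MD tag; alignment is not ungapped", call. = FALSE)
    } else {
      at <- at + 1L
      pos <- c(pos, at); base <- c(base, tk)
    }
  }
  list(pos = pos, ref = base)
}

#' Keep only primary full-length ungapped alignments
#'
#' An alignment is full-length when its CIGAR is a single match run
#' covering the whole tag (no clipping, no indels). Secondary (0x100),
#' supplementary (0x800) and unmapped (0x4) records are dropped.
#'
#' @param aln alignment tibble (as from [naive_align()] or [read_sam()]).
#' @param tag_len expected tag length (default 92).
#' @param known_tags optional vector of valid tag names; an alignment
#'   referencing an unknown tag errors.
#' @return the retained subset of `aln`.
#' @export
filter_full_length <- function(aln, tag_len = 92, known_tags = NULL) {
  if (!is.null(known_tags) && !all(aln$qname %in% known_tags)) {
    stop("filter_full_length: alignment references unknown tag(s): ",
         paste(setdiff(aln$qname, known_tags), collapse = ", "), call. = FALSE)
  }
  primary <- bitwAnd(aln$flag, bitwOr(0x4L, bitwOr(0x100L, 0x800L))) == 0L
  full <- !is.na(aln$cigar) & aln$cigar == paste0(tag_len, "M")
  aln[primary & full, , drop = FALSE]
}

#' Count tag-versus-genome mismatches in the leading tag window
#'
#' For each (already full-length-filtered) alignment, locates substitutions
#' in tag coordinates and counts those within the first `window` bases of
#' the tag. On minus-strand alignments (flag 0x10) the alignment offset `o`
#' maps to tag position `tag_len - o + 1`. Mismatch evidence is taken from
#' the MD tag when present; otherwise the aligned tag sequence is compared
#' against the supplied genome. Positions where either base is `N` never
#' count.
#'
#' @param aln filtered alignment tibble.
#' @param tag_len tag length (default 92).
#' @param window leading tag bases counted (default 90).
#' @param genome optional [Biostrings::DNAStringSet], required when an
#'   alignment lacks an MD tag.
#' @param n_tags_total total number of tags in the catalog (for the
#'   full-length percentage; defaults to the number of alignments).
#' @return object of class `divergence_report`: `n_tags_total`,
#'   `n_full_length`, `pct_full_length`, `n_mismatches_total`, `per_tag`
#'   (tibble `tag`, `n_mismatch`).
#' @export
count_mismatches <- function(aln, tag_len = 92, window = 90, genome = NULL,
                             n_tags_total = nrow(aln)) {
  n_mm <- integer(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    if (!is.na(aln$MD[i]) && nzchar(aln$MD[i])) {
      md <- parse_md(aln$MD[i])
      off <- md$pos
      refb <- md$ref
      readb <- if (length(off)) substring(aln$seq[i], off, off) else character(0)
    } else if (!is.null(genome)) {
      ct <- genome[[aln$rname[i]]]
      ref <- as.character(Biostrings::subseq(ct, aln$pos[i],
                                             aln$pos[i] + tag_len - 1L))
      r <- strsplit(aln$seq[i], "")[[1]]
      f <- strsplit(ref, "")[[1]]
      off <- which(r != f)
      refb <- f[off]; readb <- r[off]
    } else {
      stop("count_mismatches: alignment for tag ", aln$qname[i],
           " has no MD tag; supply `genome` to compare sequences", call. = FALSE)
    }
    if (length(off)) {
      tagpos <- if (bitwAnd(aln$flag[i], 0x10L) != 0L) tag_len - off + 1L else off
      ok <- refb != "N" & readb != "N" & tagpos <= window
      n_mm[i] <- sum(ok)
    }
  }
  per_tag <- tibble::tibble(tag = aln$qname, n_mismatch = n_mm)
  structure(list(n_tags_total = n_tags_total,
                 n_full_length = nrow(aln),
                 pct_full_length = if (n_tags_total > 0)
                   100 * nrow(aln) / n_tags_total else NA_real_,
                 n_mismatches_total = sum(n_mm),
                 per_tag = per_tag),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("<divergence_report> %d/%d tags full-length (%.1f%%), %d mismatches\n",
              x$n_full_length, x$n_tags_total, x$pct_full_length,
              x$n_mismatches_total))
  invisible(x)
}

#' Tag-versus-genome divergence from alignments
#'
#' Convenience wrapper: [filter_full_length()] then [count_mismatches()],
#' with the catalog size taken from `tags`.
#'
#' @param aln alignment tibble.
#' @param tags named [Biostrings::DNAStringSet] of the tag catalog.
#' @inheritParams count_mismatches
#' @return a `divergence_report`.
#' @export
divergence_report <- function(aln, tags, tag_len = 92, window = 90, genome = NULL) {
  kept <- filter_full_length(aln, tag_len, known_tags = names(tags))
  count_mismatches(kept, tag_len, window, genome, n_tags_total = length(tags))
}
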