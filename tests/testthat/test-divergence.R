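rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
revcomp <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("full-length filter keeps only primary unclipped single-run matches", {
  aln <- tibble::tibble(
    qname = c("1", "2", "3", "4", "5", "6"),
    flag = c(0L, 0L, 16L, 256L, 4L, 0L),
    rname = "contig1", pos = 1L,
    cigar = c("92M", "90M2S", "45M1D47M", "92M", NA, "92M"),
    NM = 0L, MD = "92", seq = strrep("A", 92))
  kept <- filter_full_length(aln, tag_len = 92)
  expect_identical(kept$qname, c("1", "6"))
  expect_error(filter_full_length(aln, known_tags = c("1", "2")),
               "unknown tag")
})

test_that("mismatches are counted in tag coordinates within the 90-base window", {
  seq <- strrep("A", 92)
  # MD: mismatches at alignment offsets 10 and 91 -> only offset 10 counts
  aln <- tibble::tibble(qname = "1", flag = 0L, rname = "c", pos = 1L,
                        cigar = "92M", NM = 2L, MD = "9C80C1", seq = seq)
  rep <- count_mismatches(aln, tag_len = 92, window = 90)
  expect_identical(rep$n_mismatches_total, 2L - 1L)
  # reverse strand: alignment offsets 1 and 2 map to tag positions 92 and 91
  aln_rev <- tibble::tibble(qname = "1", flag = 16L, rname = "c", pos = 1L,
                            cigar = "92M", NM = 2L, MD = "0C0C90", seq = seq)
  expect_identical(count_mismatches(aln_rev)$n_mismatches_total, 0L)
  # same mismatches on the forward strand count
  aln_fwd <- aln_rev; aln_fwd$flag <- 0L
  expect_identical(count_mismatches(aln_fwd)$n_mismatches_total, 2L)
  # N on either side never counts
  aln_n <- tibble::tibble(qname = "1", flag = 0L, rname = "c", pos = 1L,
                          cigar = "92M", NM = 1L, MD = "9N82", seq = seq)
  expect_identical(count_mismatches(aln_n)$n_mismatches_total, 0L)
  # no MD and no genome -> instructive error
  aln_no <- aln; aln_no$MD <- NA_character_
  expect_error(count_mismatches(aln_no), "supply `genome`")
})

test_that("genome-comparison path agrees with the MD path", {
  set.seed(50)
  tag <- rand_dna(92)
  g <- strsplit(tag, "")[[1]]
  g[c(10, 91)] <- vapply(g[c(10, 91)],
                         function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  genome <- Biostrings::DNAStringSet(paste(g, collapse = ""))
  names(genome) <- "c"
  tags <- Biostrings::DNAStringSet(tag); names(tags) <- "1"
  aln <- naive_align(tags, genome)
  via_md <- count_mismatches(aln)
  aln2 <- aln; aln2$MD <- NA_character_
  via_seq <- count_mismatches(aln2, genome = genome)
  expect_identical(via_md$n_mismatches_total, via_seq$n_mismatches_total)
  expect_identical(via_md$n_mismatches_total, 1L)  # offset 91 outside window
})

test_that("naive aligner finds planted placements on both strands and maps mismatches back", {
  set.seed(51)
  tagA <- rand_dna(92); tagB <- rand_dna(92); tagC <- rand_dna(92)
  # B: two substitutions, at tag positions 5 and 92, embedded reverse strand
  b <- strsplit(tagB, "")[[1]]
  for (p in c(5L, 92L)) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  genome <- Biostrings::DNAStringSet(paste0(
    rand_dna(30), tagA, rand_dna(25),
    revcomp(paste(b, collapse = "")), rand_dna(20)))
  names(genome) <- "contig1"
  tags <- Biostrings::DNAStringSet(c(tagA, tagB, tagC))
  names(tags) <- c("1", "2", "3")
  aln <- naive_align(tags, genome, max_mismatch = 4)
  expect_identical(aln$flag, c(0L, 16L, 4L))
  expect_identical(aln$pos[1], 31L)
  expect_identical(aln$NM[1:2], c(0L, 2L))
  rep <- divergence_report(aln, tags)
  expect_identical(rep$n_tags_total, 3L)
  expect_identical(rep$n_full_length, 2L)
  # tag position 92 is outside the window; position 5 counts
  expect_identical(rep$per_tag$n_mismatch, c(0L, 1L))
  expect_identical(rep$n_mismatches_total, 1L)
  # strand symmetry: reverse-complementing the genome leaves the report unchanged
  genome_rc <- Biostrings::reverseComplement(genome)
  names(genome_rc) <- "contig1"
  aln_rc <- naive_align(tags, genome_rc, max_mismatch = 4)
  rep_rc <- divergence_report(aln_rc, tags)
  expect_identical(rep_rc$per_tag$n_mismatch, rep$per_tag$n_mismatch)
  expect_identical(rep_rc$n_full_length, rep$n_full_length)
})

test_that("SAM round trip preserves alignments through Rsamtools", {
  set.seed(52)
  tag <- rand_dna(92)
  genome <- Biostrings::DNAStringSet(paste0(rand_dna(10), tag, rand_dna(10)))
  names(genome) <- "contig1"
  tags <- Biostrings::DNAStringSet(c(tag, rand_dna(92)))
  names(tags) <- c("1", "2")
  aln <- naive_align(tags, genome, max_mismatch = 3)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, sam, sq = setNames(Biostrings::width(genome), names(genome)))
  back <- read_sam(sam)
  m <- match(aln$qname, back$qname)
  expect_identical(back$flag[m], aln$flag)
  mapped <- aln$flag != 4L
  expect_identical(back$pos[m][mapped], aln$pos[mapped])
  expect_identical(back$cigar[m][mapped], aln$cigar[mapped])
  expect_identical(back$MD[m][mapped], aln$MD[mapped])
  expect_identical(back$NM[m][mapped], aln$NM[mapped])
  rep1 <- divergence_report(aln, tags)
  rep2 <- divergence_report(back, tags)
  expect_identical(rep1$n_mismatches_total, rep2$n_mismatches_total)
})
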