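#' Build a synthetic genome assembly containing the tag catalog
#'
#' Embeds each tag's sequence (with planted substitutions, on a random
#' strand) into random-spacer contigs, to exercise the tag-versus-genome
#' divergence counting with known truth. A configurable fraction of tags
#' is left out of the genome or embedded truncated, so the full-length
#' alignment rate is below 100% by construction. Planted substitution
#' positions (in tag coordinates) are logged.
#'
#' @param catalog marker catalog tibble (`tag`, `seq`).
#' @param mismatch_lambda Poisson mean of planted substitutions per
#'   embedded tag (default 0.07, the order seen when a GBS catalog is
#'   compared against an independently derived assembly).
#' @param p_absent probability a tag is absent from the genome.
#' @param p_truncate probability a tag is embedded truncated (first 60
#'   bases only), producing a partial-length alignment.
#' @param spacer_len random bases between embedded tags.
#' @param n_contigs number of contigs.
#' @param window leading tag bases used for the truth table's
#'   `n_mismatch_window` count (default 90).
#' @return list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `truth` (tibble `tag`, `status` in full/truncated/absent, `contig`,
#'   `strand`, `positions` (comma-joined tag coordinates of planted
#'   substitutions), `n_mismatch_window` counting positions <= 90).
#' @export
build_synthetic_genome <- function(catalog, mismatch_lambda = 0.07,
                                   p_absent = 0.05, p_truncate = 0.03,
                                   spacer_len = 40, n_contigs = 2,
                                   window = 90) {
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  n <- nrow(catalog)
  status <- sample(c("full", "truncated", "absent"), n, replace = TRUE,
                   prob = c(1 - p_absent - p_truncate, p_truncate, p_absent))
  contig_of <- sample.int(n_contigs, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  parts <- vector("list", n_contigs)
  for (k in seq_len(n_contigs)) parts[[k]] <- list(rand_seq(spacer_len))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    tagseq <- catalog$seq[i]
    tl <- nchar(tagseq)
    pos_str <- ""
    n_win <- 0L
    if (status[i] == "absent") {
      truth[[i]] <- tibble::tibble(tag = catalog$tag[i], status = "absent",
                                   contig = NA_character_, strand = NA_character_,
                                   positions = "", n_mismatch_window = 0L)
      next
    }
    k <- rpois(1, mismatch_lambda)
    if (status[i] == "truncated") {
      emb <- substr(tagseq, 1, 60)
      k <- 0L
    } else {
      emb <- tagseq
      if (k > 0) {
        pp <- sort(sample.int(tl, min(k, tl)))
        ch <- strsplit(emb, "")[[1]]
        for (p in pp) ch[p] <- sample(setdiff(bases, ch[p]), 1)
        emb <- paste(ch, collapse = "")
        pos_str <- paste(pp, collapse = ",")
        n_win <- sum(pp <= window)
      }
    }
    if (strand[i] == "-") {
      emb <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(emb)))
    }
    ct <- contig_of[i]
    parts[[ct]] <- c(parts[[ct]], list(emb, rand_seq(spacer_len)))
    truth[[i]] <- tibble::tibble(tag = catalog$tag[i], status = status[i],
                                 contig = sprintf("contig%d", ct),
                                 strand = strand[i], positions = pos_str,
                                 n_mismatch_window = n_win)
  }
  genome <- Biostrings::DNAStringSet(vapply(parts, function(p)
    paste(unlist(p), collapse = ""), character(1)))
  names(genome) <- sprintf("contig%d", seq_len(n_contigs))
  list(genome = genome, truth = do.call(rbind, truth))
}

#' Write the complete synthetic fixture set
#'
#' Emits, under `outdir`: `samples.tsv`, `coverage.tsv`, `efforts.tsv`,
#' `genotypes.vcf`, `tags.fasta`, and (when `genome = TRUE`)
#' `genome.fasta` plus `genome_truth.tsv` logging the planted
#' substitutions.
#'
#' @param study a [simulate_colony_study()] result.
#' @param outdir output directory (created if needed).
#' @param genome whether to also build and write a synthetic genome.
#' @param provenance optional named list stamped into every file header.
#' @param ... passed to [build_synthetic_genome()].
#' @return named list of written paths, plus `genome_truth` (tibble) when
#'   a genome was built.
#' @export
write_fixture_set <- function(study, outdir, genome = TRUE,
                              provenance = list(seed = study$cfg$seed), ...) {
  stopifnot(inherits(study, "colony_study"))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("write_fixture_set: cannot create ", outdir, call. = FALSE)
  }
  paths <- list(
    samples = file.path(outdir, "samples.tsv"),
    coverage = file.path(outdir, "coverage.tsv"),
    efforts = file.path(outdir, "efforts.tsv"),
    vcf = file.path(outdir, "genotypes.vcf"),
    tags = file.path(outdir, "tags.fasta")
  )
  write_sample_sheet(study$panel, paths$samples, provenance)
  write_coverage_table(study$coverage, paths$coverage, paths$efforts, provenance)
  write_genotype_vcf(study$gm, paths$vcf, provenance)
  write_tag_fasta(study$pool$catalog, paths$tags)
  if (genome) {
    g <- build_synthetic_genome(study$pool$catalog, ...)
    paths$genome <- file.path(outdir, "genome.fasta")
    paths$genome_truth <- file.path(outdir, "genome_truth.tsv")
    Biostrings::writeXStringSet(g$genome, paths$genome)
    write_tsv_prov(g$truth, paths$genome_truth, provenance)
    paths$genome_truth_table <- g$truth
  }
  paths
}
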