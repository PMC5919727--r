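#' Write a genotype matrix to VCF
#'
#' Biallelic SNPs, `FORMAT GT:DP`. CHROM is the tag (`tag<N>`), POS the
#' 1-based position within the tag, and the tag's chromosome class is
#' carried in `INFO` as `CLASS=`. Hemizygous calls (male X/Y) are encoded
#' haploid (`0` / `1`); zero-copy cells (Y sites in females) and missing
#' haploid calls are `.`, missing diploid calls `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain-text VCF v4.2).
#' @param provenance optional named list written as `##colonysift_<key>=`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path, provenance = NULL) {
  validate_genotype_matrix(gm)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=colonysift %s", as.character(packageVersion("colonysift"))))
  if (!is.null(provenance)) {
    hdr <- c(hdr, sprintf("##colonysift_%s=%s", names(provenance), unlist(provenance)))
  }
  hdr <- c(hdr,
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Chromosome class of the tag (autosomal/X/Y)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  ns <- nrow(gm$sites)
  lines <- character(ns)
  gt_cell <- function(a1, a2, pl) {
    if (pl == 2L) {
      if (is.na(a1)) "./." else paste0(a1, "/", a2)
    } else if (pl == 1L) {
      if (is.na(a1)) "." else as.character(a1)
    } else "."
  }
  for (i in seq_len(ns)) {
    cells <- vapply(seq_along(gm$samples), function(j) {
      dp <- gm$depth[i, j]
      paste0(gt_cell(gm$a1[i, j], gm$a2[i, j], gm$ploidy[i, j]), ":",
             if (is.na(dp)) "." else as.integer(dp))
    }, character(1))
    lines[i] <- paste(c(sprintf("tag%d", gm$sites$tag[i]), gm$sites$pos[i],
                        gm$sites$site_id[i], gm$sites$ref[i], gm$sites$alt[i],
                        ".", "PASS",
                        sprintf("CLASS=%s", gm$sites$class[i]), "GT:DP", cells),
                      collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a genotype matrix from VCF
#'
#' Inverse of [write_genotype_vcf()]. Ploidy is reconstructed from the
#' site's `CLASS` and each individual's sex in the sample sheet, so a `.`
#' at a Y site distinguishes a female (no copy) from a male missing call.
#'
#' @param path VCF path.
#' @param panel sample panel tibble covering every VCF sample.
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  cls <- sub("^.*CLASS=([^;]+).*$", "\\1", v@fix[, "INFO"])
  sites <- tibble::tibble(
    site_id = fix[, "ID"],
    tag = as.integer(sub("^tag", "", fix[, "CHROM"])),
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    class = cls)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  samples <- colnames(gt)
  m <- match(samples, panel$individual)
  if (anyNA(m)) {
    stop("read_genotype_vcf: VCF sample(s) not in sample sheet: ",
         paste(samples[is.na(m)], collapse = ", "), call. = FALSE)
  }
  sex <- panel$sex[m]
  ns <- nrow(sites); ni <- length(samples)
  a1 <- a2 <- matrix(NA_integer_, ns, ni)
  ploidy <- matrix(0L, ns, ni)
  for (j in seq_len(ni)) {
    ploidy[, j] <- copy_number(sites$class, sex[j])
    g <- gt[, j]
    dip <- ploidy[, j] == 2L & !is.na(g) & g != "./." & g != ".|."
    if (any(dip)) {
      parts <- strsplit(g[dip], "[/|]")
      a1[dip, j] <- as.integer(vapply(parts, `[`, character(1), 1L))
      a2[dip, j] <- as.integer(vapply(parts, `[`, character(1), 2L))
    }
    hap <- ploidy[, j] == 1L & !is.na(g) & g != "."
    if (any(hap)) a1[hap, j] <- as.integer(g[hap])
  }
  genotype_matrix(sites, samples, a1, a2, ploidy, depth = dp)
}
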