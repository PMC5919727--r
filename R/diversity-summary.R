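#' Per-colony, per-class diversity summary table
#'
#' One row per colony x chromosome class plus a pooled row (`"all"`,
#' covering every individual including F1 hybrids), with the number of
#' individuals, bases with sufficient coverage to evaluate diversity,
#' private- and polymorphic-site counts, nucleotide diversity and mean
#' heterozygosity at the polymorphic sites. F1 individuals are excluded
#' from single-colony rows; private counts are undefined (`NA`) for the
#' pooled row and heterozygosity is diploid-only (so `NA` for Y when the
#' group carries only hemizygous calls).
#'
#' @param gm QC-filtered [genotype_matrix()].
#' @param coverage the [coverage_table()].
#' @param panel sample panel tibble.
#' @param classes per-tag class annotation tibble (`tag`, `class`).
#' @param min_depth,min_copies,window as in [group_pi()].
#' @return tibble: `colony`, `class`, `n_individuals`, `bases`, `private`,
#'   `polymorphic`, `pi`, `het`.
#' @export
summarize_diversity <- function(gm, coverage, panel, classes,
                                min_depth = 10, min_copies = 2, window = 90) {
  colonies <- setdiff(unique(panel$colony), "F1")
  pp <- list()
  for (cl in CHROM_CLASSES) {
    idx <- gm$sites$class == cl
    pp[[cl]] <- if (any(idx)) polymorphic_and_private(gm, panel, idx) else NULL
  }
  row_for <- function(label, individuals, cl) {
    idx <- gm$sites$class == cl
    gp <- group_pi(gm, coverage, panel, individuals, classes, cl,
                   min_depth, min_copies, window)
    poly <- count_polymorphic(gm, individuals, idx)
    priv <- NA_integer_
    if (label %in% colonies && !is.null(pp[[cl]])) {
      priv <- pp[[cl]]$private[pp[[cl]]$colony == label]
    }
    het <- het_at_poly_sites(gm, individuals, idx)
    tibble::tibble(colony = label, class = cl,
                   n_individuals = length(individuals),
                   bases = gp$bases_evaluated,
                   private = priv, polymorphic = poly,
                   pi = gp$pi, het = het$het)
  }
  out <- list()
  for (colony in colonies) {
    ind <- panel$individual[panel$colony == colony]
    for (cl in CHROM_CLASSES) out[[length(out) + 1L]] <- row_for(colony, ind, cl)
  }
  for (cl in CHROM_CLASSES) {
    out[[length(out) + 1L]] <- row_for("all", panel$individual, cl)
  }
  do.call(rbind, out)
}
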