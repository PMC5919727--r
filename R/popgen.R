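#' Per-site nucleotide diversity
#'
#' Unbiased per-site diversity from allele-copy counts:
#' `pi = n/(n-1) * (1 - sum(p_i^2))` with `n` called copies and `p_i` the
#' sample allele frequencies. Equals the fraction of differing pairs over
#' all unordered pairs of called copies.
#'
#' @param counts numeric vector of per-allele copy counts at one site.
#' @return per-site pi, or `NA` when fewer than two copies are called.
#' @export
site_pi <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# vectorized over sites from a ref/alt count matrix
site_pi_vec <- function(cnt) {
  n <- cnt[, "ref"] + cnt[, "alt"]
  p <- cnt[, "ref"] / n
  q <- cnt[, "alt"] / n
  out <- n / (n - 1) * (1 - p^2 - q^2)
  out[n < 2] <- NA_real_
  out
}

#' Group nucleotide diversity over all evaluable bases
#'
#' Sums per-site pi over the group's called SNPs and divides by the number
#' of evaluable bases, counting invariant bases: a tag is evaluable for the
#' group when at least `min_copies` allele copies pass the depth rule
#' (copies are sex-aware: a male contributes one X/Y copy, a female two X
#' and no Y), and each evaluable tag contributes its first `window` bases.
#' Variant sites additionally need >= 2 called copies at the site itself;
#' sites below that are excluded from the numerator (invariant bases
#' contribute 0).
#'
#' @param gm QC-filtered [genotype_matrix()].
#' @param coverage the [coverage_table()] the depths came from.
#' @param panel sample panel tibble.
#' @param individuals individuals defining the group.
#' @param classes per-tag class annotation tibble (`tag`, `class`).
#' @param class chromosome class to evaluate (`"autosomal"`, `"X"`, `"Y"`).
#' @param min_depth per-individual depth needed for a tag's bases to count
#'   as callable (same rule as the genotype depth filter).
#' @param min_copies minimum called allele copies for an evaluable base.
#' @param window leading tag bases evaluated (default 90).
#' @return list with `pi` (NA when no base is evaluable), `bases_evaluated`,
#'   `n_tags_evaluated`, and `pi_sum` (the numerator).
#' @export
group_pi <- function(gm, coverage, panel, individuals, classes, class,
                     min_depth = 10, min_copies = 2, window = 90) {
  stopifnot(inherits(coverage, "coverage_table"))
  tags_cl <- classes$tag[classes$class == class]
  j <- match(individuals, colnames(coverage$counts))
  if (anyNA(j)) stop("group_pi: individual(s) missing from coverage", call. = FALSE)
  sex <- panel$sex[match(individuals, panel$individual)]
  cn <- copy_number(rep(class, length(sex)), sex)
  ti <- match(as.character(tags_cl), rownames(coverage$counts))
  callable <- coverage$counts[ti, j, drop = FALSE] >= min_depth
  copies <- as.vector(callable %*% cn)
  eval_tags <- tags_cl[copies >= min_copies]
  bases <- length(eval_tags) * as.integer(window)
  si <- gm$sites$class == class & gm$sites$tag %in% eval_tags &
    gm$sites$pos <= window
  pi_sum <- 0
  if (any(si)) {
    cnt <- allele_copy_counts(gm_subset_sites(gm, si), individuals)
    pv <- site_pi_vec(cnt)
    pi_sum <- sum(pv, na.rm = TRUE)
  }
  list(pi = if (bases > 0) pi_sum / bases else NA_real_,
       bases_evaluated = bases,
       n_tags_evaluated = length(eval_tags),
       pi_sum = pi_sum)
}

#' Polymorphic and private site counts per colony
#'
#' A site is polymorphic within a colony when at least two alleles segregate
#' among that colony's called copies; it carries a private allele when the
#' colony holds an allele observed in no other colony. F1 individuals are
#' excluded from colony-level privacy on both sides.
#'
#' @param gm a [genotype_matrix()].
#' @param panel sample panel tibble; colonies are the non-`"F1"` labels.
#' @param site_idx optional logical/integer subset of sites to evaluate.
#' @return tibble with `colony`, `polymorphic`, `private`.
#' @export
polymorphic_and_private <- function(gm, panel, site_idx = NULL) {
  if (!is.null(site_idx)) gm <- gm_subset_sites(gm, site_idx)
  colonies <- setdiff(unique(panel$colony), "F1")
  cnt <- lapply(colonies, function(cl) {
    allele_copy_counts(gm, panel$individual[panel$colony == cl])
  })
  names(cnt) <- colonies
  has_ref <- vapply(cnt, function(m) m[, "ref"] > 0, logical(nrow(gm$sites)))
  has_alt <- vapply(cnt, function(m) m[, "alt"] > 0, logical(nrow(gm$sites)))
  if (nrow(gm$sites) == 1L) {  # vapply drops to vector
    has_ref <- matrix(has_ref, nrow = 1, dimnames = list(NULL, colonies))
    has_alt <- matrix(has_alt, nrow = 1, dimnames = list(NULL, colonies))
  }
  out <- lapply(colonies, function(cl) {
    others <- setdiff(colonies, cl)
    priv_ref <- has_ref[, cl] & !apply(has_ref[, others, drop = FALSE], 1, any)
    priv_alt <- has_alt[, cl] & !apply(has_alt[, others, drop = FALSE], 1, any)
    tibble::tibble(colony = cl,
                   polymorphic = sum(has_ref[, cl] & has_alt[, cl]),
                   private = sum(priv_ref | priv_alt))
  })
  do.call(rbind, out)
}

#' Count polymorphic sites within one group of individuals
#' @inheritParams polymorphic_and_private
#' @param individuals the group.
#' @return integer count of segregating sites.
#' @export
count_polymorphic <- function(gm, individuals, site_idx = NULL) {
  if (!is.null(site_idx)) gm <- gm_subset_sites(gm, site_idx)
  cnt <- allele_copy_counts(gm, individuals)
  sum(cnt[, "ref"] > 0 & cnt[, "alt"] > 0)
}

#' Mean observed heterozygosity at the group's polymorphic sites
#'
#' Per polymorphic site (>= 2 alleles among the group's called copies), the
#' fraction of called diploid individuals that are heterozygous; averaged
#' over those sites. Hemizygous calls are excluded from both numerator and
#' denominator, and sites with no called diploid are excluded (counted in
#' `n_sites_haploid_only`).
#'
#' @param gm a [genotype_matrix()].
#' @param individuals the group.
#' @param site_idx optional site subset.
#' @return list with `het` (NA when no usable polymorphic site),
#'   `n_poly_sites`, `n_sites_haploid_only`.
#' @export
het_at_poly_sites <- function(gm, individuals, site_idx = NULL) {
  if (!is.null(site_idx)) gm <- gm_subset_sites(gm, site_idx)
  cnt <- allele_copy_counts(gm, individuals)
  poly <- cnt[, "ref"] > 0 & cnt[, "alt"] > 0
  if (!any(poly)) {
    return(list(het = NA_real_, n_poly_sites = 0L, n_sites_haploid_only = 0L))
  }
  g <- gm_subset_sites(gm, poly)
  j <- match(individuals, g$samples)
  a1 <- g$a1[, j, drop = FALSE]; a2 <- g$a2[, j, drop = FALSE]
  dip <- g$ploidy[, j, drop = FALSE] == 2L & !is.na(a1)
  n_dip <- rowSums(dip)
  n_het <- rowSums(dip & a1 != a2, na.rm = TRUE)
  usable <- n_dip > 0
  list(het = if (any(usable)) mean(n_het[usable] / n_dip[usable]) else NA_real_,
       n_poly_sites = sum(poly),
       n_sites_haploid_only = sum(!usable))
}
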