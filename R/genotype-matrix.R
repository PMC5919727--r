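#' Genotype matrix container
#'
#' Sites-by-individuals genotype calls with explicit ploidy. Each cell holds
#' up to two allele indices (`0` = ref, `1` = alt, `NA` = no call):
#' diploid cells use `a1`/`a2`, hemizygous cells (male X, male Y) use `a1`
#' only (`a2` is `NA`), and cells with zero copies (female Y) have ploidy 0
#' and both alleles `NA`. `depth` is the per-cell read depth used by the
#' depth filter (may be `NA` before coverage is attached).
#'
#' @param sites tibble with `site_id`, `tag`, `pos`, `ref`, `alt`, `class`.
#' @param samples character vector of individual IDs (column order).
#' @param a1,a2 integer matrices (`nrow(sites)` x `length(samples)`).
#' @param ploidy integer matrix of 2/1/0 per cell.
#' @param depth numeric matrix of per-cell depths, or `NULL`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, a1, a2, ploidy, depth = NULL) {
  sites <- tibble::as_tibble(sites)
  ns <- nrow(sites); ni <- length(samples)
  for (m in list(a1, a2, ploidy)) {
    stopifnot(is.matrix(m), nrow(m) == ns, ncol(m) == ni)
  }
  if (is.null(depth)) depth <- matrix(NA_real_, ns, ni)
  stopifnot(nrow(depth) == ns, ncol(depth) == ni)
  dn <- list(sites$site_id, samples)
  dimnames(a1) <- dimnames(a2) <- dimnames(ploidy) <- dimnames(depth) <- dn
  gm <- structure(list(sites = sites, samples = samples,
                       a1 = a1, a2 = a2, ploidy = ploidy, depth = depth),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d individuals\n",
              nrow(x$sites), length(x$samples)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$sites$class)),
                                  table(x$sites$class)), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a genotype matrix
#'
#' Checks the structural invariants: positions inside the tag, calls only
#' where ploidy allows them (a female may not carry a Y-marker call; ploidy-1
#' cells have no second allele), allele codes in \{0, 1, NA\}, depths
#' non-negative.
#'
#' @param gm a [genotype_matrix()].
#' @return `gm`, invisibly usable; errors describe the violation.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  s <- gm$sites
  if (any(s$pos < 1L)) stop("genotype_matrix: site positions must be >= 1", call. = FALSE)
  ok_allele <- function(m) all(m %in% c(0L, 1L, NA_integer_))
  if (!ok_allele(gm$a1) || !ok_allele(gm$a2)) {
    stop("genotype_matrix: allele codes must be 0, 1 or NA", call. = FALSE)
  }
  if (any(!is.na(gm$a1[gm$ploidy == 0L])) || any(!is.na(gm$a2[gm$ploidy == 0L]))) {
    stop("genotype_matrix: call present in a zero-ploidy cell (e.g. Y marker in a female)",
         call. = FALSE)
  }
  if (any(!is.na(gm$a2[gm$ploidy == 1L]))) {
    stop("genotype_matrix: hemizygous cell carries two alleles", call. = FALSE)
  }
  if (any(gm$depth < 0, na.rm = TRUE)) {
    stop("genotype_matrix: negative depth", call. = FALSE)
  }
  gm
}

#' Subset sites of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @param idx logical or integer site index.
#' @return a [genotype_matrix()] restricted to those sites.
#' @export
gm_subset_sites <- function(gm, idx) {
  structure(list(sites = gm$sites[idx, , drop = FALSE], samples = gm$samples,
                 a1 = gm$a1[idx, , drop = FALSE], a2 = gm$a2[idx, , drop = FALSE],
                 ploidy = gm$ploidy[idx, , drop = FALSE],
                 depth = gm$depth[idx, , drop = FALSE]),
            class = "genotype_matrix")
}

#' Per-site allele-copy counts within a set of individuals
#'
#' Counts called reference and alternate allele copies per site over the
#' given individuals (diploid cells contribute up to two copies, hemizygous
#' cells one).
#'
#' @param gm a [genotype_matrix()].
#' @param individuals character vector of individual IDs (default: all).
#' @return matrix with columns `ref`, `alt` (one row per site).
#' @export
allele_copy_counts <- function(gm, individuals = gm$samples) {
  j <- match(individuals, gm$samples)
  if (anyNA(j)) stop("allele_copy_counts: unknown individual(s): ",
                     paste(individuals[is.na(j)], collapse = ", "), call. = FALSE)
  a1 <- gm$a1[, j, drop = FALSE]; a2 <- gm$a2[, j, drop = FALSE]
  cbind(ref = rowSums(a1 == 0L, na.rm = TRUE) + rowSums(a2 == 0L, na.rm = TRUE),
        alt = rowSums(a1 == 1L, na.rm = TRUE) + rowSums(a2 == 1L, na.rm = TRUE))
}

# dosage (0/1/2) for diploid cells, NA elsewhere / when uncalled
gm_diploid_dosage <- function(gm, individuals = gm$samples) {
  j <- match(individuals, gm$samples)
  d <- gm$a1[, j, drop = FALSE] + gm$a2[, j, drop = FALSE]
  d[gm$ploidy[, j, drop = FALSE] != 2L] <- NA_integer_
  d
}
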