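#' Principal-component analysis of the genotype matrix
#'
#' EIGENSTRAT-style PCA: the diploid dosage matrix (0/1/2 alternate-allele
#' copies) at polymorphic sites of the chosen classes is centered by `2*p`
#' and scaled by `sqrt(p*(1-p))`, with `p` the sample alternate-allele
#' frequency over called copies; missing entries are mean-imputed (zero
#' after centering). The sample-sample covariance (crossproduct over sites,
#' divided by the site count) is eigendecomposed. Hemizygous calls are
#' excluded by default or counted as homozygous diploids
#' (`haploid = "double"`). Each eigenvector is oriented so that its
#' largest-magnitude sample coordinate is positive; percent variance is
#' taken over the positive eigenvalues.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of eigenvectors to return (truncated with a warning if
#'   fewer are available).
#' @param classes chromosome classes of sites to use (default autosomal
#'   only).
#' @param haploid `"exclude"` or `"double"`.
#' @return object of class `pca_result`: `coords` (samples x k, unit-norm
#'   eigenvectors), `eigenvalues`, `pct_var` (over positive eigenvalues,
#'   summing to 100), `n_sites`.
#' @export
genotype_pca <- function(gm, k = 10, classes = "autosomal",
                         haploid = c("exclude", "double")) {
  haploid <- match.arg(haploid)
  if (length(gm$samples) < 2) stop("genotype_pca: need >= 2 samples", call. = FALSE)
  g <- gm_subset_sites(gm, gm$sites$class %in% classes)
  d <- g$a1 + g$a2
  d[g$ploidy != 2L] <- NA_integer_
  if (haploid == "double") {
    hap <- g$ploidy == 1L & !is.na(g$a1)
    d[hap] <- 2L * g$a1[hap]
  }
  called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * called)
  keep <- called > 0 & p > 0 & p < 1
  if (!any(keep)) stop("genotype_pca: no polymorphic site available", call. = FALSE)
  d <- d[keep, , drop = FALSE]; p <- p[keep]
  x <- (d - 2 * p) / sqrt(p * (1 - p))
  x[is.na(x)] <- 0
  n_sites <- nrow(x)
  cv <- crossprod(x) / n_sites
  e <- eigen(cv, symmetric = TRUE)
  pos <- e$values > .Machine$double.eps * max(abs(e$values)) * length(e$values)
  n_avail <- sum(pos)
  if (k > n_avail) {
    warning(sprintf("genotype_pca: only %d informative eigenvectors; k truncated from %d",
                    n_avail, k))
    k <- n_avail
  }
  coords <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(gm$samples, paste0("EV", seq_len(k)))
  pct <- 100 * pmax(e$values, 0) / sum(pmax(e$values, 0))
  structure(list(coords = coords, eigenvalues = e$values, pct_var = pct,
                 n_sites = n_sites, k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d sites; EV1 %.1f%%, EV2 %.1f%% of variance\n",
              nrow(x$coords), x$n_sites, x$pct_var[1],
              if (length(x$pct_var) > 1) x$pct_var[2] else NA))
  invisible(x)
}

#' Test whether F1 hybrids are intermediate to their parent colonies
#'
#' For each F1 individual (panel rows with both `parent1` and `parent2`
#' set) and each of the top `n_ev` eigenvectors, reports whether the F1
#' coordinate lies within the closed interval spanned by the two parental
#' colony centroids. F1s without two labelled parent colonies are skipped
#' with a warning.
#'
#' @param pca a [genotype_pca()] result.
#' @param panel sample panel tibble.
#' @param n_ev number of leading eigenvectors to check (default 2).
#' @return tibble: `individual`, `ev`, `coord`, `lower`, `upper`,
#'   `intermediate`.
#' @export
f1_intermediacy <- function(pca, panel, n_ev = 2) {
  n_ev <- min(n_ev, ncol(pca$coords))
  f1 <- panel[!is.na(panel$parent1) & !is.na(panel$parent2), , drop = FALSE]
  skipped <- setdiff(panel$individual[panel$colony == "F1"], f1$individual)
  if (length(skipped)) {
    warning("f1_intermediacy: skipping F1(s) without two labelled parents: ",
            paste(skipped, collapse = ", "))
  }
  centroid <- function(colony, ev) {
    ids <- panel$individual[panel$colony == colony]
    mean(pca$coords[ids, ev])
  }
  out <- list()
  for (i in seq_len(nrow(f1))) {
    for (ev in seq_len(n_ev)) {
      c1 <- centroid(f1$parent1[i], ev)
      c2 <- centroid(f1$parent2[i], ev)
      coord <- pca$coords[f1$individual[i], ev]
      out[[length(out) + 1L]] <- tibble::tibble(
        individual = f1$individual[i], ev = ev, coord = coord,
        lower = min(c1, c2), upper = max(c1, c2),
        intermediate = coord >= min(c1, c2) & coord <= max(c1, c2))
    }
  }
  do.call(rbind, out)
}
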