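#' Weir-Cockerham F_st between two colonies
#'
#' Per-SNP variance components of Weir & Cockerham's theta for two
#' populations, aggregated as a ratio of sums:
#' `theta = sum(a) / sum(a + b + c)` with `a` the between-population,
#' `b` the between-individual-within-population, and `c` the
#' within-individual component. Autosomal sites use the diploid estimator
#' (which uses observed heterozygosity); X/Y sites use the haploid
#' estimator on allele copies (no within-individual level). Negative
#' per-SNP components are retained; only the final ratio of sums is clamped
#' to `[0, 1]` for reporting.
#'
#' @param gm a [genotype_matrix()].
#' @param panel sample panel tibble.
#' @param colony_a,colony_b colony labels.
#' @param class chromosome class of sites to use (default `"autosomal"`).
#' @return object of class `fst_result`: list with `pair`, `theta`
#'   (clamped), `theta_raw`, and `components` (tibble `site_id`, `a`, `b`,
#'   `c`).
#' @export
pairwise_fst <- function(gm, panel, colony_a, colony_b, class = "autosomal") {
  ind_a <- panel$individual[panel$colony == colony_a]
  ind_b <- panel$individual[panel$colony == colony_b]
  if (!length(ind_a) || !length(ind_b)) {
    stop("pairwise_fst: empty colony", call. = FALSE)
  }
  g <- gm_subset_sites(gm, gm$sites$class == class)
  if (class == "autosomal") {
    comp <- fst_components_diploid(g, ind_a, ind_b)
  } else {
    comp <- fst_components_haploid(g, ind_a, ind_b)
  }
  ok <- !is.na(comp$a)
  comp <- comp[ok, , drop = FALSE]
  denom <- sum(comp$a + comp$b + comp$c)
  if (nrow(comp) == 0L || denom == 0) {
    stop("pairwise_fst: no shared polymorphic site between ", colony_a,
         " and ", colony_b, call. = FALSE)
  }
  theta_raw <- sum(comp$a) / denom
  structure(list(pair = c(colony_a, colony_b),
                 theta = min(1, max(0, theta_raw)),
                 theta_raw = theta_raw,
                 components = comp),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %s vs %s: theta = %.4f (%d sites)\n",
              x$pair[1], x$pair[2], x$theta, nrow(x$components)))
  invisible(x)
}

#' Per-SNP Weir-Cockerham variance components, diploid two-population case
#'
#' For each site, using only called diploid individuals: with `r = 2`
#' populations of sizes `n_i`, alternate-allele frequencies `p_i` and
#' heterozygote fractions `h_i`,
#' `nbar = mean(n_i)`, `pbar = sum(n_i p_i)/(r nbar)`,
#' `s2 = sum(n_i (p_i - pbar)^2) / ((r-1) nbar)`,
#' `hbar = sum(n_i h_i)/(r nbar)`,
#' `nc = (r nbar - sum(n_i^2)/(r nbar)) / (r - 1)`, and
#' \deqn{a = (nbar/nc) [s2 - (pbar(1-pbar) - s2 (r-1)/r - hbar/4)/(nbar-1)]}
#' \deqn{b = nbar/(nbar-1) [pbar(1-pbar) - s2 (r-1)/r - hbar (2 nbar - 1)/(4 nbar)]}
#' \deqn{c = hbar/2.}
#' Sites where either population has no called diploid, or where
#' `nbar <= 1`, yield `NA` components.
#'
#' @param gm a [genotype_matrix()] (already subset to the wanted sites).
#' @param ind_a,ind_b individual IDs of the two populations.
#' @return tibble `site_id`, `a`, `b`, `c`.
#' @export
fst_components_diploid <- function(gm, ind_a, ind_b) {
  stats_one <- function(ind) {
    d <- gm_diploid_dosage(gm, ind)
    n <- rowSums(!is.na(d))
    p <- rowSums(d, na.rm = TRUE) / (2 * n)
    h <- rowSums(d == 1L, na.rm = TRUE) / n
    list(n = n, p = p, h = h)
  }
  A <- stats_one(ind_a); B <- stats_one(ind_b)
  r <- 2
  nbar <- (A$n + B$n) / 2
  valid <- A$n > 0 & B$n > 0 & nbar > 1
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  a[!valid] <- NA_real_; b[!valid] <- NA_real_; c_[!valid] <- NA_real_
  tibble::tibble(site_id = gm$sites$site_id,
                 a = unname(a), b = unname(b), c = unname(c_))
}

#' Per-SNP Weir-Cockerham variance components, haploid allele copies
#'
#' For sex-linked sites all called allele copies are treated as haploid
#' samples (one level of structure): with copy counts `n_i` and frequencies
#' `p_i`, the between-population component is
#' `a = (MSP - MSW)/nc` and the within component `c = MSW`, with
#' `MSP = sum(n_i (p_i - pbar)^2)/(r-1)`,
#' `MSW = sum(n_i p_i (1 - p_i))/(n. - r)`, `pbar = sum(n_i p_i)/n.`,
#' `nc = (n. - sum(n_i^2)/n.)/(r-1)`. `b` is 0 by construction.
#'
#' @inheritParams fst_components_diploid
#' @return tibble `site_id`, `a`, `b`, `c`.
#' @export
fst_components_haploid <- function(gm, ind_a, ind_b) {
  cnt_a <- allele_copy_counts(gm, ind_a)
  cnt_b <- allele_copy_counts(gm, ind_b)
  n1 <- cnt_a[, "ref"] + cnt_a[, "alt"]
  n2 <- cnt_b[, "ref"] + cnt_b[, "alt"]
  p1 <- cnt_a[, "alt"] / n1
  p2 <- cnt_b[, "alt"] / n2
  ntot <- n1 + n2
  r <- 2
  valid <- n1 > 0 & n2 > 0 & ntot > r
  pbar <- (n1 * p1 + n2 * p2) / ntot
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (ntot - r)
  nc <- (ntot - (n1^2 + n2^2) / ntot) / (r - 1)
  a <- (msp - msw) / nc
  a[!valid] <- NA_real_
  c_ <- msw; c_[!valid] <- NA_real_
  tibble::tibble(site_id = gm$sites$site_id,
                 a = unname(a), b = 0, c = unname(c_))
}
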