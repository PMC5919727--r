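test_that("per-site pi matches brute-force pairwise difference rates", {
  expect_equal(site_pi(c(4, 0)), 0)                 # monomorphic
  expect_equal(site_pi(c(2, 2)), 2 / 3)             # 4 of 6 pairs differ
  expect_equal(site_pi(c(1, 1)), 1)                 # single differing pair
  expect_true(is.na(site_pi(c(1, 0))))              # < 2 copies
  set.seed(30)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    copies <- sample(0:1, n, replace = TRUE)
    counts <- c(sum(copies == 0), sum(copies == 1))
    expect_equal(site_pi(counts), brute_pi(copies), tolerance = 1e-14)
  }
})

test_that("group pi divides summed site pi by evaluable bases, counting invariant bases", {
  # 2 evaluable tags x window 50 = 100 bases; one SNP with counts {2,2}
  calls <- matrix(c("0/1", "1/0"), 1, 2)
  gm <- make_test_gm(calls, sexes = c("F", "F"), pos = 10L, tags = 1L)
  counts <- matrix(20L, 2, 2, dimnames = list(c("1", "2"), c("s01", "s02")))
  cov <- coverage_table(counts, c(s01 = 1e6, s02 = 1e6))
  panel <- make_test_panel(c("F", "F"))
  classes <- tibble::tibble(tag = 1:2, class = "autosomal")
  gp <- group_pi(gm, cov, panel, panel$individual, classes, "autosomal",
                 min_depth = 10, window = 50)
  expect_identical(gp$bases_evaluated, 100L)
  expect_equal(gp$pi, (2 / 3) / 100)
  # a tag whose coverage fails the depth rule contributes no bases
  counts2 <- counts; counts2["2", ] <- 5L
  cov2 <- coverage_table(counts2, c(s01 = 1e6, s02 = 1e6))
  gp2 <- group_pi(gm, cov2, panel, panel$individual, classes, "autosomal",
                  min_depth = 10, window = 50)
  expect_identical(gp2$bases_evaluated, 50L)
  # no evaluable base -> undefined
  cov3 <- coverage_table(counts * 0L, c(s01 = 1e6, s02 = 1e6))
  gp3 <- group_pi(gm, cov3, panel, panel$individual, classes, "autosomal")
  expect_true(is.na(gp3$pi))
})

test_that("simulated colony pi matches the analytic expectation from planted frequencies", {
  set.seed(31)
  L <- 2000
  p <- runif(L, 0.1, 0.5)
  n_ind <- 20
  dos <- matrix(rbinom(L * n_ind, 1, p) + rbinom(L * n_ind, 1, p), L, n_ind)
  calls <- matrix(c("0/0", "0/1", "1/1")[dos + 1], L, n_ind)
  gm <- make_test_gm(calls, sexes = rep("F", n_ind), pos = rep(1L, L),
                     tags = seq_len(L))
  counts <- matrix(30L, L, n_ind,
                   dimnames = list(as.character(seq_len(L)),
                                   sprintf("s%02d", seq_len(n_ind))))
  cov <- coverage_table(counts, setNames(rep(1e6, n_ind), colnames(counts)))
  panel <- make_test_panel(rep("F", n_ind))
  classes <- tibble::tibble(tag = seq_len(L), class = "autosomal")
  gp <- group_pi(gm, cov, panel, panel$individual, classes, "autosomal",
                 window = 1)
  n <- 2 * n_ind
  per_site_expect <- 2 * p * (1 - p)  # E[n/(n-1) (1 - sum phat^2)] = 2p(1-p)
  expected <- sum(per_site_expect) / L
  se <- sd(per_site_expect) / sqrt(L)  # conservative MC scale
  expect_lt(abs(gp$pi - expected), 3 * max(se, 0.004))
})

test_that("pi is invariant to individual order and allele-label swaps", {
  calls <- matrix(c("0/1", "0/0", "1/1",
                    "0/0", "0/1", "0/1"), 2, 3, byrow = TRUE)
  gm <- make_test_gm(calls, sexes = rep("F", 3))
  cnt <- allele_copy_counts(gm)
  swapped <- cnt[, c("alt", "ref")]
  colnames(swapped) <- c("ref", "alt")
  expect_equal(apply(cnt, 1, site_pi), apply(swapped, 1, site_pi))
  gm_perm <- gm
  perm <- c(3, 1, 2)
  gm_perm$a1 <- gm$a1[, perm]; gm_perm$a2 <- gm$a2[, perm]
  gm_perm$ploidy <- gm$ploidy[, perm]; gm_perm$samples <- gm$samples[perm]
  expect_equal(allele_copy_counts(gm_perm)[, "alt"], cnt[, "alt"])
})

test_that("polymorphic and private site counts match planted truth", {
  # 3 colonies x 2 diploids; alleles planted per site
  calls <- matrix(c(
    # c1      c1     c2     c2     c3     c3
    "0/1",  "0/0", "0/0", "0/0", "0/0", "0/0",  # alt private to c1, poly c1
    "0/0",  "0/0", "0/0", "0/0", "0/0", "0/0",  # fixed ref everywhere
    "1/1",  "1/1", "0/1", "0/1", "1/1", "1/1",  # ref private to c2, poly c2
    "0/1",  "0/1", "0/1", "0/0", "0/0", "1/1"   # shared, poly in all
  ), 4, 6, byrow = TRUE)
  gm <- make_test_gm(calls, sexes = rep("F", 6))
  panel <- make_test_panel(rep("F", 6),
                           colony = rep(c("c1", "c2", "c3"), each = 2))
  pp <- polymorphic_and_private(gm, panel)
  expect_identical(pp$polymorphic[pp$colony == "c1"], 2L)
  expect_identical(pp$polymorphic[pp$colony == "c2"], 2L)
  expect_identical(pp$polymorphic[pp$colony == "c3"], 1L)
  expect_identical(pp$private[pp$colony == "c1"], 1L)
  expect_identical(pp$private[pp$colony == "c2"], 1L)
  expect_identical(pp$private[pp$colony == "c3"], 0L)
  # private attributions are exclusive across colonies at a biallelic site
  expect_lte(sum(pp$private), 2L * nrow(gm$sites))
})

test_that("pooled polymorphic count dominates every colony's count", {
  cfg <- sim_config(n_markers_per_class = c(autosomal = 300L, X = 50L, Y = 50L),
                    monomorphic_fraction = 0.5, seed = 32)
  study <- simulate_colony_study(cfg)
  qc <- apply_genotype_qc(study$gm)
  idx <- qc$gm$sites$class == "autosomal"
  pooled <- count_polymorphic(qc$gm, study$panel$individual, idx)
  for (colony in setdiff(unique(study$panel$colony), "F1")) {
    ind <- study$panel$individual[study$panel$colony == colony]
    expect_gte(pooled, count_polymorphic(qc$gm, ind, idx))
  }
})

test_that("heterozygosity at polymorphic sites is diploid-only", {
  calls <- matrix(c("0/1", "0/1", "0/1", "0/0", "0/0",
                    "0/0", "0/0", "0/0", "0/0", "0/0"),
                  2, 5, byrow = TRUE)
  gm <- make_test_gm(calls, sexes = rep("F", 5))
  h <- het_at_poly_sites(gm, gm$samples)
  expect_equal(h$het, 0.6)
  expect_identical(h$n_poly_sites, 1L)
  # all-monomorphic group -> undefined
  gm0 <- make_test_gm(matrix("0/0", 2, 3), sexes = rep("F", 3))
  expect_true(is.na(het_at_poly_sites(gm0, gm0$samples)$het))
  # haploid-only site excluded and counted
  gmy <- make_test_gm(matrix(c("0", "1", "0"), 1, 3),
                      sexes = rep("M", 3), classes = "Y")
  hy <- het_at_poly_sites(gmy, gmy$samples)
  expect_true(is.na(hy$het))
  expect_identical(hy$n_sites_haploid_only, 1L)
})

test_that("Hardy-Weinberg heterozygosity at p = 0.5 averages one half", {
  set.seed(33)
  L <- 2000; n_ind <- 50
  dos <- matrix(rbinom(L * n_ind, 2, 0.5), L, n_ind)
  calls <- matrix(c("0/0", "0/1", "1/1")[dos + 1], L, n_ind)
  gm <- make_test_gm(calls, sexes = rep("F", n_ind))
  h <- het_at_poly_sites(gm, gm$samples)
  se <- sqrt(0.5 * 0.5 / n_ind / L)
  expect_lt(abs(h$het - 0.5), 3 * se * 2)  # factor 2: site-level correlation
})

test_that("Weir-Cockerham theta hits the fixed-difference and panmictic limits", {
  calls_fix <- cbind(matrix("0/0", 2, 10), matrix("1/1", 2, 10))
  gm <- make_test_gm(calls_fix, sexes = rep("F", 20))
  panel <- make_test_panel(rep("F", 20), colony = rep(c("a", "b"), each = 10))
  fst <- pairwise_fst(gm, panel, "a", "b")
  expect_equal(fst$theta, 1)
  set.seed(34)
  L <- 3000; n <- 30
  p <- runif(L, 0.2, 0.8)
  dos <- matrix(rbinom(L * 2 * n, 2, p), L, 2 * n)
  calls <- matrix(c("0/0", "0/1", "1/1")[dos + 1], L, 2 * n)
  gm2 <- make_test_gm(calls, sexes = rep("F", 2 * n))
  panel2 <- make_test_panel(rep("F", 2 * n), colony = rep(c("a", "b"), each = n))
  fst2 <- pairwise_fst(gm2, panel2, "a", "b")
  expect_lt(abs(fst2$theta_raw), 0.01)
  # no shared polymorphic site -> error
  gm3 <- make_test_gm(matrix("0/0", 1, 4), sexes = rep("F", 4))
  panel3 <- make_test_panel(rep("F", 4), colony = rep(c("a", "b"), each = 2))
  expect_error(pairwise_fst(gm3, panel3, "a", "b"), "no shared polymorphic")
})

test_that("diploid variance components agree with the nested-ANOVA oracle on random configurations", {
  set.seed(35)
  for (i in 1:50) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    dos_a <- sample(0:2, na, replace = TRUE)
    dos_b <- sample(0:2, nb, replace = TRUE)
    calls <- matrix(c("0/0", "0/1", "1/1")[c(dos_a, dos_b) + 1], 1)
    gm <- make_test_gm(calls, sexes = rep("F", na + nb))
    comp <- fst_components_diploid(gm, gm$samples[1:na],
                                   gm$samples[(na + 1):(na + nb)])
    oracle <- wc_anova_oracle(dos_a, dos_b)
    expect_equal(comp$a, oracle$a, tolerance = 1e-12)
    expect_equal(comp$b, oracle$b, tolerance = 1e-12)
    expect_equal(comp$c, oracle$c, tolerance = 1e-12)
  }
})

test_that("diversity summary table has colony x class rows plus a pooled row including F1s", {
  cfg <- sim_config(n_markers_per_class = c(autosomal = 300L, X = 60L, Y = 60L),
                    monomorphic_fraction = 0.5, seed = 36)
  study <- simulate_colony_study(cfg)
  qc <- apply_genotype_qc(study$gm)
  classes <- study$pool$catalog[, c("tag", "class")]
  tab <- summarize_diversity(qc$gm, study$coverage, study$panel, classes)
  expect_identical(nrow(tab), 12L)  # 3 colonies x 3 classes + pooled x 3
  pooled <- tab[tab$colony == "all", ]
  expect_true(all(pooled$n_individuals == nrow(study$panel)))
  expect_true(all(is.na(pooled$private)))
  ok <- !is.na(tab$pi)
  expect_true(all(tab$pi[ok] >= 0 & tab$pi[ok] <= 1))
  expect_true(all(tab$polymorphic <= tab$bases))
  # Y heterozygosity is undefined without diploid carriers
  expect_true(all(is.na(tab$het[tab$class == "Y"])))
})
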