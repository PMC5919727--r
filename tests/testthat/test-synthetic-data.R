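test_that("founder pool is seed-reproducible and respects the frequency support", {
  cfg <- sim_config(n_markers_per_class = c(autosomal = 500L, X = 50L, Y = 50L),
                    monomorphic_fraction = 0.5, seed = 1)
  p1 <- simulate_founder_pool(cfg)
  p2 <- simulate_founder_pool(cfg)
  expect_identical(p1$catalog, p2$catalog)
  expect_identical(p1$sites, p2$sites)
  expect_true(all(p1$sites$freq > 0.05 & p1$sites$freq < 0.5))
  expect_true(all(p1$sites$pos >= 1 & p1$sites$pos <= cfg$tag_length))
  # ref allele matches the catalog sequence at the SNP position
  seq_at <- substring(p1$catalog$seq[match(p1$sites$tag, p1$catalog$tag)],
                      p1$sites$pos, p1$sites$pos)
  expect_identical(p1$sites$ref, seq_at)
  expect_true(all(p1$sites$alt != p1$sites$ref))

  mono <- simulate_founder_pool(
    sim_config(n_markers_per_class = c(autosomal = 200L, X = 0L, Y = 0L),
               monomorphic_fraction = 1, seed = 2))
  expect_identical(nrow(mono$sites), 0L)
})

test_that("uniform founder frequencies have the closed-form mean", {
  cfg <- sim_config(n_markers_per_class = c(autosomal = 10000L, X = 0L, Y = 0L),
                    monomorphic_fraction = 0, snps_per_marker = 1,
                    allele_freq_dist = list(type = "uniform", min = 0.05, max = 0.5),
                    seed = 3)
  pool <- simulate_founder_pool(cfg)
  f <- pool$sites$freq
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.275), 3 * se)
})

test_that("drift keeps frequencies in [0,1], fixes absorbed alleles, and decays heterozygosity geometrically", {
  set.seed(10)
  L <- 5000
  p0 <- c(0, 1, runif(L - 2, 0.2, 0.8))
  hist <- colony_history("c", founder_n = 5000, drift_generations = 8,
                         census_size = 25)
  p1 <- drift_frequencies(p0, rep("autosomal", L), hist)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1[1:2], c(0, 1))
  h0 <- 2 * p0 * (1 - p0); h1 <- 2 * p1 * (1 - p1)
  expected_ratio <- (1 - 1 / (2 * 5000)) * (1 - 1 / (2 * 25))^8
  se <- sd(h1) / sqrt(L) / mean(h0)
  expect_lt(abs(mean(h1) / mean(h0) - expected_ratio), 3 * se)
})

test_that("no drift from a huge founder pool leaves pool frequencies unchanged in expectation", {
  set.seed(11)
  L <- 3000
  p0 <- runif(L, 0.2, 0.8)
  hist <- colony_history("c", founder_n = 2e5, drift_generations = 0,
                         census_size = 10)
  p1 <- drift_frequencies(p0, rep("autosomal", L), hist)
  expect_lt(max(abs(p1 - p0)), 0.01)
})

test_that("sampled genotypes respect sex-dependent copy number", {
  cfg <- sim_config(n_markers_per_class = c(autosomal = 50L, X = 50L, Y = 50L),
                    monomorphic_fraction = 0, seed = 4)
  pool <- simulate_founder_pool(cfg)
  hist <- colony_history("c", founder_n = 20, drift_generations = 2,
                         census_size = 20)
  res <- simulate_colony_genotypes(pool, hist, c(F = 4L, M = 3L))
  gm <- res$gm
  n_f <- 4L; n_m <- 3L
  x <- gm$sites$class == "X"
  y <- gm$sites$class == "Y"
  x_copies <- rowSums(!is.na(gm$a1[x, , drop = FALSE])) +
    rowSums(!is.na(gm$a2[x, , drop = FALSE]))
  expect_true(all(x_copies == 2L * n_f + n_m))
  y_copies <- rowSums(!is.na(gm$a1[y, , drop = FALSE])) +
    rowSums(!is.na(gm$a2[y, , drop = FALSE]))
  expect_true(all(y_copies == n_m))

  females_only <- simulate_colony_genotypes(pool, hist, c(F = 5L, M = 0L))
  gmf <- females_only$gm
  yf <- gmf$sites$class == "Y"
  expect_true(all(gmf$ploidy[yf, ] == 0L))
  expect_true(all(is.na(gmf$a1[yf, ])))
})

test_that("a call planted in a zero-ploidy cell is rejected", {
  gm <- make_test_gm(matrix("0/1", 1, 2), sexes = c("F", "F"))
  gm$sites$class <- "Y"
  gm$ploidy[] <- 0L
  gm$a1[1, 1] <- 0L
  expect_error(validate_genotype_matrix(gm), "zero-ploidy")
})

test_that("coverage follows copy number: zero in females at Y tags, half male depth at X tags", {
  cfg <- sim_config(n_markers_per_class = c(autosomal = 200L, X = 2000L, Y = 200L),
                    monomorphic_fraction = 1, seed = 5)
  set.seed(cfg$seed)
  catalog <- simulate_marker_catalog(cfg)
  panel <- make_test_panel(rep(c("F", "M"), each = 6))
  cov <- simulate_coverage(catalog, panel, cfg)
  y <- catalog$class == "Y"
  expect_true(all(cov$counts[y, panel$sex == "F"] == 0L))
  std <- standardize_coverage(cov, panel)
  x <- catalog$class == "X"
  ratio <- mean(std$cov_male[x]) / mean(std$cov_female[x])
  expect_lt(abs(ratio - 0.5), 0.02)
})

test_that("zero dispersion and zero lognormal noise give deterministic rounded depth", {
  cfg <- sim_config(n_markers_per_class = c(autosomal = 20L, X = 10L, Y = 10L),
                    depth_dispersion = 0, tag_log_sd = 0, effort_log_sd = 0,
                    mean_tag_depth = 33, monomorphic_fraction = 1, seed = 6)
  set.seed(cfg$seed)
  catalog <- simulate_marker_catalog(cfg)
  panel <- make_test_panel(c("F", "M"))
  cov <- simulate_coverage(catalog, panel, cfg)
  for (j in 1:2) {
    mu <- 33 * copy_number(catalog$class, panel$sex[j]) / 2
    expect_identical(unname(cov$counts[, j]), as.integer(round(mu)))
  }
})

test_that("a seeded study is bit-reproducible", {
  cfg <- sim_config(n_markers_per_class = c(autosomal = 80L, X = 20L, Y = 20L),
                    monomorphic_fraction = 0.7, seed = 7)
  s1 <- simulate_colony_study(cfg)
  s2 <- simulate_colony_study(cfg)
  expect_identical(s1$gm$a1, s2$gm$a1)
  expect_identical(s1$coverage$counts, s2$coverage$counts)
  expect_identical(s1$panel, s2$panel)
})

test_that("fixture set round-trips and logs planted truth; empty catalogs write valid headers", {
  cfg <- sim_config(n_markers_per_class = c(autosomal = 60L, X = 15L, Y = 15L),
                    monomorphic_fraction = 0.6, seed = 8)
  study <- simulate_colony_study(cfg)
  out <- withr::local_tempdir()
  paths <- write_fixture_set(study, out)
  panel2 <- read_sample_sheet(paths$samples)
  expect_equal(as.data.frame(panel2), as.data.frame(study$panel))
  cov2 <- read_coverage_table(paths$coverage, paths$efforts)
  expect_identical(cov2$counts, study$coverage$counts)
  expect_equal(cov2$effort, study$coverage$effort, tolerance = 1e-12)
  gm2 <- read_genotype_vcf(paths$vcf, panel2)
  expect_identical(gm2$a1, study$gm$a1)
  expect_identical(gm2$a2, study$gm$a2)
  expect_identical(gm2$ploidy, study$gm$ploidy)
  cat2 <- read_tag_fasta(paths$tags)
  expect_identical(cat2$seq, study$pool$catalog$seq)
  expect_identical(cat2$class, study$pool$catalog$class)

  # planted mismatches are recoverable from the synthetic genome
  truth <- paths$genome_truth_table
  genome <- Biostrings::readDNAStringSet(paths$genome)
  rep <- divergence_report(
    naive_align(tags_as_stringset(study$pool$catalog), genome),
    tags_as_stringset(study$pool$catalog))
  full <- truth[truth$status == "full", ]
  got <- rep$per_tag$n_mismatch[match(full$tag, as.integer(rep$per_tag$tag))]
  expect_identical(got, full$n_mismatch_window)

  # empty marker set
  cfg0 <- sim_config(n_markers_per_class = c(autosomal = 0L, X = 0L, Y = 0L),
                     seed = 9)
  study0 <- simulate_colony_study(cfg0)
  out0 <- withr::local_tempdir()
  p0 <- write_fixture_set(study0, out0, genome = FALSE)
  expect_identical(nrow(read_coverage_table(p0$coverage, p0$efforts)$counts), 0L)
  vcf_lines <- readLines(p0$vcf)
  expect_true(any(startsWith(vcf_lines, "#CHROM")))
  expect_false(any(!startsWith(vcf_lines, "#")))
})
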