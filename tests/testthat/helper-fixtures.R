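# Small in-code fixture builders shared by the test files.

# Build a genotype_matrix from a character matrix of VCF-style calls
# ("0/1", "1/1", "./.", "0", "1", ".") with per-site classes and per-sample
# sexes. Ploidy is derived from class and sex; "." in a zero-ploidy cell is
# an absent call, elsewhere a missing call.
make_test_gm <- function(calls, sexes, classes = rep("autosomal", nrow(calls)),
                         pos = NULL, tags = NULL, depth = NULL) {
  calls <- as.matrix(calls)
  ns <- nrow(calls); ni <- ncol(calls)
  if (is.null(pos)) pos <- rep(1L, ns)
  if (is.null(tags)) tags <- seq_len(ns)
  samples <- colnames(calls)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ni))
  a1 <- a2 <- matrix(NA_integer_, ns, ni)
  ploidy <- matrix(0L, ns, ni)
  for (j in seq_len(ni)) {
    ploidy[, j] <- colonysift::copy_number(classes, sexes[j])
    for (i in seq_len(ns)) {
      g <- calls[i, j]
      if (ploidy[i, j] == 2L && grepl("/", g) && g != "./.") {
        ab <- strsplit(g, "/")[[1]]
        a1[i, j] <- as.integer(ab[1]); a2[i, j] <- as.integer(ab[2])
      } else if (ploidy[i, j] == 1L && g %in% c("0", "1")) {
        a1[i, j] <- as.integer(g)
      }
    }
  }
  sites <- tibble::tibble(site_id = sprintf("tag%d_%d", tags, pos),
                          tag = tags, pos = pos, ref = "A", alt = "C",
                          class = classes)
  colonysift::genotype_matrix(sites, samples, a1, a2, ploidy, depth)
}

make_test_panel <- function(sexes, colony = "c1", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(sexes))
  tibble::tibble(individual = ids, sex = sexes,
                 colony = rep_len(colony, length(sexes)),
                 parent1 = NA_character_, parent2 = NA_character_)
}

# Independently coded textbook oracle for the two-population diploid
# Weir-Cockerham variance components: nested ANOVA on allele indicators
# (pops / individuals / copies), components from the mean squares. Input:
# two integer dosage vectors (0/1/2 per individual).
wc_anova_oracle <- function(dos_a, dos_b) {
  copies <- function(dos) lapply(dos, function(d) {
    switch(as.character(d), "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
  })
  ya <- copies(dos_a); yb <- copies(dos_b)
  r <- 2
  n1 <- length(ya); n2 <- length(yb); ntot <- n1 + n2
  all_y <- c(unlist(ya), unlist(yb))
  gmean <- mean(all_y)
  pop_mean <- c(mean(unlist(ya)), mean(unlist(yb)))
  ssg <- ssi <- 0
  for (pop in 1:2) {
    yy <- if (pop == 1) ya else yb
    for (ind in yy) {
      ssg <- ssg + sum((ind - mean(ind))^2)
      ssi <- ssi + 2 * (mean(ind) - pop_mean[pop])^2
    }
  }
  ssp <- 2 * (n1 * (pop_mean[1] - gmean)^2 + n2 * (pop_mean[2] - gmean)^2)
  msg <- ssg / ntot
  msi <- ssi / (ntot - r)
  msp <- ssp / (r - 1)
  nc <- (ntot - (n1^2 + n2^2) / ntot) / (r - 1)
  list(a = (msp - msi) / (2 * nc), b = (msi - msg) / 2, c = msg)
}

random_diploid_gm <- function(L, n, seed, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(L, 0.1, 0.9)
  dos <- matrix(rbinom(L * n, 2, p), L, n)
  make_test_gm(matrix(c("0/0", "0/1", "1/1")[dos + 1], L, n),
               sexes = rep("F", n))
}

# independent dense PCA oracle: same normalization, coordinates via svd of
# the centered/scaled site-by-sample matrix instead of eigen of the
# covariance
pca_svd_oracle <- function(gm, k) {
  d <- gm$a1 + gm$a2
  called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * called)
  keep <- p > 0 & p < 1
  d <- d[keep, , drop = FALSE]; p <- p[keep]
  x <- (d - 2 * p) / sqrt(p * (1 - p))
  x[is.na(x)] <- 0
  sv <- svd(x)
  v <- sv$v[, seq_len(k), drop = FALSE]
  list(coords = v, values = sv$d^2 / nrow(x))
}

# brute-force per-site pi: fraction of differing unordered pairs of copies
brute_pi <- function(copies) {
  n <- length(copies)
  if (n < 2) return(NA_real_)
  diff <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (copies[i] != copies[j]) diff <- diff + 1
  }
  diff / tot
}
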