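#' Simulate the marker catalog
#'
#' Random fixed-length tag sequences with chromosome-class labels
#' (autosomal / X / Y) in the configured proportions. Tag IDs are the
#' integers `1..n_tags` in catalog order.
#'
#' @param cfg a [sim_config()].
#' @return tibble with columns `tag` (integer ID), `class`, `seq`.
#' @export
simulate_marker_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_markers_per_class
  class <- rep(names(n), times = n)
  n_tags <- length(class)
  seqs <- vapply(seq_len(n_tags), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$tag_length, replace = TRUE), collapse = "")
  }, character(1))
  tibble::tibble(tag = seq_len(n_tags), class = class, seq = seqs)
}

draw_allele_freqs <- function(n, dist) {
  if (n == 0L) return(numeric(0))
  switch(dist$type,
    uniform = runif(n, dist$min, dist$max),
    beta = rbeta(n, dist$shape1, dist$shape2),
    stop("unknown allele frequency distribution: ", dist$type, call. = FALSE)
  )
}

#' Simulate the founder (base-pool) allele frequencies
#'
#' Seeds the RNG from `cfg$seed`, generates a marker catalog, chooses which
#' tags are polymorphic in the base pool (`1 - monomorphic_fraction` of
#' them), places one or two SNPs per polymorphic tag within the tag, and
#' draws each SNP's alternate-allele frequency from the configured
#' distribution. Monomorphic tags carry no site rows (their alternate-allele
#' frequency is 0 everywhere, so downstream diversity from them is 0).
#'
#' @param cfg a [sim_config()].
#' @return object of class `founder_pool`: list with `catalog` (see
#'   [simulate_marker_catalog()]), `sites` (tibble `site_id`, `tag`,
#'   `class`, `pos`, `ref`, `alt`, `freq` with `freq` in (0,1)), and `cfg`.
#' @export
simulate_founder_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  catalog <- simulate_marker_catalog(cfg)
  n_tags <- nrow(catalog)
  poly <- runif(n_tags) >= cfg$monomorphic_fraction
  poly_tags <- catalog$tag[poly]
  extra <- rbinom(length(poly_tags), 1L, cfg$snps_per_marker - 1)
  tag_of_site <- rep(poly_tags, times = 1L + extra)
  n_sites <- length(tag_of_site)
  if (n_sites == 0L) {
    sites <- tibble::tibble(site_id = character(0), tag = integer(0),
                            class = character(0), pos = integer(0),
                            ref = character(0), alt = character(0),
                            freq = numeric(0))
    return(structure(list(catalog = catalog, sites = sites, cfg = cfg),
                     class = "founder_pool"))
  }
  # distinct positions within a tag: sample without replacement per tag
  pos <- integer(n_sites)
  for (t in unique(tag_of_site)) {
    idx <- which(tag_of_site == t)
    pos[idx] <- sort(sample.int(cfg$tag_length, length(idx)))
  }
  tagseq <- catalog$seq[match(tag_of_site, catalog$tag)]
  ref <- substring(tagseq, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1), USE.NAMES = FALSE)
  sites <- tibble::tibble(
    site_id = sprintf("tag%d_%d", tag_of_site, pos),
    tag = tag_of_site,
    class = catalog$class[match(tag_of_site, catalog$tag)],
    pos = pos,
    ref = ref,
    alt = alt,
    freq = draw_allele_freqs(n_sites, cfg$allele_freq_dist)
  )
  ord <- order(sites$tag, sites$pos)
  sites <- sites[ord, ]
  structure(list(catalog = catalog, sites = sites, cfg = cfg),
            class = "founder_pool")
}
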