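#' Simulation configuration
#'
#' Parameters of the synthetic GBS study generator. Defaults emulate the
#' study conditions of a small multi-colony gerbil panel: 92-bp tags, a mean
#' sequencing effort of 7.8 million reads per individual, a marker catalog
#' that is overwhelmingly monomorphic (97% of tags carry no SNP), and
#' overdispersed per-tag read depth.
#'
#' Depth overdispersion has two sources, reflecting how GBS depth behaves:
#' a per-tag capture-efficiency multiplier (lognormal with `tag_log_sd`,
#' shared by all individuals at that tag; restriction-site and GC effects)
#' and a residual per-individual negative-binomial dispersion
#' (`depth_dispersion`; `0` means depth is the rounded expectation).
#'
#' @param n_markers_per_class named integer vector: tags per chromosome
#'   class (`autosomal`, `X`, `Y`).
#' @param tag_length tag length in bases (>= 3).
#' @param allele_freq_dist founder-pool minor-allele-frequency distribution
#'   for polymorphic sites: `list(type = "uniform", min=, max=)` or
#'   `list(type = "beta", shape1=, shape2=)`.
#' @param monomorphic_fraction fraction of tags with no segregating SNP in
#'   the founder pool.
#' @param snps_per_marker mean SNPs per polymorphic tag (>= 1; extra SNPs
#'   beyond the first are added with probability `snps_per_marker - 1`).
#' @param mean_effort mean total reads per individual.
#' @param effort_log_sd lognormal sd of per-individual sequencing effort.
#' @param mean_tag_depth expected reads per tag for a diploid individual at
#'   mean effort and average capture efficiency.
#' @param depth_dispersion negative-binomial dispersion of per-cell depth
#'   (variance = mu + dispersion * mu^2); `0` gives `round(mu)`.
#' @param tag_log_sd lognormal sdlog of the per-tag capture-efficiency
#'   multiplier (mean 1).
#' @param missing_rate probability that an otherwise callable genotype is
#'   dropped.
#' @param seed mandatory RNG seed (integer).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_markers_per_class = c(autosomal = 3000L, X = 300L, Y = 300L),
                       tag_length = 92L,
                       allele_freq_dist = list(type = "uniform", min = 0.05, max = 0.5),
                       monomorphic_fraction = 0.97,
                       snps_per_marker = 1.25,
                       mean_effort = 7.8e6,
                       effort_log_sd = 0.3,
                       mean_tag_depth = 80,
                       depth_dispersion = 0.05,
                       tag_log_sd = 0.6,
                       missing_rate = 0.02,
                       seed = NULL) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("sim_config: `seed` is mandatory for reproducibility", call. = FALSE)
  }
  n_markers_per_class <- as.integer(n_markers_per_class[CHROM_CLASSES])
  names(n_markers_per_class) <- CHROM_CLASSES
  if (anyNA(n_markers_per_class) || any(n_markers_per_class < 0)) {
    stop("sim_config: n_markers_per_class must give a non-negative count for autosomal, X and Y",
         call. = FALSE)
  }
  if (tag_length < 3) stop("sim_config: tag_length must be >= 3", call. = FALSE)
  if (!is.list(allele_freq_dist) || is.null(allele_freq_dist$type) ||
      !allele_freq_dist$type %in% c("uniform", "beta")) {
    stop("sim_config: allele_freq_dist must be list(type = \"uniform\"|\"beta\", ...)",
         call. = FALSE)
  }
  if (allele_freq_dist$type == "uniform") {
    mn <- allele_freq_dist$min; mx <- allele_freq_dist$max
    if (is.null(mn) || is.null(mx) || mn <= 0 || mx >= 1 || mn >= mx) {
      stop("sim_config: uniform allele_freq_dist needs 0 < min < max < 1", call. = FALSE)
    }
  } else {
    if (is.null(allele_freq_dist$shape1) || is.null(allele_freq_dist$shape2) ||
        allele_freq_dist$shape1 <= 0 || allele_freq_dist$shape2 <= 0) {
      stop("sim_config: beta allele_freq_dist needs positive shape1/shape2", call. = FALSE)
    }
  }
  for (p in c(monomorphic_fraction, missing_rate)) {
    if (p < 0 || p > 1) stop("sim_config: probabilities must lie in [0,1]", call. = FALSE)
  }
  if (snps_per_marker < 1 || snps_per_marker > 2) {
    stop("sim_config: snps_per_marker must lie in [1,2]", call. = FALSE)
  }
  if (mean_effort <= 0 || mean_tag_depth <= 0) {
    stop("sim_config: mean_effort and mean_tag_depth must be positive", call. = FALSE)
  }
  if (depth_dispersion < 0 || tag_log_sd < 0 || effort_log_sd < 0) {
    stop("sim_config: dispersion parameters must be non-negative", call. = FALSE)
  }
  structure(list(
    n_markers_per_class = n_markers_per_class,
    tag_length = as.integer(tag_length),
    allele_freq_dist = allele_freq_dist,
    monomorphic_fraction = monomorphic_fraction,
    snps_per_marker = snps_per_marker,
    mean_effort = mean_effort,
    effort_log_sd = effort_log_sd,
    mean_tag_depth = mean_tag_depth,
    depth_dispersion = depth_dispersion,
    tag_log_sd = tag_log_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Colony demographic history
#'
#' One colony's history since it split from the base (founder) pool:
#' `founder_n` diploid founders, then `drift_generations` generations of
#' Wright-Fisher drift at breeding size `census_size`, with optional serial
#' bottlenecks (a transfer in which only `n_sampled` animals move on).
#'
#' @param name colony label.
#' @param founder_n number of diploid founders sampled from the base pool.
#' @param drift_generations generations of drift after founding (>= 0).
#' @param census_size breeding population size during drift.
#' @param serial_bottlenecks list of `list(generation =, n_sampled =)`
#'   events; at the start of that generation the colony is resampled through
#'   `n_sampled` individuals.
#' @return object of class `colony_history`.
#' @export
colony_history <- function(name, founder_n, drift_generations, census_size,
                           serial_bottlenecks = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (founder_n < 1 || census_size < 1 || drift_generations < 0) {
    stop("colony_history: founder_n >= 1, census_size >= 1, drift_generations >= 0",
         call. = FALSE)
  }
  for (b in serial_bottlenecks) {
    if (is.null(b$generation) || is.null(b$n_sampled) ||
        b$generation < 1 || b$generation > drift_generations ||
        b$n_sampled < 1 || b$n_sampled > census_size) {
      stop("colony_history: each bottleneck needs 1 <= generation <= drift_generations and 1 <= n_sampled <= census_size",
           call. = FALSE)
    }
  }
  structure(list(
    name = name,
    founder_n = as.integer(founder_n),
    drift_generations = as.integer(drift_generations),
    census_size = as.integer(census_size),
    serial_bottlenecks = serial_bottlenecks
  ), class = "colony_history")
}

#' Default colony histories
#'
#' Three colonies derived from one commercial base stock. Bottleneck and
#' census numbers beyond the founder counts are not recorded anywhere for
#' real colonies of this kind; these are plausible defaults for a small
#' university colony (documented as such) chosen once: roughly two
#' generations per year, breeding census a few tens of animals, the oldest
#' colony having passed through one extra transfer bottleneck.
#'
#' @return named list of [colony_history()] objects
#'   (`bangor`, `sheffield`, `edinburgh`).
#' @export
default_colony_histories <- function() {
  list(
    bangor = colony_history("bangor", founder_n = 12, drift_generations = 1,
                            census_size = 12),
    sheffield = colony_history("sheffield", founder_n = 12, drift_generations = 5,
                               census_size = 30),
    edinburgh = colony_history("edinburgh", founder_n = 8, drift_generations = 22,
                               census_size = 30,
                               serial_bottlenecks = list(list(generation = 18, n_sampled = 7)))
  )
}

#' Default sampled panel
#'
#' The default sequencing panel: 12 bangor animals (7 F, 5 M), 5 sheffield
#' (2 F, 3 M), 5 edinburgh (3 F, 2 M), plus 2 F1 offspring of an edinburgh
#' dam and a sheffield sire.
#'
#' @return list with `colonies` (named list of `c(F=,M=)` counts) and `f1`
#'   (list of `list(dam=, sire=, sex=)`).
#' @export
default_panel_spec <- function() {
  list(
    colonies = list(
      bangor = c(F = 7L, M = 5L),
      sheffield = c(F = 2L, M = 3L),
      edinburgh = c(F = 3L, M = 2L)
    ),
    f1 = list(
      list(dam = "edinburgh", sire = "sheffield", sex = "F"),
      list(dam = "edinburgh", sire = "sheffield", sex = "M")
    )
  )
}
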