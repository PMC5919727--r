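# allele copies carried by a breeding population of size n for each class,
# assuming a balanced sex ratio (females = ceiling(n/2))
class_copies <- function(class, n) {
  n_f <- ceiling(n / 2); n_m <- floor(n / 2)
  cp <- switch(class,
    autosomal = 2L * n,
    X = 2L * n_f + n_m,
    Y = n_m,
    stop("unknown class: ", class, call. = FALSE)
  )
  max(1L, as.integer(cp))
}

#' Wright-Fisher drift of allele frequencies through a colony history
#'
#' Binomial resampling of per-site allele frequencies: a founder sampling
#' event (`founder_n` diploids drawn from the base pool), then
#' `drift_generations` generations at `census_size`, with any serial
#' bottleneck applied at the start of its generation. Copy numbers are
#' class-aware (autosomal 2N; X 1.5N; Y 0.5N under a balanced sex ratio).
#' Fixed alleles (frequency 0 or 1) are absorbing.
#'
#' @param freq numeric vector of base-pool alternate-allele frequencies.
#' @param class character vector of site classes (same length as `freq`).
#' @param history a [colony_history()].
#' @return numeric vector of terminal colony allele frequencies.
#' @export
drift_frequencies <- function(freq, class, history) {
  stopifnot(inherits(history, "colony_history"), length(freq) == length(class))
  p <- freq
  resample <- function(p, n) {
    for (cl in unique(class)) {
      i <- class == cl
      cp <- class_copies(cl, n)
      p[i] <- rbinom(sum(i), cp, p[i]) / cp
    }
    p
  }
  p <- resample(p, history$founder_n)
  bn <- history$serial_bottlenecks
  bn_gen <- vapply(bn, function(b) as.integer(b$generation), integer(1))
  if (history$drift_generations > 0) {
    for (g in seq_len(history$drift_generations)) {
      hit <- which(bn_gen == g)
      for (h in hit) p <- resample(p, bn[[h]]$n_sampled)
      p <- resample(p, history$census_size)
    }
  }
  p
}

make_panel_row <- function(individual, sex, colony, parent1 = NA_character_,
                           parent2 = NA_character_) {
  tibble::tibble(individual = individual, sex = sex, colony = colony,
                 parent1 = parent1, parent2 = parent2)
}

# draw genotype calls for one set of individuals at the colony's terminal
# frequencies; X males get their single allele, Y females carry nothing
draw_calls <- function(sites, freqs, sexes) {
  ns <- nrow(sites); ni <- length(sexes)
  a1 <- a2 <- matrix(NA_integer_, ns, ni)
  ploidy <- matrix(0L, ns, ni)
  for (j in seq_len(ni)) {
    cn <- copy_number(sites$class, sexes[j])
    ploidy[, j] <- cn
    has1 <- cn >= 1L
    a1[has1, j] <- rbinom(sum(has1), 1L, freqs[has1])
    has2 <- cn == 2L
    a2[has2, j] <- rbinom(sum(has2), 1L, freqs[has2])
  }
  list(a1 = a1, a2 = a2, ploidy = ploidy)
}

#' Simulate sampled genotypes for one colony
#'
#' Drifts the base-pool frequencies through the colony's history
#' ([drift_frequencies()]) and draws the sampled individuals'
#' genotypes by Hardy-Weinberg sampling from the terminal frequencies.
#' X markers: females diploid, males hemizygous; Y markers: males
#' hemizygous, females carry no copy.
#'
#' @param pool a [simulate_founder_pool()] result.
#' @param history a [colony_history()].
#' @param panel_spec named counts `c(F = , M = )` of sampled individuals.
#' @return list with `gm` (a [genotype_matrix()]), `panel` (tibble), and
#'   `terminal_freqs` (per-site colony allele frequencies, used for F1s).
#' @export
simulate_colony_genotypes <- function(pool, history, panel_spec) {
  stopifnot(inherits(pool, "founder_pool"))
  sites <- pool$sites
  p_term <- drift_frequencies(sites$freq, sites$class, history)
  sexes <- c(rep("F", panel_spec[["F"]]), rep("M", panel_spec[["M"]]))
  ids <- sprintf("%s_%s%02d", history$name, sexes, c(seq_len(panel_spec[["F"]]),
                                                    seq_len(panel_spec[["M"]])))
  calls <- draw_calls(sites, p_term, sexes)
  gm <- genotype_matrix(sites[, c("site_id", "tag", "pos", "ref", "alt", "class")],
                        ids, calls$a1, calls$a2, calls$ploidy)
  panel <- make_panel_row(ids, sexes, history$name)
  list(gm = gm, panel = panel, terminal_freqs = p_term)
}

#' Simulate an F1 hybrid between two colonies
#'
#' Draws one gamete from each parent colony's terminal allele frequencies.
#' X markers: a female F1 receives an X from each parent; a male F1 receives
#' his single X from the dam. Y markers: a male F1 carries the sire colony's
#' Y; a female F1 carries none.
#'
#' @param sites site table (as in a [simulate_founder_pool()]).
#' @param dam_freqs,sire_freqs terminal allele frequencies of the two
#'   parent colonies.
#' @param sex `"F"` or `"M"`.
#' @return list with `a1`, `a2`, `ploidy` column vectors for the F1.
#' @export
simulate_f1_calls <- function(sites, dam_freqs, sire_freqs, sex) {
  ns <- nrow(sites)
  a1 <- a2 <- rep(NA_integer_, ns)
  ploidy <- copy_number(sites$class, sex)
  auto <- sites$class == "autosomal"
  a1[auto] <- rbinom(sum(auto), 1L, dam_freqs[auto])
  a2[auto] <- rbinom(sum(auto), 1L, sire_freqs[auto])
  x <- sites$class == "X"
  a1[x] <- rbinom(sum(x), 1L, dam_freqs[x])
  if (sex == "F") a2[x] <- rbinom(sum(x), 1L, sire_freqs[x])
  y <- sites$class == "Y"
  if (sex == "M") a1[y] <- rbinom(sum(y), 1L, sire_freqs[y])
  list(a1 = a1, a2 = a2, ploidy = ploidy)
}

#' Simulate a complete multi-colony GBS study
#'
#' End-to-end synthetic data set: founder pool, per-colony drift and
#' sampling, F1 hybrids, GBS coverage, per-call depth, and random genotype
#' dropout at `cfg$missing_rate`. Every source of randomness is governed by
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param histories named list of [colony_history()] (default
#'   [default_colony_histories()]).
#' @param panel_spec a panel specification (default [default_panel_spec()]).
#' @return object of class `colony_study`: list with `pool`, `panel`
#'   (tibble `individual`, `sex`, `colony`, `parent1`, `parent2`), `gm`
#'   (with depth attached), `coverage` (a `coverage_table`), and
#'   `terminal_freqs` (named list per colony).
#' @export
simulate_colony_study <- function(cfg,
                                  histories = default_colony_histories(),
                                  panel_spec = default_panel_spec()) {
  pool <- simulate_founder_pool(cfg)  # seeds the RNG from cfg$seed
  sites <- pool$sites
  gms <- list(); panels <- list(); term <- list()
  for (nm in names(histories)) {
    spec <- panel_spec$colonies[[nm]]
    if (is.null(spec)) stop("no panel counts for colony ", nm, call. = FALSE)
    res <- simulate_colony_genotypes(pool, histories[[nm]], spec)
    gms[[nm]] <- res$gm; panels[[nm]] <- res$panel
    term[[nm]] <- res$terminal_freqs
  }
  a1 <- do.call(cbind, lapply(gms, function(g) g$a1))
  a2 <- do.call(cbind, lapply(gms, function(g) g$a2))
  ploidy <- do.call(cbind, lapply(gms, function(g) g$ploidy))
  samples <- unlist(lapply(gms, function(g) g$samples), use.names = FALSE)
  panel <- do.call(rbind, panels)
  for (k in seq_along(panel_spec$f1)) {
    f1 <- panel_spec$f1[[k]]
    calls <- simulate_f1_calls(sites, term[[f1$dam]], term[[f1$sire]], f1$sex)
    a1 <- cbind(a1, matrix(calls$a1, ncol = 1))
    a2 <- cbind(a2, matrix(calls$a2, ncol = 1))
    ploidy <- cbind(ploidy, matrix(calls$ploidy, ncol = 1))
    id <- sprintf("f1_%s%02d", f1$sex, k)
    samples <- c(samples, id)
    panel <- rbind(panel, make_panel_row(id, f1$sex, "F1", f1$dam, f1$sire))
  }
  gm <- genotype_matrix(sites[, c("site_id", "tag", "pos", "ref", "alt", "class")],
                        samples, a1, a2, ploidy)
  coverage <- simulate_coverage(pool$catalog, panel, cfg)
  gm <- attach_depth(gm, coverage)
  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(length(gm$a1)) < cfg$missing_rate,
                   nrow(gm$a1), ncol(gm$a1))
    drop <- drop & gm$ploidy > 0L
    gm$a1[drop] <- NA_integer_
    gm$a2[drop] <- NA_integer_
  }
  structure(list(pool = pool, panel = panel, gm = gm, coverage = coverage,
                 terminal_freqs = term, cfg = cfg),
            class = "colony_study")
}
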