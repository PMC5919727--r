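#' Simulate GBS read counts per tag per individual
#'
#' Each individual's sequencing effort (total reads) is lognormal around
#' `cfg$mean_effort`; each tag has a lognormal capture-efficiency
#' multiplier (mean 1, sdlog `cfg$tag_log_sd`) shared by all individuals.
#' Expected depth is
#' `mean_tag_depth * efficiency * (effort / mean_effort) * copy_number / 2`,
#' so X tags average half depth in males and Y tags are always zero in
#' females. Realized depth is negative-binomial with dispersion
#' `cfg$depth_dispersion` (variance `mu + dispersion * mu^2`); a dispersion
#' of exactly 0 yields the rounded expectation.
#'
#' @param catalog marker catalog tibble (`tag`, `class`, ...).
#' @param panel sample panel tibble (`individual`, `sex`, ...).
#' @param cfg a [sim_config()].
#' @return object of class `coverage_table`: list with `counts` (tags x
#'   individuals integer matrix), `effort` (named per-individual total
#'   reads), and `tags` (tag IDs, row order of `counts`).
#' @export
simulate_coverage <- function(catalog, panel, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_tags <- nrow(catalog); n_ind <- nrow(panel)
  effort <- rlnorm(n_ind, log(cfg$mean_effort) - cfg$effort_log_sd^2 / 2,
                   cfg$effort_log_sd)
  names(effort) <- panel$individual
  eff_tag <- rlnorm(n_tags, -cfg$tag_log_sd^2 / 2, cfg$tag_log_sd)
  counts <- matrix(0L, n_tags, n_ind,
                   dimnames = list(as.character(catalog$tag), panel$individual))
  base <- cfg$mean_tag_depth * eff_tag
  for (j in seq_len(n_ind)) {
    cn <- copy_number(catalog$class, panel$sex[j])
    mu <- base * (effort[j] / cfg$mean_effort) * cn / 2
    if (cfg$depth_dispersion == 0) {
      counts[, j] <- as.integer(round(mu))  # degenerate-noise limit
    } else {
      pos <- mu > 0
      cj <- integer(n_tags)
      cj[pos] <- as.integer(rnbinom(sum(pos), mu = mu[pos],
                                    size = 1 / cfg$depth_dispersion))
      counts[, j] <- cj
    }
  }
  coverage_table(counts, effort)
}

#' Coverage table container
#'
#' @param counts tags x individuals integer matrix of read counts (rownames
#'   are tag IDs, colnames individual IDs).
#' @param effort named numeric vector of per-individual total read counts
#'   (sequencing effort), covering every column of `counts`.
#' @return object of class `coverage_table`.
#' @export
coverage_table <- function(counts, effort) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)))
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("coverage_table: rownames (tag IDs) required",
                               call. = FALSE)
    rownames(counts) <- character(0)
  }
  if (!all(colnames(counts) %in% names(effort))) {
    stop("coverage_table: every individual in `counts` needs an effort entry",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("coverage_table: negative read counts", call. = FALSE)
  structure(list(counts = counts,
                 effort = effort[colnames(counts)],
                 tags = as.integer(rownames(counts))),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat(sprintf("<coverage_table> %d tags x %d individuals (median effort %.3g reads)\n",
              nrow(x$counts), ncol(x$counts), stats::median(x$effort)))
  invisible(x)
}

#' Attach per-call depth from a coverage table
#'
#' Sets each genotype cell's depth to the read count of its tag in that
#' individual (GBS calls at a site are supported by the tag's reads).
#'
#' @param gm a [genotype_matrix()].
#' @param coverage a [coverage_table()].
#' @return `gm` with `depth` filled in.
#' @export
attach_depth <- function(gm, coverage) {
  stopifnot(inherits(coverage, "coverage_table"))
  i <- match(as.character(gm$sites$tag), rownames(coverage$counts))
  j <- match(gm$samples, colnames(coverage$counts))
  if (anyNA(i)) stop("attach_depth: site tag missing from coverage table", call. = FALSE)
  if (anyNA(j)) stop("attach_depth: individual missing from coverage table", call. = FALSE)
  gm$depth <- coverage$counts[i, j, drop = FALSE]
  dimnames(gm$depth) <- list(gm$sites$site_id, gm$samples)
  gm
}
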