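#' Mask genotype calls below a depth threshold
#'
#' Calls with depth below `min_depth` are set to missing (the call is
#' masked, never altered); sites left with no called individual are dropped
#' and counted. The threshold is inclusive: depth equal to `min_depth`
#' passes, matching a minimum-stack-depth filter of 10.
#'
#' @param gm a [genotype_matrix()] with depths attached.
#' @param min_depth minimum per-call depth (default 10).
#' @return list with `gm` (filtered), `calls_masked`, `sites_dropped`.
#' @export
depth_filter <- function(gm, min_depth = 10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(gm$depth < 0, na.rm = TRUE)) stop("depth_filter: negative depth", call. = FALSE)
  low <- !is.na(gm$depth) & gm$depth < min_depth
  called <- !is.na(gm$a1)
  masked <- low & called
  gm$a1[masked] <- NA_integer_
  gm$a2[masked] <- NA_integer_
  keep <- rowSums(!is.na(gm$a1)) >= 1L
  list(gm = gm_subset_sites(gm, keep),
       calls_masked = sum(masked),
       sites_dropped = sum(!keep))
}

#' Drop SNPs outside the leading window of the tag
#'
#' Removes sites whose within-tag position exceeds `max_pos` (default 90 of
#' a 92-base tag, i.e. the final two bases are blacklisted).
#'
#' @param gm a [genotype_matrix()].
#' @param max_pos last retained position (1-based, default 90).
#' @param tag_len tag length; positions outside `[1, tag_len]` error.
#' @return list with `gm` (filtered) and `sites_dropped`.
#' @export
position_filter <- function(gm, max_pos = 90, tag_len = 92) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(gm$sites$pos < 1L | gm$sites$pos > tag_len)) {
    stop("position_filter: site position outside the tag", call. = FALSE)
  }
  keep <- gm$sites$pos <= max_pos
  list(gm = gm_subset_sites(gm, keep), sites_dropped = sum(!keep))
}

#' QC summary of a filter chain
#'
#' @param before the input [genotype_matrix()].
#' @param after the filtered [genotype_matrix()].
#' @param steps optional named integer vector of per-filter site removals;
#'   when given it must account for the whole difference.
#' @return tibble with sites/calls before, after, and removed.
#' @export
qc_report <- function(before, after, steps = NULL) {
  n_calls <- function(g) sum(!is.na(g$a1)) + sum(!is.na(g$a2))
  rep <- tibble::tibble(
    sites_in = nrow(before$sites),
    sites_out = nrow(after$sites),
    sites_removed = nrow(before$sites) - nrow(after$sites),
    calls_in = n_calls(before),
    calls_out = n_calls(after),
    calls_removed = n_calls(before) - n_calls(after)
  )
  if (!is.null(steps) && sum(steps) != rep$sites_removed) {
    stop("qc_report: per-filter removals (", sum(steps),
         ") do not sum to total sites removed (", rep$sites_removed, ")",
         call. = FALSE)
  }
  rep
}

#' Apply the standard genotype QC chain
#'
#' Depth mask (>= `min_depth` per call) then SNP-position window
#' (<= `max_pos`).
#'
#' @inheritParams depth_filter
#' @inheritParams position_filter
#' @return list with `gm`, `report` (a [qc_report()] tibble) and the
#'   per-step counts.
#' @export
apply_genotype_qc <- function(gm, min_depth = 10, max_pos = 90, tag_len = 92) {
  d <- depth_filter(gm, min_depth)
  p <- position_filter(d$gm, max_pos, tag_len)
  list(gm = p$gm,
       report = qc_report(gm, p$gm,
                          steps = c(depth = d$sites_dropped,
                                    position = p$sites_dropped)),
       calls_masked = d$calls_masked,
       sites_dropped_depth = d$sites_dropped,
       sites_dropped_position = p$sites_dropped)
}
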