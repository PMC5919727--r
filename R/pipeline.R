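#' Cross-check pipeline inputs
#'
#' Validates that the sample sheet, genotype samples and coverage columns
#' agree: every genotype/coverage individual appears in the sheet, sexes
#' are F/M, individual IDs are unique, efforts positive. All problems are
#' reported at once.
#'
#' @param panel sample panel tibble.
#' @param gm optional [genotype_matrix()].
#' @param coverage optional [coverage_table()].
#' @param strict error (rather than return) when problems are found.
#' @return character vector of problems (empty when consistent).
#' @export
validate_inputs <- function(panel, gm = NULL, coverage = NULL, strict = FALSE) {
  problems <- character(0)
  if (anyDuplicated(panel$individual)) {
    problems <- c(problems, sprintf("duplicate individual ID(s): %s",
      paste(unique(panel$individual[duplicated(panel$individual)]), collapse = ", ")))
  }
  bad_sex <- !panel$sex %in% c("F", "M")
  if (any(bad_sex)) {
    problems <- c(problems, sprintf("invalid sex for: %s",
      paste(panel$individual[bad_sex], collapse = ", ")))
  }
  if (!is.null(gm)) {
    miss <- setdiff(gm$samples, panel$individual)
    if (length(miss)) {
      problems <- c(problems, sprintf("genotype sample(s) absent from sample sheet: %s",
                                      paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(coverage)) {
    miss <- setdiff(colnames(coverage$counts), panel$individual)
    if (length(miss)) {
      problems <- c(problems, sprintf("coverage column(s) absent from sample sheet: %s",
                                      paste(miss, collapse = ", ")))
    }
    if (any(coverage$effort <= 0)) {
      problems <- c(problems, "individual(s) with non-positive sequencing effort")
    }
  }
  if (strict && length(problems)) {
    stop("validate_inputs:\n  - ", paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  problems
}

#' Run the whole synthetic-study pipeline
#'
#' Orchestrates simulate -> classify -> genotype QC -> diversity summary ->
#' pairwise F_st -> PCA (+ F1 intermediacy) -> tag-versus-genome
#' divergence, writing every stage's artifact under `out_dir` with a
#' provenance header (package version, seed, thresholds).
#'
#' @param out_dir output directory.
#' @param cfg a [sim_config()] (its seed governs all randomness).
#' @param histories,panel_spec study design (defaults as in
#'   [simulate_colony_study()]).
#' @param min_depth,max_pos QC thresholds.
#' @param t_unknown,t_y,x_slope,x_intercept classification constants.
#' @param k_pca eigenvectors to report.
#' @param max_mismatch naive-aligner substitution budget.
#' @return (invisibly) list with every in-memory stage result and the
#'   written paths.
#' @export
run_colony_pipeline <- function(out_dir, cfg,
                                histories = default_colony_histories(),
                                panel_spec = default_panel_spec(),
                                min_depth = 10, max_pos = 90,
                                t_unknown = 10, t_y = 1,
                                x_slope = 0.75, x_intercept = -5,
                                k_pca = 10, max_mismatch = 8) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prov <- list(tool = paste0("colonysift ", packageVersion("colonysift")),
               seed = cfg$seed,
               min_depth = min_depth, max_pos = max_pos,
               t_unknown = t_unknown, t_y = t_y,
               x_slope = x_slope, x_intercept = x_intercept)
  study <- simulate_colony_study(cfg, histories, panel_spec)
  validate_inputs(study$panel, study$gm, study$coverage, strict = TRUE)
  fixtures <- write_fixture_set(study, file.path(out_dir, "inputs"),
                                provenance = prov)

  std <- standardize_coverage(study$coverage, study$panel)
  tags <- classify_tags(std, t_unknown, t_y, x_slope, x_intercept)
  truth <- study$pool$catalog$class[match(tags$tag, study$pool$catalog$tag)]
  class_report <- classification_report(tags$class, truth, study$panel)
  write_tsv_prov(tags, file.path(out_dir, "tag_classes.tsv"), prov)

  qc <- apply_genotype_qc(study$gm, min_depth = min_depth, max_pos = max_pos,
                          tag_len = cfg$tag_length)
  write_genotype_vcf(qc$gm, file.path(out_dir, "genotypes_filtered.vcf"), prov)
  write_tsv_prov(qc$report, file.path(out_dir, "qc_report.tsv"), prov)

  # diversity over the simulator's true classes (the classifier's accuracy
  # is reported separately; statistics should not inherit its errors)
  classes_true <- study$pool$catalog[, c("tag", "class")]
  diversity <- summarize_diversity(qc$gm, study$coverage, study$panel,
                                   classes_true, min_depth = min_depth,
                                   window = max_pos)
  write_tsv_prov(diversity, file.path(out_dir, "diversity_summary.tsv"), prov)

  colonies <- setdiff(unique(study$panel$colony), "F1")
  fst <- list()
  for (i in seq_along(colonies)) for (j in seq_len(i - 1L)) {
    key <- paste(colonies[j], colonies[i], sep = "_vs_")
    fst[[key]] <- tryCatch(
      pairwise_fst(qc$gm, study$panel, colonies[j], colonies[i]),
      error = function(e) NULL)
  }
  fst_tab <- do.call(rbind, lapply(names(fst), function(k) {
    if (is.null(fst[[k]])) return(NULL)
    tibble::tibble(pair = k, theta = fst[[k]]$theta,
                   n_sites = nrow(fst[[k]]$components))
  }))
  if (!is.null(fst_tab)) write_tsv_prov(fst_tab, file.path(out_dir, "fst.tsv"), prov)

  pca <- genotype_pca(qc$gm, k = k_pca)
  coords <- tibble::tibble(individual = rownames(pca$coords),
                           colony = study$panel$colony[
                             match(rownames(pca$coords), study$panel$individual)])
  coords <- cbind(coords, as.data.frame(pca$coords))
  write_tsv_prov(coords, file.path(out_dir, "pca_coords.tsv"), prov)
  f1 <- f1_intermediacy(pca, study$panel)
  if (!is.null(f1)) write_tsv_prov(f1, file.path(out_dir, "f1_intermediacy.tsv"), prov)

  genome <- Biostrings::readDNAStringSet(fixtures$genome)
  aln <- naive_align(tags_as_stringset(study$pool$catalog), genome,
                     max_mismatch = max_mismatch)
  write_sam(aln, file.path(out_dir, "tags_vs_genome.sam"),
            sq = setNames(Biostrings::width(genome), names(genome)))
  div <- divergence_report(aln, tags_as_stringset(study$pool$catalog),
                           tag_len = cfg$tag_length, window = max_pos,
                           genome = genome)
  write_tsv_prov(div$per_tag, file.path(out_dir, "divergence_per_tag.tsv"), prov)

  summary <- list(
    provenance = prov,
    classification = class_report$counts,
    qc = as.list(qc$report),
    fst = if (is.null(fst_tab)) NULL else
      setNames(as.list(fst_tab$theta), fst_tab$pair),
    pca_pct_var = pca$pct_var[seq_len(min(5, length(pca$pct_var)))],
    divergence = list(n_tags_total = div$n_tags_total,
                      n_full_length = div$n_full_length,
                      pct_full_length = div$pct_full_length,
                      n_mismatches_total = div$n_mismatches_total)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, tags = tags, class_report = class_report,
                 qc = qc, diversity = diversity, fst = fst, pca = pca,
                 f1 = f1, divergence = div, paths = out_dir))
}
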