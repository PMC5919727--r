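#' Standardize coverage by sequencing effort, summed within each sex
#'
#' Per tag, each individual's read count is divided by that individual's
#' total read count (sequencing effort), multiplied by 1,000,000, and the
#' resulting counts-per-million are summed separately over females and
#' males.
#'
#' @param coverage a [coverage_table()].
#' @param panel sample panel tibble with `individual` and `sex` (`F`/`M`);
#'   every coverage column must match a panel row.
#' @return tibble with one row per tag: `tag`, `cov_female`, `cov_male`,
#'   `cov_total` (= `cov_female + cov_male`).
#' @export
standardize_coverage <- function(coverage, panel) {
  stopifnot(inherits(coverage, "coverage_table"))
  ids <- colnames(coverage$counts)
  m <- match(ids, panel$individual)
  if (anyNA(m)) {
    stop("standardize_coverage: coverage column(s) not in the sample sheet: ",
         paste(ids[is.na(m)], collapse = ", "), call. = FALSE)
  }
  eff <- coverage$effort[ids]
  if (any(!is.finite(eff)) || any(eff <= 0)) {
    stop("standardize_coverage: every individual must have total reads > 0",
         call. = FALSE)
  }
  sex <- panel$sex[m]
  cpm <- sweep(coverage$counts, 2, eff, "/") * 1e6
  cov_f <- rowSums(cpm[, sex == "F", drop = FALSE])
  cov_m <- rowSums(cpm[, sex == "M", drop = FALSE])
  tibble::tibble(tag = coverage$tags,
                 cov_female = unname(cov_f),
                 cov_male = unname(cov_m),
                 cov_total = unname(cov_f + cov_m))
}

#' Classify tags as autosomal, X, Y or unknown from standardized coverage
#'
#' Rules, applied in order with strict inequalities:
#' \enumerate{
#'   \item total standardized coverage < `t_unknown` (default 10) — `unknown`;
#'   \item else female standardized coverage < `t_y` (default 1) — `Y`;
#'   \item else male coverage < `x_slope` * female coverage + `x_intercept`
#'     (default `3/4 * cov_female - 5`) — `X`;
#'   \item else — `autosomal`.
#' }
#' The default constants are calibrated to a ~24-individual panel at a mean
#' effort of several million reads; other designs may need recalibration.
#'
#' @param std standardized coverage tibble from [standardize_coverage()].
#' @param t_unknown,t_y,x_slope,x_intercept classification constants.
#' @return `std` with a `class` column added (one class per tag).
#' @export
classify_tags <- function(std, t_unknown = 10, t_y = 1,
                          x_slope = 0.75, x_intercept = -5) {
  stopifnot(all(c("tag", "cov_female", "cov_male", "cov_total") %in% names(std)),
            all(is.finite(c(t_unknown, t_y, x_slope, x_intercept))))
  cls <- rep("autosomal", nrow(std))
  is_x <- std$cov_male < x_slope * std$cov_female + x_intercept
  cls[is_x] <- "X"
  is_y <- std$cov_female < t_y
  cls[is_y] <- "Y"
  is_unknown <- std$cov_total < t_unknown
  cls[is_unknown] <- "unknown"
  out <- std
  out$class <- cls
  out
}

#' Summarise a tag classification, optionally against planted truth
#'
#' @param classes character vector of assigned classes (`autosomal`, `X`,
#'   `Y`, `unknown`).
#' @param truth optional character vector of true classes (same length);
#'   enables the confusion matrix and per-class sensitivity/specificity.
#' @param panel optional sample panel; if it contains no males, the report
#'   carries a warning flag (X/autosome discrimination is unreliable
#'   without male coverage).
#' @return list with `counts` (named, all four classes, summing to the tag
#'   total), and when truth is given `confusion`, `sensitivity`,
#'   `specificity`; plus `warnings`.
#' @export
classification_report <- function(classes, truth = NULL, panel = NULL) {
  lev <- c("autosomal", "X", "Y", "unknown")
  stopifnot(all(classes %in% lev))
  counts <- table(factor(classes, levels = lev))
  out <- list(counts = setNames(as.integer(counts), lev), warnings = character(0))
  if (!is.null(panel) && !any(panel$sex == "M")) {
    out$warnings <- c(out$warnings,
                      "no males in panel: X/autosome discrimination unreliable")
  }
  if (!is.null(truth)) {
    if (length(truth) != length(classes)) {
      stop("classification_report: truth and classes lengths differ", call. = FALSE)
    }
    conf <- table(truth = factor(truth, levels = lev),
                  called = factor(classes, levels = lev))
    sens <- spec <- setNames(rep(NA_real_, 3), CHROM_CLASSES)
    for (cl in CHROM_CLASSES) {
      pos <- truth == cl
      if (any(pos)) sens[cl] <- mean(classes[pos] == cl)
      if (any(!pos)) spec[cl] <- mean(classes[!pos] != cl)
    }
    out$confusion <- conf
    out$sensitivity <- sens
    out$specificity <- spec
  }
  out
}
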