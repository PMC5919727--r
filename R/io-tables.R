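#' Write / read a TSV with a provenance comment header
#'
#' Plain tab-separated tables; `provenance` entries are written as leading
#' `# key=value` comment lines, which the reader skips.
#'
#' @param df data frame to write.
#' @param path file path.
#' @param provenance optional named list for the comment header.
#' @return the path (writer) / a data frame (reader).
#' @export
write_tsv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s=%s", names(provenance), unlist(provenance)), con)
  }
  df <- as.data.frame(df)
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.15g", col) else col
  })
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_prov
#' @export
read_tsv_prov <- function(path) {
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write / read the sample sheet
#'
#' TSV with columns `individual`, `sex` (F/M), `colony`, and for F1
#' hybrids `parent1`/`parent2`.
#'
#' @param panel sample panel tibble.
#' @param path file path.
#' @param provenance optional named list written as `# key=value` comments.
#' @return the path (writer) or the panel tibble (reader).
#' @export
write_sample_sheet <- function(panel, path, provenance = NULL) {
  write_tsv_prov(panel, path, provenance)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_prov(path)
  need <- c("individual", "sex", "colony")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$parent1)) df$parent1 <- NA_character_
  if (is.null(df$parent2)) df$parent2 <- NA_character_
  df$parent1[df$parent1 %in% c("", "NA")] <- NA_character_
  df$parent2[df$parent2 %in% c("", "NA")] <- NA_character_
  tibble::as_tibble(df)
}

#' Write / read the coverage table
#'
#' Coverage is a TSV with a `tag` column then one integer column per
#' individual; sequencing effort is a sidecar TSV (`individual`,
#' `total_reads`).
#'
#' @param coverage a [coverage_table()].
#' @param counts_path,efforts_path file paths.
#' @param provenance optional named list of provenance comments.
#' @return paths (writer) or a [coverage_table()] (reader).
#' @export
write_coverage_table <- function(coverage, counts_path, efforts_path,
                                 provenance = NULL) {
  df <- data.frame(tag = coverage$tags, coverage$counts, check.names = FALSE)
  write_tsv_prov(df, counts_path, provenance)
  eff <- data.frame(individual = names(coverage$effort),
                    total_reads = unname(coverage$effort))
  write_tsv_prov(eff, efforts_path, provenance)
  invisible(c(counts_path, efforts_path))
}

#' @rdname write_coverage_table
#' @export
read_coverage_table <- function(counts_path, efforts_path) {
  df <- read_tsv_prov(counts_path)
  eff <- read_tsv_prov(efforts_path)
  counts <- as.matrix(df[, setdiff(names(df), "tag"), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- as.character(df$tag)
  coverage_table(counts, setNames(eff$total_reads, eff$individual))
}

#' Tag catalog as a DNAStringSet
#'
#' @param catalog marker catalog tibble (`tag`, `seq`).
#' @return named [Biostrings::DNAStringSet] (names are tag IDs).
#' @export
tags_as_stringset <- function(catalog) {
  x <- Biostrings::DNAStringSet(catalog$seq)
  names(x) <- as.character(catalog$tag)
  x
}

#' Write / read the tag catalog FASTA
#'
#' One record per tag; the chromosome class (when known) is carried in the
#' header as `class=<class>` after the tag ID.
#'
#' @param catalog marker catalog tibble (`tag`, `seq`, optionally `class`).
#' @param path FASTA path.
#' @return the path (writer); the reader returns a tibble `tag`, `class`
#'   (NA when absent from the header), `seq`.
#' @export
write_tag_fasta <- function(catalog, path) {
  x <- Biostrings::DNAStringSet(catalog$seq)
  names(x) <- if (!is.null(catalog$class)) {
    sprintf("%d class=%s", catalog$tag, catalog$class)
  } else as.character(catalog$tag)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_tag_fasta
#' @export
read_tag_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("^(\\S+).*$", "\\1", names(x))
  cls <- ifelse(grepl("class=", names(x)),
                sub(".*class=(\\S+).*", "\\1", names(x)), NA_character_)
  tibble::tibble(tag = as.integer(ids), class = unname(cls),
                 seq = unname(as.character(x)))
}
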