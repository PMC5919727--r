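#!/usr/bin/env Rscript
# Per-colony diversity summary (bases, private/polymorphic sites, pi,
# heterozygosity) by chromosome class, plus pairwise Weir-Cockerham F_st.

suppressPackageStartupMessages(library(colonysift))

panel <- read_sample_sheet("results/inputs/samples.tsv")
coverage <- read_coverage_table("results/inputs/coverage.tsv",
                                "results/inputs/efforts.tsv")
catalog <- read_tag_fasta("results/inputs/tags.fasta")
gm <- read_genotype_vcf("results/genotypes_filtered.vcf", panel)

tab <- summarize_diversity(gm, coverage, panel, catalog[, c("tag", "class")])
write_tsv_prov(tab, "results/diversity_summary.tsv")
cat("Diversity summary (colony x class):\n")
print(as.data.frame(tab), digits = 4)

colonies <- setdiff(unique(panel$colony), "F1")
fst_rows <- list()
for (i in seq_along(colonies)) for (j in seq_len(i - 1L)) {
  f <- pairwise_fst(gm, panel, colonies[j], colonies[i])
  fst_rows[[length(fst_rows) + 1L]] <-
    tibble::tibble(pair = paste(colonies[j], colonies[i], sep = "_vs_"),
                   theta = f$theta, n_sites = nrow(f$components))
}
fst_tab <- do.call(rbind, fst_rows)
write_tsv_prov(fst_tab, "results/fst.tsv")
cat("\nPairwise F_st (autosomal, ratio of sums):\n")
print(as.data.frame(fst_tab), digits = 3)
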