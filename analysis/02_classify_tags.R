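#!/usr/bin/env Rscript
# Annotate every tag as autosomal / X / Y / unknown from sex-specific
# standardized coverage, and score the annotation against the simulator's
# planted classes.

suppressPackageStartupMessages(library(colonysift))

panel <- read_sample_sheet("results/inputs/samples.tsv")
coverage <- read_coverage_table("results/inputs/coverage.tsv",
                                "results/inputs/efforts.tsv")
catalog <- read_tag_fasta("results/inputs/tags.fasta")

std <- standardize_coverage(coverage, panel)
tags <- classify_tags(std)
rep <- classification_report(tags$class,
                             truth = catalog$class[match(tags$tag, catalog$tag)],
                             panel = panel)
write_tsv_prov(tags, "results/tag_classes.tsv")

cat("Tag classification (counts):\n")
print(rep$counts)
cat("Recovery of planted classes (sensitivity):\n")
print(round(rep$sensitivity, 4))
cat("Confusion matrix:\n")
print(rep$confusion)
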