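#!/usr/bin/env Rscript
# Genotype QC: mask calls below 10x depth, drop sites left with no call,
# and blacklist SNPs beyond base 90 of the 92-base tags.

suppressPackageStartupMessages(library(colonysift))

panel <- read_sample_sheet("results/inputs/samples.tsv")
gm <- read_genotype_vcf("results/inputs/genotypes.vcf", panel)

qc <- apply_genotype_qc(gm, min_depth = 10, max_pos = 90, tag_len = 92)
write_genotype_vcf(qc$gm, "results/genotypes_filtered.vcf")
write_tsv_prov(qc$report, "results/qc_report.tsv")

cat(sprintf("Sites: %d in, %d out (%d dropped by depth, %d by position)\n",
            qc$report$sites_in, qc$report$sites_out,
            qc$sites_dropped_depth, qc$sites_dropped_position))
cat(sprintf("Calls masked below 10x: %d\n", qc$calls_masked))
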