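#!/usr/bin/env Rscript
# Colony structure: PCA of the autosomal genotype dosages and the
# F1-intermediacy check on the leading eigenvectors.

suppressPackageStartupMessages(library(colonysift))

panel <- read_sample_sheet("results/inputs/samples.tsv")
gm <- read_genotype_vcf("results/genotypes_filtered.vcf", panel)

pca <- genotype_pca(gm, k = 10)
coords <- tibble::tibble(
  individual = rownames(pca$coords),
  colony = panel$colony[match(rownames(pca$coords), panel$individual)])
coords <- cbind(coords, as.data.frame(pca$coords))
write_tsv_prov(coords, "results/pca_coords.tsv")
write_tsv_prov(tibble::tibble(ev = seq_along(pca$pct_var),
                              eigenvalue = pca$eigenvalues[seq_along(pca$pct_var)],
                              pct_var = pca$pct_var),
               "results/pca_eigenvalues.tsv")

cat(sprintf("PCA on %d autosomal SNPs, %d samples\n", pca$n_sites,
            nrow(pca$coords)))
cat(sprintf("EV1 explains %.1f%%, EV2 %.1f%% of the variance\n",
            pca$pct_var[1], pca$pct_var[2]))

f1 <- f1_intermediacy(pca, panel, n_ev = 2)
write_tsv_prov(f1, "results/f1_intermediacy.tsv")
cat("\nF1 intermediacy relative to parental colony centroids:\n")
print(as.data.frame(f1), digits = 3)
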