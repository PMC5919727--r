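Package: colonysift
Title: Genetic Diversity and Divergence in Isolated Laboratory Rodent Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying standing genetic variation in small,
    isolated laboratory colonies from genotyping-by-sequencing (GBS) data:
    coverage-based annotation of sex-linked tags (autosomal/X/Y/unknown),
    genotype-call and SNP-position quality filters, per-colony nucleotide
    diversity, heterozygosity, private- and polymorphic-site counts,
    Weir-Cockerham F_st between colonies, principal-component analysis of
    colony structure with an F1-intermediacy check, and tag-versus-genome
    divergence counting from alignments. Includes a Wright-Fisher colony
    simulator (founder sampling, serial bottlenecks, drift, sex-dependent
    marker copy number, overdispersed GBS read depth) so the whole pipeline
    runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    Biostrings,
    Rsamtools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
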