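Package: candgene
Title: Candidate-Gene Nucleotide Diversity, Linkage Disequilibrium and
    Mixed-Model Association Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for candidate-gene resequencing and association studies in
    structured plant populations: nucleotide diversity (pi, Watterson's theta)
    and neutrality tests (Tajima's D, Fu and Li's D*) per annotated gene
    region with Nei-Gojobori synonymous/non-synonymous partitioning; pairwise
    linkage disequilibrium with permutation significance and Hill-Weir decay
    fitting; Ritland marker-based kinship and Q+K restricted-maximum-likelihood
    mixed-model single-SNP association with positive-FDR q-values and
    gene-action decomposition; EM haplotype-frequency estimation and haplotype
    trend regression on sliding marker windows; and seeded generators for
    coalescent panels, copying-model haplotypes, structured genotypes and
    mixed-model phenotypes so every stage can be exercised and calibrated on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
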