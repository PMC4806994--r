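Package: minormatch
Title: Genome-Wide Donor-Recipient Mismatch Association for Minor
    Histocompatibility Loci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Association analysis of donor-recipient genotype mismatches
    with transplant outcome in semi-inbred animal lines. Provides
    within-line homozygosity and fixation profiling of SNP-array
    genotypes, mismatch coding of donor-recipient pairs under a
    directional (host-versus-graft) and a symmetric rejection model, a
    per-SNP likelihood-ratio (G) test of match status against graft
    outcome with a maxT permutation genome-wide significance threshold,
    grouping of significant SNPs into genomic blocks with outcome-group
    concordance reporting, and a simulator of multi-line semi-inbred
    genotype cohorts with planted causal minor-histocompatibility loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
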