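#!/usr/bin/env Rscript
# Stage 2: within-line homozygosity profile of the cohort from stage 1.
#
# Produces the per-line, per-chromosome fixation / MAF / heterozygosity
# table, the across-line jointly-fixed fraction, and a per-animal
# genotype-category map of chromosome 7 (the MHC chromosome in the pig:
# each line should appear fully fixed there for its own haplotype).

library(minormatch)

gm <- read_genotypes("results/cohort/cohort", "ped_map")

st <- line_stats(gm, by = "chromosome")
utils::write.table(st, "results/homozygosity_stats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
tot <- st[st$chromosome == "Total", ]
cat("genome-wide fixation by line:\n")
print(tot[, c("line", "n_snps", "prop_fixed", "mean_maf", "mean_het")],
      row.names = FALSE)
cat(sprintf("fixed for the same allele across all lines: %.3f\n",
            cross_line_fixed(gm)))

map <- homozygosity_map(gm, "7")
write_homozygosity_map(map, "results/homozygosity_map_chr7.tsv")
grDevices::png("results/homozygosity_map_chr7.png", 900, 500)
plot(map, main = "chromosome 7 genotype categories by animal")
grDevices::dev.off()
cat("map exported for", nrow(map$loci), "chromosome-7 loci\n")
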