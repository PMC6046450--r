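#!/usr/bin/env Rscript
# Alpha diversity (richness, Shannon, Pielou evenness) with its age
# models, presence-absence Jaccard beta diversity, and phylum-level
# composition shifts between day 8 and day 15.

library(fosterbiome)

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
tabf <- file.path("results", "qc", "filtered_table.tsv")
meta <- read_metadata(file.path("results", "data", "metadata.tsv"))
mmeta <- merged_metadata(meta)
tab <- read_otu_table(tabf, role_map = setNames(mmeta$sample_role,
                                                mmeta$sample_id))
mmeta <- mmeta[mmeta$sample_id %in% sample_ids(tab), ]
tax <- read_taxonomy(file.path("results", "data", "taxonomy.tsv"))

alpha <- alpha_diversity(tab)
a <- merge(alpha, mmeta, by = "sample_id")
cat(sprintf("mean OTU richness: D8 %.2f -> D15 %.2f\n",
            mean(a$richness[a$age_class == "D8"]),
            mean(a$richness[a$age_class == "D15"])))
cat(sprintf("mean Shannon H': D8 %.3f -> D15 %.3f\n",
            mean(a$shannon[a$age_class == "D8"]),
            mean(a$shannon[a$age_class == "D15"])))

a$log_richness <- log(a$richness)
a$age_class <- factor(a$age_class, levels = c("D8", "D15"))
fit <- fit_random_intercept_model(a, "log_richness", fixed = "age_class",
                                  groups = c("bird_id", "nest_of_rearing"))
cat("log richness ~ age, random bird and nest intercepts:\n")
print(fit)

jacc <- jaccard_matrix(tab)
phyla <- aggregate_taxa(tab, tax, "phylum")
cat("phylum means by age:\n")
for (ph in rownames(phyla)) {
  cat(sprintf("  %-16s D8 %.3f  D15 %.3f\n", ph,
              mean(phyla[ph, a$sample_id[a$age_class == "D8"]]),
              mean(phyla[ph, a$sample_id[a$age_class == "D15"]])))
}

write_results(list(alpha = alpha, jaccard = unclass(jacc),
                   phylum_composition = phyla),
              file.path("results", "diversity"), seed = seed)
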