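#!/usr/bin/env Rscript
# Generate the synthetic cross-fostering study that the rest of the
# workflow analyses: 26 nests (18 cross-fostered in 9 pairs, 8 control),
# 6 nestlings per nest sampled at day 8 and day 15, two PCR replicates
# per sample, plus blank tag combinations and negative controls, with
# planted reagent contaminants and known latent community truth.

library(fosterbiome)

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
out <- file.path("results", "data")

man <- write_fixture(out, sim_params(seed = seed))
cat("synthetic study written under", out, "\n")
print(man)

meta <- read_metadata(file.path(out, "metadata.tsv"))
tab <- read_otu_table(file.path(out, "otu_table.tsv"),
                      role_map = setNames(meta$sample_role, meta$sample_id))
rep <- validate_dataset(tab, meta)
print(rep)
stopifnot(rep$pass)
cat(sprintf("%d OTUs x %d samples; %d biological replicates\n",
            n_otus(tab), n_samples(tab),
            sum(tab$roles == "biological")))
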