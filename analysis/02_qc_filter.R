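#!/usr/bin/env Rscript
# Decontamination and filtering cascade: average the two PCR replicates of
# each biological sample, subtract the mean mistag signal measured in the
# blanks, remove OTUs that behave like reagent contaminants (higher max
# AND mean abundance in negative controls than in biological samples),
# drop singleton and <0.005%-abundance OTUs, and rarefy every sample to
# 1000 reads.

library(fosterbiome)

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
dat <- file.path("results", "data")

meta <- read_metadata(file.path(dat, "metadata.tsv"))
tab <- read_otu_table(file.path(dat, "otu_table.tsv"),
                      role_map = setNames(meta$sample_role, meta$sample_id))

qc <- qc_pipeline(tab, meta, filter_params(seed = seed))

cat("filtering cascade:\n")
print(qc$audit)
cat(sprintf("contaminant OTUs removed: %d (%.1f%% of biological reads)\n",
            length(qc$contaminants),
            100 * qc$audit_detail$contaminant$contaminant_fraction_of_reads))
cat("samples below rarefaction depth:",
    if (length(qc$dropped_samples)) qc$dropped_samples else "none", "\n")

write_results(list(filtered_table = qc$table, merged_metadata = qc$meta,
                   audit = qc$audit,
                   contaminants = list(otu_ids = qc$contaminants)),
              file.path("results", "qc"), seed = seed,
              config = qc$params)
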