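#!/usr/bin/env Rscript
# Design-specific contrasts: within-bird community change between the two
# ages by treatment (control / CFstay / CFmove), day-8 OTU retention,
# foster-sibling versus separated-true-sibling similarity at day 15, and
# per-treatment Mantel correlation between the ages.

library(fosterbiome)

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
mmeta <- merged_metadata(read_metadata(
  file.path("results", "data", "metadata.tsv")))
tab <- read_otu_table(file.path("results", "qc", "filtered_table.tsv"),
                      role_map = setNames(mmeta$sample_role,
                                          mmeta$sample_id))
mmeta <- mmeta[mmeta$sample_id %in% sample_ids(tab), ]
jacc <- jaccard_matrix(tab)
tr <- assign_treatment(mmeta)

iic <- merge(intra_individual_change(jacc, mmeta), tr, by = "bird_id")
cat("within-bird Jaccard distance D8->D15 by treatment:\n")
print(round(tapply(iic$distance, iic$label, mean), 3))
iic$moved <- iic$label == "CFmove"
print(fit_random_intercept_model(iic, "distance", fixed = "moved",
                                 groups = "nest_of_rearing"))

ret <- merge(retention_by_bird(tab, mmeta), tr, by = "bird_id")
cat("proportion of D8 OTUs still present at D15 (%):\n")
print(round(tapply(100 * ret$retention, ret$label, mean), 2))

ids <- split(mmeta$sample_id, mmeta$age_class)
j8 <- dist_matrix(jacc[ids$D8, ids$D8])
j15 <- dist_matrix(jacc[ids$D15, ids$D15])

sib <- sibling_similarity_contrast(j15, mmeta, tr)
cat(sprintf("foster-sibling mean distance %.3f vs separated true siblings %.3f\n",
            sib$mean_foster, sib$mean_separated))
print(sib$model)

mt <- mantel_by_treatment(j8, j15, tr, n_perm = 999, seed = seed)
for (g in names(mt)) {
  cat(sprintf("Mantel %-8s r = %.3f, p = %.4f (n = %d birds)\n",
              g, mt[[g]]$statistic, mt[[g]]$p_value, mt[[g]]$n))
}

write_results(list(
  intra_individual = iic, retention = ret,
  sibling_pairs = sib$pair_table, sibling_nest_means = sib$nest_means,
  mantel = data.frame(group = names(mt),
                      r = vapply(mt, function(x) x$statistic, numeric(1)),
                      p = vapply(mt, function(x) x$p_value, numeric(1)))),
  file.path("results", "crossfoster"), seed = seed)
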