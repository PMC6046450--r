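#!/usr/bin/env Rscript
# Community structure: marginal PERMANOVA of nest identity on the Jaccard
# matrices per age, principal coordinates, and homogeneity of dispersion
# of nestlings around their nest centroid.

library(fosterbiome)

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
mmeta <- merged_metadata(read_metadata(
  file.path("results", "data", "metadata.tsv")))
tab <- read_otu_table(file.path("results", "qc", "filtered_table.tsv"),
                      role_map = setNames(mmeta$sample_role,
                                          mmeta$sample_id))
mmeta <- mmeta[mmeta$sample_id %in% sample_ids(tab), ]
jacc <- jaccard_matrix(tab)

results <- list()
for (age in c("D8", "D15")) {
  ids <- mmeta$sample_id[mmeta$age_class == age]
  d <- dist_matrix(jacc[ids, ids])
  nest <- mmeta$nest_of_rearing[match(ids, mmeta$sample_id)]
  pv <- permanova(d, data.frame(nest = nest), n_perm = 999, seed = seed)
  cat(sprintf("PERMANOVA %s: nest F = %.3f, R2 = %.3f, p = %.4f\n", age,
              pv$pseudo_F[1], pv$R2[1], pv$p_value[1]))
  disp <- dispersion_to_centroid(d, nest, n_perm = 999, seed = seed)
  cat(sprintf("dispersion %s: F = %.3f, p = %.4f, mean distance %.3f\n",
              age, disp$test$statistic, disp$test$p_value,
              mean(disp$distances$distance)))
  ord <- pcoa(d)
  cat(sprintf("PCoA %s: first two axes explain %.1f%% of positive inertia\n",
              age, 100 * sum(ord$pos_eigenvalues[1:2]) /
                sum(ord$pos_eigenvalues)))
  results[[paste0("permanova_", age)]] <- pv
  results[[paste0("dispersion_", age)]] <- disp$distances
  results[[paste0("pcoa_", age)]] <- data.frame(
    sample_id = ord$labels, axis1 = ord$vectors[, 1],
    axis2 = ord$vectors[, 2])
}

write_results(results, file.path("results", "community"), seed = seed)
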