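#!/usr/bin/env Rscript
# Body condition: scaled mass index (mass standardized to the reference
# tarsus length via the log-log SMA slope), weight gain between the ages,
# and their association with diversity retention and community stability.
# Birds that did not gain weight are excluded from the gain models.

library(fosterbiome)

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
mmeta <- merged_metadata(read_metadata(
  file.path("results", "data", "metadata.tsv")))
tab <- read_otu_table(file.path("results", "qc", "filtered_table.tsv"),
                      role_map = setNames(mmeta$sample_role,
                                          mmeta$sample_id))
mmeta <- mmeta[mmeta$sample_id %in% sample_ids(tab), ]

# allometry estimated from this dataset itself, then the fixed study values
bio15 <- mmeta[mmeta$age_class == "D15" & mmeta$sample_role == "biological", ]
est <- sma_slope(log(bio15$tarsus_mm), log(bio15$body_mass_g))
cat(sprintf("SMA slope of log mass on log tarsus: %.3f (se %.3f, r = %.3f)\n",
            est$slope, est$slope_se, est$r))
cat(sprintf("mean tarsus length: %.2f mm\n", mean(bio15$tarsus_mm)))

cond <- compute_condition(mmeta)   # fixed slope 1.87, reference 19.3 mm
alpha <- alpha_diversity(tab)
a8 <- alpha[match(paste0(cond$bird_id, "_D8"), alpha$sample_id), ]
a15 <- alpha[match(paste0(cond$bird_id, "_D15"), alpha$sample_id), ]
cond$richness_d15 <- a15$richness
cond$delta_shannon <- a15$shannon - a8$shannon
jacc <- jaccard_matrix(tab)
iic <- intra_individual_change(jacc, mmeta)
cond$similarity <- 1 - iic$distance[match(cond$bird_id, iic$bird_id)]
tr <- assign_treatment(mmeta)
cond <- merge(cond, tr[, c("bird_id", "nest_of_rearing")], by = "bird_id")

cat(sprintf("birds excluded from gain models (no weight gain): %d\n",
            sum(!cond$included_in_gain_models)))

cat("\nSMI ~ D15 richness, random nest intercept:\n")
print(fit_random_intercept_model(cond, "smi", fixed = "richness_d15",
                                 groups = "nest_of_rearing"))
gain <- cond[cond$included_in_gain_models, ]
cat("\nweight gain ~ change in Shannon, random nest intercept:\n")
print(fit_random_intercept_model(gain, "weight_gain",
                                 fixed = "delta_shannon",
                                 groups = "nest_of_rearing"))
cat("\nweight gain ~ within-bird similarity, random nest intercept:\n")
print(fit_random_intercept_model(gain, "weight_gain", fixed = "similarity",
                                 groups = "nest_of_rearing"))

write_results(list(condition = cond,
                   sma = list(slope = est$slope, se = est$slope_se,
                              r = est$r, mean_tarsus = mean(bio15$tarsus_mm))),
              file.path("results", "condition"), seed = seed)
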