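#' Run the full study analysis end to end
#'
#' Orchestrates every analysis block of the study over one dataset:
#' the decontamination/filtering cascade, alpha diversity with its age
#' model, per-age PERMANOVA on nest identity, dispersion of nestlings
#' around their nest centroid, within-bird community change by treatment,
#' day-8 OTU retention by treatment, the foster- versus separated-sibling
#' contrast, per-treatment Mantel correlations between the ages, phylum
#' shifts with age, and the condition models (SMI ~ richness; weight gain
#' ~ diversity change and community stability).  Every block records its
#' inputs, parameters and sample sizes; the whole run is reproducible from
#' `seed`.
#'
#' @param otu raw per-replicate [otu_table].
#' @param meta per-replicate metadata.
#' @param taxonomy taxonomy table.
#' @param params a [filter_params]; its `seed` also seeds every
#'   permutation test.
#' @param n_perm permutations for all permutation tests (default 1000).
#' @param smi_slope,smi_l0,estimate_smi_params forwarded to
#'   [compute_condition].
#' @return list of class `study_report`; see Details for the block names.
#' @details Blocks: `qc`, `alpha_age`, `permanova_nest`, `dispersion`,
#'   `intra_individual`, `retention`, `sibling_contrast`,
#'   `mantel_by_treatment`, `phylum_shift`, `condition`.
#' @export
run_pipeline <- function(otu, meta, taxonomy, params = filter_params(),
                         n_perm = 1000L, smi_slope = 1.87, smi_l0 = 19.3,
                         estimate_smi_params = FALSE) {
  seed <- params$seed
  stage <- "qc"
  report <- list()
  tryCatch({
    qc <- qc_pipeline(otu, meta, params)
    report$qc <- list(audit = qc$audit,
                      n_contaminants = length(qc$contaminants),
                      contaminants = qc$contaminants,
                      dropped_samples = qc$dropped_samples,
                      params = unclass(params))
    tab <- qc$table
    mmeta <- qc$meta
    treatments <- assign_treatment(mmeta)

    stage <- "alpha_age"
    alpha <- alpha_diversity(tab)
    adat <- merge(alpha, mmeta, by = "sample_id")
    adat <- merge(adat, treatments[, c("bird_id", "label")], by = "bird_id")
    adat$log_richness <- log(adat$richness)
    adat$age_class <- factor(adat$age_class, levels = c("D8", "D15"))
    adat$crossfostered <- adat$label != "control"
    fit_alpha <- function(resp) fit_random_intercept_model(
      adat, resp, fixed = c("age_class", "crossfostered"),
      groups = c("bird_id", "nest_of_rearing"))
    report$alpha_age <- list(
      mean_richness_d8 = mean(adat$richness[adat$age_class == "D8"]),
      mean_richness_d15 = mean(adat$richness[adat$age_class == "D15"]),
      mean_shannon_d8 = mean(adat$shannon[adat$age_class == "D8"]),
      mean_shannon_d15 = mean(adat$shannon[adat$age_class == "D15"]),
      log_richness = fit_alpha("log_richness"),
      shannon = fit_alpha("shannon"),
      evenness = fit_random_intercept_model(
        adat[!is.na(adat$evenness), ], "evenness",
        fixed = c("age_class", "crossfostered"),
        groups = c("bird_id", "nest_of_rearing")),
      n = nrow(adat))

    stage <- "beta_diversity"
    jacc <- jaccard_matrix(tab)
    by_age <- split(mmeta$sample_id, mmeta$age_class)
    jacc_d8 <- dist_matrix(jacc[by_age$D8, by_age$D8])
    jacc_d15 <- dist_matrix(jacc[by_age$D15, by_age$D15])

    stage <- "permanova_nest"
    pn <- function(d, ids) {
      nest <- mmeta$nest_of_rearing[match(rownames(d), mmeta$sample_id)]
      permanova(d, data.frame(nest = nest), terms = "nest",
                n_perm = n_perm, seed = seed)
    }
    d15_control <- mmeta$sample_id[mmeta$age_class == "D15" &
                                     mmeta$nest_treatment == "control"]
    d15_cf <- mmeta$sample_id[mmeta$age_class == "D15" &
                                mmeta$nest_treatment == "crossfostered"]
    report$permanova_nest <- list(
      d8_all = pn(jacc_d8),
      d15_control = pn(dist_matrix(jacc[d15_control, d15_control])),
      d15_cf = pn(dist_matrix(jacc[d15_cf, d15_cf])),
      n_permutations = n_perm)

    stage <- "dispersion"
    disp <- function(d) {
      nest <- mmeta$nest_of_rearing[match(rownames(d), mmeta$sample_id)]
      dispersion_to_centroid(d, nest, n_perm = n_perm, seed = seed)
    }
    disp_d8 <- disp(jacc_d8); disp_d15 <- disp(jacc_d15)
    disp_tab <- rbind(
      transform(disp_d8$distances, age_class = "D8"),
      transform(disp_d15$distances, age_class = "D15"))
    disp_tab <- merge(disp_tab,
                      mmeta[, c("sample_id", "bird_id")], by = "sample_id")
    disp_tab <- merge(disp_tab, treatments[, c("bird_id", "label")],
                      by = "bird_id")
    report$dispersion <- list(
      d8 = disp_d8$test, d15 = disp_d15$test,
      table = disp_tab,
      group_means = stats::aggregate(
        distance ~ age_class + label, data = disp_tab, FUN = mean))

    stage <- "intra_individual"
    iic <- intra_individual_change(jacc, mmeta)
    iic <- merge(iic, treatments, by = "bird_id")
    iic$moved <- iic$label == "CFmove"
    report$intra_individual <- list(
      table = iic,
      group_means = tapply(iic$distance, iic$label, mean),
      model = fit_random_intercept_model(
        iic, "distance", fixed = "moved", groups = "nest_of_rearing"),
      n = nrow(iic))

    stage <- "retention"
    ret <- retention_by_bird(tab, mmeta)
    ret <- merge(ret, treatments[, c("bird_id", "label",
                                     "nest_of_rearing")], by = "bird_id")
    cf_ret <- ret[ret$label %in% c("CFstay", "CFmove"), ]
    cf_ret$moved <- cf_ret$label == "CFmove"
    report$retention <- list(
      table = ret,
      group_means_pct = tapply(100 * ret$retention, ret$label, mean),
      model = fit_random_intercept_model(
        cf_ret, "retention", fixed = "moved", groups = "nest_of_rearing"),
      n = nrow(ret))

    stage <- "sibling_contrast"
    report$sibling_contrast <- sibling_similarity_contrast(
      jacc_d15, mmeta, treatments)

    stage <- "mantel_by_treatment"
    report$mantel_by_treatment <- mantel_by_treatment(
      jacc_d8, jacc_d15, treatments, n_perm = n_perm, seed = seed)

    stage <- "phylum_shift"
    phyla <- aggregate_taxa(tab, taxonomy, "phylum")
    pdat <- mmeta
    pdat$age_class <- factor(pdat$age_class, levels = c("D8", "D15"))
    shift <- list()
    for (ph in intersect(c("Firmicutes", "Proteobacteria"),
                         rownames(phyla))) {
      pdat$abund <- phyla[ph, pdat$sample_id]
      shift[[ph]] <- list(
        mean_d8 = mean(pdat$abund[pdat$age_class == "D8"]),
        mean_d15 = mean(pdat$abund[pdat$age_class == "D15"]),
        model = fit_random_intercept_model(
          pdat, "abund", fixed = "age_class",
          groups = c("bird_id", "nest_of_rearing")))
    }
    report$phylum_shift <- shift

    stage <- "condition"
    cond <- compute_condition(mmeta, slope = smi_slope, l0 = smi_l0,
                              estimate_params = estimate_smi_params)
    a8 <- alpha[match(paste0(cond$bird_id, "_D8"), alpha$sample_id), ]
    a15 <- alpha[match(paste0(cond$bird_id, "_D15"), alpha$sample_id), ]
    cond$richness_d15 <- a15$richness
    cond$delta_richness <- a15$richness - a8$richness
    cond$delta_shannon <- a15$shannon - a8$shannon
    cond$similarity <- 1 - iic$distance[match(cond$bird_id, iic$bird_id)]
    cond <- merge(cond, treatments[, c("bird_id", "nest_of_rearing")],
                  by = "bird_id")
    gain <- cond[cond$included_in_gain_models, ]
    report$condition <- list(
      table = cond,
      smi_params = attr(cond, "smi_params"),
      n_excluded_nonpositive_gain = sum(!cond$included_in_gain_models,
                                        na.rm = TRUE),
      smi_richness = fit_random_intercept_model(
        cond, "smi", fixed = "richness_d15", groups = "nest_of_rearing"),
      gain_delta_richness = fit_random_intercept_model(
        gain, "weight_gain", fixed = "delta_richness",
        groups = "nest_of_rearing"),
      gain_delta_shannon = fit_random_intercept_model(
        gain, "weight_gain", fixed = "delta_shannon",
        groups = "nest_of_rearing"),
      gain_similarity = fit_random_intercept_model(
        gain, "weight_gain", fixed = "similarity",
        groups = "nest_of_rearing"))

    report$run <- list(seed = seed, n_perm = n_perm,
                       smi = list(slope = smi_slope, l0 = smi_l0,
                                  estimated = estimate_smi_params))
    structure(report, class = "study_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Day-8 to day-15 OTU retention per bird
#'
#' @param tab rarefied [otu_table] over merged samples of both ages.
#' @param mmeta merged metadata.
#' @return data.frame `bird_id`, `retention` (proportion of day-8 OTUs
#'   still present at day 15) for birds with both samples.
#' @export
retention_by_bird <- function(tab, mmeta) {
  bio <- mmeta[!is.na(mmeta$sample_role) &
                 mmeta$sample_role == "biological", ]
  birds <- unique(bio$bird_id)
  s8 <- bird_samples(sample_ids(tab), birds, "D8")
  s15 <- bird_samples(sample_ids(tab), birds, "D15")
  both <- intersect(names(s8), names(s15))
  data.frame(bird_id = both,
             retention = vapply(both, function(b)
               otu_retention(tab$counts[, s8[b]], tab$counts[, s15[b]]),
               numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report with blocks:",
      paste(setdiff(names(x), "run"), collapse = ", "), "\n")
  invisible(x)
}
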