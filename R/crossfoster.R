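#' Assign each bird its experimental treatment label
#'
#' `control` for birds in control nests; within cross-fostered nests,
#' `CFmove` for birds whose nest of rearing differs from their nest of
#' origin and `CFstay` for those that remained.  Labels are derived from
#' the day-15 records (rearing can only differ after the swap).
#'
#' @param meta merged or per-replicate metadata containing both ages for
#'   every bird.
#' @return data.frame `bird_id`, `label`, `nest_of_origin`,
#'   `nest_of_rearing` (at D15).
#' @export
assign_treatment <- function(meta) {
  bio <- meta[!is.na(meta$sample_role) & meta$sample_role == "biological", ]
  birds <- unique(bio$bird_id)
  rows <- lapply(birds, function(b) {
    rec <- bio[bio$bird_id == b, ]
    if (length(unique(rec$nest_of_origin)) != 1L ||
        length(unique(rec$nest_treatment)) != 1L) {
      stop("bird '", b, "' has inconsistent nest records", call. = FALSE)
    }
    d15 <- rec[rec$age_class == "D15", ]
    rearing <- if (nrow(d15)) d15$nest_of_rearing[1L] else
      rec$nest_of_rearing[1L]
    origin <- rec$nest_of_origin[1L]
    label <- if (rec$nest_treatment[1L] == "control") "control"
    else if (rearing != origin) "CFmove" else "CFstay"
    data.frame(bird_id = b, label = label, nest_of_origin = origin,
               nest_of_rearing = rearing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# bird -> merged sample id lookup for one age, restricted to samples
# actually present in the distance matrix
bird_samples <- function(labels, birds, age) {
  ids <- paste(birds, age, sep = "_")
  found <- ids %in% labels
  stats::setNames(ids[found], birds[found])
}

#' Within-bird community change between the two ages
#'
#' For every bird with both its day-8 and day-15 samples in the matrix,
#' the Jaccard distance between the two samples; birds missing one age are
#' excluded and listed.
#'
#' @param jacc a [dist_matrix] over merged samples of both ages (labels
#'   `<bird>_<age>`).
#' @param meta merged metadata.
#' @return data.frame `bird_id`, `distance`, plus attribute `excluded`.
#' @export
intra_individual_change <- function(jacc, meta) {
  jacc <- dist_matrix(jacc)
  bio <- meta[!is.na(meta$sample_role) & meta$sample_role == "biological", ]
  birds <- unique(bio$bird_id)
  s8 <- bird_samples(rownames(jacc), birds, "D8")
  s15 <- bird_samples(rownames(jacc), birds, "D15")
  both <- intersect(names(s8), names(s15))
  out <- data.frame(bird_id = both,
                    distance = jacc[cbind(s8[both], s15[both])],
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- setdiff(birds, both)
  out
}

#' Foster-sibling versus separated-true-sibling similarity at day 15
#'
#' Within cross-fostered nests only: foster-sibling pairs share the nest of
#' rearing but not the nest of origin; separated-true-sibling pairs share
#' the nest of origin but not the nest of rearing.  Pairwise day-15 Jaccard
#' distances are averaged per nest (nest of rearing for foster pairs, nest
#' of origin for separated pairs) to avoid pseudo-replication, and the
#' foster-minus-separated difference is tested with a random-intercept
#' model with nest as grouping factor.  The per-pair table is also
#' returned.
#'
#' @param jacc_d15 [dist_matrix] over day-15 merged samples.
#' @param meta merged metadata.
#' @param treatments output of [assign_treatment] (recomputed if NULL).
#' @return list with `pair_table`, `nest_means`, `mean_foster`,
#'   `mean_separated`, and `model` (a `model_fit` on the nest-level means;
#'   negative `pair_type` estimate = foster pairs more similar).
#' @export
sibling_similarity_contrast <- function(jacc_d15, meta, treatments = NULL) {
  jacc_d15 <- dist_matrix(jacc_d15)
  if (is.null(treatments)) treatments <- assign_treatment(meta)
  cf <- treatments[treatments$label != "control", ]
  if (!nrow(cf)) stop("no cross-fostered birds", call. = FALSE)
  s15 <- bird_samples(rownames(jacc_d15), cf$bird_id, "D15")
  cf <- cf[cf$bird_id %in% names(s15), ]
  pairs <- list()
  n <- nrow(cf)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    same_rear <- cf$nest_of_rearing[i] == cf$nest_of_rearing[j]
    same_orig <- cf$nest_of_origin[i] == cf$nest_of_origin[j]
    type <- if (same_rear && !same_orig) "foster"
    else if (same_orig && !same_rear) "separated"
    else next
    pairs[[length(pairs) + 1L]] <- data.frame(
      bird_1 = cf$bird_id[i], bird_2 = cf$bird_id[j], pair_type = type,
      nest = if (type == "foster") cf$nest_of_rearing[i] else
        cf$nest_of_origin[i],
      distance = jacc_d15[s15[cf$bird_id[i]], s15[cf$bird_id[j]]],
      stringsAsFactors = FALSE)
  }
  if (!length(pairs)) {
    stop("no qualifying sibling pairs in cross-fostered nests",
         call. = FALSE)
  }
  pair_table <- do.call(rbind, pairs)
  nest_means <- stats::aggregate(distance ~ nest + pair_type,
                                 data = pair_table, FUN = mean)
  nest_means$pair_type <- factor(nest_means$pair_type,
                                 levels = c("foster", "separated"))
  model <- fit_random_intercept_model(nest_means, "distance",
                                      fixed = "pair_type",
                                      groups = "nest")
  list(pair_table = pair_table, nest_means = nest_means,
       mean_foster = mean(pair_table$distance[
         pair_table$pair_type == "foster"]),
       mean_separated = mean(pair_table$distance[
         pair_table$pair_type == "separated"]),
       model = model)
}

#' Mantel correlation between the two ages, per treatment group
#'
#' For each treatment group the day-8 and day-15 Jaccard sub-matrices are
#' restricted to that group's birds (rows matched by bird) and correlated
#' by [mantel].  Groups with fewer than 4 birds having both samples are
#' skipped with a warning.
#'
#' @param jacc_d8,jacc_d15 [dist_matrix] objects over merged samples.
#' @param treatments output of [assign_treatment].
#' @param n_perm,seed forwarded to [mantel].
#' @return named list of `perm_test` results (control, CFstay, CFmove as
#'   available).
#' @export
mantel_by_treatment <- function(jacc_d8, jacc_d15, treatments,
                                n_perm = 1000L, seed = 1L) {
  jacc_d8 <- dist_matrix(jacc_d8); jacc_d15 <- dist_matrix(jacc_d15)
  out <- list()
  for (gr in intersect(c("control", "CFstay", "CFmove"),
                       unique(treatments$label))) {
    birds <- treatments$bird_id[treatments$label == gr]
    s8 <- bird_samples(rownames(jacc_d8), birds, "D8")
    s15 <- bird_samples(rownames(jacc_d15), birds, "D15")
    both <- intersect(names(s8), names(s15))
    if (length(both) < 4L) {
      warning("treatment group '", gr, "' has fewer than 4 birds; skipped")
      next
    }
    m8 <- jacc_d8[s8[both], s8[both]]
    m15 <- jacc_d15[s15[both], s15[both]]
    dimnames(m8) <- dimnames(m15) <- list(both, both)
    out[[gr]] <- mantel(dist_matrix(m8), dist_matrix(m15),
                        n_perm = n_perm, seed = seed)
  }
  out
}

#' Scaled mass index and weight gain per bird
#'
#' SMI standardizes day-15 body mass to the reference tarsus length:
#' `smi = mass_D15 * (l0 / tarsus)^slope`.  Defaults are the study-wide
#' allometry values (SMA slope 1.87, mean tarsus 19.3 mm); both can be
#' re-estimated from the data with `estimate_params = TRUE`, which runs
#' [sma_slope] on (log tarsus, log day-15 mass) and uses the mean tarsus.
#' Weight gain is day-15 minus day-8 mass; only birds with positive gain
#' are flagged for the gain models.
#'
#' @param meta merged metadata with day-8 and day-15 mass and day-15
#'   tarsus.
#' @param slope,l0 SMI allometry parameters.
#' @param estimate_params recompute `slope` and `l0` from the data.
#' @return data.frame `bird_id`, `mass_d8`, `mass_d15`, `tarsus`, `smi`,
#'   `weight_gain`, `included_in_gain_models`; attribute `smi_params`
#'   records the slope/l0 used and their provenance.
#' @export
compute_condition <- function(meta, slope = 1.87, l0 = 19.3,
                              estimate_params = FALSE) {
  bio <- meta[!is.na(meta$sample_role) & meta$sample_role == "biological", ]
  d8 <- bio[bio$age_class == "D8", ]
  d15 <- bio[bio$age_class == "D15", ]
  birds <- unique(bio$bird_id)
  out <- data.frame(
    bird_id = birds,
    mass_d8 = d8$body_mass_g[match(birds, d8$bird_id)],
    mass_d15 = d15$body_mass_g[match(birds, d15$bird_id)],
    tarsus = d15$tarsus_mm[match(birds, d15$bird_id)],
    stringsAsFactors = FALSE)
  provenance <- "fixed"
  if (estimate_params) {
    ok <- !is.na(out$tarsus) & !is.na(out$mass_d15)
    fit <- sma_slope(log(out$tarsus[ok]), log(out$mass_d15[ok]))
    slope <- fit$slope
    l0 <- mean(out$tarsus[ok])
    provenance <- "estimated"
  }
  out$smi <- out$mass_d15 * (l0 / out$tarsus)^slope
  out$weight_gain <- out$mass_d15 - out$mass_d8
  out$included_in_gain_models <- !is.na(out$weight_gain) &
    out$weight_gain > 0
  attr(out, "smi_params") <- list(slope = slope, l0 = l0,
                                  provenance = provenance)
  out
}
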