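#' Parameters for the synthetic cross-fostering study generator
#'
#' Defaults reproduce the study design: 26 nests of which 18 are
#' cross-fostered (9 pairs) and 8 are controls, 6 nestlings per nest
#' sampled at both ages, 3 of 6 swapped between paired nests, two PCR
#' replicates per biological sample, blanks and negative controls
#' alongside, and the study's allometry constants (SMA slope 1.87, mean
#' tarsus 19.3 mm).
#'
#' @param n_nests number of nests (default 26).
#' @param n_cf_pairs cross-fostered nest pairs (default 9, i.e. 18 CF
#'   nests); `2 * n_cf_pairs <= n_nests`.
#' @param nestlings_per_nest nestlings sampled per nest (default 6; must
#'   be even so half can be swapped).
#' @param n_otus real OTUs in the pool (default 300).
#' @param n_contaminants reagent-contaminant OTUs (default 30).
#' @param phylum_props named day-8 expected phylum shares (sums to 1).
#' @param firmicutes_up,proteobacteria_down multiplicative reweighting of
#'   the Firmicutes / Proteobacteria shares in the day-15 target.
#' @param diversity_drop in [0, 1]: strength of geometric down-weighting
#'   of rare OTUs in the day-15 target (0 = none).
#' @param tail_exponent steepness of the down-weighting in
#'   `exp(-tail_exponent * diversity_drop * rank_quantile)`.
#' @param lambda convergence weight of the rearing-nest day-15 target in
#'   each bird's day-15 profile (0 = bird keeps its day-8 profile).
#' @param lambda_concentration Beta concentration of per-bird lambda
#'   heterogeneity (`Inf` for a common lambda).
#' @param nestmate_influence weight of the current occupants' mean day-8
#'   profile, versus the physical nest's own profile, in the day-15
#'   target.
#' @param nest_concentration Dirichlet concentration of nest day-8
#'   profiles around the OTU pool.
#' @param bird_concentration Dirichlet concentration of individual
#'   profiles around their latent expectation at both ages (larger = less
#'   individuality).
#' @param otu_lognormal_sd sd of the log-normal rank-abundance weights of
#'   the OTU pool; together with the concentrations it sets the rarefied
#'   richness scale.
#' @param depth expected reads per PCR replicate (Poisson).
#' @param n_blanks,blank_rate blank tag combinations and their expected
#'   total mistag reads each.
#' @param n_negatives negative-control samples.
#' @param contaminant_neg_mean expected reads per contaminant OTU per
#'   negative control.
#' @param contaminant_trace_rate expected reads per contaminant OTU per
#'   biological replicate (cross-contamination trace).
#' @param negative_crosstalk expected real-community reads per negative
#'   control.
#' @param sma_slope,mean_tarsus,tarsus_sd,mass_noise_sd morphometric
#'   allometry: slope of log mass on log tarsus, mean and sd of tarsus
#'   (mm), and residual noise sd on the log-mass scale (an error of
#'   `mass_noise_sd / sma_slope` is placed on log tarsus as well, the
#'   error-in-variables structure SMA regression assumes).
#' @param condition_coupling gamma: effect of a bird's latent diversity
#'   retention (centred) on log day-15 mass.
#' @param neg_gain_frac fraction of birds constructed to lose weight.
#' @param seed integer seed; all randomness flows from it through one
#'   stream in documented order.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_nests = 26L, n_cf_pairs = 9L,
                       nestlings_per_nest = 6L,
                       n_otus = 300L, n_contaminants = 30L,
                       phylum_props = c(Firmicutes = 0.30,
                                        Actinobacteria = 0.28,
                                        Proteobacteria = 0.30,
                                        Bacteroidetes = 0.07,
                                        Other = 0.05),
                       firmicutes_up = 2.0, proteobacteria_down = 0.35,
                       diversity_drop = 0.6, tail_exponent = 8,
                       lambda = 0.7, lambda_concentration = 12,
                       nestmate_influence = 0.3,
                       nest_concentration = 50,
                       bird_concentration = 35,
                       otu_lognormal_sd = 1.4,
                       depth = 10000L,
                       n_blanks = 4L, blank_rate = 50,
                       n_negatives = 4L,
                       contaminant_neg_mean = 80,
                       contaminant_trace_rate = 0.2,
                       negative_crosstalk = 100,
                       sma_slope = 1.87, mean_tarsus = 19.3,
                       tarsus_sd = 0.6, mass_noise_sd = 0.015,
                       condition_coupling = 0.15,
                       neg_gain_frac = 0.025,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_cf_pairs * 2L <= p$n_nests,
            p$nestlings_per_nest %% 2L == 0L,
            p$lambda >= 0, p$lambda <= 1,
            p$diversity_drop >= 0, p$diversity_drop <= 1,
            abs(sum(p$phylum_props) - 1) < 1e-8,
            p$depth >= 1, p$seed == round(p$seed))
  structure(p, class = "sim_params")
}

rdirichlet_one <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape)
  if (sum(g) == 0) g[which.max(shape)] <- 1
  g / sum(g)
}

#' Simulate nestling morphometrics with SMA-consistent noise
#'
#' Latent log size drives both measurements: log tarsus gets error
#' `noise_sd / slope`, log mass gets error `noise_sd`, so the population
#' standardized-major-axis slope of log mass on log tarsus equals `slope`
#' exactly (errors on both axes in the slope's proportion).  Day-8 mass is
#' derived from day-15 mass through a positive log gain, inverted for a
#' `neg_gain_frac` fraction of birds.
#'
#' @param n number of birds.
#' @param slope,mean_tarsus,tarsus_sd,noise_sd allometry parameters (see
#'   [sim_params]).
#' @param retention optional per-bird latent diversity retention; centred
#'   and scaled by `gamma` into log day-15 mass.
#' @param gamma coupling of retention to log mass.
#' @param mean_mass expected day-15 mass (g) at the mean tarsus.
#' @param neg_gain_frac fraction of birds that lose weight.
#' @param seed optional seed; leave `NULL` to consume the current RNG
#'   stream (as [generate_dataset] does).
#' @return data.frame `tarsus`, `mass_d15`, `mass_d8`.
#' @export
simulate_morphometrics <- function(n, slope = 1.87, mean_tarsus = 19.3,
                                   tarsus_sd = 0.6, noise_sd = 0.015,
                                   retention = NULL, gamma = 0,
                                   mean_mass = 18, neg_gain_frac = 0.025,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  size_sd <- tarsus_sd / mean_tarsus
  s <- stats::rnorm(n, 0, size_sd)
  log_tarsus <- log(mean_tarsus) + s + stats::rnorm(n, 0, noise_sd / slope)
  a <- log(mean_mass) - slope * log(mean_tarsus)
  ret_c <- if (is.null(retention)) 0 else retention - mean(retention)
  log_mass <- a + slope * (log(mean_tarsus) + s) + gamma * ret_c +
    stats::rnorm(n, 0, noise_sd)
  mass_d15 <- exp(log_mass)
  # retention also promotes growth directly: birds keeping their community
  # gain relatively more weight between the two ages
  log_gain_ratio <- 0.4 + 2 * gamma * ret_c + stats::rnorm(n, 0, 0.1)
  losers <- stats::runif(n) < neg_gain_frac
  log_gain_ratio[losers] <- -abs(stats::rnorm(sum(losers), 0.02, 0.01))
  data.frame(tarsus = exp(log_tarsus), mass_d15 = mass_d15,
             mass_d8 = mass_d15 * exp(-log_gain_ratio))
}

#' Generate a complete synthetic cross-fostering study
#'
#' Produces an OTU table with two PCR replicates per biological sample
#' plus blanks and negative controls, the matching metadata and taxonomy,
#' and the full latent truth.  Generation order (one RNG stream from
#' `params$seed`): OTU pool and taxonomy; nest day-8 profiles; swap
#' choices; per-bird day-8 profiles and convergence weights; day-15
#' targets and profiles; read counts per sample in sample order;
#' technical samples; morphometrics.
#'
#' The community model is Dirichlet-multinomial.  Each nest's day-8
#' profile is Dirichlet around a phylum-weighted log-normal OTU pool; each
#' bird's day-8 profile is Dirichlet around its nest's.  The day-15 target
#' of a nest mixes the physical nest's profile with the current
#' occupants' mean day-8 profile (`nestmate_influence`), reweights phyla
#' by the age multipliers, and geometrically down-weights rare OTUs
#' (`diversity_drop`); a bird's day-15 profile is
#' `lambda_i * target(rearing nest) + (1 - lambda_i) * own day-8 profile`.
#' Contaminant OTUs are abundant in negative controls and trace-level in
#' biological samples; blanks carry Poisson mistag reads from the pooled
#' community.
#'
#' @param params a [sim_params].
#' @return list with `otu` (an [otu_table]), `meta`, `taxonomy`, and
#'   `truth` (nest profiles, per-bird profiles and mixing weights,
#'   contaminant ids, latent retention, the params).
#' @export
generate_dataset <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  phyla <- names(p$phylum_props)

  # --- OTU pool & taxonomy ------------------------------------------------
  otu_id <- sprintf("OTU%04d", seq_len(p$n_otus))
  otu_phylum <- sample(phyla, p$n_otus, replace = TRUE,
                       prob = p$phylum_props)
  w <- stats::rlnorm(p$n_otus, 0, p$otu_lognormal_sd)
  # scale weights so each phylum's expected share matches phylum_props
  for (ph in phyla) {
    i <- otu_phylum == ph
    if (any(i)) w[i] <- w[i] / sum(w[i]) * p$phylum_props[[ph]]
  }
  contam_id <- if (p$n_contaminants > 0)
    sprintf("CONTAM%03d", seq_len(p$n_contaminants)) else character()
  contam_phylum <- sample(c("Proteobacteria", "Actinobacteria"),
                          p$n_contaminants, replace = TRUE)
  taxonomy <- parse_taxonomy(
    c(otu_id, contam_id),
    paste0("Bacteria;", c(otu_phylum, contam_phylum)))

  # --- nests, birds, cross-foster design ----------------------------------
  cf_nests <- seq_len(2L * p$n_cf_pairs)
  nest_id <- sprintf("N%02d", seq_len(p$n_nests))
  nest_treatment <- ifelse(seq_len(p$n_nests) %in% cf_nests,
                           "crossfostered", "control")
  nest_profile_d8 <- vapply(seq_len(p$n_nests), function(k)
    rdirichlet_one(p$nest_concentration * w), numeric(p$n_otus))
  colnames(nest_profile_d8) <- nest_id

  k <- p$nestlings_per_nest
  birds <- data.frame(
    bird_id = sprintf("B%02d_%d", rep(seq_len(p$n_nests), each = k),
                      rep(seq_len(k), p$n_nests)),
    origin = rep(nest_id, each = k),
    treatment = rep(nest_treatment, each = k),
    stringsAsFactors = FALSE)
  birds$rearing <- birds$origin
  for (pair in seq_len(p$n_cf_pairs)) {
    a <- nest_id[2L * pair - 1L]; b <- nest_id[2L * pair]
    move_a <- sample(which(birds$origin == a), k %/% 2L)
    move_b <- sample(which(birds$origin == b), k %/% 2L)
    birds$rearing[move_a] <- b
    birds$rearing[move_b] <- a
  }
  n_birds <- nrow(birds)

  # --- latent profiles ----------------------------------------------------
  p8 <- vapply(seq_len(n_birds), function(i)
    rdirichlet_one(p$bird_concentration *
                     nest_profile_d8[, birds$origin[i]]),
    numeric(p$n_otus))
  colnames(p8) <- birds$bird_id
  lambda_i <- if (p$lambda <= 0 || p$lambda >= 1 ||
                  !is.finite(p$lambda_concentration)) {
    rep(p$lambda, n_birds)
  } else {
    stats::rbeta(n_birds, p$lambda * p$lambda_concentration,
                 (1 - p$lambda) * p$lambda_concentration)
  }

  phylum_factor <- rep(1, p$n_otus)
  phylum_factor[otu_phylum == "Firmicutes"] <- p$firmicutes_up
  phylum_factor[otu_phylum == "Proteobacteria"] <- p$proteobacteria_down
  d15_target <- vapply(seq_len(p$n_nests), function(nk) {
    occ <- birds$rearing == nest_id[nk]
    m_occ <- rowMeans(p8[, occ, drop = FALSE])
    base <- (1 - p$nestmate_influence) * nest_profile_d8[, nk] +
      p$nestmate_influence * m_occ
    q <- (rank(-base, ties.method = "first") - 1) / (p$n_otus - 1)
    v <- base * phylum_factor *
      exp(-p$tail_exponent * p$diversity_drop * q)
    v / sum(v)
  }, numeric(p$n_otus))
  colnames(d15_target) <- nest_id

  p15 <- vapply(seq_len(n_birds), function(i) {
    mix <- lambda_i[i] * d15_target[, birds$rearing[i]] +
      (1 - lambda_i[i]) * p8[, i]
    # individual day-15 colonization noise; expectation stays at the mix
    rdirichlet_one(p$bird_concentration * mix)
  }, numeric(p$n_otus))
  colnames(p15) <- birds$bird_id
  retention <- vapply(seq_len(n_birds), function(i)
    sum(pmin(p8[, i], p15[, i])), numeric(1))

  # --- read counts --------------------------------------------------------
  n_all <- p$n_otus + p$n_contaminants
  all_ids <- c(otu_id, contam_id)
  draw_bio <- function(profile) {
    reads <- stats::rmultinom(1L, stats::rpois(1L, p$depth), profile)[, 1L]
    c(reads, stats::rpois(p$n_contaminants, p$contaminant_trace_rate))
  }
  cols <- list(); roles <- character(); meta_rows <- list()
  add_sample <- function(id, counts, role, meta_row) {
    cols[[id]] <<- counts
    roles[id] <<- role
    meta_rows[[id]] <<- meta_row
  }
  blank_meta <- function(id, role) data.frame(
    sample_id = id, bird_id = NA, nest_of_origin = NA,
    nest_of_rearing = NA, age_class = NA, nest_treatment = NA,
    body_mass_g = NA_real_, tarsus_mm = NA_real_, replicate_id = NA,
    sample_role = role, stringsAsFactors = FALSE)

  # morphometrics drawn after profiles, before counts, so the count draws
  # do not shift when morphometric parameters change
  morph <- simulate_morphometrics(
    n_birds, slope = p$sma_slope, mean_tarsus = p$mean_tarsus,
    tarsus_sd = p$tarsus_sd, noise_sd = p$mass_noise_sd,
    retention = retention, gamma = p$condition_coupling,
    neg_gain_frac = p$neg_gain_frac)

  for (i in seq_len(n_birds)) {
    for (age in c("D8", "D15")) {
      prof <- if (age == "D8") p8[, i] else p15[, i]
      for (r in 1:2) {
        id <- sprintf("%s_%s_r%d", birds$bird_id[i], age, r)
        add_sample(id, draw_bio(prof), "biological", data.frame(
          sample_id = id, bird_id = birds$bird_id[i],
          nest_of_origin = birds$origin[i],
          nest_of_rearing = if (age == "D8") birds$origin[i] else
            birds$rearing[i],
          age_class = age, nest_treatment = birds$treatment[i],
          body_mass_g = if (age == "D8") morph$mass_d8[i] else
            morph$mass_d15[i],
          tarsus_mm = if (age == "D8") NA_real_ else morph$tarsus[i],
          replicate_id = paste0("r", r), sample_role = "biological",
          stringsAsFactors = FALSE))
      }
    }
  }
  pooled <- rowMeans(cbind(p8, p15))
  for (j in seq_len(p$n_negatives)) {
    id <- sprintf("NEG%02d", j)
    counts <- c(stats::rmultinom(1L, stats::rpois(1L, p$negative_crosstalk),
                                 pooled)[, 1L],
                stats::rpois(p$n_contaminants, p$contaminant_neg_mean))
    add_sample(id, counts, "negative_control", blank_meta(id,
      "negative_control"))
  }
  for (j in seq_len(p$n_blanks)) {
    id <- sprintf("BLANK%02d", j)
    counts <- c(stats::rmultinom(1L, stats::rpois(1L, p$blank_rate),
                                 pooled)[, 1L],
                stats::rpois(p$n_contaminants,
                             p$contaminant_trace_rate))
    add_sample(id, counts, "blank", blank_meta(id, "blank"))
  }

  counts <- matrix(unlist(cols, use.names = FALSE), nrow = n_all,
                   dimnames = list(all_ids, names(cols)))
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL

  list(otu = otu_table(counts, roles),
       meta = meta,
       taxonomy = taxonomy,
       truth = list(birds = birds, nest_profile_d8 = nest_profile_d8,
                    d15_target = d15_target, bird_profile_d8 = p8,
                    bird_profile_d15 = p15, lambda = lambda_i,
                    retention = retention, contaminants = contam_id,
                    otu_phylum = otu_phylum, morphometrics = morph,
                    params = p))
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' @param out_dir output directory (created if needed).
#' @param params a [sim_params].
#' @return data.frame manifest of the five files written (counts TSV,
#'   metadata TSV, taxonomy TSV, truth JSON, params JSON).
#' @export
write_fixture <- function(out_dir, params = sim_params()) {
  sim <- generate_dataset(params)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c(otu_table = "otu_table.tsv", metadata = "metadata.tsv",
             taxonomy = "taxonomy.tsv", truth = "truth.json",
             params = "params.json")
  write_otu_table(sim$otu, file.path(out_dir, files["otu_table"]))
  write_metadata(sim$meta, file.path(out_dir, files["metadata"]))
  write_taxonomy(sim$taxonomy, file.path(out_dir, files["taxonomy"]))
  truth_slim <- list(contaminants = sim$truth$contaminants,
                     lambda = sim$truth$lambda,
                     retention = sim$truth$retention,
                     birds = sim$truth$birds)
  jsonlite::write_json(truth_slim, file.path(out_dir, files["truth"]),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(params), file.path(out_dir, files["params"]),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.frame(name = names(files),
             file = file.path(out_dir, unname(files)),
             stringsAsFactors = FALSE)
}
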