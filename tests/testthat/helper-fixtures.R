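# shared fixture builders and independent oracles

make_table <- function(counts, roles = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("OTU%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  }
  if (is.null(roles)) roles <- rep("biological", ncol(counts))
  otu_table(counts, roles)
}

# one metadata row per argument set, with sensible defaults
meta_row <- function(sample_id, bird_id = NA, origin = NA, rearing = origin,
                     age = NA, treatment = NA, mass = NA_real_,
                     tarsus = NA_real_, rep_id = NA, role = "biological") {
  data.frame(sample_id = sample_id, bird_id = bird_id,
             nest_of_origin = origin, nest_of_rearing = rearing,
             age_class = age, nest_treatment = treatment,
             body_mass_g = mass, tarsus_mm = tarsus,
             replicate_id = rep_id, sample_role = role,
             stringsAsFactors = FALSE)
}

# metadata for n birds in one nest, both ages, two replicates each
nest_meta <- function(birds, origin = "N1", rearing_d15 = origin,
                      treatment = "control") {
  do.call(rbind, lapply(birds, function(b) {
    do.call(rbind, lapply(c("D8", "D15"), function(age) {
      do.call(rbind, lapply(c("r1", "r2"), function(r) {
        meta_row(paste(b, age, r, sep = "_"), bird_id = b,
                 origin = origin,
                 rearing = if (age == "D8") origin else rearing_d15,
                 age = age, treatment = treatment,
                 mass = if (age == "D8") 12 else 18,
                 tarsus = if (age == "D15") 19.3 else NA_real_,
                 rep_id = r)
      }))
    }))
  }))
}

# Euclidean distance matrix with labels, from a coordinate matrix
euclid_dist <- function(coords) {
  if (is.null(rownames(coords))) {
    rownames(coords) <- sprintf("s%d", seq_len(nrow(coords)))
  }
  dist_matrix(as.matrix(stats::dist(coords)))
}

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# exact Mantel p-value by full enumeration over relabelings of d2
mantel_exact_p <- function(d1, d2) {
  v1 <- d1[lower.tri(d1)]
  r_obs <- stats::cor(v1, d2[lower.tri(d2)])
  rs <- vapply(all_perms(nrow(d1)), function(p)
    stats::cor(v1, d2[p, p][lower.tri(d2)]), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# one-factor pseudo-F from a distance matrix via group read-off of squared
# distances (independent of the Gower/hat-matrix route in the package)
pseudo_f_groups <- function(d, groups) {
  n <- nrow(d)
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ss_within <- ss_within +
      sum(d[i, i][lower.tri(d[i, i])]^2) / length(i)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# exact one-factor PERMANOVA p by enumeration over all label permutations
permanova_exact_p <- function(d, groups) {
  f_obs <- pseudo_f_groups(d, groups)
  fs <- vapply(all_perms(nrow(d)), function(p)
    pseudo_f_groups(d, groups[p]), numeric(1))
  mean(fs >= f_obs - 1e-12)
}
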