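# two paired CF nests (3 of 6 swapped) plus one control nest, merged samples
cf_fixture_meta <- function() {
  swap <- function(meta, birds, new_nest) {
    i <- meta$bird_id %in% birds & meta$age_class == "D15"
    meta$nest_of_rearing[i] <- new_nest
    meta
  }
  m <- rbind(
    nest_meta(paste0("a", 1:6), origin = "NA1", treatment = "crossfostered"),
    nest_meta(paste0("b", 1:6), origin = "NB1", treatment = "crossfostered"),
    nest_meta(paste0("c", 1:6), origin = "NC1", treatment = "control"))
  m <- swap(m, paste0("a", 4:6), "NB1")
  m <- swap(m, paste0("b", 4:6), "NA1")
  merged_metadata(m)
}

test_that("treatment labels follow origin, rearing, and nest treatment", {
  tr <- assign_treatment(cf_fixture_meta())
  expect_setequal(tr$label[tr$bird_id %in% paste0("c", 1:6)], "control")
  expect_setequal(tr$label[tr$bird_id %in% c(paste0("a", 1:3),
                                             paste0("b", 1:3))], "CFstay")
  expect_setequal(tr$label[tr$bird_id %in% c(paste0("a", 4:6),
                                             paste0("b", 4:6))], "CFmove")
  # partition is exhaustive and disjoint
  expect_equal(nrow(tr), 18)
  expect_false(anyDuplicated(tr$bird_id) > 0)

  bad <- cf_fixture_meta()
  bad$nest_of_origin[bad$bird_id == "a1" & bad$age_class == "D15"] <- "NX"
  expect_error(assign_treatment(bad), "inconsistent")
})

test_that("within-bird change is the Jaccard distance between its two ages", {
  meta <- merged_metadata(nest_meta(c("b1", "b2")))
  counts <- cbind(
    b1_D8 = c(1, 1, 0, 0), b1_D15 = c(1, 1, 0, 0),   # identical
    b2_D8 = c(1, 1, 0, 0), b2_D15 = c(0, 0, 1, 1))   # disjoint
  rownames(counts) <- sprintf("OTU%d", 1:4)
  jac <- jaccard_matrix(make_table(counts))
  res <- intra_individual_change(jac, meta)
  expect_equal(res$distance[res$bird_id == "b1"], 0)
  expect_equal(res$distance[res$bird_id == "b2"], 1)
  # matches direct recomputation on the column pairs
  expect_equal(res$distance,
               c(jac["b1_D8", "b1_D15"], jac["b2_D8", "b2_D15"]))
  # a bird missing one age is excluded and reported
  res2 <- intra_individual_change(
    dist_matrix(jac[-2, -2]), meta)
  expect_identical(res2$bird_id, "b2")
  expect_identical(attr(res2, "excluded"), "b1")
})

test_that("sibling contrast separates foster from separated-sib pairs", {
  meta <- cf_fixture_meta()
  # foster siblings identical, separated true siblings disjoint:
  # birds reared in NA1 share community X, birds reared in NB1 share Y
  d15 <- meta[meta$age_class == "D15" & meta$sample_role == "biological", ]
  counts <- vapply(seq_len(nrow(d15)), function(i) {
    if (d15$nest_of_rearing[i] == "NA1") c(1, 1, 0, 0)
    else if (d15$nest_of_rearing[i] == "NB1") c(0, 0, 1, 1)
    else c(1, 0, 1, 0)
  }, numeric(4))
  colnames(counts) <- d15$sample_id
  rownames(counts) <- sprintf("OTU%d", 1:4)
  jac <- jaccard_matrix(make_table(counts))
  res <- suppressWarnings(sibling_similarity_contrast(jac, meta))
  expect_equal(res$mean_foster, 0)
  expect_equal(res$mean_separated, 1)
  # pair classification: same rearing & different origin vs the reverse
  with(res$pair_table, {
    expect_true(all(pair_type %in% c("foster", "separated")))
    expect_equal(sum(pair_type == "foster"), 18)     # 2 nests x 3x3 pairs
    expect_equal(sum(pair_type == "separated"), 18)  # 2 origins x 3x3
  })
  expect_error(
    sibling_similarity_contrast(jac, meta[meta$nest_treatment == "control" |
                                            is.na(meta$nest_treatment), ]),
    "cross-fostered")
})

test_that("per-treatment Mantel returns r = 1 when ages agree", {
  meta <- cf_fixture_meta()
  tr <- assign_treatment(meta)
  set.seed(17)
  bio <- meta[meta$sample_role == "biological", ]
  counts <- matrix(rbinom(40 * nrow(bio), 1, 0.4), 40,
                   dimnames = list(sprintf("o%d", 1:40), bio$sample_id))
  # make D15 sample = D8 sample per bird so the sub-matrices coincide
  for (b in unique(bio$bird_id)) {
    counts[, paste0(b, "_D15")] <- counts[, paste0(b, "_D8")]
  }
  jac <- jaccard_matrix(make_table(counts))
  ids8 <- bio$sample_id[bio$age_class == "D8"]
  ids15 <- bio$sample_id[bio$age_class == "D15"]
  res <- mantel_by_treatment(dist_matrix(jac[ids8, ids8]),
                             dist_matrix(jac[ids15, ids15]),
                             tr, n_perm = 99, seed = 1)
  expect_setequal(names(res), c("control", "CFstay", "CFmove"))
  for (r in res) expect_equal(r$statistic, 1)
  # invariant to reordering of the treatment table
  res2 <- mantel_by_treatment(dist_matrix(jac[ids8, ids8]),
                              dist_matrix(jac[ids15, ids15]),
                              tr[rev(seq_len(nrow(tr))), ],
                              n_perm = 99, seed = 1)
  expect_equal(res2$CFstay$statistic, res$CFstay$statistic)
})

test_that("SMI and weight gain follow the allometric formula", {
  meta <- merged_metadata(nest_meta(c("b1", "b2", "b3")))
  set_val <- function(meta, bird, col, age, val) {
    meta[[col]][meta$bird_id == bird & meta$age_class == age] <- val
    meta
  }
  meta <- set_val(meta, "b1", "tarsus_mm", "D15", 19.3)
  meta <- set_val(meta, "b2", "tarsus_mm", "D15", 20.0)
  meta <- set_val(meta, "b3", "tarsus_mm", "D15", NA_real_)
  meta <- set_val(meta, "b2", "body_mass_g", "D8", 18.0)  # zero gain
  cond <- compute_condition(meta)
  # tarsus at the reference length: SMI equals mass
  expect_equal(cond$smi[cond$bird_id == "b1"], 18.0)
  # independent evaluation of mass * (l0/tarsus)^slope
  expect_equal(cond$smi[cond$bird_id == "b2"], 18.0 * (19.3 / 20)^1.87,
               tolerance = 1e-12)
  expect_equal(round(cond$smi[cond$bird_id == "b2"], 2), 16.84)
  # missing tarsus: SMI missing but the bird keeps its gain record
  expect_true(is.na(cond$smi[cond$bird_id == "b3"]))
  expect_true(cond$included_in_gain_models[cond$bird_id == "b3"])
  # zero gain is excluded from the gain models
  expect_false(cond$included_in_gain_models[cond$bird_id == "b2"])
  # re-estimation path recovers parameters from the data itself
  meta2 <- meta
  i15 <- meta2$age_class == "D15" & meta2$sample_role == "biological"
  meta2$tarsus_mm[i15] <- c(18.5, 19.3, 20.4)
  meta2$body_mass_g[i15] <- 18 * (meta2$tarsus_mm[i15] / 19.3)^1.87
  cond2 <- compute_condition(meta2, estimate_params = TRUE)
  pars <- attr(cond2, "smi_params")
  expect_identical(pars$provenance, "estimated")
  expect_equal(pars$slope, 1.87, tolerance = 1e-8)
  expect_equal(pars$l0, mean(c(18.5, 19.3, 20.4)))
})
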