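test_that("replicate merging averages reads per OTU, zeros included", {
  meta <- nest_meta("b1")
  counts <- matrix(0, 2, 4, dimnames = list(c("OTU1", "OTU2"),
                                            meta$sample_id))
  counts["OTU1", c("b1_D8_r1", "b1_D8_r2")] <- c(10, 20)
  counts["OTU2", c("b1_D8_r1", "b1_D8_r2")] <- c(0, 4)
  counts[, c("b1_D15_r1", "b1_D15_r2")] <- 5
  tab <- otu_table(counts, setNames(meta$sample_role, meta$sample_id))
  merged <- merge_replicates(tab, meta)
  expect_equal(merged$counts[, "b1_D8"], c(OTU1 = 15, OTU2 = 2))
  expect_equal(n_samples(merged), 2)

  # single-replicate sample passes through unchanged
  one <- meta[meta$replicate_id == "r1", ]
  m1 <- merge_replicates(subset_table(tab, samples = one$sample_id), one)
  expect_equal(m1$counts[, "b1_D8"], counts[, "b1_D8_r1"])
})

test_that("blank subtraction removes the mean mistag signal, floored at 0", {
  counts <- rbind(OTU1 = c(50, 3, 4, 6), OTU2 = c(9, 9, 0, 0))
  colnames(counts) <- c("s1", "s2", "bl1", "bl2")
  tab <- make_table(counts, c("biological", "biological", "blank", "blank"))
  out <- subtract_blank_signal(tab)
  expect_equal(out$table$counts[, "s1"], c(OTU1 = 45, OTU2 = 9))
  expect_equal(out$table$counts[, "s2"], c(OTU1 = 0, OTU2 = 9))  # floored
  expect_false(any(out$table$roles == "blank"))
  expect_equal(out$blank_means, c(OTU1 = 5))

  no_blank <- make_table(counts[, 1:2], c("biological", "biological"))
  expect_warning(res <- subtract_blank_signal(no_blank), "no blank")
  expect_identical(res$table$counts, no_blank$counts)
})

test_that("contaminant calls need strictly higher max AND mean in negatives", {
  counts <- rbind(
    contam = c(20, 5, 100, 60),    # neg max/mean win on both -> contaminant
    spiky  = c(50, 60, 100, 2),    # neg mean loses -> clean
    tied   = c(10, 10, 10, 10))    # ties -> clean (strict inequality)
  colnames(counts) <- c("b1", "b2", "n1", "n2")
  tab <- make_table(counts, c("biological", "biological",
                              "negative_control", "negative_control"))
  expect_identical(identify_contaminants(tab), "contam")
  only_bio <- make_table(counts[, 1:2], c("biological", "biological"))
  expect_warning(res <- identify_contaminants(only_bio), "no negative")
  expect_identical(res, character())
})

test_that("low-abundance filter uses a strict fraction cutoff and drops singletons", {
  counts <- cbind(s1 = c(a = 9, b = 10, c = 1, d = 199980))
  tab <- make_table(counts)
  # grand total 200000 -> cutoff 10 reads at the 0.005% default
  out <- filter_low_abundance(tab, filter_params(min_total_fraction = 5e-5))
  expect_identical(otu_ids(out), c("b", "d"))
  # singleton removed even when above the fraction cutoff
  out2 <- filter_low_abundance(make_table(cbind(s1 = c(a = 1, b = 50))),
                               filter_params(min_total_fraction = 0))
  expect_identical(otu_ids(out2), "b")
  # all OTUs above cutoff -> unchanged
  big <- make_table(cbind(s1 = c(a = 100, b = 100)))
  expect_identical(filter_low_abundance(big)$counts, big$counts)
})

test_that("rarefaction yields exact depth, drops shallow samples, reproducible", {
  set.seed(42)
  counts <- cbind(deep = rpois(30, 200), exact = 0, shallow = rpois(30, 5))
  counts[1:10, "exact"] <- 100  # sums to exactly 1000
  rownames(counts) <- sprintf("OTU%d", 1:30)
  tab <- make_table(counts)
  res <- rarefy(tab, filter_params(rarefaction_depth = 1000, seed = 3))
  expect_true(all(colSums(res$table$counts) == 1000))
  expect_identical(res$dropped, "shallow")
  expect_equal(res$table$counts[, "exact"], counts[, "exact"])
  res2 <- rarefy(tab, filter_params(rarefaction_depth = 1000, seed = 3))
  expect_identical(res$table$counts, res2$table$counts)
  expect_error(rarefy(tab, filter_params(rarefaction_depth = 0)))
})

test_that("rarefied counts match the hypergeometric mean within 3 SE", {
  x <- c(OTU1 = 600, OTU2 = 300, OTU3 = 80, OTU4 = 20)
  depth <- 500
  tab <- make_table(cbind(s1 = x))
  draws <- vapply(1:1000, function(s)
    rarefy(tab, filter_params(rarefaction_depth = depth,
                              seed = s))$table$counts[, 1],
    numeric(4))
  n <- sum(x)
  expected <- depth * x / n
  # multivariate hypergeometric variance per cell
  v <- depth * (x / n) * (1 - x / n) * (n - depth) / (n - 1)
  se <- sqrt(v / 1000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("rarefaction preserves abundance ranking in expectation", {
  set.seed(11)
  for (s in 1:5) {
    x <- rpois(40, 60) + 1
    tab <- make_table(cbind(s1 = x))
    r <- rarefy(tab, filter_params(rarefaction_depth = 500, seed = s))
    keep <- x > 0
    expect_gt(cor(x[keep], r$table$counts[keep, 1], method = "spearman"), 0)
  }
})

test_that("relative abundance normalizes columns to one", {
  tab <- make_table(cbind(s1 = c(250, 750), s2 = c(4, 12)))
  rel <- relative_abundance(tab)
  expect_equal(rel[, "s1"], c(OTU1 = 0.25, OTU2 = 0.75))
  expect_true(all(abs(colSums(rel) - 1) < 1e-12))
  expect_error(relative_abundance(make_table(cbind(s1 = c(0, 0)))), "s1")
})

test_that("the cascade balances read accounting at every stage", {
  sim <- generate_dataset(sim_params(n_nests = 6, n_cf_pairs = 2,
                                     n_otus = 80, n_contaminants = 8,
                                     depth = 3000, seed = 5))
  qc <- qc_pipeline(sim$otu, sim$meta, filter_params(seed = 5))
  with(qc$audit, expect_equal(reads_in, reads_out + reads_removed))
  # stages are chained: output of one is input of the next
  expect_equal(qc$audit$reads_in[-1], qc$audit$reads_out[-nrow(qc$audit)])
  expect_true(all(colSums(qc$table$counts) == 1000))
  expect_true(all(qc$table$roles == "biological"))
})

test_that("planted contaminants are recovered with few false flags", {
  # lighter version of the acceptance check: 5 seeds, reduced design
  sens <- fp <- numeric(0)
  for (s in 1:5) {
    sim <- generate_dataset(sim_params(n_nests = 6, n_cf_pairs = 2,
                                       n_otus = 80, n_contaminants = 8,
                                       depth = 3000, seed = s))
    merged <- merge_replicates(sim$otu, sim$meta)
    tab <- subtract_blank_signal(merged)$table
    found <- identify_contaminants(tab)
    truth <- sim$truth$contaminants
    sens <- c(sens, length(intersect(found, truth)) / length(truth))
    fp <- c(fp, length(setdiff(found, truth)) /
              (n_otus(tab) - length(truth)))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fp), 0.02)
})
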