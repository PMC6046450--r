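test_that("mantel statistic and guards behave", {
  set.seed(4)
  d <- euclid_dist(matrix(rnorm(12), 6))
  self <- mantel(d, d, n_perm = 99, seed = 1)
  expect_equal(self$statistic, 1)
  expect_true(self$p_value > 0 && self$p_value <= 1)

  d2 <- euclid_dist(matrix(rnorm(12), 6))
  rownames(d2) <- colnames(d2) <- letters[1:6]
  expect_error(mantel(d, d2), "labels")
  flat <- dist_matrix(matrix(1, 5, 5,
                             dimnames = list(letters[1:5], letters[1:5])) -
                        diag(5))
  expect_error(mantel(flat, flat), "zero variance")
  expect_error(mantel(euclid_dist(matrix(rnorm(6), 3)),
                      euclid_dist(matrix(rnorm(6), 3))), "4 samples")
})

test_that("mantel r matches vegan and p matches exhaustive enumeration", {
  set.seed(9)
  for (n in c(4, 5)) {
    x <- matrix(rnorm(2 * n), n)
    y <- x + matrix(rnorm(2 * n, sd = 0.7), n)
    d1 <- euclid_dist(x); d2 <- euclid_dist(y)
    res <- mantel(d1, d2, n_perm = 1000, seed = 2)
    ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 0)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    p_exact <- mantel_exact_p(d1, d2)
    se <- sqrt(p_exact * (1 - p_exact) / 1000)
    expect_lt(abs(res$p_value - p_exact), 2 * se + 2 / 1000)
  }
})

test_that("permanova reduces to one-way ANOVA F on univariate Euclidean data", {
  set.seed(12)
  for (rep in 1:5) {
    y <- rnorm(14)
    g <- factor(rep(c("a", "b"), 7))
    d <- euclid_dist(cbind(y))
    res <- permanova(d, data.frame(g = g), n_perm = 49, seed = 1)
    f_ref <- unname(summary(stats::aov(y ~ g))[[1]]$`F value`[1])
    expect_equal(res$pseudo_F[1], f_ref, tolerance = 1e-8)
  }
})

test_that("permanova matches vegan::adonis2 on a Jaccard matrix", {
  set.seed(19)
  m <- matrix(rbinom(50 * 12, 1, 0.35) * rpois(50 * 12, 4), 50, 12,
              dimnames = list(sprintf("o%d", 1:50), sprintf("s%d", 1:12)))
  m[, 1] <- pmax(m[, 1], 1)
  d <- jaccard_matrix(m)
  design <- data.frame(g = factor(rep(c("a", "b", "c"), each = 4)),
                       x = rnorm(12))
  res <- permanova(d, design, terms = c("g", "x"), n_perm = 99, seed = 1,
                   mode = "margin")
  ref <- as.data.frame(vegan::adonis2(as.dist(d) ~ g + x, data = design,
                                      permutations = 99, by = "margin"))
  expect_equal(res$sum_sq[1:2], ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(res$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(res$df[1:2], ref$Df[1:2])
})

test_that("single-term permanova partitions R2 to one", {
  set.seed(5)
  d <- euclid_dist(matrix(rnorm(20), 10))
  res <- permanova(d, data.frame(g = factor(rep(1:2, 5))),
                   n_perm = 19, seed = 1)
  expect_equal(sum(res$R2[res$term %in% c("g", "residual")]), 1,
               tolerance = 1e-10)
  expect_error(permanova(d, data.frame(g = factor(c(1, rep(2, 9)))),
                         n_perm = 9), "singleton")
  expect_error(permanova(d, data.frame(g = factor(rep(1:2, 5)),
                                       h = factor(rep(1:2, 5))),
                         n_perm = 9), "aliased")
})

test_that("permanova p matches exhaustive enumeration on the 0/1 toy", {
  # two groups of 3, within-group distance 0, between-group 1:
  # only the true labelling and its complement reach the maximal F
  m <- matrix(1, 6, 6) - diag(6)
  m[1:3, 1:3] <- 0; m[4:6, 4:6] <- 0; diag(m) <- 0
  dimnames(m) <- list(letters[1:6], letters[1:6])
  g <- rep(c("a", "b"), each = 3)
  p_exact <- permanova_exact_p(dist_matrix(m), g)
  expect_equal(p_exact, 2 / 20)
  res <- permanova(dist_matrix(m), data.frame(g = factor(g)),
                   n_perm = 999, seed = 7)
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p_value[1] - p_exact), 2 * se + 2 / 999)
})

test_that("mantel and permanova are invariant to simultaneous relabeling", {
  set.seed(31)
  d1 <- euclid_dist(matrix(rnorm(16), 8))
  d2 <- euclid_dist(matrix(rnorm(16), 8))
  g <- data.frame(g = factor(rep(1:2, each = 4)))
  p <- sample(8)
  perm_d <- function(d) dist_matrix(d[p, p])
  r1 <- mantel(d1, d2, n_perm = 99, seed = 3)$statistic
  r2 <- mantel(perm_d(d1), perm_d(d2), n_perm = 99, seed = 3)$statistic
  expect_equal(r1, r2, tolerance = 1e-12)
  f1 <- permanova(d1, g, n_perm = 9, seed = 1)$pseudo_F[1]
  f2 <- permanova(perm_d(d1), data.frame(g = g$g[p]), n_perm = 9,
                  seed = 1)$pseudo_F[1]
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("pcoa reconstructs distances, including non-Euclidean ones", {
  set.seed(14)
  coords <- matrix(rnorm(8), 4)
  d <- euclid_dist(coords)
  ord <- pcoa(d)
  expect_equal(sum(ord$eigenvalues > 1e-8), 2)
  expect_equal(pcoa_distances(ord), unclass(d), tolerance = 1e-8,
               ignore_attr = TRUE)

  m <- matrix(rbinom(30 * 7, 1, 0.4), 30, 7)
  m[, 1] <- pmax(m[, 1], 1)
  dj <- jaccard_matrix(make_table(m))
  ordj <- pcoa(dj)
  expect_equal(pcoa_distances(ordj), unclass(dj), tolerance = 1e-8,
               ignore_attr = TRUE)

  # equidistant configuration (regular simplex): one repeated eigenvalue
  m5 <- 0.6 * (matrix(1, 5, 5) - diag(5))
  dimnames(m5) <- list(letters[1:5], letters[1:5])
  ds <- dist_matrix(m5)
  ords <- pcoa(ds)
  expect_equal(max(ords$pos_eigenvalues) / min(ords$pos_eigenvalues), 1,
               tolerance = 1e-8)
  expect_equal(pcoa_distances(ords), unclass(ds), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("centroid distances match direct coordinates and vegan", {
  set.seed(16)
  coords <- matrix(rnorm(24), 12)
  rownames(coords) <- sprintf("s%d", 1:12)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- euclid_dist(coords)
  disp <- dispersion_to_centroid(d, g, n_perm = 99, seed = 1)
  direct <- vapply(seq_len(12), function(i) {
    cen <- colMeans(coords[g == g[i], , drop = FALSE])
    sqrt(sum((coords[i, ] - cen)^2))
  }, numeric(1))
  expect_equal(disp$distances$distance, direct, tolerance = 1e-8)

  # non-Euclidean input: agree with vegan::betadisper (centroid type)
  m <- matrix(rbinom(40 * 9, 1, 0.4), 40, 9)
  m[, 1] <- pmax(m[, 1], 1)
  dj <- jaccard_matrix(make_table(m))
  g2 <- rep(c("a", "b", "c"), each = 3)
  ours <- dispersion_to_centroid(dj, g2, n_perm = 9, seed = 1)
  ref <- vegan::betadisper(as.dist(dj), g2, type = "centroid")
  expect_equal(ours$distances$distance, unname(ref$distances),
               tolerance = 1e-8)
})

test_that("dispersion is symmetric for equivalent groups", {
  # all pairwise distances equal in one group: all centroid distances equal
  m <- 0.8 * (matrix(1, 4, 4) - diag(4))
  dimnames(m) <- list(letters[1:4], letters[1:4])
  disp <- dispersion_to_centroid(dist_matrix(m), rep("g", 4),
                                 n_perm = 9, seed = 1)
  expect_equal(diff(range(disp$distances$distance)), 0, tolerance = 1e-10)

  # two congruent (mirror-image) groups: F ~ 0, p ~ 1
  set.seed(2)
  a <- matrix(rnorm(10), 5)
  coords <- rbind(a, cbind(-a[, 1], a[, 2]) + 10)
  rownames(coords) <- sprintf("s%d", 1:10)
  disp2 <- dispersion_to_centroid(euclid_dist(coords),
                                  rep(c("g1", "g2"), each = 5),
                                  n_perm = 199, seed = 1)
  expect_lt(disp2$test$statistic, 1e-8)
  expect_gt(disp2$test$p_value, 0.9)
})

test_that("welch+BH matches the stats oracle and handles degeneracy", {
  set.seed(23)
  f <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(sprintf("f%d", 1:5), NULL))
  g <- rep(c("x", "y"), each = 6)
  res <- welch_bh(f, g)
  ref <- t.test(f[3, g == "x"], f[3, g == "y"], var.equal = FALSE)
  expect_equal(res$t[3], unname(ref$statistic))
  expect_equal(res$p_value[3], ref$p.value)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))

  # identical groups -> t=0, p=q=1; single feature -> q = p
  same <- matrix(rep(c(1, 2, 3), 4), 1)
  expect_equal(welch_bh(same, rep(c("x", "y"), each = 6))[, c("t", "p_value",
                                                              "q_value")],
               data.frame(t = 0, p_value = 1, q_value = 1))
  one <- matrix(rnorm(8), 1)
  r1 <- welch_bh(one, rep(c("x", "y"), 4))
  expect_equal(r1$q_value, r1$p_value)
})

test_that("SMA regression has the closed form and its symmetries", {
  x <- c(1, 2, 3, 4, 5)
  fit <- sma_slope(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)
  expect_equal(fit$intercept, 0)

  set.seed(26)
  xr <- rnorm(50); yr <- 1.3 * xr + rnorm(50, sd = 0.6)
  f <- sma_slope(xr, yr)
  ols <- unname(coef(lm(yr ~ xr))[2])
  expect_equal(f$slope, ols / abs(f$r), tolerance = 1e-12)
  expect_equal(sma_slope(yr, xr)$slope, 1 / f$slope, tolerance = 1e-12)
  expect_error(sma_slope(rep(1, 5), rnorm(5)), "zero variance")
})
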