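#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the strictly-lower-triangle
#' entries; the null distribution is generated by permuting sample labels
#' of the second matrix (simultaneous row/column permutation); the p-value
#' is one-tailed for positive association with the +1 correction,
#' p = (#\{perm r >= observed r\} + 1) / (n_perm + 1).
#'
#' @param d1,d2 [dist_matrix] objects over the same labels in the same
#'   order, n >= 4.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list of class `perm_test` with `statistic`, `p_value`,
#'   `n_permutations`, `seed`, `scheme`, `n`.
#' @export
mantel <- function(d1, d2, n_perm = 1000L, seed = 1L) {
  d1 <- dist_matrix(d1); d2 <- dist_matrix(d2)
  if (!identical(rownames(d1), rownames(d2))) {
    stop("distance matrices have different labels", call. = FALSE)
  }
  n <- nrow(d1)
  if (n < 4L) stop("Mantel test needs at least 4 samples", call. = FALSE)
  v1 <- lower_tri(d1)
  if (stats::sd(v1) == 0 || stats::sd(lower_tri(d2)) == 0) {
    stop("zero variance in a distance-matrix triangle", call. = FALSE)
  }
  r_obs <- stats::cor(v1, lower_tri(d2))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    r_b <- stats::cor(v1, lower_tri(d2[p, p]))
    # tolerance so permutations tied with the observed statistic are
    # counted as such despite floating-point noise
    if (r_b >= r_obs - 1e-10) hits <- hits + 1L
  }
  perm_test(statistic = r_obs, stat_name = "r",
            p_value = (hits + 1) / (n_perm + 1),
            n_permutations = n_perm, seed = seed,
            scheme = "free label permutation of d2", n = n)
}

perm_test <- function(statistic, stat_name, p_value, n_permutations, seed,
                      scheme, n) {
  structure(list(statistic = statistic, stat_name = stat_name,
                 p_value = p_value, n_permutations = n_permutations,
                 seed = seed, scheme = scheme, n = n),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: %s = %.4f, p = %.4g (%d permutations)\n",
              x$stat_name, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

# Gower-centred inner-product matrix of squared dissimilarities
gower_matrix <- function(d) {
  a <- -0.5 * unclass(d)^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

# hat (projection) matrix of a model-matrix column span
hat_matrix <- function(x) {
  q <- qr.Q(qr(x))[, seq_len(qr(x)$rank), drop = FALSE]
  tcrossprod(q)
}

#' Permutational multivariate ANOVA (marginal terms)
#'
#' Distance-based multivariate ANOVA via partitioning of the Gower-centred
#' inner-product matrix.  In `mode = "margin"` each term's sum of squares
#' is the reduction from the full model to the model with that term
#' dropped (its marginal effect with every other term retained); in
#' `mode = "sequential"` terms are added in order.  Pseudo-F uses the full
#' model's residual; p-values come from free permutation of the sample
#' labels with the +1 correction.
#'
#' @param d a [dist_matrix].
#' @param design data.frame of factors/covariates, rows aligned with the
#'   labels of `d`.
#' @param terms character vector of column names of `design` to test.
#' @param n_perm permutations (default 1000).
#' @param mode `"margin"` (default) or `"sequential"`.
#' @param seed integer seed.
#' @return data.frame with one row per term plus a residual and total row:
#'   `term`, `df`, `sum_sq`, `pseudo_F`, `R2`, `p_value`.
#' @export
permanova <- function(d, design, terms = colnames(design), n_perm = 1000L,
                      mode = c("margin", "sequential"), seed = 1L) {
  mode <- match.arg(mode)
  d <- dist_matrix(d)
  n <- nrow(d)
  stopifnot(nrow(design) == n)
  design <- as.data.frame(design)[, terms, drop = FALSE]
  for (tm in terms) {
    if (is.character(design[[tm]])) design[[tm]] <- factor(design[[tm]])
    if (is.factor(design[[tm]])) {
      sizes <- table(droplevels(design[[tm]]))
      if (length(sizes) < 2L) {
        stop("term '", tm, "' has fewer than 2 levels", call. = FALSE)
      }
      if (any(sizes < 2L)) {
        stop("singleton level '", names(sizes)[sizes < 2L][1L],
             "' in term '", tm, "'", call. = FALSE)
      }
    }
  }
  g <- gower_matrix(d)
  ss_total <- sum(diag(g))

  mm_full <- stats::model.matrix(
    stats::reformulate(terms), data = design)
  rank_full <- qr(mm_full)$rank
  if (rank_full < ncol(mm_full)) {
    stop("aliased (confounded) design columns", call. = FALSE)
  }
  h_full <- hat_matrix(mm_full)
  df_res <- n - rank_full
  ss_res <- ss_total - sum(h_full * g)

  # reduced-model hat matrix per term; in sequential mode the "reduced"
  # model holds the preceding terms only
  h_red <- list()
  df_term <- numeric(length(terms))
  for (i in seq_along(terms)) {
    others <- if (mode == "margin") terms[-i] else terms[seq_len(i - 1L)]
    mm_red <- if (length(others)) {
      stats::model.matrix(stats::reformulate(others), data = design)
    } else {
      matrix(1, n, 1)
    }
    h_red[[i]] <- hat_matrix(mm_red)
    if (mode == "margin") {
      df_term[i] <- rank_full - qr(mm_red)$rank
    } else {
      mm_upto <- stats::model.matrix(
        stats::reformulate(terms[seq_len(i)]), data = design)
      df_term[i] <- qr(mm_upto)$rank - qr(mm_red)$rank
      h_full_i <- hat_matrix(mm_upto)
      attr(h_red[[i]], "h_upper") <- h_full_i
    }
  }

  term_ss <- function(gmat) {
    res <- numeric(length(terms))
    for (i in seq_along(terms)) {
      h_up <- if (mode == "margin") h_full else attr(h_red[[i]], "h_upper")
      res[i] <- sum(h_up * gmat) - sum(h_red[[i]] * gmat)
    }
    res
  }
  # residual SS can come out as round-off negatives when a term explains
  # everything; treat it as exactly zero (F = Inf for nonzero term SS)
  tol <- 1e-12 * max(ss_total, 1)
  pseudo_f <- function(ss, ssr) {
    ssr <- max(ssr, 0)
    if (ssr <= tol) ifelse(ss <= tol, 0, Inf)
    else (ss / df_term) / (ssr / df_res)
  }
  f_stats <- function(gmat) {
    ssr <- sum(diag(gmat)) - sum(h_full * gmat)
    pseudo_f(term_ss(gmat), ssr)
  }

  ss_obs <- term_ss(g)
  f_obs <- pseudo_f(ss_obs, ss_res)
  ss_res <- max(ss_res, 0)

  set.seed(seed)
  # count permutations tied with the observed F despite rounding noise
  f_tol <- ifelse(is.finite(f_obs), 1e-8 * pmax(1, abs(f_obs)), 0)
  hits <- integer(length(terms))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    f_b <- f_stats(g[p, p])
    hits <- hits + (f_b >= f_obs - f_tol)
  }
  p_val <- (hits + 1) / (n_perm + 1)

  out <- data.frame(
    term = c(terms, "residual", "total"),
    df = c(df_term, df_res, n - 1L),
    sum_sq = c(ss_obs, ss_res, ss_total),
    pseudo_F = c(f_obs, NA, NA),
    R2 = c(ss_obs, ss_res, ss_total) / ss_total,
    p_value = c(p_val, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  out
}

#' Principal coordinates analysis with negative-eigenvalue bookkeeping
#'
#' Eigendecomposition of the Gower-centred squared-distance matrix.  Axes
#' with positive eigenvalues give real coordinates; axes with negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Jaccard) are kept separately as imaginary coordinates rather than being
#' discarded or shifted by an additive constant, because dispersion
#' distances need them.  With all axes retained the original
#' dissimilarities are recovered as
#' sqrt(real squared distance - imaginary squared distance).
#'
#' @param d a [dist_matrix], n >= 3.
#' @return list of class `pcoa` with `labels`, `vectors` (n x k real
#'   coordinates), `imaginary` (n x m imaginary coordinates), `eigenvalues`
#'   (all, decreasing), `pos_eigenvalues`, `neg_eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- dist_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("PCoA needs at least 3 samples", call. = FALSE)
  g <- gower_matrix(d)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9 + 1e-12
  pos <- e$values > tol
  neg <- e$values < -tol
  vectors <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  imaginary <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  rownames(vectors) <- rownames(imaginary) <- rownames(d)
  structure(list(labels = rownames(d), vectors = vectors,
                 imaginary = imaginary, eigenvalues = e$values,
                 pos_eigenvalues = e$values[pos],
                 neg_eigenvalues = e$values[neg]),
            class = "pcoa")
}

#' Reconstruct pairwise distances from a PCoA embedding
#' @param ord a [pcoa] object.
#' @return matrix of reconstructed distances (squared differences on real
#'   axes minus squared differences on imaginary axes, floored at 0 before
#'   the square root).
#' @export
pcoa_distances <- function(ord) {
  sq <- function(coord) {
    if (ncol(coord) == 0L) return(matrix(0, nrow(coord), nrow(coord)))
    s <- rowSums(coord^2)
    outer(s, s, "+") - 2 * tcrossprod(coord)
  }
  d2 <- sq(ord$vectors) - sq(ord$imaginary)
  d <- sqrt(pmax(d2, 0))
  dimnames(d) <- list(ord$labels, ord$labels)
  diag(d) <- 0
  d
}

#' Multivariate dispersion: distance to group centroid
#'
#' Embeds the dissimilarity matrix by [pcoa], computes each sample's
#' distance to its group centroid with the real/imaginary correction
#' (squared real-part distance minus squared imaginary-part distance,
#' floored at zero before the square root), and tests homogeneity of
#' dispersion among groups with an F statistic on those distances whose
#' null distribution is obtained by permuting the distances freely among
#' samples.  Groups of size 1 get distance 0 and are excluded from the F
#' test.
#'
#' @param d a [dist_matrix].
#' @param groups grouping vector aligned with the labels of `d`.
#' @param n_perm permutations for the homogeneity test (default 1000).
#' @param seed integer seed.
#' @return list of class `dispersion` with `distances` (data.frame
#'   sample/group/distance), `test` (a `perm_test` with the F statistic),
#'   `group_means`.
#' @export
dispersion_to_centroid <- function(d, groups, n_perm = 1000L, seed = 1L) {
  d <- dist_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  ord <- pcoa(d)
  dist_to_centroid <- numeric(nrow(d))
  for (gr in unique(groups)) {
    idx <- which(groups == gr)
    cen_r <- colMeans(ord$vectors[idx, , drop = FALSE])
    cen_i <- colMeans(ord$imaginary[idx, , drop = FALSE])
    dr2 <- rowSums((ord$vectors[idx, , drop = FALSE] -
                      rep(cen_r, each = length(idx)))^2)
    di2 <- rowSums((ord$imaginary[idx, , drop = FALSE] -
                      rep(cen_i, each = length(idx)))^2)
    dist_to_centroid[idx] <- sqrt(pmax(dr2 - di2, 0))
  }
  sizes <- table(groups)
  testable <- groups %in% names(sizes)[sizes >= 2L]
  z <- dist_to_centroid[testable]
  gf <- factor(groups[testable])
  f_of <- function(z) {
    gm <- tapply(z, gf, mean)
    ssb <- sum(table(gf) * (gm - mean(z))^2)
    ssw <- sum((z - gm[gf])^2)
    dfb <- nlevels(gf) - 1L
    dfw <- length(z) - nlevels(gf)
    if (ssw == 0) {
      if (ssb == 0) 0 else Inf
    } else (ssb / dfb) / (ssw / dfw)
  }
  test <- if (nlevels(gf) < 2L) {
    perm_test(statistic = NA_real_, stat_name = "F", p_value = NA_real_,
              n_permutations = 0L, seed = seed,
              scheme = "not performed (fewer than 2 testable groups)",
              n = length(z))
  } else {
    f_obs <- f_of(z)
    f_tol <- if (is.finite(f_obs)) 1e-8 * max(1, abs(f_obs)) else 0
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (f_of(z[sample.int(length(z))]) >= f_obs - f_tol) hits <- hits + 1L
    }
    perm_test(statistic = f_obs, stat_name = "F",
              p_value = (hits + 1) / (n_perm + 1),
              n_permutations = n_perm, seed = seed,
              scheme = "free permutation of centroid distances",
              n = length(z))
  }
  structure(list(
    distances = data.frame(sample_id = rownames(d), group = groups,
                           distance = dist_to_centroid,
                           in_test = testable, stringsAsFactors = FALSE),
    test = test,
    group_means = tapply(dist_to_centroid, groups, mean)),
    class = "dispersion")
}

#' Per-feature Welch t-tests with Benjamini-Hochberg correction
#'
#' @param features numeric matrix, feature x sample.
#' @param group two-level grouping vector over the samples (>= 2 samples
#'   per group).
#' @return data.frame `feature`, `mean_1`, `mean_2`, `t`, `df`, `p_value`,
#'   `q_value` (BH over all tested features).  A feature with zero
#'   variance in both groups and equal means gets t = 0, p = 1.
#' @export
welch_bh <- function(features, group) {
  features <- as.matrix(features)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(group) < 2L)) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  i1 <- group == levels(group)[1L]
  res <- lapply(seq_len(nrow(features)), function(i) {
    x <- features[i, i1]; y <- features[i, !i1]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        return(data.frame(t = 0, df = NA_real_, p_value = 1,
                          mean_1 = mean(x), mean_2 = mean(y)))
      }
      return(data.frame(t = Inf * sign(mean(x) - mean(y)), df = NA_real_,
                        p_value = 0, mean_1 = mean(x), mean_2 = mean(y)))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, mean_1 = mean(x), mean_2 = mean(y))
  })
  out <- do.call(rbind, res)
  out <- data.frame(feature = rownames(features) %||%
                      as.character(seq_len(nrow(features))),
                    out[, c("mean_1", "mean_2", "t", "df", "p_value")],
                    stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardized major axis (type-2) regression
#'
#' slope = sign(r) * sd(y)/sd(x); intercept = mean(y) - slope * mean(x).
#' Symmetric in the two variables: swapping x and y inverts the slope.
#'
#' @param x,y numeric vectors (n >= 3, both with positive variance);
#'   for allometry these are log tarsus and log mass.
#' @return list with `slope`, `intercept`, `r`, `n`, and `slope_se` (the
#'   large-sample standard error slope * sqrt((1 - r^2)/(n - 2))).
#' @export
sma_slope <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("SMA regression needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y)
  slope <- (if (r < 0) -1 else 1) * stats::sd(y) / stats::sd(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r,
       n = n, slope_se = abs(slope) * sqrt((1 - r^2) / (n - 2)))
}
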