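#' Per-sample alpha diversity
#'
#' Richness is the number of OTUs with abundance > 0; Shannon H' is
#' computed in nats over the nonzero relative abundances; evenness is
#' Pielou's J' = H'/ln(richness), undefined (NA) when richness <= 1.
#'
#' @param table an [otu_table] or abundance matrix (OTU x sample); counts
#'   or compositions both work since H' is scale-invariant per sample.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `evenness`.
#' @export
alpha_diversity <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    s <- length(x)
    h <- if (s == 0L) 0 else {
      p <- x / sum(x)
      -sum(p * log(p))
    }
    data.frame(sample_id = colnames(m)[j], richness = s, shannon = h,
               evenness = if (s > 1L) h / log(s) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Presence-absence Jaccard dissimilarity matrix
#'
#' d(A, B) = 1 - |A intersect B| / |A union B| over the presence sets
#' (abundance > 0).  Two empty samples are at distance 0 by convention so
#' the matrix is total.
#'
#' @param table an [otu_table] or abundance matrix (OTU x sample) with at
#'   least 2 samples.
#' @return a [dist_matrix] over the samples.
#' @export
jaccard_matrix <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  p <- (m > 0) * 1
  shared <- crossprod(p)                    # |A intersect B|
  sizes <- diag(shared)
  union <- outer(sizes, sizes, "+") - shared
  d <- ifelse(union > 0, 1 - shared / union, 0)
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  dist_matrix(d)
}

#' Aggregate relative abundances to a taxonomic rank
#'
#' @param table an [otu_table] or abundance matrix; converted to relative
#'   abundances first.
#' @param taxonomy taxonomy data.frame from [read_taxonomy].
#' @param rank one of kingdom, phylum, class, order, family, genus,
#'   species.
#' @return matrix taxon x sample of relative abundances; OTUs with an
#'   empty rank or absent from the taxonomy are pooled as `"Unassigned"`
#'   (absence triggers a warning).  Columns sum to 1.
#' @export
aggregate_taxa <- function(table, taxonomy, rank = "phylum") {
  rank <- match.arg(rank, taxonomy_ranks)
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (ncol(m) == 0L || nrow(m) == 0L) {
    return(matrix(numeric(), 0, ncol(m),
                  dimnames = list(NULL, colnames(m))))
  }
  rel <- relative_abundance(m)
  idx <- match(rownames(rel), taxonomy$otu_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " OTU(s) missing from taxonomy; pooled as ",
            "'Unassigned'")
  }
  taxon <- ifelse(is.na(idx) | taxonomy[[rank]][idx] == "",
                  "Unassigned", taxonomy[[rank]][idx])
  rowsum(rel, group = taxon)
}

#' Proportion of time-1 OTUs still present at time 2
#'
#' @param sample_t1,sample_t2 abundance vectors over the same OTU universe.
#' @return scalar in [0, 1]; `NA` when the time-1 sample is empty.
#' @export
otu_retention <- function(sample_t1, sample_t2) {
  stopifnot(length(sample_t1) == length(sample_t2))
  p1 <- sample_t1 > 0
  if (!any(p1)) return(NA_real_)
  sum(p1 & sample_t2 > 0) / sum(p1)
}
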