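#' Filtering parameters for the decontamination cascade
#'
#' @param min_total_fraction OTUs whose dataset-wide total abundance is
#'   strictly lower than this fraction of the grand total are removed
#'   (default 0.00005, i.e. 0.005 percent).
#' @param rarefaction_depth reads per sample after rarefaction (default
#'   1000).
#' @param drop_singletons remove OTUs with total abundance <= 1 read
#'   (default TRUE).
#' @param seed integer seed governing the rarefaction draws.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_total_fraction = 5e-5,
                          rarefaction_depth = 1000L,
                          drop_singletons = TRUE,
                          seed = 1L) {
  stopifnot(min_total_fraction >= 0, min_total_fraction < 1,
            rarefaction_depth >= 1)
  structure(list(min_total_fraction = min_total_fraction,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 drop_singletons = isTRUE(drop_singletons),
                 seed = as.integer(seed)),
            class = "filter_params")
}

audit_stage <- function(stage, before, after, extra = list()) {
  c(list(stage = stage,
         otus_in = n_otus(before), otus_out = n_otus(after),
         samples_in = n_samples(before), samples_out = n_samples(after),
         reads_in = sum(before$counts), reads_out = sum(after$counts),
         reads_removed = sum(before$counts) - sum(after$counts)),
    extra)
}

#' Identifier of the merged biological sample a metadata row belongs to
#'
#' Biological replicates of one bird at one age share `<bird>_<age>`;
#' technical samples keep their own sample id (they are never merged).
#'
#' @param meta metadata data.frame.
#' @return character vector parallel to `meta` rows.
#' @export
biological_sample_id <- function(meta) {
  ifelse(!is.na(meta$sample_role) & meta$sample_role == "biological",
         paste(meta$bird_id, meta$age_class, sep = "_"),
         meta$sample_id)
}

#' Collapse metadata to one row per merged sample
#'
#' @param meta metadata data.frame (per-replicate rows).
#' @return data.frame with `sample_id` set to the merged identifier and
#'   `replicate_id` dropped; non-biological rows pass through.
#' @export
merged_metadata <- function(meta) {
  meta$sample_id <- biological_sample_id(meta)
  keep <- !duplicated(meta$sample_id)
  out <- meta[keep, setdiff(colnames(meta), "replicate_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average PCR replicates into one column per biological sample
#'
#' Each biological sample was amplified twice; the cascade starts by taking
#' the arithmetic mean of the replicate read counts per OTU (an OTU absent
#' from one replicate contributes a zero), which yields fractional counts.
#' Technical samples (blanks, controls) are carried through unchanged.
#'
#' @param table an [otu_table] with one column per sequenced replicate.
#' @param meta metadata with a row for every column of `table`.
#' @return [otu_table] with one column per merged sample, named
#'   `<bird>_<age>` for biological samples.
#' @export
merge_replicates <- function(table, meta) {
  ids <- sample_ids(table)
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(m$sample_id)) {
    stop("metadata missing for sample(s): ",
         paste(ids[is.na(m$sample_id)], collapse = ", "), call. = FALSE)
  }
  bio <- !is.na(m$sample_role) & m$sample_role == "biological"
  if (any(bio & (is.na(m$bird_id) | is.na(m$age_class)))) {
    stop("biological replicate without bird_id/age_class", call. = FALSE)
  }
  group <- biological_sample_id(m)
  groups <- unique(group)
  merged <- vapply(groups, function(g) {
    rowMeans(table$counts[, group == g, drop = FALSE])
  }, numeric(n_otus(table)))
  merged <- matrix(merged, nrow = n_otus(table),
                   dimnames = list(otu_ids(table), groups))
  roles <- vapply(groups, function(g) unique(m$sample_role[group == g])[1L],
                  character(1))
  otu_table(merged, stats::setNames(roles, groups))
}

#' Subtract mean blank (mistag) signal from every sample
#'
#' Blank tag combinations were sequenced without any sample; reads landing
#' there measure tag switching.  For every OTU observed in at least one
#' blank, its mean abundance across blank samples is subtracted from that
#' OTU in every non-blank sample, flooring at zero, and the blank columns
#' are then dropped.
#'
#' @param table an [otu_table] containing blank samples.
#' @return list with elements `table` (blanks removed, counts corrected)
#'   and `blank_means` (named vector over the OTUs that were corrected).
#'   With no blanks present the table passes through and a warning is
#'   recorded via `warning()`.
#' @export
subtract_blank_signal <- function(table) {
  is_blank <- table$roles == "blank"
  if (!any(is_blank)) {
    warning("no blank samples present; mistag subtraction skipped")
    return(list(table = table,
                blank_means = stats::setNames(numeric(), character())))
  }
  blank_mean <- rowMeans(table$counts[, is_blank, drop = FALSE])
  hit <- blank_mean > 0
  out <- table$counts[, !is_blank, drop = FALSE]
  out[hit, ] <- pmax(out[hit, , drop = FALSE] - blank_mean[hit], 0)
  list(table = otu_table(out, table$roles[!is_blank]),
       blank_means = blank_mean[hit])
}

#' Identify reagent/lab contaminant OTUs from negative controls
#'
#' An OTU is called contaminant when it has BOTH a strictly higher maximum
#' abundance and a strictly higher mean abundance in negative-control
#' samples than in biological samples; means are taken over all samples of
#' each role, zeros included.  Ties are conservatively retained as
#' non-contaminants.
#'
#' @param table an [otu_table] with negative-control and biological samples.
#' @return character vector of contaminant OTU ids (empty, with a warning,
#'   when no negative controls are present).
#' @export
identify_contaminants <- function(table) {
  neg <- table$roles == "negative_control"
  bio <- table$roles == "biological"
  if (!any(neg)) {
    warning("no negative-control samples; contaminant screen skipped")
    return(character())
  }
  if (!any(bio)) stop("no biological samples present", call. = FALSE)
  negm <- table$counts[, neg, drop = FALSE]
  biom <- table$counts[, bio, drop = FALSE]
  hit <- apply(negm, 1L, max) > apply(biom, 1L, max) &
    rowMeans(negm) > rowMeans(biom)
  otu_ids(table)[hit]
}

#' Remove singleton and rare OTUs
#'
#' Drops OTUs whose total abundance across the table is strictly lower than
#' `min_total_fraction` of the grand total, and (when `drop_singletons`)
#' OTUs totalling at most one read.  The cutoff is evaluated on the table
#' as passed, i.e. after blank subtraction and contaminant removal, over
#' biological samples only.
#'
#' @param table an [otu_table] of biological samples.
#' @param params a [filter_params].
#' @return filtered [otu_table].
#' @export
filter_low_abundance <- function(table, params = filter_params()) {
  if (n_otus(table) == 0L) return(table)
  totals <- rowSums(table$counts)
  cutoff <- params$min_total_fraction * sum(totals)
  keep <- totals >= cutoff
  if (params$drop_singletons) keep <- keep & totals > 1
  subset_table(table, otus = keep)
}

# one multivariate-hypergeometric draw: subsample `depth` reads without
# replacement from integer count vector x
subsample_counts <- function(x, depth) {
  reads <- sample.int(sum(x), depth)
  breaks <- c(0, cumsum(x))
  tabulate(findInterval(reads, breaks, left.open = TRUE), nbins = length(x))
}

#' Rarefy every sample to a common depth
#'
#' Counts are rounded half-to-even to integers (they are fractional after
#' replicate averaging and blank subtraction), then each sample is
#' subsampled without replacement to exactly `rarefaction_depth` reads.
#' Samples with fewer reads than the depth are dropped and reported.
#' Draws consume one RNG stream seeded from `params$seed`, in sample
#' (column) order, so the result is reproducible.
#'
#' @param table an [otu_table].
#' @param params a [filter_params]; uses `rarefaction_depth` and `seed`.
#' @return list with `table` (rarefied) and `dropped` (sample ids below
#'   depth).
#' @export
rarefy <- function(table, params = filter_params()) {
  depth <- params$rarefaction_depth
  if (depth < 1) stop("rarefaction depth must be >= 1", call. = FALSE)
  ints <- round(table$counts)
  totals <- colSums(ints)
  keep <- totals >= depth
  out <- ints[, keep, drop = FALSE]
  set.seed(params$seed)
  for (j in seq_len(ncol(out))) {
    if (sum(out[, j]) > depth) {
      out[, j] <- subsample_counts(out[, j], depth)
    }
  }
  list(table = otu_table(out, table$roles[keep]),
       dropped = sample_ids(table)[!keep])
}

#' Convert counts to within-sample relative abundances
#'
#' @param table an [otu_table] (or bare matrix) of counts.
#' @return matrix of the same shape whose columns each sum to 1.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    stop("zero-sum sample(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(m, 2L, tot, "/")
}

#' Run the full decontamination and filtering cascade
#'
#' Fixed stage order: replicate averaging, blank (mistag) subtraction,
#' negative-control contaminant removal, singleton/low-abundance filtering
#' on biological samples, rarefaction.  The returned audit balances reads
#' in = reads out + reads removed at every stage.
#'
#' @param table raw per-replicate [otu_table].
#' @param meta per-replicate metadata.
#' @param params a [filter_params].
#' @return list with `table` (rarefied biological-sample table), `meta`
#'   (merged, restricted to retained samples), `contaminants` (OTU ids),
#'   `audit` (per-stage accounting data.frame), `dropped_samples`.
#' @export
qc_pipeline <- function(table, meta, params = filter_params()) {
  audit <- list()
  merged <- merge_replicates(table, meta)
  audit$merge <- audit_stage("merge_replicates", table, merged)

  bs <- subtract_blank_signal(merged)
  audit$blank <- audit_stage("subtract_blank_signal", merged, bs$table,
                             list(otus_corrected = length(bs$blank_means)))

  contaminants <- identify_contaminants(bs$table)
  bio <- keep_roles(bs$table, "biological")
  audit$technical <- audit_stage("drop_technical_samples", bs$table, bio)
  decon <- subset_table(bio, otus = setdiff(otu_ids(bio), contaminants))
  audit$contaminant <- audit_stage("remove_contaminants", bio, decon,
    list(contaminant_otus = length(contaminants),
         contaminant_fraction_of_reads =
           1 - sum(decon$counts) / max(sum(bio$counts), 1)))

  lowpass <- filter_low_abundance(decon, params)
  audit$abundance <- audit_stage("filter_low_abundance", decon, lowpass)

  rar <- rarefy(lowpass, params)
  audit$rarefy <- audit_stage("rarefy", lowpass, rar$table,
                              list(samples_dropped = length(rar$dropped)))

  mmeta <- merged_metadata(meta)
  mmeta <- mmeta[mmeta$sample_id %in% sample_ids(rar$table), , drop = FALSE]
  audit_df <- do.call(rbind, lapply(audit, function(a)
    data.frame(a[c("stage", "otus_in", "otus_out", "samples_in",
                   "samples_out", "reads_in", "reads_out",
                   "reads_removed")], stringsAsFactors = FALSE)))
  rownames(audit_df) <- NULL
  list(table = rar$table, meta = mmeta, contaminants = contaminants,
       audit = audit_df, audit_detail = audit,
       dropped_samples = rar$dropped, params = params)
}
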