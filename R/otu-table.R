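#' OTU count table with sample roles
#'
#' The central container of the package: a numeric matrix of read counts
#' (OTU rows x sample columns) together with one role per sample.  Counts
#' may be fractional after PCR-replicate averaging; they are non-negative
#' everywhere.  Roles distinguish biological samples from the technical
#' samples the decontamination cascade consumes (blank tag combinations,
#' field/reagent negative controls, PCR positive controls).
#'
#' @param counts numeric matrix, OTU x sample, with unique non-empty
#'   dimnames and no negative or missing values.
#' @param roles character vector of sample roles, one per column of
#'   `counts`, each one of `"biological"`, `"blank"`, `"negative_control"`,
#'   `"positive_control"`.  Either named by sample id or in column order.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (the matrix) and `roles` (named character vector).
#' @examples
#' m <- matrix(c(5, 0, 2, 7), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("s1", "s2")))
#' tab <- otu_table(m, c(s1 = "biological", s2 = "blank"))
#' n_samples(tab)
#' @export
otu_table <- function(counts, roles) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("'counts' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    stop("'counts' must have OTU ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    stop("'counts' must have sample ids as colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(counts)) stop("'counts' contains missing values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  roles <- validate_roles(roles, colnames(counts))
  structure(list(counts = counts, roles = roles), class = "otu_table")
}

sample_role_levels <- c("biological", "blank", "negative_control",
                        "positive_control")

validate_roles <- function(roles, sample_ids) {
  roles <- as.character(roles)
  if (length(roles) != length(sample_ids)) {
    stop("need exactly one role per sample", call. = FALSE)
  }
  if (!is.null(names(roles))) {
    if (!setequal(names(roles), sample_ids)) {
      stop("role names do not match sample ids", call. = FALSE)
    }
    roles <- roles[sample_ids]
  } else {
    names(roles) <- sample_ids
  }
  bad <- setdiff(unique(roles), sample_role_levels)
  if (length(bad)) {
    stop("unknown sample role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  roles
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tb <- table(factor(x$roles, levels = sample_role_levels))
  cat("roles:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
n_otus <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_samples <- function(x) ncol(x$counts)

#' @rdname otu_table
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Subset an OTU table by samples and/or OTUs
#'
#' @param x an `otu_table`.
#' @param samples sample ids or logical/integer index over columns.
#' @param otus OTU ids or logical/integer index over rows.
#' @return An `otu_table` restricted to the selection, order preserved as
#'   given.
#' @export
subset_table <- function(x, samples = NULL, otus = NULL) {
  counts <- x$counts
  roles <- x$roles
  if (!is.null(otus)) counts <- counts[otus, , drop = FALSE]
  if (!is.null(samples)) {
    counts <- counts[, samples, drop = FALSE]
    roles <- roles[colnames(counts)]
  }
  otu_table(counts, roles)
}

#' Keep only samples of the given role(s)
#'
#' @param x an `otu_table`.
#' @param roles character vector of roles to keep.
#' @export
keep_roles <- function(x, roles) {
  subset_table(x, samples = names(x$roles)[x$roles %in% roles])
}

#' Labelled symmetric dissimilarity matrix
#'
#' Light validation wrapper used by every routine that consumes pairwise
#' dissimilarities: square numeric matrix, matching dimnames, zero diagonal,
#' symmetric to 1e-12.
#'
#' @param m square numeric matrix with identical row/column names.
#' @return The validated matrix, with class `dist_matrix` prepended.
#' @export
dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("distance matrix needs identical row and column labels",
         call. = FALSE)
  }
  if (anyNA(m)) stop("distance matrix contains missing values", call. = FALSE)
  if (any(abs(diag(m)) > 1e-12)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(m < -1e-12)) stop("negative dissimilarities", call. = FALSE)
  class(m) <- c("dist_matrix", class(m))
  m
}

#' Strictly-lower-triangle vector of a distance matrix
#' @param m square matrix.
#' @return numeric vector, column-major lower triangle.
#' @keywords internal
lower_tri <- function(m) m[lower.tri(m)]
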