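#' Read an OTU count table from TSV
#'
#' Expects a UTF-8 tab-delimited file whose header row holds sample ids and
#' whose first column (named `otu_id`) holds OTU ids; every other cell must
#' parse as a non-negative number.  Sample roles come either from a named
#' `role_map` argument or from the `sample_role` column of a metadata table.
#'
#' @param path path to the TSV file.
#' @param role_map named character vector mapping sample id to role; if
#'   `NULL` every sample is assumed `"biological"`.
#' @param transpose set to `TRUE` if the file is written sample-rows x
#'   OTU-columns (the other common dialect).
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, role_map = NULL, transpose = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 1L) stop("empty OTU table file", call. = FALSE)
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  num <- if (nrow(body) == 0L) {
    matrix(numeric(0), nrow = 0L, ncol = ncol(body),
           dimnames = list(NULL, colnames(body)))
  } else {
    matrix(suppressWarnings(
      vapply(body, function(col) as.numeric(col), numeric(nrow(body)))),
      nrow = nrow(body), dimnames = list(ids, colnames(body)))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at OTU '%s', sample '%s'",
                 ids[bad[1L]], colnames(num)[bad[2L]]), call. = FALSE)
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 ids[bad[1L]], colnames(num)[bad[2L]]), call. = FALSE)
  }
  if (transpose) num <- t(num)
  roles <- if (is.null(role_map)) {
    stats::setNames(rep("biological", ncol(num)), colnames(num))
  } else {
    missing <- setdiff(colnames(num), names(role_map))
    if (length(missing)) {
      stop("no role for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    role_map[colnames(num)]
  }
  otu_table(num, roles)
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table]; roles are not stored in the file (they live
#' in the metadata), so a write/read round trip needs the same role map.
#'
#' @param x an [otu_table].
#' @param path output path.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(otu_id = otu_ids(x), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

metadata_columns <- c("sample_id", "bird_id", "nest_of_origin",
                      "nest_of_rearing", "age_class", "nest_treatment",
                      "body_mass_g", "tarsus_mm", "replicate_id",
                      "sample_role")

#' Read the sample metadata table
#'
#' One row per sequenced sample (one per PCR replicate before merging).
#' Technical samples (blanks, controls) leave the design columns empty.
#' Tarsus length is measured at day 15 only, so day-8 rows normally carry an
#' empty `tarsus_mm` cell; missing morphometrics are kept as `NA`.
#'
#' @param path TSV with columns `sample_id, bird_id, nest_of_origin,
#'   nest_of_rearing, age_class, nest_treatment, body_mass_g, tarsus_mm,
#'   replicate_id, sample_role`.
#' @return A data.frame with those columns, numeric morphometrics, and
#'   validated factor levels (`age_class` in D8/D15, `nest_treatment` in
#'   control/crossfostered).
#' @export
read_metadata <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "",
                            na.strings = c("", "NA"))
  missing <- setdiff(metadata_columns, colnames(meta))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[, metadata_columns]
  meta$body_mass_g <- as.numeric(meta$body_mass_g)
  meta$tarsus_mm <- as.numeric(meta$tarsus_mm)
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  bio <- meta[!is.na(meta$sample_role) & meta$sample_role == "biological", ]
  bad_age <- setdiff(stats::na.omit(unique(bio$age_class)), c("D8", "D15"))
  if (length(bad_age)) {
    stop("unknown age_class level(s): ", paste(bad_age, collapse = ", "),
         call. = FALSE)
  }
  bad_tr <- setdiff(stats::na.omit(unique(bio$nest_treatment)),
                    c("control", "crossfostered"))
  if (length(bad_tr)) {
    stop("unknown nest_treatment level(s): ", paste(bad_tr, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(stats::na.omit(unique(meta$sample_role)),
                      sample_role_levels)
  if (length(bad_role)) {
    stop("unknown sample_role level(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  # a bird must sit in exactly one nest of rearing at each age
  key <- paste(bio$bird_id, bio$age_class)
  nests <- tapply(bio$nest_of_rearing, key,
                  function(v) length(unique(v)))
  if (any(nests > 1L)) {
    stop("bird recorded in two nests at one age: ",
         paste(names(nests)[nests > 1L], collapse = ", "), call. = FALSE)
  }
  meta
}

#' Write a metadata table to TSV
#' @param meta metadata data.frame as returned by [read_metadata].
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an OTU taxonomy table
#'
#' @param path TSV with columns `otu_id` and `lineage`, the latter a
#'   semicolon-delimited ranked lineage (kingdom ... genus, at most 7
#'   ranks, unassigned ranks empty).
#' @return data.frame with columns `otu_id`, `lineage`, plus one column per
#'   rank (`kingdom`, `phylum`, `class`, `order`, `family`, `genus`,
#'   `species`), empty string where unassigned.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "",
                           na.strings = character())
  if (!all(c("otu_id", "lineage") %in% colnames(tax))) {
    stop("taxonomy needs columns 'otu_id' and 'lineage'", call. = FALSE)
  }
  parse_taxonomy(tax$otu_id, tax$lineage)
}

taxonomy_ranks <- c("kingdom", "phylum", "class", "order", "family",
                    "genus", "species")

#' Build a taxonomy table from id/lineage vectors
#'
#' @param otu_id character vector of unique OTU ids.
#' @param lineage semicolon-delimited lineages, at most 7 ranks each.
#' @return As [read_taxonomy].
#' @export
parse_taxonomy <- function(otu_id, lineage) {
  if (anyDuplicated(otu_id)) {
    stop("duplicate otu_id in taxonomy", call. = FALSE)
  }
  parts <- strsplit(lineage, ";", fixed = TRUE)
  too_long <- lengths(parts) > length(taxonomy_ranks)
  if (any(too_long)) {
    stop("lineage with more than 7 ranks for OTU ",
         otu_id[which(too_long)[1L]], call. = FALSE)
  }
  ranks <- t(vapply(parts, function(p) {
    p <- trimws(p)
    c(p, rep("", length(taxonomy_ranks) - length(p)))
  }, character(length(taxonomy_ranks))))
  colnames(ranks) <- taxonomy_ranks
  data.frame(otu_id = otu_id, lineage = lineage, ranks,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a taxonomy table to TSV
#' @param tax taxonomy data.frame.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax[, c("otu_id", "lineage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validate an OTU table against its metadata
#'
#' Collects findings rather than raising: sample id agreement in both
#' directions, role agreement between table and metadata, the two-PCR-
#' replicate contract for every biological sample, and day-8/day-15 pairing
#' per bird.  Never errors on any input.
#'
#' @param otu an [otu_table].
#' @param meta metadata data.frame.
#' @return list of class `validation_report` with elements `findings`
#'   (data.frame severity/message) and `pass` (FALSE iff any `error`).
#' @export
validate_dataset <- function(otu, meta) {
  findings <- list()
  note <- function(severity, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, message = message, stringsAsFactors = FALSE)
  }
  sm <- tryCatch(as.character(meta$sample_id), error = function(e) character())
  st <- tryCatch(sample_ids(otu), error = function(e) character())
  for (s in setdiff(st, sm)) note("error", paste0("sample '", s,
    "' present in counts but not in metadata"))
  for (s in setdiff(sm, st)) note("warning", paste0("sample '", s,
    "' present in metadata but not in counts"))
  both <- intersect(st, sm)
  if (length(both)) {
    mrole <- meta$sample_role[match(both, meta$sample_id)]
    trole <- otu$roles[both]
    for (i in which(!is.na(mrole) & mrole != trole)) {
      note("error", sprintf(
        "sample '%s': role '%s' in counts but '%s' in metadata",
        both[i], trole[i], mrole[i]))
    }
  }
  bio <- meta[!is.na(meta$sample_role) & meta$sample_role == "biological" &
                meta$sample_id %in% st, , drop = FALSE]
  if (nrow(bio)) {
    key <- paste(bio$bird_id, bio$age_class, sep = "|")
    reps <- table(key)
    for (k in names(reps)[reps != 2L]) {
      note("error", sprintf(
        "biological sample '%s' has %d PCR replicate(s), expected 2",
        k, reps[[k]]))
    }
    ages <- tapply(bio$age_class, bio$bird_id,
                   function(a) sort(unique(a)))
    for (b in names(ages)[!vapply(ages, function(a)
      identical(a, c("D15", "D8")), logical(1))]) {
      note("warning", sprintf(
        "bird '%s' sampled at %s only", b,
        paste(ages[[b]], collapse = "/")))
    }
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(severity = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(findings = findings,
                 pass = !any(findings$severity == "error")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: %s (%d finding(s))\n",
              if (x$pass) "PASS" else "FAIL", nrow(x$findings)))
  if (nrow(x$findings)) {
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  [%s] %s\n", x$findings$severity[i],
                  x$findings$message[i]))
    }
  }
  invisible(x)
}

#' Write a result bundle to disk
#'
#' Serializes every element of `bundle` under `out_dir`: `otu_table`s and
#' matrices/data.frames as TSV, everything else as JSON, plus a `run_log.json`
#' carrying the seed, a hash of the configuration, and the file manifest.
#' Re-running with identical inputs and seed reproduces byte-identical
#' numeric outputs.
#'
#' @param bundle named list of results.
#' @param out_dir output directory (created if absent).
#' @param seed the seed the run used (stored in the log).
#' @param config optional configuration object, hashed into the log.
#' @return data.frame manifest (name, file).
#' @export
write_results <- function(bundle, out_dir, seed = NA_integer_,
                          config = NULL) {
  stopifnot(is.list(bundle), !is.null(names(bundle)),
            all(nzchar(names(bundle))))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory ", out_dir, call. = FALSE)
    }
  }
  manifest <- data.frame(name = character(), file = character(),
                         stringsAsFactors = FALSE)
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (inherits(x, "otu_table")) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write_otu_table(x, f)
    } else if (is.matrix(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(strip_for_json(x), f, auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
    }
    manifest <- rbind(manifest,
                      data.frame(name = nm, file = basename(f),
                                 stringsAsFactors = FALSE))
  }
  log <- list(seed = seed,
              config_hash = rlang::hash(config),
              files = manifest$file,
              package_version = as.character(
                utils::packageVersion("fosterbiome")))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

# drop function elements / model objects that jsonlite cannot serialize
strip_for_json <- function(x) {
  if (is.function(x)) return(NULL)
  if (inherits(x, c("lmerMod", "lmerModLmerTest"))) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_for_json)
    x[!vapply(x, is.null, logical(1))]
  } else x
}
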