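# Long-format subject x tract x feature measurement tables, one per pipeline.

SEX_LEVELS <- c("male", "female")

normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("m", "male")] <- "male"
  out[s %in% c("f", "female")] <- "female"
  if (anyNA(out)) {
    bad <- unique(sex[is.na(out)])
    abort(paste0("unrecognized sex label(s): ", paste(bad, collapse = ", "),
                 " (accepted: M/F, male/female, case-insensitive)"))
  }
  out
}

#' Construct a tract-feature table
#'
#' A tract-feature table holds one scalar measurement per (subject, tract,
#' feature) triple for a single pipeline, in long format, together with each
#' subject's sex. Missing measurements are absent rows, never sentinel values.
#' Values stay in their native units (diffusivities in mm^2/s, volume in mm^3,
#' the rest dimensionless); all downstream statistics are unit-free.
#'
#' @param data A data frame with columns `subject_id`, `sex`, `tract`,
#'   `feature`, `value`.
#' @param pipeline_id Label identifying the pipeline that produced the table.
#' @param tracts,features Registries used to validate labels ([tract_registry()]
#'   and [feature_registry()] by default). Pass `NULL` to accept arbitrary
#'   labels (used by the synthetic generator).
#' @return A tibble of class `tract_feature_table` with attribute
#'   `pipeline_id`; `sex` normalized to `"male"`/`"female"`.
#' @export
tract_feature_table <- function(data, pipeline_id,
                                tracts = tract_registry(),
                                features = feature_registry()) {
  stopifnot(is.character(pipeline_id), length(pipeline_id) == 1)
  required <- c("subject_id", "sex", "tract", "feature", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(data[required])
  tbl$subject_id <- as.character(tbl$subject_id)
  tbl$tract <- as.character(tbl$tract)
  tbl$feature <- as.character(tbl$feature)
  tbl$sex <- normalize_sex(tbl$sex)

  if (!is.numeric(tbl$value)) {
    parsed <- suppressWarnings(as.numeric(tbl$value))
    bad <- which(is.na(parsed) & !is.na(tbl$value))
    if (length(bad)) {
      abort(paste0("non-numeric value in row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    tbl$value <- parsed
  }
  if (anyNA(tbl$value)) {
    abort(paste0("NA value in row(s): ",
                 paste(head(which(is.na(tbl$value)), 5), collapse = ", "),
                 "; encode missing measurements as absent rows"))
  }

  if (!is.null(tracts)) {
    unknown <- setdiff(unique(tbl$tract), tracts$abbreviation)
    if (length(unknown)) {
      abort(paste0("unknown tract label(s): ", paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(features)) {
    unknown <- setdiff(unique(tbl$feature), features$feature)
    if (length(unknown)) {
      abort(paste0("unknown feature label(s): ", paste(unknown, collapse = ", ")))
    }
  }

  key <- paste(tbl$subject_id, tbl$tract, tbl$feature, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tbl[duplicated(key), , drop = FALSE]
    abort(paste0("duplicate (subject, tract, feature) triple(s), e.g. (",
                 dup$subject_id[1], ", ", dup$tract[1], ", ", dup$feature[1], ")"))
  }

  sex_per_subject <- tapply(tbl$sex, tbl$subject_id,
                            function(s) length(unique(s)))
  if (any(sex_per_subject > 1)) {
    abort(paste0("conflicting sex labels for subject(s): ",
                 paste(names(sex_per_subject)[sex_per_subject > 1], collapse = ", ")))
  }

  structure(tbl,
            pipeline_id = pipeline_id,
            class = c("tract_feature_table", class(tbl)))
}

#' @export
print.tract_feature_table <- function(x, ...) {
  cat("<tract_feature_table> pipeline:", pipeline_id(x), "\n")
  cat("  ", length(unique(x$subject_id)), "subjects,",
      length(unique(x$tract)), "tracts,",
      length(unique(x$feature)), "features,",
      nrow(x), "measurements\n")
  NextMethod()
}

#' Pipeline label of a tract-feature table
#' @param x A `tract_feature_table`.
#' @return The pipeline identifier string.
#' @export
pipeline_id <- function(x) attr(x, "pipeline_id")

#' Read a tract-feature table from a delimited file
#'
#' Expects long format with header columns `subject_id`, `sex`, `tract`,
#' `feature`, `value` (tab-separated by default, UTF-8). Every label is
#' validated against the registries; duplicated triples, unknown labels and
#' non-numeric values are errors, so a table that reads cleanly is safe for
#' every downstream stage.
#'
#' @param path File path.
#' @param pipeline_id Label for the pipeline the file came from.
#' @param delim Field delimiter, `"\t"` by default; use `","` for CSV.
#' @inheritParams tract_feature_table
#' @return A validated [tract_feature_table()].
#' @export
read_tract_table <- function(path, pipeline_id, delim = "\t",
                             tracts = tract_registry(),
                             features = feature_registry()) {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    subject_id = readr::col_character(),
    sex = readr::col_character(),
    tract = readr::col_character(),
    feature = readr::col_character(),
    value = readr::col_character()
  ))
  tract_feature_table(raw, pipeline_id, tracts = tracts, features = features)
}

#' Write a tract-feature table to a delimited file
#'
#' Values are written with full precision (`readr` default 15 significant
#' digits plus shortest round-trip representation), so
#' `read_tract_table(write_tract_table(x))` reproduces `x` exactly.
#'
#' @param x A `tract_feature_table`.
#' @param path Output file path.
#' @param delim Field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_tract_table <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "tract_feature_table"))
  readr::write_delim(tibble::as_tibble(x), path, delim = delim)
  invisible(path)
}

#' Align two pipelines' cohorts
#'
#' Restricts two tract-feature tables to their shared subjects, tracts and
#' features, with identical subject ordering, so that every downstream paired
#' analysis (agreement classification, paired bootstrap) compares the same
#' people measured twice. Errors if the same subject carries different sex
#' labels in the two tables, or if no subject is shared.
#'
#' @param a,b Two `tract_feature_table` objects.
#' @return A list with elements `a` and `b`, both restricted and sorted by
#'   (subject_id, tract, feature).
#' @export
align_cohorts <- function(a, b) {
  stopifnot(inherits(a, "tract_feature_table"),
            inherits(b, "tract_feature_table"))
  if (nrow(a) == 0 || nrow(b) == 0) abort("cannot align an empty table")

  subjects <- intersect(unique(a$subject_id), unique(b$subject_id))
  if (length(subjects) == 0) abort("no shared subjects between the two tables")

  sex_a <- dplyr::distinct(tibble::as_tibble(a), .data$subject_id, .data$sex)
  sex_b <- dplyr::distinct(tibble::as_tibble(b), .data$subject_id, .data$sex)
  merged <- dplyr::inner_join(sex_a, sex_b, by = "subject_id",
                              suffix = c("_a", "_b"))
  clash <- merged$subject_id[merged$sex_a != merged$sex_b]
  if (length(clash)) {
    abort(paste0("conflicting sex labels between tables for subject(s): ",
                 paste(clash, collapse = ", ")))
  }

  tracts <- intersect(unique(a$tract), unique(b$tract))
  features <- intersect(unique(a$feature), unique(b$feature))

  restrict <- function(x) {
    out <- tibble::as_tibble(x)
    out <- out[out$subject_id %in% subjects &
                 out$tract %in% tracts &
                 out$feature %in% features, , drop = FALSE]
    out <- dplyr::arrange(out, .data$subject_id, .data$tract, .data$feature)
    tract_feature_table(out, pipeline_id(x), tracts = NULL, features = NULL)
  }
  list(a = restrict(a), b = restrict(b))
}
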