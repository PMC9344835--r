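#' Central repository of harmonized records
#'
#' An in-process store for the harmonized entity-attribute-value records
#' produced by [standardize()], optionally persisted as newline-delimited
#' JSON (one record per line, diff-able, no database required). Stored
#' records can be queried by study, variable, subject, modality and status;
#' storing the identical record twice is a no-op.
#'
#' @param model the [data_model()] the records are harmonized against (used
#'   to resolve modality filters).
#' @param path optional NDJSON file; if it exists its records are loaded,
#'   and every [repo_store()] rewrites it.
#' @return an object of class `harmonized_repo` (an environment).
#' @export
harmonized_repo <- function(model, path = NULL) {
  repo <- new.env(parent = emptyenv())
  repo$model <- model
  repo$path <- path
  repo$records <- empty_records()
  class(repo) <- "harmonized_repo"
  if (!is.null(path) && file.exists(path)) {
    repo$records <- read_records_ndjson(path)
  }
  repo
}

#' @export
print.harmonized_repo <- function(x, ...) {
  cat(sprintf("<harmonized_repo> %d records (%s)\n", nrow(x$records),
              if (is.null(x$path)) "in-memory" else x$path))
  invisible(x)
}

record_keys <- function(records) {
  paste(records$study_id, records$subject_id,
        ifelse(is.na(records$visit_id), "", records$visit_id),
        records$variable_id, records$raw_value, records$status, sep = "\r")
}

#' Store harmonized records in the repository
#'
#' Idempotent for identical records: a record whose
#' (study, subject, visit, variable, raw value, status) key is already
#' present is not duplicated.
#'
#' @param repo a [harmonized_repo()].
#' @param records a `harmonized_records` data frame from [standardize()].
#' @return the repo, invisibly; `repo$records` is updated in place.
#' @export
repo_store <- function(repo, records) {
  unknown <- setdiff(unique(records$variable_id), variable_ids(repo$model))
  if (length(unknown)) {
    dst_abort("unknown_variable", paste("records reference unknown variable:",
                                        paste(unknown, collapse = ", ")))
  }
  new <- records[!record_keys(records) %in% record_keys(repo$records), ,
                 drop = FALSE]
  if (nrow(new)) {
    combined <- rbind(repo$records, new)
    rownames(combined) <- NULL
    class(combined) <- c("harmonized_records", "data.frame")
    repo$records <- combined
    if (!is.null(repo$path)) write_records_ndjson(repo$records, repo$path)
  }
  invisible(repo)
}

#' Query the harmonized repository
#'
#' Returns the records matching the conjunction of all supplied filters;
#' with no filters, all records.
#'
#' @param repo a [harmonized_repo()].
#' @param study_id,variable_id,subject_id,status exact-match filters
#'   (vectors allowed).
#' @param modality filter on the modality of the record's variable.
#' @return a `harmonized_records` data frame.
#' @export
repo_query <- function(repo, study_id = NULL, variable_id = NULL,
                       subject_id = NULL, modality = NULL, status = NULL) {
  recs <- repo$records
  if (!is.null(variable_id)) {
    unknown <- setdiff(variable_id, variable_ids(repo$model))
    if (length(unknown)) {
      dst_abort("unknown_variable",
                paste("unknown variable:", paste(unknown, collapse = ", ")))
    }
  }
  keep <- rep(TRUE, nrow(recs))
  if (!is.null(study_id)) keep <- keep & recs$study_id %in% study_id
  if (!is.null(variable_id)) keep <- keep & recs$variable_id %in% variable_id
  if (!is.null(subject_id)) keep <- keep & recs$subject_id %in% subject_id
  if (!is.null(status)) keep <- keep & recs$status %in% status
  if (!is.null(modality)) {
    mods <- vapply(repo$model$variables, `[[`, character(1), "modality")
    keep <- keep & recs$variable_id %in% names(mods)[mods %in% modality]
  }
  out <- recs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("harmonized_records", "data.frame")
  out
}

# ---- NDJSON / CSV persistence --------------------------------------------

#' Write harmonized records as newline-delimited JSON
#'
#' One JSON object per line; the typed `value` is a scalar (or `null` for
#' non-ok records).
#'
#' @param records a `harmonized_records` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records_ndjson <- function(records, path) {
  if (nrow(records) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  flat <- records
  flat$value <- lapply(records$value, function(v)
    if (is.null(v)) NULL else jsonlite::unbox(v))
  class(flat) <- "data.frame"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(flat, con, verbose = FALSE, digits = NA, na = "null",
                       always_decimal = TRUE)
  invisible(path)
}

#' Read harmonized records from newline-delimited JSON
#' @param path NDJSON file written by [write_records_ndjson()].
#' @return a `harmonized_records` data frame.
#' @export
read_records_ndjson <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_records())
  parsed <- lapply(lines, jsonlite::fromJSON)
  df <- data.frame(
    study_id = vapply(parsed, function(p) p$study_id, character(1)),
    subject_id = vapply(parsed, function(p) as.character(p$subject_id),
                        character(1)),
    visit_id = vapply(parsed, function(p)
      if (is.null(p$visit_id)) NA_character_ else as.character(p$visit_id),
      character(1)),
    variable_id = vapply(parsed, function(p) p$variable_id, character(1)),
    raw_value = vapply(parsed, function(p) as.character(p$raw_value),
                       character(1)),
    status = vapply(parsed, function(p) p$status, character(1)),
    stringsAsFactors = FALSE)
  df$value <- lapply(parsed, function(p)
    if (is.null(p$value) || length(p$value) == 0L) NULL else p$value)
  class(df) <- c("harmonized_records", "data.frame")
  df
}

#' Write harmonized records as CSV
#'
#' The typed value is serialized to its canonical string form in a `value`
#' column next to the raw value and status.
#'
#' @param records a `harmonized_records` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  flat <- records[c("study_id", "subject_id", "visit_id", "variable_id",
                    "raw_value", "status")]
  flat$value <- vapply(records$value, function(v)
    if (is.null(v)) "" else as.character(v), character(1))
  utils::write.csv(flat, path, row.names = FALSE, na = "")
  invisible(path)
}
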