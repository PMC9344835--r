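DEFAULT_MISSING_TOKENS <- c("", "NA", "N/A", "NaN", ".")

RECORD_STATUSES <- c("ok", "missing", "out_of_range", "type_error")

#' Ingest a 2D study table
#'
#' Reads a subjects-by-variables CSV into an untyped `raw_table`: every cell
#' is kept as a string; typing happens later in [standardize()]. Ragged rows,
#' duplicate column names and a missing subject column are rejected up
#' front with row locators.
#'
#' @param path CSV file (UTF-8).
#' @param study_id identifier of the study the table comes from.
#' @param subject_column name of the column holding subject identifiers.
#' @param visit_column optional name of a visit identifier column, carried
#'   through verbatim.
#' @param sep field delimiter (default comma).
#' @return an object of class `raw_table`.
#' @export
ingest_table <- function(path, study_id, subject_column,
                         visit_column = NULL, sep = ",") {
  if (!file.exists(path)) dst_abort("io", paste("no such file:", path))
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            blank.lines.skip = TRUE)
  if (length(nf) == 0L) dst_abort("schema", "empty file")
  ragged <- which(nf != nf[1])
  if (length(ragged)) {
    dst_abort("schema", sprintf(
      "ragged row: line %d has %d fields, header has %d",
      ragged[1], nf[ragged[1]], nf[1]))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, sep = sep,
                         colClasses = "character", na.strings = NULL,
                         check.names = FALSE, encoding = "UTF-8")
  raw_table(tab, study_id, subject_column, visit_column)
}

#' Construct a raw study table from a data frame
#'
#' @param data data.frame of character columns (coerced).
#' @param study_id study identifier.
#' @param subject_column name of the subject-id column (must exist).
#' @param visit_column optional visit-id column name.
#' @return an object of class `raw_table`.
#' @export
raw_table <- function(data, study_id, subject_column, visit_column = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(data)) data[[j]] <- as.character(data[[j]])
  if (anyDuplicated(names(data))) {
    dst_abort("schema", paste("duplicate column name:",
                              names(data)[duplicated(names(data))][1]))
  }
  if (!subject_column %in% names(data)) {
    dst_abort("schema", paste("subject column not found:", subject_column))
  }
  if (!is.null(visit_column) && !visit_column %in% names(data)) {
    dst_abort("schema", paste("visit column not found:", visit_column))
  }
  structure(list(study_id = as.character(study_id), data = data,
                 subject_column = subject_column,
                 visit_column = visit_column),
            class = "raw_table")
}

#' @export
print.raw_table <- function(x, ...) {
  cat(sprintf("<raw_table> study '%s': %d rows x %d columns\n",
              x$study_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

# data columns = all columns except subject and visit
data_columns <- function(raw) {
  setdiff(names(raw$data), c(raw$subject_column, raw$visit_column))
}

#' Resolve study columns to CDM variables
#'
#' The semi-automatic step of the pipeline: every data column (subject and
#' visit columns are excluded) is matched against the model with
#' [suggest_mappings()]. Columns whose best candidate reaches the auto
#' threshold are resolved automatically; columns in the review band or below
#' stay unmapped unless a manual override names their target. Manual
#' overrides always take precedence over the fuzzy decision.
#'
#' @param raw a [raw_table()].
#' @param model a [data_model()].
#' @param config a [match_config()].
#' @param manual_overrides named character vector / list mapping column name
#'   to `variable_id`.
#' @return data.frame of class `column_resolution` with columns `column`,
#'   `variable_id` (`NA` = unmapped), `origin` (`"auto"`/`"manual"`), `score`.
#' @export
resolve_columns <- function(raw, model, config = match_config(),
                            manual_overrides = NULL) {
  if (n_variables(model) == 0L) dst_abort("schema", "model has no variables")
  cols <- data_columns(raw)
  overrides <- unlist(manual_overrides) %||% character()
  unknown <- setdiff(overrides, variable_ids(model))
  if (length(unknown)) {
    dst_abort("unknown_variable", paste("override to unknown variable:",
                                        paste(unknown, collapse = ", ")))
  }
  sugg <- suggest_mappings(cols, model, config)
  top <- sugg[sugg$rank == 1L, , drop = FALSE]
  res <- data.frame(column = cols, variable_id = NA_character_,
                    origin = NA_character_, score = NA_real_,
                    stringsAsFactors = FALSE)
  idx <- match(res$column, top$source_label)
  auto <- !is.na(idx) & top$decision[idx] == "auto"
  res$variable_id[auto] <- top$variable_id[idx[auto]]
  res$origin[auto] <- "auto"
  res$score[auto] <- top$score[idx[auto]]
  manual <- res$column %in% names(overrides)
  res$variable_id[manual] <- overrides[res$column[manual]]
  res$origin[manual] <- "manual"
  res$score[manual] <- NA_real_
  structure(res, class = c("column_resolution", "data.frame"))
}

# ---- value coercion -------------------------------------------------------

# vectorized coercion of one column of raw strings against one variable
# spec; returns list(value = list-column, status = character)
coerce_column <- function(values, spec, missing_tokens) {
  n <- length(values)
  trimmed <- trimws(values)
  status <- rep("ok", n)
  out <- vector("list", n)
  is_missing <- trimmed %in% missing_tokens
  status[is_missing] <- "missing"
  todo <- !is_missing
  vr <- spec$value_range
  if (spec$data_type %in% c("integer", "float")) {
    num <- suppressWarnings(as.numeric(trimmed))
    if (spec$data_type == "integer") {
      ok_int <- grepl("^[+-]?[0-9]+$", trimmed)
      bad <- todo & (!ok_int | is.na(num))
    } else {
      bad <- todo & (is.na(num) | !is.finite(num))
    }
    status[bad] <- "type_error"
    inrange <- rep(TRUE, n)
    if (vr$kind == "numeric") inrange <- num >= vr$min & num <= vr$max
    oor <- todo & !bad & !inrange
    status[oor] <- "out_of_range"
    good <- which(status == "ok")
    for (i in good) out[[i]] <- if (spec$data_type == "integer")
      as.integer(num[i]) else num[i]
  } else if (spec$data_type == "boolean") {
    low <- tolower(trimmed)
    truth <- c("true" = TRUE, "1" = TRUE, "yes" = TRUE,
               "false" = FALSE, "0" = FALSE, "no" = FALSE)
    val <- truth[low]
    bad <- todo & is.na(val)
    status[bad] <- "type_error"
    for (i in which(status == "ok")) out[[i]] <- unname(val[i])
  } else if (spec$data_type == "date") {
    ok_fmt <- grepl("^\\d{4}-\\d{2}-\\d{2}$", trimmed)
    parsed <- as.Date(rep(NA_character_, n))
    parsed[ok_fmt] <- as.Date(trimmed[ok_fmt], format = "%Y-%m-%d",
                              optional = TRUE)
    bad <- todo & (!ok_fmt | is.na(parsed))
    status[bad] <- "type_error"
    for (i in which(status == "ok")) out[[i]] <- format(parsed[i], "%Y-%m-%d")
  } else if (spec$data_type == "categorical") {
    canon <- vr$categories
    idx <- match(tolower(trimmed), tolower(canon))
    bad <- todo & is.na(idx)
    status[bad] <- "type_error"
    for (i in which(status == "ok")) out[[i]] <- canon[idx[i]]
  } else {  # string
    for (i in which(status == "ok")) out[[i]] <- trimmed[i]
  }
  out[status != "ok"] <- list(NULL)
  list(value = out, status = status)
}

#' Standardize a raw study table against the model
#'
#' The core harmonization step: every (row, mapped column) cell becomes one
#' harmonized entity-attribute-value record, typed and validated against the
#' target variable's metadata. Coercion rules: integers must parse as whole
#' numbers; floats as finite numerics; booleans accept true/false, 1/0,
#' yes/no case-insensitively; dates must be ISO-8601 (`YYYY-MM-DD`);
#' categorical values are matched case-insensitively against the enumeration
#' and stored in canonical case. Numeric values outside the variable's range
#' are flagged `out_of_range`; unparseable values `type_error`; configured
#' missing tokens become `missing`. Nothing is dropped: flagged records keep
#' their raw value and a `NULL` typed value.
#'
#' @param raw a [raw_table()].
#' @param resolution a [resolve_columns()] result covering the table's data
#'   columns.
#' @param model a [data_model()].
#' @param strict if `TRUE`, the first non-ok record aborts with a
#'   `dst_validation_failure` error carrying the report.
#' @param missing_tokens strings treated as missing (after trimming).
#' @return list with elements `records` (a `harmonized_records` data.frame
#'   with list-column `value`) and `report` (a `validation_report`).
#' @export
standardize <- function(raw, resolution, model, strict = FALSE,
                        missing_tokens = DEFAULT_MISSING_TOKENS) {
  cols <- data_columns(raw)
  uncovered <- setdiff(cols, resolution$column)
  if (length(uncovered)) {
    dst_abort("schema", paste("resolution does not cover columns:",
                              paste(uncovered, collapse = ", ")))
  }
  mapped <- resolution[!is.na(resolution$variable_id), , drop = FALSE]
  unmapped_cols <- setdiff(cols, mapped$column)
  nrows <- nrow(raw$data)
  subjects <- raw$data[[raw$subject_column]]
  visits <- if (!is.null(raw$visit_column)) raw$data[[raw$visit_column]]
            else rep(NA_character_, nrows)

  rec_list <- vector("list", nrow(mapped))
  issues <- list()
  for (j in seq_len(nrow(mapped))) {
    colname <- mapped$column[j]
    vid <- mapped$variable_id[j]
    spec <- get_variable(model, vid)
    raw_vals <- raw$data[[colname]]
    cc <- coerce_column(raw_vals, spec, missing_tokens)
    rec_list[[j]] <- data.frame(
      study_id = rep(raw$study_id, nrows), subject_id = subjects,
      visit_id = visits, variable_id = rep(vid, nrows),
      raw_value = raw_vals, status = cc$status, stringsAsFactors = FALSE)
    rec_list[[j]]$value <- cc$value
    flag <- cc$status %in% c("type_error", "out_of_range")
    if (any(flag)) {
      issues[[length(issues) + 1L]] <- data.frame(
        column = colname, row = which(flag), raw_value = raw_vals[flag],
        reason = cc$status[flag], stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rec_list)) do.call(rbind, rec_list)
             else empty_records()
  # row-major order (subject by subject) reads naturally in exports
  if (nrow(records)) {
    ord <- order(rep(seq_len(nrows), nrow(mapped)))
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  class(records) <- c("harmonized_records", "data.frame")
  counts <- table(factor(records$status, levels = RECORD_STATUSES))
  report <- structure(
    list(counts = stats::setNames(as.integer(counts), RECORD_STATUSES),
         issues = if (length(issues)) do.call(rbind, issues) else
           data.frame(column = character(), row = integer(),
                      raw_value = character(), reason = character(),
                      stringsAsFactors = FALSE),
         unmapped_columns = unmapped_cols,
         n_rows = nrows, n_mapped_columns = nrow(mapped)),
    class = "validation_report")
  if (strict && any(records$status != "ok")) {
    dst_abort("validation_failure",
              sprintf("strict standardization failed: %d non-ok record(s)",
                      sum(records$status != "ok")),
              data = list(report = report))
  }
  list(records = records, report = report)
}

empty_records <- function() {
  df <- data.frame(study_id = character(), subject_id = character(),
                   visit_id = character(), variable_id = character(),
                   raw_value = character(), status = character(),
                   stringsAsFactors = FALSE)
  df$value <- list()
  df
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  %d rows x %d mapped columns = %d records\n",
              x$n_rows, x$n_mapped_columns, sum(x$counts)))
  cat("  status:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                         collapse = ", "), "\n")
  if (length(x$unmapped_columns)) {
    cat("  unmapped columns:", paste(x$unmapped_columns, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report a `validation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  doc <- unclass(report)
  doc$counts <- as.list(doc$counts)  # keep status names as JSON keys
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
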