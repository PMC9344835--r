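VAR_CSV_COLUMNS <- c("variable_id", "label", "definition", "modality",
                     "data_type", "range_kind", "min", "max", "categories",
                     "ontology_refs")

# flatten one variable_spec to a one-row data.frame for the CSV catalog;
# categories and ontology refs are pipe-separated
spec_to_row <- function(v) {
  vr <- v$value_range
  data.frame(
    variable_id = v$variable_id, label = v$label, definition = v$definition,
    modality = v$modality, data_type = v$data_type, range_kind = vr$kind,
    # full precision so the text round-trip is loss-free
    min = if (vr$kind == "numeric") sprintf("%.17g", vr$min) else "",
    max = if (vr$kind == "numeric") sprintf("%.17g", vr$max) else "",
    categories = paste(vr$categories %||% character(), collapse = "|"),
    ontology_refs = paste(v$ontology_refs, collapse = "|"),
    stringsAsFactors = FALSE)
}

row_to_spec <- function(row, locator) {
  kind <- row$range_kind
  if (is.na(kind) || !kind %in% c("numeric", "enumeration", "unconstrained")) {
    dst_abort("schema", sprintf("%s: unknown range_kind '%s'", locator, kind))
  }
  vr <- tryCatch(
    switch(kind,
           numeric = value_range("numeric", min = as.numeric(row$min),
                                 max = as.numeric(row$max)),
           enumeration = value_range("enumeration",
                                     categories = split_pipe(row$categories)),
           unconstrained = value_range("unconstrained")),
    dst_error = function(e) {
      dst_abort("schema", sprintf("%s: %s", locator, conditionMessage(e)))
    })
  tryCatch(
    variable_spec(row$variable_id, row$label,
                  definition = if (is.na(row$definition)) "" else row$definition,
                  modality = row$modality, data_type = row$data_type,
                  value_range = vr,
                  ontology_refs = split_pipe(row$ontology_refs)),
    dst_error = function(e) {
      dst_abort("schema", sprintf("%s: %s", locator, conditionMessage(e)))
    })
}

split_pipe <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(character())
  strsplit(s, "|", fixed = TRUE)[[1]]
}

mappings_csv_path <- function(path) {
  sub("\\.csv$", "_mappings.csv", path, ignore.case = TRUE)
}

#' Save a clinical data model to disk
#'
#' JSON stores the whole model (metadata, variables, mappings) in one file.
#' CSV writes the variable catalog to `path` (one row per variable, with
#' `categories` and `ontology_refs` pipe-separated) and the mappings to a
#' companion file `<path>_mappings.csv`; model metadata goes on a `#meta`
#' comment line above the header. `load_model(save_model(m))` reproduces the
#' model field by field.
#'
#' @param model a [data_model()].
#' @param path destination file.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = NULL) {
  validate_model(model)
  format <- format %||% infer_format(path)
  if (format == "json") {
    doc <- list(
      metadata = model$metadata,
      variables = lapply(unname(model$variables), function(v) {
        list(variable_id = v$variable_id, label = v$label,
             definition = v$definition, modality = v$modality,
             data_type = v$data_type, range_kind = v$value_range$kind,
             min = v$value_range$min, max = v$value_range$max,
             categories = as.list(v$value_range$categories %||% character()),
             ontology_refs = as.list(v$ontology_refs))
      }),
      mappings = model$mappings)
    # digits=I(17): exact double round-trip for range bounds and scores
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, na = "null", dataframe = "rows")
  } else if (format == "csv") {
    rows <- do.call(rbind, c(lapply(unname(model$variables), spec_to_row),
                             list(empty_var_rows())))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("#meta ", jsonlite::toJSON(model$metadata,
                                                 auto_unbox = TRUE)), con)
    utils::write.csv(rows, con, row.names = FALSE, na = "")
    utils::write.csv(model$mappings, mappings_csv_path(path),
                     row.names = FALSE, na = "")
  } else {
    dst_abort("schema", paste("unknown model format:", format))
  }
  invisible(path)
}

empty_var_rows <- function() {
  df <- data.frame(variable_id = character(), label = character(),
                   definition = character(), modality = character(),
                   data_type = character(), range_kind = character(),
                   min = character(), max = character(),
                   categories = character(),
                   ontology_refs = character(), stringsAsFactors = FALSE)
  df
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) return(ext)
  dst_abort("schema",
            paste("cannot infer model format from extension of", path))
}

#' Load a clinical data model from disk
#'
#' Reads a model saved by [save_model()] (or any file conforming to the same
#' catalog dialect). For CSV, the mappings companion file
#' `<path>_mappings.csv` is read when present.
#'
#' @param path model file (`.json` or `.csv` catalog).
#' @param format `"json"` or `"csv"`; inferred from the extension when omitted.
#' @return a validated [data_model()].
#' @export
load_model <- function(path, format = NULL) {
  if (!file.exists(path)) dst_abort("io", paste("no such file:", path))
  format <- format %||% infer_format(path)
  if (format == "json") {
    doc <- jsonlite::read_json(path)
    scl <- function(x, default) if (length(x) != 1L) default else x[[1]]
    vars <- lapply(doc$variables, function(v) {
      row <- data.frame(
        variable_id = scl(v$variable_id, NA_character_),
        label = scl(v$label, NA_character_),
        definition = scl(v$definition, ""),
        modality = scl(v$modality, NA_character_),
        data_type = scl(v$data_type, NA_character_),
        range_kind = scl(v$range_kind, NA_character_),
        min = scl(v$min, NA_real_), max = scl(v$max, NA_real_),
        categories = paste(unlist(v$categories), collapse = "|"),
        ontology_refs = paste(unlist(v$ontology_refs), collapse = "|"),
        stringsAsFactors = FALSE)
      row_to_spec(row, sprintf("variable '%s'", row$variable_id))
    })
    mp <- if (length(doc$mappings)) {
      do.call(rbind, lapply(doc$mappings, function(m) data.frame(
        cdm_variable_id = m$cdm_variable_id, study_id = m$study_id,
        source_label = m$source_label, method = m$method,
        score = as.numeric(m$score %||% NA_real_), stringsAsFactors = FALSE)))
    } else empty_mappings()
    meta <- doc$metadata %||% list()
    build_model(vars, mp, meta)
  } else if (format == "csv") {
    first <- readLines(path, n = 1L, encoding = "UTF-8")
    meta <- list()
    if (length(first) && startsWith(first, "#meta ")) {
      meta <- jsonlite::fromJSON(sub("^#meta ", "", first))
    }
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character", na.strings = NULL,
                           encoding = "UTF-8")
    missing_cols <- setdiff(VAR_CSV_COLUMNS, names(tab))
    if (length(missing_cols)) {
      dst_abort("schema", paste("catalog CSV missing columns:",
                                paste(missing_cols, collapse = ", ")))
    }
    vars <- lapply(seq_len(nrow(tab)), function(i) {
      row <- tab[i, ]
      row$min <- if (nzchar(row$min)) as.numeric(row$min) else NA_real_
      row$max <- if (nzchar(row$max)) as.numeric(row$max) else NA_real_
      row_to_spec(row, sprintf("row %d", i))
    })
    mpath <- mappings_csv_path(path)
    mp <- if (file.exists(mpath)) {
      m <- utils::read.csv(mpath, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = "",
                           encoding = "UTF-8")
      if (nrow(m)) m$score <- as.numeric(m$score)
      m
    } else empty_mappings()
    build_model(vars, mp, meta)
  } else {
    dst_abort("schema", paste("unknown model format:", format))
  }
}

build_model <- function(vars, mappings, meta) {
  ids <- vapply(vars, `[[`, character(1), "variable_id")
  if (anyDuplicated(ids)) {
    dst_abort("duplicate_variable",
              paste("duplicate variable_id:", ids[duplicated(ids)][1]))
  }
  data_model(vars, mappings,
             name = meta$name %||% "cdm",
             version = meta$version %||% "0.0.0",
             provenance = meta$provenance %||% "")
}
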