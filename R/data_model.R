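#' Create a clinical data model (CDM)
#'
#' A `data_model` is the central catalog: a set of [variable_spec()] entries
#' keyed by `variable_id`, plus the mappings recorded so far from study
#' column names onto those variables, plus free-form metadata (name, version,
#' provenance note).
#'
#' @param variables list of [variable_spec()] objects.
#' @param mappings data frame with columns `cdm_variable_id`, `study_id`,
#'   `source_label`, `method` (auto/manual/ontology), `score` (0-1 or NA for
#'   manual mappings).
#' @param name,version,provenance model metadata strings.
#'
#' @return An object of class `data_model`.
#' @seealso [add_variable()], [add_mapping()], [load_model()], [save_model()]
#' @export
data_model <- function(variables = list(), mappings = empty_mappings(),
                       name = "cdm", version = "0.0.0", provenance = "") {
  vars <- list()
  for (v in variables) vars[[v$variable_id]] <- v
  m <- structure(
    list(variables = vars,
         mappings = as_mappings(mappings),
         metadata = list(name = as.character(name),
                         version = as.character(version),
                         provenance = as.character(provenance))),
    class = "data_model"
  )
  validate_model(m)
  m
}

MAPPING_METHODS <- c("auto", "manual", "ontology")

empty_mappings <- function() {
  data.frame(cdm_variable_id = character(), study_id = character(),
              source_label = character(), method = character(),
              score = numeric(), stringsAsFactors = FALSE)
}

as_mappings <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) return(empty_mappings())
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- names(empty_mappings())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    dst_abort("schema", paste("mappings missing columns:",
                              paste(missing_cols, collapse = ", ")))
  }
  df <- df[need]
  df$score <- as.numeric(df$score)
  for (col in setdiff(need, "score")) df[[col]] <- as.character(df[[col]])
  rownames(df) <- NULL
  df
}

#' Validate a data model
#'
#' Checks every variable spec, the uniqueness of variable ids, that every
#' mapping resolves to an existing variable and that no
#' `(study_id, source_label)` pair is mapped twice.
#'
#' @param model a [data_model()].
#' @return The model, invisibly; signals a classed error on violation.
#' @export
validate_model <- function(model) {
  if (!inherits(model, "data_model")) dst_abort("schema", "not a data_model")
  ids <- vapply(model$variables, function(v) v$variable_id, character(1))
  if (length(ids) && any(names(model$variables) != ids)) {
    dst_abort("schema", "variable list names out of sync with variable_ids")
  }
  if (anyDuplicated(ids)) {
    dst_abort("duplicate_variable",
              paste("duplicate variable_id:", ids[duplicated(ids)][1]))
  }
  for (v in model$variables) validate_variable_spec(v)
  mp <- model$mappings
  if (nrow(mp)) {
    unknown <- setdiff(mp$cdm_variable_id, ids)
    if (length(unknown)) {
      dst_abort("unknown_variable",
                paste("mapping targets unknown variable:",
                      paste(unknown, collapse = ", ")))
    }
    if (!all(mp$method %in% MAPPING_METHODS)) {
      dst_abort("schema", "mapping method must be auto, manual or ontology")
    }
    key <- paste(mp$study_id, mp$source_label, sep = "\r")
    if (anyDuplicated(key)) {
      dst_abort("mapping_conflict",
                "duplicate (study_id, source_label) pair in mappings")
    }
    sc <- mp$score[!is.na(mp$score)]
    if (any(sc < 0 | sc > 1)) dst_abort("schema", "mapping score outside [0,1]")
  }
  invisible(model)
}

#' Number of variables in a model
#' @param model a [data_model()].
#' @return integer count.
#' @export
n_variables <- function(model) length(model$variables)

#' Variable ids of a model
#' @param model a [data_model()].
#' @return character vector of variable ids (insertion order).
#' @export
variable_ids <- function(model) names(model$variables)

#' Look up one variable spec
#' @param model a [data_model()].
#' @param variable_id id to fetch.
#' @return the [variable_spec()]; error of class `dst_unknown_variable` if absent.
#' @export
get_variable <- function(model, variable_id) {
  v <- model$variables[[variable_id]]
  if (is.null(v)) {
    dst_abort("unknown_variable", paste("unknown variable:", variable_id))
  }
  v
}

#' Add a variable to a model
#'
#' @param model a [data_model()].
#' @param spec a [variable_spec()].
#' @return the updated model.
#' @export
add_variable <- function(model, spec) {
  validate_variable_spec(spec)
  if (spec$variable_id %in% names(model$variables)) {
    dst_abort("duplicate_variable",
              paste("variable already exists:", spec$variable_id))
  }
  model$variables[[spec$variable_id]] <- spec
  model
}

#' Record a mapping from a study column onto a CDM variable
#'
#' A mapping links the verbatim column name (`source_label`) of a study
#' (`study_id`) to a CDM variable. Re-adding the identical mapping is a
#' no-op; mapping the same (study, column) pair to a *different* variable is
#' a conflict.
#'
#' @param model a [data_model()].
#' @param cdm_variable_id target variable id (must exist).
#' @param study_id study identifier.
#' @param source_label verbatim column name in the study.
#' @param method how the mapping was made: `"auto"`, `"manual"` or
#'   `"ontology"`.
#' @param score matching score in `[0,1]`; `NA` for manual mappings.
#' @return the updated model.
#' @export
add_mapping <- function(model, cdm_variable_id, study_id, source_label,
                        method = "manual", score = NA_real_) {
  if (!cdm_variable_id %in% names(model$variables)) {
    dst_abort("unknown_variable",
              paste("mapping target not in model:", cdm_variable_id))
  }
  if (!method %in% MAPPING_METHODS) {
    dst_abort("schema", paste("unknown mapping method:", method))
  }
  mp <- model$mappings
  hit <- mp$study_id == study_id & mp$source_label == source_label
  if (any(hit)) {
    if (all(mp$cdm_variable_id[hit] == cdm_variable_id)) {
      return(model)  # idempotent
    }
    dst_abort("mapping_conflict", sprintf(
      "(%s, %s) already mapped to '%s'", study_id, source_label,
      mp$cdm_variable_id[hit][1]))
  }
  model$mappings <- rbind(mp, data.frame(
    cdm_variable_id = cdm_variable_id, study_id = study_id,
    source_label = source_label, method = method, score = as.numeric(score),
    stringsAsFactors = FALSE))
  rownames(model$mappings) <- NULL
  model
}

# aliases (stored source labels) of one variable, used by mapper and search
variable_aliases <- function(model, variable_id) {
  mp <- model$mappings
  mp$source_label[mp$cdm_variable_id == variable_id]
}

#' @export
print.data_model <- function(x, ...) {
  cat(sprintf("<data_model> %s v%s\n", x$metadata$name, x$metadata$version))
  cat(sprintf("  %d variables, %d mappings\n",
              n_variables(x), nrow(x$mappings)))
  tab <- table(vapply(x$variables, function(v) v$modality, character(1)))
  if (length(tab)) {
    cat("  modalities:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a model as a data frame
#'
#' One row per variable: id, label, modality, data type, formatted range,
#' number of recorded study mappings.
#'
#' @param object a [data_model()].
#' @param ... unused.
#' @return a data.frame.
#' @export
summary.data_model <- function(object, ...) {
  vars <- object$variables
  data.frame(
    variable_id = vapply(vars, `[[`, character(1), "variable_id"),
    label = vapply(vars, `[[`, character(1), "label"),
    modality = vapply(vars, `[[`, character(1), "modality"),
    data_type = vapply(vars, `[[`, character(1), "data_type"),
    range = vapply(vars, function(v) format(v$value_range), character(1)),
    n_mappings = vapply(vars, function(v)
      sum(object$mappings$cdm_variable_id == v$variable_id), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
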