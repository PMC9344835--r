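CDM_MODALITIES <- c("demographics", "diagnostics", "neuropsychology",
                    "biomarker", "genetics", "imaging", "other")

CDM_DATA_TYPES <- c("integer", "float", "categorical", "boolean", "date",
                    "string")

#' Specification of one CDM variable
#'
#' A `variable_spec` holds the metadata the clinical data model records about
#' a single standardized variable: a stable identifier, a human-readable
#' label, a free-text definition, the data modality it belongs to, its data
#' type, its admissible [value_range()] and optional cross-references to
#' ontology terms (CURIEs such as `"NCIT:C28421"`).
#'
#' Type/range coherence is enforced: categorical variables must carry an
#' enumeration range, and integer/float variables a numeric or unconstrained
#' range.
#'
#' @param variable_id unique slug, lowercase `[a-z0-9_]`.
#' @param label human-readable name.
#' @param definition free-text definition (may be empty).
#' @param modality one of demographics, diagnostics, neuropsychology,
#'   biomarker, genetics, imaging, other.
#' @param data_type one of integer, float, categorical, boolean, date, string.
#' @param value_range a [value_range()] object.
#' @param ontology_refs character vector of CURIEs (`PREFIX:LOCALID`).
#'
#' @return An object of class `variable_spec`.
#' @examples
#' variable_spec("mmse_total", "MMSE total score",
#'   definition = "Mini-Mental State Examination total score",
#'   modality = "neuropsychology", data_type = "integer",
#'   value_range = value_range("numeric", 0, 30),
#'   ontology_refs = "NCIT:C75186")
#' @export
variable_spec <- function(variable_id, label, definition = "",
                          modality = "other", data_type = "string",
                          value_range = NULL,
                          ontology_refs = character()) {
  if (is.null(value_range)) {
    value_range <- if (identical(data_type, "categorical")) {
      dst_abort("schema", "categorical variable needs an enumeration value_range")
    } else {
      value_range("unconstrained")
    }
  }
  spec <- structure(
    list(variable_id = as.character(variable_id),
         label = as.character(label),
         definition = as.character(definition %||% ""),
         modality = as.character(modality),
         data_type = as.character(data_type),
         value_range = value_range,
         ontology_refs = as.character(ontology_refs)),
    class = "variable_spec"
  )
  validate_variable_spec(spec)
  spec
}

validate_variable_spec <- function(spec) {
  if (!inherits(spec, "variable_spec")) dst_abort("schema", "not a variable_spec")
  if (!is_string(spec$variable_id) ||
      !grepl("^[a-z0-9_]+$", spec$variable_id)) {
    dst_abort("schema", sprintf(
      "variable_id '%s' is not a lowercase [a-z0-9_] slug",
      paste(spec$variable_id, collapse = ",")))
  }
  if (!is_string(spec$label) || !nzchar(spec$label)) {
    dst_abort("schema", sprintf("variable '%s': label must be a non-empty string",
                                spec$variable_id))
  }
  if (!spec$modality %in% CDM_MODALITIES) {
    dst_abort("schema", sprintf("variable '%s': unknown modality '%s'",
                                spec$variable_id, spec$modality))
  }
  if (!spec$data_type %in% CDM_DATA_TYPES) {
    dst_abort("schema", sprintf("variable '%s': unknown data_type '%s'",
                                spec$variable_id, spec$data_type))
  }
  validate_value_range(spec$value_range)
  kind <- spec$value_range$kind
  if (spec$data_type == "categorical" && kind != "enumeration") {
    dst_abort("schema", sprintf(
      "variable '%s': categorical data_type requires an enumeration range",
      spec$variable_id))
  }
  if (kind == "enumeration" && spec$data_type != "categorical") {
    dst_abort("schema", sprintf(
      "variable '%s': enumeration range requires categorical data_type",
      spec$variable_id))
  }
  if (spec$data_type %in% c("integer", "float") &&
      !kind %in% c("numeric", "unconstrained")) {
    dst_abort("schema", sprintf(
      "variable '%s': numeric data_type requires numeric or unconstrained range",
      spec$variable_id))
  }
  bad <- spec$ontology_refs[!grepl("^[A-Za-z0-9_.]+:\\S+$", spec$ontology_refs)]
  if (length(bad)) {
    dst_abort("schema", sprintf("variable '%s': malformed CURIE(s): %s",
                                spec$variable_id, paste(bad, collapse = ", ")))
  }
  invisible(spec)
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s (%s)\n", x$variable_id, x$label))
  cat(sprintf("  modality: %s | type: %s | range: %s\n",
              x$modality, x$data_type, format(x$value_range)))
  if (length(x$ontology_refs)) {
    cat("  ontology:", paste(x$ontology_refs, collapse = ", "), "\n")
  }
  invisible(x)
}
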