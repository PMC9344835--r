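FHIR_CODE_SYSTEM <- "https://w3id.org/cdmsteward/codes"

#' Export harmonized records as a FHIR R4 bundle
#'
#' Builds a `Bundle` of type `"collection"` holding one `Patient` resource
#' per distinct subject and one `Observation` per record with status `ok`.
#' Observations carry the CDM variable id as their code (local code system
#' URI) and the typed value as `valueQuantity` (integer/float),
#' `valueCodeableConcept` (categorical), `valueBoolean`, `valueDateTime`
#' (date) or `valueString`. Records with non-ok status are skipped and
#' counted in the `n_skipped` element.
#'
#' @param records a `harmonized_records` data frame (see [standardize()]).
#' @param model the [data_model()] the records conform to.
#' @param study_id study the records belong to; records from other studies
#'   are rejected.
#' @return list of class `fhir_export` with elements `bundle` (nested list,
#'   ready for [write_fhir()]) and `n_skipped`.
#' @export
export_fhir <- function(records, model, study_id) {
  if (nrow(records) && !all(records$study_id == study_id)) {
    dst_abort("schema", "records from a different study present")
  }
  unknown <- setdiff(unique(records$variable_id), variable_ids(model))
  if (length(unknown)) {
    dst_abort("unknown_variable", paste("records reference unknown variable:",
                                        paste(unknown, collapse = ", ")))
  }
  ok <- records[records$status == "ok", , drop = FALSE]
  n_skipped <- nrow(records) - nrow(ok)
  subjects <- unique(records$subject_id)
  pid <- function(s) paste0(study_id, "-", gsub("[^A-Za-z0-9.-]", "-", s))
  patient_entries <- lapply(subjects, function(s) {
    list(fullUrl = paste0("urn:cdm:Patient/", pid(s)),
         resource = list(
           resourceType = "Patient", id = pid(s),
           identifier = list(list(system = paste0("urn:cdm:study:", study_id),
                                  value = s))))
  })
  specs <- model$variables
  # column vectors, not per-row data.frame slices: bundles can be large
  ok_subject <- ok$subject_id
  ok_vid <- ok$variable_id
  ok_visit <- ok$visit_id
  ok_value <- ok$value
  obs_entries <- lapply(seq_len(nrow(ok)), function(i) {
    spec <- specs[[ok_vid[i]]]
    value <- ok_value[[i]]
    obs <- list(
      resourceType = "Observation",
      id = paste0("obs-", i),
      status = "final",
      code = list(coding = list(list(system = FHIR_CODE_SYSTEM,
                                     code = spec$variable_id,
                                     display = spec$label))),
      subject = list(reference = paste0("urn:cdm:Patient/",
                                        pid(ok_subject[i]))))
    if (!is.na(ok_visit[i])) {
      obs$encounter <- list(display = ok_visit[i])
    }
    obs <- c(obs, switch(spec$data_type,
      integer = ,
      float = list(valueQuantity = list(value = value)),
      categorical = list(valueCodeableConcept = list(coding = list(list(
        system = paste0(FHIR_CODE_SYSTEM, "/", spec$variable_id),
        code = value)))),
      boolean = list(valueBoolean = value),
      date = list(valueDateTime = value),
      list(valueString = as.character(value))))
    list(fullUrl = paste0("urn:cdm:Observation/obs-", i), resource = obs)
  })
  bundle <- list(resourceType = "Bundle", type = "collection",
                 total = length(patient_entries) + length(obs_entries),
                 entry = c(patient_entries, obs_entries))
  structure(list(bundle = bundle, n_skipped = n_skipped),
            class = "fhir_export")
}

#' @export
print.fhir_export <- function(x, ...) {
  cat(sprintf("<fhir_export> Bundle with %d entries (%d records skipped)\n",
              x$bundle$total, x$n_skipped))
  invisible(x)
}

#' Write a FHIR bundle to JSON
#' @param export a [export_fhir()] result (or a bare bundle list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fhir <- function(export, path) {
  bundle <- if (inherits(export, "fhir_export")) export$bundle else export
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
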