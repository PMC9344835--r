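OMOP_DOMAINS <- c("person", "measurement", "observation")

# standard OMOP gender concept ids
OMOP_GENDER <- c(m = 8507L, male = 8507L, f = 8532L, female = 8532L)

#' Build a default OMOP concept map for a model
#'
#' Assigns every variable an OMOP domain by rule: sex/gender and birth-year
#' variables feed the PERSON table; numeric biomarker and neuropsychology
#' variables become MEASUREMENT rows; everything else becomes OBSERVATION
#' rows. `omop_concept_id` is 0 ("no matching concept") throughout — the
#' OMOP convention for source values without a vocabulary mapping; supply
#' your own map to override.
#'
#' @param model a [data_model()].
#' @return data.frame with columns `variable_id`, `omop_domain`,
#'   `omop_concept_id`, `unit_source_value`.
#' @export
default_concept_map <- function(model) {
  vars <- model$variables
  rows <- lapply(vars, function(v) {
    domain <- if (v$variable_id %in% c("sex", "gender", "birth_year",
                                       "year_of_birth")) {
      "person"
    } else if (v$modality %in% c("biomarker", "neuropsychology") &&
               v$data_type %in% c("integer", "float")) {
      "measurement"
    } else {
      "observation"
    }
    data.frame(variable_id = v$variable_id, omop_domain = domain,
               omop_concept_id = 0L, unit_source_value = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    variable_id = character(), omop_domain = character(),
    omop_concept_id = integer(), unit_source_value = character(),
    stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Export harmonized records to OMOP-aligned tables
#'
#' Writes the OMOP CDM v5.4 core tables (column subset) as CSV:
#' `person.csv` (one row per subject; gender and year of birth filled from
#' person-domain records when present), `measurement.csv` (numeric results
#' with `value_as_number`) and `observation.csv` (everything else, with
#' `value_as_string`). Every status-ok record lands in exactly one place:
#' a measurement row, an observation row, or a person attribute.
#'
#' @param records a `harmonized_records` data frame.
#' @param model the [data_model()] the records conform to.
#' @param concept_map data.frame as produced by [default_concept_map()];
#'   must cover every variable present in the records.
#' @param out_dir output directory (created if needed).
#' @return list of class `omop_export`: `files` (paths), `counts`
#'   (`person_rows`, `measurement_rows`, `observation_rows`,
#'   `person_attribute_records`, `ok_records`).
#' @export
export_omop <- function(records, model, concept_map = NULL, out_dir) {
  concept_map <- concept_map %||% default_concept_map(model)
  if (!all(concept_map$omop_domain %in% OMOP_DOMAINS)) {
    dst_abort("schema", "concept map domain must be person/measurement/observation")
  }
  present <- unique(records$variable_id)
  gap <- setdiff(present, concept_map$variable_id)
  if (length(gap)) {
    dst_abort("mapping_gap", paste("concept map does not cover:",
                                   paste(gap, collapse = ", ")),
              data = list(variable_ids = gap))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ok <- records[records$status == "ok", , drop = FALSE]
  domain <- concept_map$omop_domain[match(ok$variable_id,
                                          concept_map$variable_id)]
  concept <- concept_map$omop_concept_id[match(ok$variable_id,
                                               concept_map$variable_id)]
  unit <- concept_map$unit_source_value[match(ok$variable_id,
                                              concept_map$variable_id)]
  subjects <- unique(records$subject_id)
  person_id <- stats::setNames(seq_along(subjects), subjects)

  # PERSON: one row per subject; gender/birth-year from person-domain records
  pers <- data.frame(person_id = unname(person_id),
                     gender_concept_id = rep(0L, length(subjects)),
                     year_of_birth = rep(NA_integer_, length(subjects)),
                     person_source_value = subjects,
                     gender_source_value = rep(NA_character_,
                                               length(subjects)),
                     stringsAsFactors = FALSE)
  pmask <- domain == "person"
  n_person_attr <- sum(pmask)
  if (any(pmask)) {
    prec <- ok[pmask, , drop = FALSE]
    for (i in seq_len(nrow(prec))) {
      row <- person_id[[prec$subject_id[i]]]
      val <- prec$value[[i]]
      vid <- prec$variable_id[i]
      if (vid %in% c("sex", "gender")) {
        g <- OMOP_GENDER[tolower(as.character(val))]
        pers$gender_concept_id[row] <- if (is.na(g)) 0L else unname(g)
        pers$gender_source_value[row] <- as.character(val)
      } else {
        pers$year_of_birth[row] <- as.integer(val)
      }
    }
  }

  labels <- vapply(model$variables, `[[`, character(1), "label")
  meas <- ok[domain == "measurement", , drop = FALSE]
  measurement <- data.frame(
    measurement_id = seq_len(nrow(meas)),
    person_id = unname(person_id[meas$subject_id]),
    measurement_concept_id = concept[domain == "measurement"],
    measurement_date = rep(NA_character_, nrow(meas)),
    value_as_number = vapply(meas$value, function(v) as.numeric(v),
                             numeric(1)),
    unit_source_value = unit[domain == "measurement"],
    measurement_source_value = unname(labels[meas$variable_id]),
    stringsAsFactors = FALSE)

  obs <- ok[domain == "observation", , drop = FALSE]
  observation <- data.frame(
    observation_id = seq_len(nrow(obs)),
    person_id = unname(person_id[obs$subject_id]),
    observation_concept_id = concept[domain == "observation"],
    observation_date = rep(NA_character_, nrow(obs)),
    value_as_string = vapply(obs$value, function(v) as.character(v),
                             character(1)),
    value_as_concept_id = rep(0L, nrow(obs)),
    observation_source_value = unname(labels[obs$variable_id]),
    stringsAsFactors = FALSE)

  files <- c(person = file.path(out_dir, "person.csv"),
             measurement = file.path(out_dir, "measurement.csv"),
             observation = file.path(out_dir, "observation.csv"))
  utils::write.csv(pers, files["person"], row.names = FALSE, na = "")
  utils::write.csv(measurement, files["measurement"], row.names = FALSE,
                   na = "")
  utils::write.csv(observation, files["observation"], row.names = FALSE,
                   na = "")
  structure(list(
    files = files,
    counts = list(person_rows = nrow(pers),
                  measurement_rows = nrow(measurement),
                  observation_rows = nrow(observation),
                  person_attribute_records = n_person_attr,
                  ok_records = nrow(ok))),
    class = "omop_export")
}

#' @export
print.omop_export <- function(x, ...) {
  cat("<omop_export>\n")
  cat(sprintf("  person: %d rows | measurement: %d | observation: %d\n",
              x$counts$person_rows, x$counts$measurement_rows,
              x$counts$observation_rows))
  invisible(x)
}
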