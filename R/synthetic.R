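# run code under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Built-in dementia-cohort schema
#'
#' A compact clinical data model covering the variable families that
#' dementia cohort studies share: demographics (age, sex, education),
#' diagnosis (CN / MCI / AD), neuropsychological test scores (MMSE,
#' ADAS-Cog 13, CDR sum of boxes, Boston Naming Test), CSF biomarkers
#' (amyloid-beta 1-42, total tau, phosphorylated tau) and APOE epsilon-4
#' genetics. Each variable carries a definition, data type, value range and
#' modality, plus stored column-name mappings for an ADNI-style study so the
#' fuzzy mapper can demonstrate alias matching.
#'
#' @return a validated [data_model()].
#' @export
builtin_schema <- function() {
  v <- list(
    variable_spec("age", "Age", "Age of the subject at baseline visit, in years.",
                  "demographics", "float", value_range("numeric", 55, 90),
                  ontology_refs = "NCIT:C25150"),
    variable_spec("sex", "Sex", "Biological sex of the subject.",
                  "demographics", "categorical",
                  value_range("enumeration", categories = c("M", "F")),
                  ontology_refs = "NCIT:C28421"),
    variable_spec("education_years", "Education",
                  "Completed years of formal education.",
                  "demographics", "integer", value_range("numeric", 0, 25)),
    variable_spec("diagnosis", "Diagnosis",
                  "Clinical diagnosis at baseline: cognitively normal (CN), mild cognitive impairment (MCI) or Alzheimer's disease (AD).",
                  "diagnostics", "categorical",
                  value_range("enumeration", categories = c("CN", "MCI", "AD")),
                  ontology_refs = "NCIT:C15220"),
    variable_spec("mmse_total", "MMSE total score",
                  "Mini-Mental State Examination total score; lower scores indicate stronger cognitive impairment.",
                  "neuropsychology", "integer", value_range("numeric", 0, 30),
                  ontology_refs = "NCIT:C75186"),
    variable_spec("adas_cog13", "ADAS-Cog 13 total score",
                  "Alzheimer's Disease Assessment Scale cognitive subscale, 13-task version; higher scores indicate stronger impairment.",
                  "neuropsychology", "float", value_range("numeric", 0, 85)),
    variable_spec("cdr_sb", "CDR sum of boxes",
                  "Clinical Dementia Rating scale, sum-of-boxes scoring.",
                  "neuropsychology", "float", value_range("numeric", 0, 18)),
    variable_spec("boston_naming_test", "Boston Naming Test",
                  "Boston Naming Test total of correctly named items (30-item version).",
                  "neuropsychology", "integer", value_range("numeric", 0, 30)),
    variable_spec("csf_abeta42", "CSF amyloid-beta 1-42",
                  "Amyloid-beta 1-42 peptide concentration in cerebrospinal fluid, pg/ml.",
                  "biomarker", "float", value_range("numeric", 200, 2000)),
    variable_spec("csf_tau", "CSF total tau",
                  "Total tau protein concentration in cerebrospinal fluid, pg/ml.",
                  "biomarker", "float", value_range("numeric", 80, 800)),
    variable_spec("csf_ptau", "CSF phosphorylated tau",
                  "Tau phosphorylated at threonine 181 in cerebrospinal fluid, pg/ml.",
                  "biomarker", "float", value_range("numeric", 8, 120)),
    variable_spec("apoe4_alleles", "APOE e4 allele count",
                  "Number of apolipoprotein E epsilon-4 alleles carried (0, 1 or 2).",
                  "genetics", "integer", value_range("numeric", 0, 2))
  )
  m <- data_model(v, name = "dementia-cdm", version = "1.0.0",
                  provenance = "built-in dementia cohort schema")
  adni <- c(age = "AGE", sex = "PTGENDER", education_years = "PTEDUCAT",
            diagnosis = "DX_bl", mmse_total = "MMSE",
            adas_cog13 = "ADAS13", cdr_sb = "CDRSB",
            boston_naming_test = "BNTTOTAL", csf_abeta42 = "ABETA",
            csf_tau = "TAU", csf_ptau = "PTAU", apoe4_alleles = "APOE4")
  for (vid in names(adni)) {
    m <- add_mapping(m, vid, "ADNI", adni[[vid]], method = "manual")
  }
  m
}

# truncated-normal draw clipped into [lo, hi]
rclip <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

#' Generate virtual dementia-cohort patients
#'
#' Draws `n` virtual patients against the built-in schema. A baseline
#' diagnosis (CN/MCI/AD) is drawn first; cognitive scores and CSF biomarkers
#' are then drawn from diagnosis-conditioned normal distributions clipped to
#' the schema's value ranges, reproducing the familiar gradients (MMSE and
#' Boston Naming falling, ADAS-Cog/CDR-SB/tau rising, CSF amyloid-beta
#' falling from CN to AD). Fully deterministic for a fixed `(n, seed)`; the
#' caller's RNG state is untouched.
#'
#' @param n number of patients (`>= 0`).
#' @param schema the [data_model()] to generate against; defaults to
#'   [builtin_schema()]. Generation rules exist for the built-in variables.
#' @param seed integer RNG seed.
#' @return a [raw_table()] (study id `"SYNTH"`, subject column
#'   `"subject_id"`, ids `SYN-0001`, ...), with every cell serialized as a
#'   string ready for [standardize()].
#' @export
generate_patients <- function(n, schema = builtin_schema(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    dst_abort("value", "n must be a non-negative integer")
  }
  n <- as.integer(n)
  local_seed(seed, {
    dx <- sample(c("CN", "MCI", "AD"), n, replace = TRUE,
                 prob = c(0.35, 0.40, 0.25))
    # diagnosis-conditioned distribution parameter lookup
    cond <- function(cn, mci, ad) unname(c(CN = cn, MCI = mci, AD = ad)[dx])
    df <- data.frame(
      subject_id = sprintf("SYN-%04d", seq_len(n)),
      AGE = sprintf("%.1f", rclip(n, 73, 7, 55, 90)),
      PTGENDER = sample(c("M", "F"), n, replace = TRUE),
      PTEDUCAT = sprintf("%d", round(rclip(n, 16, 3, 0, 25))),
      DX_bl = dx,
      MMSE = sprintf("%d", round(rclip(n, cond(29, 27, 21),
                                       cond(1, 2, 4), 0, 30))),
      ADAS13 = sprintf("%.1f", rclip(n, cond(9, 16, 30),
                                     cond(4, 6, 8), 0, 85)),
      CDRSB = sprintf("%.1f", round(rclip(n, cond(0.2, 1.5, 6),
                                          cond(0.3, 1.0, 2.5), 0, 18) * 2) / 2),
      BNTTOTAL = sprintf("%d", round(rclip(n, cond(27, 24, 18),
                                           cond(2, 3, 5), 0, 30))),
      ABETA = sprintf("%.1f", rclip(n, cond(1100, 900, 600),
                                    cond(200, 250, 150), 200, 2000)),
      TAU = sprintf("%.1f", rclip(n, cond(240, 300, 380),
                                  cond(60, 90, 100), 80, 800)),
      PTAU = sprintf("%.1f", rclip(n, cond(21, 27, 35),
                                   cond(6, 9, 10), 8, 120)),
      APOE4 = as.character(vapply(dx, function(d) sample(0:2, 1, prob = switch(d,
        CN = c(0.72, 0.25, 0.03), MCI = c(0.55, 0.38, 0.07),
        AD = c(0.35, 0.47, 0.18))), integer(1))),
      stringsAsFactors = FALSE, check.names = FALSE)
    raw_table(df, study_id = "SYNTH", subject_column = "subject_id")
  })
}

#' Expand a base cohort by duplication
#'
#' Duplicates the base patients row by row (cycling) until the table has
#' `target_n` rows, assigning fresh unique subject ids. With `jitter =
#' FALSE` (the default) every new row is an exact copy of a base row except
#' for the subject id; with `jitter = TRUE`, numeric values are perturbed by
#' seeded Gaussian noise (sd = 2% of the variable's range width) and clipped
#' back into range. If `target_n` equals the base size the base table is
#' returned unchanged, ids included.
#'
#' @param base a [raw_table()] with at least one row.
#' @param target_n desired number of rows (`>=` base rows).
#' @param jitter perturb duplicated numeric values?
#' @param seed integer RNG seed (used only when `jitter = TRUE`).
#' @param schema model supplying data types and ranges for jittering;
#'   defaults to [builtin_schema()].
#' @return a [raw_table()] with exactly `target_n` rows.
#' @export
expand_cohort <- function(base, target_n, jitter = FALSE, seed = 1L,
                          schema = builtin_schema()) {
  nb <- nrow(base$data)
  if (nb < 1L) dst_abort("value", "base cohort is empty")
  if (target_n < nb) {
    dst_abort("value", sprintf("target_n (%d) below base size (%d)",
                               target_n, nb))
  }
  if (target_n == nb) return(base)
  target_n <- as.integer(target_n)
  idx <- rep(seq_len(nb), length.out = target_n)
  df <- base$data[idx, , drop = FALSE]
  width <- max(4L, nchar(as.character(target_n)))
  df[[base$subject_column]] <- sprintf(paste0("SYN-%0", width, "d"),
                                       seq_len(target_n))
  rownames(df) <- NULL
  if (jitter) {
    res <- resolve_columns(raw_table(df, base$study_id, base$subject_column,
                                     base$visit_column),
                           schema, match_config())
    local_seed(seed, {
      for (j in seq_len(nrow(res))) {
        vid <- res$variable_id[j]
        if (is.na(vid)) next
        spec <- get_variable(schema, vid)
        vr <- spec$value_range
        if (!spec$data_type %in% c("integer", "float") ||
            vr$kind != "numeric") next
        col <- res$column[j]
        num <- suppressWarnings(as.numeric(df[[col]]))
        noise <- stats::rnorm(target_n, 0, 0.02 * (vr$max - vr$min))
        out <- pmin(vr$max, pmax(vr$min, num + noise))
        df[[col]] <- ifelse(is.na(num), df[[col]],
                            if (spec$data_type == "integer")
                              sprintf("%d", round(out))
                            else sprintf("%.1f", out))
      }
    })
  }
  raw_table(df, base$study_id, base$subject_column, base$visit_column)
}

#' Write a raw table to CSV
#'
#' The on-disk dialect is identical to what [ingest_table()] reads back.
#'
#' @param raw a [raw_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raw_table <- function(raw, path) {
  utils::write.csv(raw$data, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Synthetic full-scale dementia CDM catalog
#'
#' Programmatically builds a synthetic stand-in for a full-scale dementia
#' clinical data model of a chosen size: the built-in core schema extended
#' with templated neuropsychological item scores, biomarker assays, imaging
#' readouts, diagnostic instruments and genetic markers until the requested
#' variable count is reached. It is synthetic — the generated variables are
#' placeholders, not curated clinical content — but every entry satisfies
#' the full variable-spec invariants, making it a realistic-scale input for
#' catalog loading, search and RDF export.
#'
#' @param n_variables total number of variables (default 277, the scale of a
#'   curated dementia CDM); must be at least the built-in core size.
#' @return a validated [data_model()].
#' @export
synthetic_dementia_cdm <- function(n_variables = 277L) {
  m <- builtin_schema()
  core <- n_variables(m)
  if (n_variables < core) {
    dst_abort("value", sprintf("n_variables must be >= %d", core))
  }
  templates <- list(
    list(prefix = "np_item", label = "Neuropsychological item %d",
         def = "Score on synthetic neuropsychological test item %d.",
         modality = "neuropsychology", type = "integer",
         range = function() value_range("numeric", 0, 10)),
    list(prefix = "csf_assay", label = "CSF assay %d",
         def = "Synthetic cerebrospinal fluid analyte %d concentration, pg/ml.",
         modality = "biomarker", type = "float",
         range = function() value_range("numeric", 0, 1000)),
    list(prefix = "mri_roi", label = "MRI region volume %d",
         def = "Synthetic MRI regional volume %d, cubic millimetres.",
         modality = "imaging", type = "float",
         range = function() value_range("numeric", 0, 20000)),
    list(prefix = "dx_flag", label = "Diagnostic flag %d",
         def = "Synthetic dichotomous diagnostic indicator %d.",
         modality = "diagnostics", type = "boolean",
         range = function() value_range("unconstrained")),
    list(prefix = "snp", label = "Genetic marker %d",
         def = "Synthetic genotyped marker %d, minor allele count.",
         modality = "genetics", type = "integer",
         range = function() value_range("numeric", 0, 2)))
  i <- 0L
  while (n_variables(m) < n_variables) {
    i <- i + 1L
    tpl <- templates[[(i - 1L) %% length(templates) + 1L]]
    m <- add_variable(m, variable_spec(
      sprintf("%s_%03d", tpl$prefix, i), sprintf(tpl$label, i),
      definition = sprintf(tpl$def, i), modality = tpl$modality,
      data_type = tpl$type, value_range = tpl$range()))
  }
  m$metadata$name <- "synthetic-dementia-cdm"
  m$metadata$provenance <- sprintf(
    "synthetic full-scale catalog (%d variables), generated", n_variables)
  m
}
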