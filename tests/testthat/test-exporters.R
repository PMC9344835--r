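test_that("RDF export/import round-trips toy and empty models", {
  for (ext in c(".ttl", ".rdf")) {
    toy <- toy_model()
    path <- withr::local_tempfile(fileext = ext)
    export_model_rdf(toy, path)
    expect_identical(import_model_rdf(path), toy)
    empty <- data_model(name = "empty")
    path2 <- withr::local_tempfile(fileext = ext)
    export_model_rdf(empty, path2)
    back <- import_model_rdf(path2)
    expect_equal(n_variables(back), 0L)
    expect_equal(back$metadata$name, "empty")
  }
})

test_that("RDF round-trip preserves random models in both syntaxes", {
  withr::local_seed(77)
  for (i in 1:8) {
    m <- random_model(n_vars = sample(1:30, 1), n_mappings = sample(0:6, 1))
    for (ext in c(".ttl", ".rdf")) {
      path <- withr::local_tempfile(fileext = ext)
      export_model_rdf(m, path)
      expect_identical(import_model_rdf(path), m)
    }
  }
})

test_that("Turtle output carries the SKOS concept structure", {
  m <- toy_model()
  path <- withr::local_tempfile(fileext = ".ttl")
  export_model_rdf(m, path)
  ttl <- readLines(path)
  expect_length(grep("skos/core#Concept>", ttl, fixed = TRUE), 3)  # 2 vars + 1 modality
  expect_length(grep("ConceptScheme", ttl), 1)
  expect_length(grep("skos/core#broader", ttl), 2)
})

test_that("Turtle output is valid RDF for an independent parser", {
  # rdflib (python) as external oracle for syntax validity and triple count
  m <- builtin_schema()
  path <- withr::local_tempfile(fileext = ".ttl")
  export_model_rdf(m, path)
  out <- suppressWarnings(system2(
    "python",
    c("-c", shQuote(paste0(
      "import rdflib; g = rdflib.Graph(); g.parse('", path,
      "', format='turtle'); print(len(g))"))),
    stdout = TRUE, stderr = TRUE))
  expect_true(is.null(attr(out, "status")) || attr(out, "status") == 0)
  n_own <- length(grep("^<", readLines(path)))
  expect_equal(as.integer(out[length(out)]), n_own)
})

test_that("truncated or foreign RDF files are rejected", {
  m <- toy_model()
  path <- withr::local_tempfile(fileext = ".ttl")
  export_model_rdf(m, path)
  lines <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".ttl")
  writeLines(substr(lines[seq_len(length(lines) - 1)], 1,
                    nchar(lines[seq_len(length(lines) - 1)]) - 3), trunc)
  expect_error(import_model_rdf(trunc), class = "dst_schema")
  foreign <- withr::local_tempfile(fileext = ".ttl")
  writeLines('<http://x/a> <http://x/b> "c" .', foreign)
  expect_error(import_model_rdf(foreign), class = "dst_schema")
  badxml <- withr::local_tempfile(fileext = ".rdf")
  writeLines("<rdf:RDF", badxml)
  expect_error(import_model_rdf(badxml), class = "dst_schema")
})

test_that("FHIR bundles count patients plus ok observations", {
  m <- builtin_schema()
  # empty input -> empty collection bundle
  fx0 <- export_fhir(empty_records_for_test(), m, "SYNTH")
  expect_equal(fx0$bundle$type, "collection")
  expect_length(fx0$bundle$entry, 0)
  raw <- generate_patients(1, m, seed = 5)
  two <- raw_table(raw$data[c("subject_id", "AGE", "PTGENDER")], "SYNTH",
                   "subject_id")
  std <- standardize(two, resolve_columns(two, m), m)
  fx <- export_fhir(std$records, m, "SYNTH")
  # 1 subject with 2 ok records -> 3 entries
  expect_length(fx$bundle$entry, 3)
  expect_equal(fx$n_skipped, 0)
})

test_that("FHIR referential integrity holds on a synthetic cohort", {
  m <- builtin_schema()
  raw <- generate_patients(10, m, seed = 42)
  raw$data$MMSE[3] <- "31"   # one skipped record
  std <- standardize(raw, resolve_columns(raw, m), m)
  fx <- export_fhir(std$records, m, "SYNTH")
  n_ok <- sum(std$records$status == "ok")
  expect_length(fx$bundle$entry, 10 + n_ok)
  expect_equal(fx$n_skipped, nrow(std$records) - n_ok)
  entries <- fx$bundle$entry
  urls <- vapply(entries, `[[`, character(1), "fullUrl")
  expect_false(anyDuplicated(urls) > 0)
  types <- vapply(entries, function(e) e$resource$resourceType, character(1))
  patient_urls <- urls[types == "Patient"]
  refs <- vapply(entries[types == "Observation"],
                 function(e) e$resource$subject$reference, character(1))
  expect_true(all(refs %in% patient_urls))
  # typed values: numeric -> valueQuantity, categorical -> CodeableConcept
  obs <- entries[types == "Observation"]
  codes <- vapply(obs, function(e) e$resource$code$coding[[1]]$code,
                  character(1))
  q <- obs[[which(codes == "age")[1]]]$resource
  expect_true(is.numeric(q$valueQuantity$value))
  cc <- obs[[which(codes == "sex")[1]]]$resource
  expect_false(is.null(cc$valueCodeableConcept))
  # written bundle is valid JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_fhir(fx, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$resourceType, "Bundle")
  expect_length(doc$entry, length(entries))
})

test_that("OMOP export partitions ok records across the three tables", {
  m <- builtin_schema()
  out <- withr::local_tempdir()
  # empty records -> header-only files
  ox0 <- export_omop(empty_records_for_test(), m, out_dir = out)
  for (f in ox0$files) {
    expect_true(file.exists(f))
    expect_equal(nrow(utils::read.csv(f)), 0L)
  }
  # toy partition, hand-enumerated: age+sex+mmse for 2 subjects
  toy <- data_model(list(
    variable_spec("age", "Age", modality = "demographics",
                  data_type = "float",
                  value_range = value_range("numeric", 55, 90)),
    variable_spec("sex", "Sex", modality = "demographics",
                  data_type = "categorical",
                  value_range = value_range("enumeration",
                                            categories = c("M", "F"))),
    variable_spec("mmse_total", "MMSE total score",
                  modality = "neuropsychology", data_type = "integer",
                  value_range = value_range("numeric", 0, 30))))
  df <- data.frame(sid = c("S1", "S2"), Age = c("70.1", "66.0"),
                   Sex = c("M", "F"), `MMSE total score` = c("30", "28"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  raw <- raw_table(df, "S", "sid")
  std <- standardize(raw, resolve_columns(raw, toy), toy)
  ox <- export_omop(std$records, toy, out_dir = out)
  pers <- utils::read.csv(file.path(out, "person.csv"))
  meas <- utils::read.csv(file.path(out, "measurement.csv"))
  obs <- utils::read.csv(file.path(out, "observation.csv"))
  expect_equal(nrow(pers), 2L)                 # one row per subject
  expect_equal(nrow(meas), 2L)                 # the two MMSE records
  expect_equal(meas$measurement_source_value,
               rep("MMSE total score", 2))
  expect_equal(sort(meas$value_as_number), c(28, 30))
  # sex consumed as person attribute (gender concept), age -> observation
  expect_setequal(pers$gender_concept_id, c(8507L, 8532L))
  expect_equal(nrow(obs), 2L)
  expect_equal(ox$counts$ok_records,
               ox$counts$measurement_rows + ox$counts$observation_rows +
                 ox$counts$person_attribute_records)
  # concept_id 0 fallback preserved
  expect_true(all(meas$measurement_concept_id == 0L))
})

test_that("OMOP export reconciles with the validation report on cohorts", {
  m <- builtin_schema()
  raw <- generate_patients(25, m, seed = 12)
  raw$data$TAU[5] <- "junk"
  std <- standardize(raw, resolve_columns(raw, m), m)
  out <- withr::local_tempdir()
  ox <- export_omop(std$records, m, out_dir = out)
  expect_equal(ox$counts$ok_records, unname(std$report$counts["ok"]))
  expect_equal(ox$counts$ok_records,
               ox$counts$measurement_rows + ox$counts$observation_rows +
                 ox$counts$person_attribute_records)
  # unmapped variable in records -> mapping gap
  cm <- default_concept_map(m)
  expect_error(export_omop(std$records, m, cm[cm$variable_id != "age", ],
                           out_dir = out),
               class = "dst_mapping_gap")
})
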