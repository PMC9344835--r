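toy3 <- function() {
  data_model(list(
    variable_spec("age", "Age", data_type = "float",
                  value_range = value_range("numeric", 55, 90)),
    variable_spec("sex", "Sex", data_type = "categorical",
                  value_range = value_range("enumeration",
                                            categories = c("M", "F"))),
    variable_spec("mmse_total", "MMSE total score",
                  modality = "neuropsychology", data_type = "integer",
                  value_range = value_range("numeric", 0, 30))),
    name = "toy3")
}

test_that("ingest_table reads a 2D CSV and rejects malformed input", {
  path <- write_temp_csv(c("subject_id,Age,Sex",
                           "S1,70.5,M",
                           "S2,80.1,F"))
  raw <- ingest_table(path, "STUDY", "subject_id")
  expect_s3_class(raw, "raw_table")
  expect_equal(nrow(raw$data), 2L)
  expect_error(ingest_table(path, "STUDY", "patient"), class = "dst_schema")
  ragged <- write_temp_csv(c("subject_id,Age,Sex", "S1,70.5,M", "S2,80.1"))
  err <- expect_error(ingest_table(ragged, "S", "subject_id"),
                      class = "dst_schema")
  expect_match(conditionMessage(err), "line 3")
  dup <- write_temp_csv(c("subject_id,Age,Age", "S1,1,2"))
  expect_error(ingest_table(dup, "S", "subject_id"), class = "dst_schema")
})

test_that("resolve_columns composes fuzzy decisions with manual overrides", {
  m <- toy3()
  path <- write_temp_csv(c("subject_id,Age,PTGENDER,MMSE total score",
                           "S1,70.5,M,30"))
  raw <- ingest_table(path, "STUDY", "subject_id")
  res <- resolve_columns(raw, m)
  # exact labels auto-resolve; PTGENDER does not reach the auto threshold
  expect_equal(res$variable_id[res$column == "Age"], "age")
  expect_equal(res$origin[res$column == "Age"], "auto")
  expect_true(is.na(res$variable_id[res$column == "PTGENDER"]))
  res2 <- resolve_columns(raw, m, manual_overrides = c(PTGENDER = "sex"))
  expect_equal(res2$variable_id[res2$column == "PTGENDER"], "sex")
  expect_equal(res2$origin[res2$column == "PTGENDER"], "manual")
  expect_error(resolve_columns(raw, m, manual_overrides = c(PTGENDER = "zz")),
               class = "dst_unknown_variable")
  # subject column never appears among resolution targets
  expect_false("subject_id" %in% res$column)
})

test_that("column-wise resolution equals applying suggest_mappings", {
  m <- builtin_schema()
  cfg <- match_config()
  withr::local_seed(55)
  cols <- c("MMSE", "random_junk_col", "ADAS13", "age", "xyz_q")
  df <- as.data.frame(setNames(rep(list("1"), length(cols) + 1),
                               c("sid", cols)), check.names = FALSE)
  raw <- raw_table(df, "S", "sid")
  res <- resolve_columns(raw, m, cfg)
  sugg <- suggest_mappings(cols, m, cfg)
  for (cn in cols) {
    top <- sugg[sugg$source_label == cn & sugg$rank == 1, ]
    expected <- if (top$decision == "auto") top$variable_id else NA_character_
    expect_equal(res$variable_id[res$column == cn], expected, label = cn)
  }
})

test_that("standardize coerces, flags and conserves counts", {
  m <- toy3()
  path <- write_temp_csv(c(
    "subject_id,Age,Sex,MMSE total score",
    "S1,70.5,m,27",       # lowercase category -> canonical M
    "S2,91,F,31",         # age out of range; mmse 31 > 30
    "S3,NA,female,abc",   # missing; type_error (not in enum); type_error
    "S4,60.0,F,30"))      # boundary mmse = 30 is in range
  raw <- ingest_table(path, "STUDY", "subject_id")
  res <- resolve_columns(raw, m)
  std <- standardize(raw, res, m)
  expect_equal(nrow(std$records), 4 * 3)
  expect_equal(sum(std$report$counts), 12L)
  expect_equal(std$report$counts,
               c(ok = 7L, missing = 1L, out_of_range = 2L, type_error = 2L))
  # canonical casing of categorical values
  s1sex <- std$records[std$records$subject_id == "S1" &
                       std$records$variable_id == "sex", ]
  expect_identical(s1sex$value[[1]], "M")
  expect_identical(s1sex$raw_value, "m")
  # typed values: integer stays integer, float double
  s4 <- std$records[std$records$subject_id == "S4", ]
  expect_identical(s4$value[[which(s4$variable_id == "mmse_total")]], 30L)
  expect_identical(s4$value[[which(s4$variable_id == "age")]], 60.0)
  # flagged records carry no value
  expect_true(all(vapply(
    std$records$value[std$records$status != "ok"], is.null, logical(1))))
  # issue list localizes the bad cells
  expect_setequal(std$report$issues$reason,
                  c("out_of_range", "type_error"))
  expect_true(all(std$report$issues$row %in% c(2L, 3L)))
  # strict mode raises and carries the report
  err <- expect_error(standardize(raw, res, m, strict = TRUE),
                      class = "dst_validation_failure")
  expect_s3_class(err$report, "validation_report")
})

test_that("boolean and date coercion follow the documented rules", {
  m <- data_model(list(
    variable_spec("carrier", "Carrier flag", data_type = "boolean"),
    variable_spec("visit_date", "Visit date", data_type = "date")))
  df <- data.frame(sid = sprintf("S%d", 1:6),
                   `Carrier flag` = c("TRUE", "Yes", "0", "nope", "1", "NA"),
                   `Visit date` = c("2020-01-31", "2020-13-01", "31/01/2020",
                                    "2020-02-30", "2021-12-01", ""),
                   check.names = FALSE, stringsAsFactors = FALSE)
  raw <- raw_table(df, "S", "sid")
  std <- standardize(raw, resolve_columns(raw, m), m)
  rec <- function(sid, vid)
    std$records[std$records$subject_id == sid &
                std$records$variable_id == vid, ]
  expect_identical(rec("S1", "carrier")$value[[1]], TRUE)
  expect_identical(rec("S2", "carrier")$value[[1]], TRUE)
  expect_identical(rec("S3", "carrier")$value[[1]], FALSE)
  expect_equal(rec("S4", "carrier")$status, "type_error")
  expect_equal(rec("S6", "carrier")$status, "missing")
  expect_identical(rec("S1", "visit_date")$value[[1]], "2020-01-31")
  expect_equal(rec("S2", "visit_date")$status, "type_error")  # month 13
  expect_equal(rec("S3", "visit_date")$status, "type_error")  # wrong format
  expect_equal(rec("S4", "visit_date")$status, "type_error")  # Feb 30
  expect_equal(rec("S6", "visit_date")$status, "missing")
})

test_that("conservation and validity hold on random generated tables", {
  m <- builtin_schema()
  withr::local_seed(66)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    raw <- generate_patients(n, m, seed = sample(1e6, 1))
    # corrupt a few cells
    n_bad <- sample(0:3, 1)
    for (b in seq_len(n_bad)) {
      raw$data$MMSE[sample(n, 1)] <- "999"
    }
    res <- resolve_columns(raw, m)
    std <- standardize(raw, res, m)
    expect_equal(nrow(std$records), n * sum(!is.na(res$variable_id)))
    expect_equal(sum(std$report$counts), nrow(std$records))
    # every ok numeric value within range, every ok categorical in enum
    for (j in seq_len(nrow(std$records))) {
      if (std$records$status[j] != "ok") next
      spec <- get_variable(m, std$records$variable_id[j])
      v <- std$records$value[[j]]
      if (spec$value_range$kind == "numeric") {
        expect_gte(v, spec$value_range$min)
        expect_lte(v, spec$value_range$max)
      } else if (spec$value_range$kind == "enumeration") {
        expect_true(v %in% spec$value_range$categories)
      }
    }
  }
})

test_that("standardize is deterministic", {
  m <- builtin_schema()
  raw <- generate_patients(20, m, seed = 9)
  res <- resolve_columns(raw, m)
  a <- standardize(raw, res, m)
  b <- standardize(raw, res, m)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(a$report, p1)
  write_report_json(b$report, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical report
})

test_that("repository stores idempotently and queries by conjunction", {
  m <- builtin_schema()
  raw <- generate_patients(8, m, seed = 3)
  std <- standardize(raw, resolve_columns(raw, m), m)
  repo <- harmonized_repo(m)
  repo_store(repo, std$records)
  n0 <- nrow(repo$records)
  repo_store(repo, std$records)            # idempotent
  expect_equal(nrow(repo$records), n0)
  expect_equal(nrow(repo_query(repo)), n0) # empty filter set -> everything
  expect_equal(nrow(repo_query(repo, study_id = "SYNTH")), n0)
  expect_equal(nrow(repo_query(repo, study_id = "OTHER")), 0L)
  one <- repo_query(repo, subject_id = "SYN-0001", variable_id = "mmse_total")
  expect_equal(nrow(one), 1L)
  expect_error(repo_query(repo, variable_id = "bogus"),
               class = "dst_unknown_variable")
  # modality filter equals a brute-force filter over variable specs
  got <- repo_query(repo, modality = "neuropsychology")
  np_vars <- names(Filter(function(v) v$modality == "neuropsychology",
                          m$variables))
  expect_setequal(unique(got$variable_id), np_vars)
  expect_equal(nrow(got), sum(repo$records$variable_id %in% np_vars))
})

test_that("repository persists as NDJSON and reloads identically", {
  m <- builtin_schema()
  raw <- generate_patients(5, m, seed = 4)
  raw$data$AGE[2] <- "17"    # one out-of-range record in the mix
  std <- standardize(raw, resolve_columns(raw, m), m)
  path <- withr::local_tempfile(fileext = ".ndjson")
  repo <- harmonized_repo(m, path = path)
  repo_store(repo, std$records)
  reloaded <- harmonized_repo(m, path = path)
  expect_identical(reloaded$records, repo$records)
  expect_identical(read_records_ndjson(path), std$records)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(std$records, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(std$records))
})
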