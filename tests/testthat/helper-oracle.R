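# Independent brute-force oracles, deliberately naive: everything here is
# plain dynamic programming / exhaustive scanning, sharing no code with the
# package implementation.

# classic Wagner-Fischer edit distance, O(nm) table
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

oracle_normalize <- function(s) {
  trimws(gsub("[^a-z0-9]+", " ", tolower(s), perl = TRUE))
}

oracle_ratio <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  1 - dp_levenshtein(a, b) / max(na, nb)
}

# the full similarity contract, recomputed from first principles
oracle_similarity <- function(a, b) {
  a <- oracle_normalize(a)
  b <- oracle_normalize(b)
  srt <- function(s) paste(sort(strsplit(s, " ", fixed = TRUE)[[1]]),
                           collapse = " ")
  max(oracle_ratio(a, b), oracle_ratio(srt(a), srt(b)))
}

random_label <- function(len_max = 12L) {
  alphabet <- c(letters[1:5], " ", "_")
  n <- sample(0:len_max, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random but always-valid model for round-trip property tests
random_model <- function(n_vars = 8L, n_mappings = 3L) {
  types <- c("integer", "float", "categorical", "boolean", "date", "string")
  vars <- lapply(seq_len(n_vars), function(i) {
    ty <- sample(types, 1)
    vr <- if (ty == "categorical") {
      value_range("enumeration",
                  categories = paste0("cat", sample(100, sample(2:5, 1))))
    } else if (ty %in% c("integer", "float") && stats::runif(1) < 0.7) {
      lo <- round(stats::runif(1, -50, 50), 2)
      value_range("numeric", lo, lo + round(stats::runif(1, 0, 100), 2))
    } else {
      value_range("unconstrained")
    }
    variable_spec(
      sprintf("var_%03d_%s", i, paste(sample(letters, 4), collapse = "")),
      label = paste(sample(c("score", "level", "total", "index", "value",
                             "test", "memory", "fluid", "scan"),
                           sample(2:3, 1)), collapse = " "),
      definition = if (stats::runif(1) < 0.8)
        paste("Synthetic definition", i) else "",
      modality = sample(c("demographics", "diagnostics", "neuropsychology",
                          "biomarker", "genetics", "imaging", "other"), 1),
      data_type = ty, value_range = vr,
      ontology_refs = if (stats::runif(1) < 0.5)
        sprintf("NCIT:C%d", sample(99999, sample(1:2, 1))) else character())
  })
  m <- data_model(vars, name = paste0("random-", sample(1e6, 1)),
                  version = "0.0.1", provenance = "random test model")
  ids <- variable_ids(m)
  for (k in seq_len(min(n_mappings, n_vars))) {
    m <- add_mapping(m, sample(ids, 1), paste0("STUDY", sample(3, 1)),
                     paste0("COL", k, "_", sample(1e6, 1)),
                     method = sample(c("auto", "manual", "ontology"), 1),
                     score = if (stats::runif(1) < 0.5) NA_real_
                             else round(stats::runif(1), 3))
  }
  m
}

toy_model <- function() {
  data_model(list(
    variable_spec("age", "Age", "Age in years at baseline.",
                  "demographics", "float", value_range("numeric", 55, 90)),
    variable_spec("sex", "Sex", "Biological sex.",
                  "demographics", "categorical",
                  value_range("enumeration", categories = c("M", "F")))),
    name = "toy", version = "0.1.0")
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

VAR_CSV_COLUMNS_FOR_TEST <- c("variable_id", "label", "definition",
                              "modality", "data_type", "range_kind", "min",
                              "max", "categories", "ontology_refs")

# zero-row harmonized record set with the right columns and classes
empty_records_for_test <- function() {
  m <- toy_model()
  df <- data.frame(sid = character(), Age = character(),
                   stringsAsFactors = FALSE)
  raw <- raw_table(df, "S", "sid")
  standardize(raw, resolve_columns(raw, m), m)$records
}
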