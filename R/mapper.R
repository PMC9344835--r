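#' Normalize a variable label for matching
#'
#' Lowercases, replaces every run of non-alphanumeric characters (anything
#' outside `a-z0-9`, including unicode letters) by a single space and trims.
#' Idempotent: `normalize_label(normalize_label(s)) == normalize_label(s)`.
#'
#' @param s character vector.
#' @return normalized character vector.
#' @examples
#' normalize_label("MMSE_Total ")       # "mmse total"
#' normalize_label("Aβ-42 (CSF)")  # "a 42 csf"
#' @export
normalize_label <- function(s) {
  s <- tolower(as.character(s))
  s <- gsub("[^a-z0-9]+", " ", s, perl = TRUE)
  trimws(s)
}

# Levenshtein similarity ratio: 1 - d/max(nchar); both empty -> 1, one -> 0.
# Vectorized over b for one a (used by the ranking operations).
lev_ratio <- function(a, b) {
  na <- nchar(a)
  nb <- nchar(b)
  d <- as.numeric(utils::adist(a, b))
  r <- 1 - d / pmax(na, nb)
  r[na == 0 & nb == 0] <- 1
  r[xor(na == 0, nb == 0)] <- 0
  r
}

token_sort <- function(s) {
  vapply(strsplit(s, " ", fixed = TRUE), function(tk)
    paste(sort(tk), collapse = " "), character(1))
}

#' Fuzzy similarity of two labels
#'
#' The matching score used throughout the package: both strings are
#' normalized ([normalize_label()]), then scored as the maximum of
#' (a) the Levenshtein ratio `1 - editdistance / max(length)` and
#' (b) the same ratio after sorting whitespace tokens alphabetically
#' (token-sort ratio), so word order does not matter.
#' Symmetric; two empty strings score 1, exactly one empty string scores 0.
#'
#' @param a,b character vectors (recycled to common length).
#' @return numeric vector of scores in `[0, 1]`.
#' @examples
#' similarity("boston naming test", "Naming Test, Boston")  # 1
#' similarity("mmse", "mmse total")
#' @export
similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(normalize_label(a), n)
  b <- rep_len(normalize_label(b), n)
  plain <- mapply(lev_ratio, a, b, USE.NAMES = FALSE)
  sorted <- mapply(lev_ratio, token_sort(a), token_sort(b), USE.NAMES = FALSE)
  as.numeric(pmax(plain, sorted))
}

# similarity of one query against many candidates (pre-normalized inputs
# avoided on the hot path of suggest_mappings/search)
similarity_one_many <- function(query, candidates) {
  q <- normalize_label(query)
  cands <- normalize_label(candidates)
  pmax(lev_ratio(q, cands), lev_ratio(token_sort(q), token_sort(cands)))
}

#' Matching configuration
#'
#' Thresholds steering the semi-automatic mapping decisions: a candidate at
#' or above `auto_threshold` is accepted automatically; one in
#' `[review_threshold, auto_threshold)` is flagged for manual review; below
#' `review_threshold` the source label is considered unmapped.
#'
#' @param auto_threshold score in `[0,1]` above which a match is auto-accepted.
#' @param review_threshold score in `[0,1]` above which a match is proposed
#'   for review; must be `<= auto_threshold`.
#' @param k number of candidates to return per source label.
#' @return an object of class `match_config`.
#' @export
match_config <- function(auto_threshold = 0.95, review_threshold = 0.70,
                         k = 5L) {
  if (!is.numeric(auto_threshold) || auto_threshold < 0 || auto_threshold > 1 ||
      !is.numeric(review_threshold) || review_threshold < 0 ||
      review_threshold > 1) {
    dst_abort("schema", "thresholds must lie in [0,1]")
  }
  if (review_threshold > auto_threshold) {
    dst_abort("schema", "review_threshold must not exceed auto_threshold")
  }
  if (!is.numeric(k) || k < 1) dst_abort("schema", "k must be >= 1")
  structure(list(auto_threshold = auto_threshold,
                 review_threshold = review_threshold, k = as.integer(k)),
            class = "match_config")
}

#' Suggest CDM mappings for study column names
#'
#' For every source label, each CDM variable is scored as the maximum
#' [similarity()] of the label against the variable's canonical label and
#' against every source label already mapped to it (its aliases). The
#' top `k` candidates per source label are returned, ranked by descending
#' score with ties broken by `variable_id`. The decision column applies the
#' [match_config()] thresholds: if the best candidate reaches
#' `auto_threshold` it is `"auto"`; if the best reaches only
#' `review_threshold` the candidates are `"review"`; if even the best falls
#' below `review_threshold` all candidates are `"unmapped"`.
#'
#' @param source_labels character vector of study column names.
#' @param model a [data_model()].
#' @param config a [match_config()].
#' @return data.frame with columns `source_label`, `variable_id`, `score`,
#'   `decision`, `rank`.
#' @export
suggest_mappings <- function(source_labels, model, config = match_config()) {
  empty <- data.frame(source_label = character(), variable_id = character(),
                      score = numeric(), decision = character(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (length(source_labels) == 0L || n_variables(model) == 0L) return(empty)
  ids <- variable_ids(model)
  # candidate strings per variable: canonical label + stored aliases
  cand_ids <- ids
  cand_strings <- vapply(model$variables, `[[`, character(1), "label")
  mp <- model$mappings
  if (nrow(mp)) {
    cand_ids <- c(cand_ids, mp$cdm_variable_id)
    cand_strings <- c(cand_strings, mp$source_label)
  }
  out <- lapply(source_labels, function(lbl) {
    sc <- similarity_one_many(lbl, cand_strings)
    best_per_var <- vapply(split(sc, cand_ids), max, numeric(1))
    best_per_var <- best_per_var[order(-best_per_var, names(best_per_var))]
    k <- min(config$k, length(best_per_var))
    top <- best_per_var[seq_len(k)]
    best <- top[1]
    decision <- if (best < config$review_threshold) {
      rep("unmapped", k)
    } else {
      ifelse(top >= config$auto_threshold, "auto", "review")
    }
    data.frame(source_label = lbl, variable_id = names(top),
               score = as.numeric(top), decision = decision,
               rank = seq_len(k), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
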