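#' Load an offline ontology-term catalog
#'
#' The term catalog is the offline stand-in for an ontology lookup service:
#' a CSV with columns `curie`, `label`, `ontology` (e.g.
#' `NCIT:C74985,Mini Mental State Examination,ncit`). A small demonstration
#' catalog ships in `inst/extdata/term_catalog_demo.csv`.
#'
#' @param path CSV file with columns curie, label, ontology.
#' @return data.frame of class `term_catalog`.
#' @export
load_term_catalog <- function(path) {
  if (!file.exists(path)) {
    dst_abort("catalog_unavailable", paste("no term catalog at", path))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(c("curie", "label", "ontology"), names(tab))
  if (length(missing_cols)) {
    dst_abort("schema", paste("term catalog missing columns:",
                              paste(missing_cols, collapse = ", ")))
  }
  bad <- tab$curie[!grepl("^[A-Za-z0-9_.]+:\\S+$", tab$curie)]
  if (length(bad)) {
    dst_abort("schema", paste("malformed CURIE(s) in catalog:",
                              paste(utils::head(bad, 3), collapse = ", ")))
  }
  structure(tab[c("curie", "label", "ontology")],
            class = c("term_catalog", "data.frame"))
}

#' Autosuggest ontology terms for a label
#'
#' Ranks the catalog terms by [similarity()] between the query label and the
#' term label, returning the top `k`. Ties are broken deterministically by
#' CURIE. Used when a study column cannot be mapped to any existing CDM
#' variable and a new, ontology-anchored variable should be created instead.
#'
#' @param label study column name or free-text query.
#' @param catalog a `term_catalog` from [load_term_catalog()] (or any data
#'   frame with curie/label/ontology columns).
#' @param k number of suggestions; `k = 0` returns an empty result.
#' @return data.frame with columns `curie`, `label`, `ontology`, `score`,
#'   ranked by descending score.
#' @export
lookup_terms <- function(label, catalog, k = 5L) {
  if (is.null(catalog) || nrow(catalog) == 0L) {
    dst_abort("catalog_unavailable", "ontology term catalog is empty")
  }
  k <- as.integer(k)
  out <- data.frame(curie = catalog$curie, label = catalog$label,
                    ontology = catalog$ontology,
                    score = similarity_one_many(label, catalog$label),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$curie), , drop = FALSE]
  out <- utils::head(out, max(k, 0L))
  rownames(out) <- NULL
  out
}
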