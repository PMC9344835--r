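#' Full-text search across the data model
#'
#' Scores the query against each variable's label, definition and the source
#' labels already mapped to it, using the package's fuzzy [similarity()]
#' plus an exact-substring bonus (+0.25, capped at 1) when the normalized
#' query occurs verbatim inside the normalized field — that is what turns
#' the catalog into a searchable variable index: a single word occurring in
#' one definition will surface that variable. Results are ranked by
#' descending score, ties broken lexicographically by `variable_id`, so
#' repeated queries return identical rankings.
#'
#' @param model a [data_model()].
#' @param query search string (non-empty after trimming).
#' @param k maximum number of hits (`>= 1`).
#' @return data.frame with columns `variable_id`, `score`, `matched_field`
#'   (one of `"label"`, `"definition"`, `"source_label"`).
#' @export
search_model <- function(model, query, k = 10L) {
  if (!is_string(query) || !nzchar(trimws(query))) {
    dst_abort("empty_query", "search query is empty")
  }
  if (!is.numeric(k) || k < 1) dst_abort("schema", "k must be >= 1")
  if (n_variables(model) == 0L) {
    return(data.frame(variable_id = character(), score = numeric(),
                      matched_field = character(), stringsAsFactors = FALSE))
  }
  nq <- normalize_label(query)
  score_field <- function(field_text) {
    s <- similarity_one_many(query, field_text)
    nf <- normalize_label(field_text)
    bonus <- nzchar(nq) & vapply(nf, function(f)
      grepl(nq, f, fixed = TRUE), logical(1), USE.NAMES = FALSE)
    pmin(1, s + 0.25 * bonus)
  }
  rows <- lapply(model$variables, function(v) {
    fields <- c(label = v$label, definition = v$definition)
    aliases <- variable_aliases(model, v$variable_id)
    scores <- c(score_field(fields),
                if (length(aliases)) max(score_field(aliases)) else NULL)
    names(scores) <- c("label", "definition",
                       if (length(aliases)) "source_label")
    best <- which.max(scores)
    data.frame(variable_id = v$variable_id, score = as.numeric(scores[best]),
               matched_field = names(scores)[best], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$variable_id), , drop = FALSE]
  res <- utils::head(res, min(as.integer(k), nrow(res)))
  rownames(res) <- NULL
  res
}

#' Graph projection of a data model
#'
#' Projects the model onto a layered graph for exploration: one node per
#' modality in use, per variable and per distinct (study, source label)
#' pair; edges run modality -> variable and variable -> source label. There
#' are never variable -> variable edges.
#'
#' @param model a [data_model()].
#' @return list of class `cdm_graph` with data.frames `nodes` (`id`, `kind`,
#'   `label`) and `edges` (`from`, `to`, `kind`).
#' @seealso [write_graph_json()], [write_graphml()]
#' @export
to_graph <- function(model) {
  pre <- function(prefix, x) if (length(x)) paste0(prefix, x) else character()
  vars <- model$variables
  modality <- vapply(vars, `[[`, character(1), "modality")
  mods <- sort(unique(modality))
  var_ids <- names(vars)
  mp <- model$mappings
  src_key <- if (nrow(mp)) paste(mp$study_id, mp$source_label, sep = "/")
             else character()
  keep <- !duplicated(src_key)
  nodes <- rbind(
    data.frame(id = pre("modality:", mods),
               kind = rep("modality", length(mods)),
               label = mods, stringsAsFactors = FALSE),
    data.frame(id = pre("variable:", var_ids),
               kind = rep("variable", length(var_ids)),
               label = vapply(vars, `[[`, character(1), "label"),
               stringsAsFactors = FALSE),
    data.frame(id = pre("source:", src_key[keep]),
               kind = rep("source_label", sum(keep)),
               label = mp$source_label[keep], stringsAsFactors = FALSE))
  edges <- rbind(
    data.frame(from = pre("modality:", modality),
               to = pre("variable:", var_ids),
               kind = rep("has_variable", length(var_ids)),
               stringsAsFactors = FALSE),
    data.frame(from = pre("variable:", mp$cdm_variable_id),
               to = pre("source:", src_key),
               kind = rep("mapped_from", nrow(mp)),
               stringsAsFactors = FALSE))
  edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cdm_graph")
}

#' @export
print.cdm_graph <- function(x, ...) {
  cat(sprintf("<cdm_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a model graph as node-link JSON
#'
#' @param graph a [to_graph()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(list(nodes = graph$nodes, links = graph$edges), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}

#' Write a model graph as GraphML
#'
#' @param graph a [to_graph()] result.
#' @param path output file (.graphml).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(
    graph$edges[c("from", "to", "kind")], directed = TRUE,
    vertices = graph$nodes[c("id", "kind", "label")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
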