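CDM_BASE <- "https://w3id.org/cdmsteward/"
SKOS <- "http://www.w3.org/2004/02/skos/core#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
XSD <- "http://www.w3.org/2001/XMLSchema#"
IDENTIFIERS <- "https://identifiers.org/"

cdm_uri <- function(...) paste0(CDM_BASE, ...)

# ---- model <-> triples ----------------------------------------------------

# One triple per row. type: "iri" or "literal"; dt: datatype IRI or NA
triple <- function(s, p, o, type = "literal", dt = NA_character_) {
  data.frame(s = s, p = p, o = as.character(o), type = type, dt = dt,
             stringsAsFactors = FALSE)
}

model_to_triples <- function(model) {
  scheme <- cdm_uri("scheme")
  tr <- list(
    triple(scheme, paste0(RDF_NS, "type"), paste0(SKOS, "ConceptScheme"),
           "iri"),
    triple(scheme, cdm_uri("name"), model$metadata$name),
    triple(scheme, cdm_uri("version"), model$metadata$version))
  if (nzchar(model$metadata$provenance)) {
    tr <- c(tr, list(triple(scheme, cdm_uri("provenance"),
                            model$metadata$provenance)))
  }
  mods <- unique(vapply(model$variables, `[[`, character(1), "modality"))
  for (m in sort(mods)) {
    mu <- cdm_uri("modality/", m)
    tr <- c(tr, list(
      triple(mu, paste0(RDF_NS, "type"), paste0(SKOS, "Concept"), "iri"),
      triple(mu, paste0(SKOS, "topConceptOf"), scheme, "iri"),
      triple(mu, paste0(SKOS, "prefLabel"), m)))
  }
  dbl <- paste0(XSD, "double")
  for (v in model$variables) {
    vu <- cdm_uri("variable/", v$variable_id)
    vr <- v$value_range
    tr <- c(tr, list(
      triple(vu, paste0(RDF_NS, "type"), paste0(SKOS, "Concept"), "iri"),
      triple(vu, paste0(SKOS, "inScheme"), scheme, "iri"),
      triple(vu, paste0(SKOS, "notation"), v$variable_id),
      triple(vu, paste0(SKOS, "prefLabel"), v$label),
      triple(vu, paste0(SKOS, "broader"), cdm_uri("modality/", v$modality),
             "iri"),
      triple(vu, cdm_uri("dataType"), v$data_type),
      triple(vu, cdm_uri("rangeKind"), vr$kind)))
    if (nzchar(v$definition)) {
      tr <- c(tr, list(triple(vu, paste0(SKOS, "definition"), v$definition)))
    }
    if (vr$kind == "numeric") {
      # full double precision so ranges survive the text round-trip
      tr <- c(tr, list(
        triple(vu, cdm_uri("rangeMin"), sprintf("%.17g", vr$min), dt = dbl),
        triple(vu, cdm_uri("rangeMax"), sprintf("%.17g", vr$max), dt = dbl)))
    }
    for (cat in vr$categories %||% character()) {
      tr <- c(tr, list(triple(vu, cdm_uri("category"), cat)))
    }
    for (ref in v$ontology_refs) {
      tr <- c(tr, list(triple(vu, paste0(SKOS, "exactMatch"),
                              paste0(IDENTIFIERS, ref), "iri")))
    }
  }
  # mappings as annotation triples on the variable concept
  mp <- model$mappings
  for (i in seq_len(nrow(mp))) {
    vu <- cdm_uri("variable/", mp$cdm_variable_id[i])
    # "i" keeps the catalog's mapping order stable across serializations
    enc <- jsonlite::toJSON(list(i = i, study_id = mp$study_id[i],
                                 source_label = mp$source_label[i],
                                 method = mp$method[i],
                                 score = mp$score[i]),
                            auto_unbox = TRUE, digits = NA, null = "null",
                            na = "null")
    tr <- c(tr, list(triple(vu, cdm_uri("mapping"), as.character(enc))))
  }
  out <- do.call(rbind, tr)
  rownames(out) <- NULL
  out
}

triples_to_model <- function(tr) {
  if (is.null(tr) || nrow(tr) == 0L) {
    dst_abort("schema", "no triples found in RDF document")
  }
  known_ns <- c(CDM_BASE, SKOS, RDF_NS)
  if (!any(startsWith(tr$p, CDM_BASE) | startsWith(tr$p, SKOS))) {
    dst_abort("schema", "document does not use the CDM vocabulary")
  }
  scheme <- cdm_uri("scheme")
  pick <- function(s, p) {
    o <- tr$o[tr$s == s & tr$p == p]
    if (length(o)) o[1] else NULL
  }
  pick_all <- function(s, p) tr$o[tr$s == s & tr$p == p]
  var_uris <- unique(tr$s[tr$p == paste0(SKOS, "inScheme") &
                          tr$o == scheme])
  # preserve catalog order via the notation triple order in the document
  notation_order <- tr$s[tr$p == paste0(SKOS, "notation")]
  var_uris <- notation_order[notation_order %in% var_uris]
  vars <- lapply(var_uris, function(vu) {
    vid <- pick(vu, paste0(SKOS, "notation"))
    kind <- pick(vu, cdm_uri("rangeKind")) %||% "unconstrained"
    vr <- switch(kind,
      numeric = value_range("numeric",
                            min = as.numeric(pick(vu, cdm_uri("rangeMin"))),
                            max = as.numeric(pick(vu, cdm_uri("rangeMax")))),
      enumeration = value_range("enumeration",
                                categories = pick_all(vu, cdm_uri("category"))),
      unconstrained = value_range("unconstrained"),
      dst_abort("schema", paste("unknown rangeKind:", kind)))
    broader <- pick(vu, paste0(SKOS, "broader"))
    refs <- pick_all(vu, paste0(SKOS, "exactMatch"))
    variable_spec(
      vid, pick(vu, paste0(SKOS, "prefLabel")) %||% vid,
      definition = pick(vu, paste0(SKOS, "definition")) %||% "",
      modality = if (is.null(broader)) "other" else
        sub(paste0("^", cdm_uri("modality/")), "", broader),
      data_type = pick(vu, cdm_uri("dataType")) %||% "string",
      value_range = vr,
      ontology_refs = sub(paste0("^", IDENTIFIERS), "", refs))
  })
  map_json <- tr[tr$p == cdm_uri("mapping"), , drop = FALSE]
  mappings <- if (nrow(map_json)) {
    rows <- do.call(rbind, lapply(seq_len(nrow(map_json)), function(i) {
      m <- jsonlite::fromJSON(map_json$o[i])
      data.frame(ord = as.integer(m$i %||% i),
                 cdm_variable_id = sub(paste0("^", cdm_uri("variable/")), "",
                                       map_json$s[i]),
                 study_id = m$study_id, source_label = m$source_label,
                 method = m$method, score = as.numeric(m$score %||% NA_real_),
                 stringsAsFactors = FALSE)
    }))
    rows <- rows[order(rows$ord), names(rows) != "ord", drop = FALSE]
    rownames(rows) <- NULL
    rows
  } else empty_mappings()
  build_model(vars, mappings,
              list(name = pick(scheme, cdm_uri("name")),
                   version = pick(scheme, cdm_uri("version")),
                   provenance = pick(scheme, cdm_uri("provenance")) %||% ""))
}

# ---- Turtle serialization -------------------------------------------------

escape_literal <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s
}

unescape_literal <- function(s) {
  out <- character(length(s))
  for (i in seq_along(s)) {
    x <- s[i]
    res <- ""
    j <- 1L
    chars <- strsplit(x, "")[[1]]
    while (j <= length(chars)) {
      ch <- chars[j]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        res <- paste0(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                                  "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        res <- paste0(res, ch)
        j <- j + 1L
      }
    }
    out[i] <- res
  }
  out
}

format_object <- function(o, type, dt) {
  if (type == "iri") return(paste0("<", o, ">"))
  lit <- paste0("\"", escape_literal(o), "\"")
  if (!is.na(dt)) lit <- paste0(lit, "^^<", dt, ">")
  lit
}

write_turtle <- function(triples, path) {
  lines <- c(
    paste0("@prefix skos: <", SKOS, "> ."),
    paste0("@prefix cdm: <", CDM_BASE, "> ."),
    "",
    sprintf("<%s> <%s> %s .", triples$s, triples$p,
            mapply(format_object, triples$o, triples$type, triples$dt,
                   USE.NAMES = FALSE)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

TTL_TRIPLE_RE <- paste0(
  "^<([^>]*)>\\s+<([^>]*)>\\s+",
  "(?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^<([^>]*)>)?)",
  "\\s+\\.\\s*$")

read_turtle <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@prefix") &
                 !startsWith(lines, "#")]
  if (!length(lines)) dst_abort("schema", "empty or truncated RDF document")
  m <- regmatches(lines, regexec(TTL_TRIPLE_RE, lines, perl = TRUE))
  bad <- which(vapply(m, length, integer(1)) == 0L)
  if (length(bad)) {
    dst_abort("schema", sprintf("malformed Turtle statement at line %d: %s",
                                bad[1], substr(lines[bad[1]], 1, 60)))
  }
  rows <- lapply(m, function(g) {
    is_iri <- nzchar(g[4])
    triple(g[2], g[3],
           if (is_iri) g[4] else unescape_literal(g[5]),
           type = if (is_iri) "iri" else "literal",
           dt = if (!is_iri && nzchar(g[6])) g[6] else NA_character_)
  })
  do.call(rbind, rows)
}

# ---- RDF/XML serialization ------------------------------------------------

write_rdfxml <- function(triples, path) {
  doc <- xml2::xml_new_root("rdf:RDF",
    "xmlns:rdf" = RDF_NS, "xmlns:skos" = SKOS, "xmlns:cdm" = CDM_BASE)
  split_prop <- function(p) {
    if (startsWith(p, SKOS)) paste0("skos:", sub(SKOS, "", p, fixed = TRUE))
    else if (startsWith(p, RDF_NS)) paste0("rdf:", sub(RDF_NS, "", p,
                                                       fixed = TRUE))
    else if (startsWith(p, CDM_BASE)) paste0("cdm:", sub(CDM_BASE, "", p,
                                                         fixed = TRUE))
    else dst_abort("schema", paste("cannot serialize property", p))
  }
  for (s in unique(triples$s)) {
    desc <- xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = s)
    sub_tr <- triples[triples$s == s, , drop = FALSE]
    for (i in seq_len(nrow(sub_tr))) {
      qname <- split_prop(sub_tr$p[i])
      if (sub_tr$type[i] == "iri") {
        xml2::xml_add_child(desc, qname, "rdf:resource" = sub_tr$o[i])
      } else if (!is.na(sub_tr$dt[i])) {
        xml2::xml_add_child(desc, qname, sub_tr$o[i],
                            "rdf:datatype" = sub_tr$dt[i])
      } else {
        xml2::xml_add_child(desc, qname, sub_tr$o[i])
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_rdfxml <- function(path) {
  doc <- tryCatch(suppressWarnings(xml2::read_xml(path)),
                  error = function(e) {
    dst_abort("schema", paste("not parseable RDF/XML:", conditionMessage(e)))
  })
  descs <- xml2::xml_find_all(doc, ".//rdf:Description",
                              ns = c(rdf = RDF_NS))
  rows <- list()
  for (d in descs) {
    s <- xml2::xml_attr(d, "about")
    ns_map <- xml2::xml_ns(doc)
    for (child in xml2::xml_children(d)) {
      # resolve the qualified element name against the document namespaces
      full <- xml2::xml_name(child, ns = ns_map)
      parts <- strsplit(full, ":", fixed = TRUE)[[1]]
      p <- paste0(ns_map[[parts[1]]], parts[2])
      res <- xml2::xml_attr(child, "resource")
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <- triple(s, p, res, "iri")
      } else {
        dt <- xml2::xml_attr(child, "datatype")
        rows[[length(rows) + 1L]] <- triple(s, p, xml2::xml_text(child),
                                            "literal",
                                            dt = if (is.na(dt))
                                              NA_character_ else dt)
      }
    }
  }
  if (!length(rows)) dst_abort("schema", "no RDF descriptions found")
  do.call(rbind, rows)
}

# ---- public API -----------------------------------------------------------

rdf_syntax_for <- function(path, syntax = NULL) {
  if (!is.null(syntax)) return(match.arg(syntax, c("turtle", "rdfxml")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ttl", "nt")) "turtle"
  else if (ext %in% c("rdf", "xml", "owl")) "rdfxml"
  else dst_abort("schema", paste("cannot infer RDF syntax from", path))
}

#' Export the data model as SKOS/RDF
#'
#' Serializes the model as a SKOS concept scheme: each variable is a
#' `skos:Concept` carrying its label (`skos:prefLabel`), definition,
#' identifier (`skos:notation`), data type, range and category annotations
#' (custom properties under a stable base URI), `skos:broader` links to its
#' modality concept and `skos:exactMatch` cross-references to its ontology
#' terms. [import_model_rdf()] restores a field-identical model.
#'
#' @param model a [data_model()].
#' @param path output file.
#' @param syntax `"turtle"` or `"rdfxml"`; inferred from the extension
#'   (`.ttl` / `.rdf`) when omitted.
#' @return `path`, invisibly.
#' @export
export_model_rdf <- function(model, path, syntax = NULL) {
  validate_model(model)
  syntax <- rdf_syntax_for(path, syntax)
  tr <- model_to_triples(model)
  if (syntax == "turtle") write_turtle(tr, path) else write_rdfxml(tr, path)
  invisible(path)
}

#' Import a data model from SKOS/RDF
#'
#' Inverse of [export_model_rdf()]: reads a Turtle or RDF/XML document using
#' the package's SKOS vocabulary and rebuilds the [data_model()].
#'
#' @param path RDF file (`.ttl` or `.rdf`/`.xml`/`.owl`).
#' @param syntax `"turtle"` or `"rdfxml"`; inferred when omitted.
#' @return a validated [data_model()].
#' @export
import_model_rdf <- function(path, syntax = NULL) {
  if (!file.exists(path)) dst_abort("io", paste("no such file:", path))
  syntax <- rdf_syntax_for(path, syntax)
  tr <- if (syntax == "turtle") read_turtle(path) else read_rdfxml(path)
  triples_to_model(tr)
}
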