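#' Load an ontology file into the property-graph model
#'
#' Parses an OBO 1.4 flat file or an OWL RDF/XML file into an
#' [ontology_graph()]: one term per named class, one edge per asserted
#' named-class subsumption. Anonymous classes and restriction expressions
#' are never materialized as terms; classes without an asserted parent are
#' attached to the virtual root. Equivalence axioms and existential
#' restrictions are ignored (a hook for future relation types exists in the
#' OWL reader but only `rdfs:subClassOf` to a named class is followed).
#'
#' @param path path to a `.obo` or `.owl`/`.rdf`/`.xml` file; the format is
#'   chosen by extension (anything not ending in `.obo` is parsed as
#'   RDF/XML).
#' @param tag short uppercase ontology abbreviation recorded on every term
#'   (e.g. `"EFO"`).
#' @param prefix_map CURIE prefix map, see [normalize_term_id()].
#' @return an `ontology_graph`.
#' @export
load_ontology <- function(path, tag, prefix_map = default_prefix_map()) {
  if (!is.character(tag) || length(tag) != 1L || !nzchar(tag)) {
    onto_error("ontology tag must be a non-empty string", "ontoscout_format_error")
  }
  if (!file.exists(path)) {
    onto_error(sprintf("ontology file not found: %s", path), "ontoscout_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "obo") parse_obo(path, tag, prefix_map)
  else parse_owl_rdfxml(path, tag, prefix_map)
}

## OBO 1.4 stanza parser. Only [Term] stanzas are read; obsolete terms are
## skipped; is_a lines carry the subclass edges. Trailing "! comment" text
## after an id is stripped per the OBO spec.
parse_obo <- function(path, tag, prefix_map) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) {
    onto_error(sprintf("%s: no stanzas found; not an OBO file?", path),
               "ontoscout_format_error")
  }
  ids <- character(); labels <- character()
  synonyms <- list(); parents <- list()
  i <- 1L
  n_st <- length(stanza_starts)
  for (k in seq_len(n_st)) {
    start <- stanza_starts[k]
    end <- if (k < n_st) stanza_starts[k + 1L] - 1L else length(lines)
    if (trimws(lines[start]) != "[Term]") next
    block <- lines[(start + 1L):end]
    block <- block[nzchar(trimws(block))]
    kv <- regmatches(block, regexec("^([a-zA-Z_]+):\\s*(.*)$", block))
    id <- NULL; name <- NULL; syns <- character(); isas <- character()
    obsolete <- FALSE
    for (j in seq_along(kv)) {
      if (length(kv[[j]]) != 3L) {
        onto_error(sprintf("%s: malformed line %d: '%s'", path,
                           start + j, block[j]),
                   "ontoscout_format_error")
      }
      key <- kv[[j]][2]; val <- kv[[j]][3]
      if (key == "id") id <- trimws(val)
      else if (key == "name") name <- trimws(val)
      else if (key == "is_a") isas <- c(isas, trimws(sub("!.*$", "", val)))
      else if (key == "is_obsolete" && trimws(val) == "true") obsolete <- TRUE
      else if (key == "synonym") {
        m <- regmatches(val, regexec('^"([^"]*)"', val))[[1]]
        if (length(m) == 2L) syns <- c(syns, m[2])
      }
    }
    if (obsolete || is.null(id)) next
    id <- normalize_term_id(id, prefix_map)
    if (id %in% ids) next  # duplicate stanza: first wins
    ids <- c(ids, id)
    labels[id] <- if (is.null(name)) id else name
    synonyms[[id]] <- unique(syns)
    parents[[id]] <- normalize_term_id(isas, prefix_map)
  }
  build_parsed_graph(ids, labels, synonyms, parents, tag, path)
}

## OWL RDF/XML parser over xml2: owl:Class nodes with rdf:about,
## rdfs:subClassOf with rdf:resource (named superclasses only; blank-node
## restrictions are skipped), rdfs:label and oboInOwl synonym properties.
parse_owl_rdfxml <- function(path, tag, prefix_map) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    onto_error(sprintf("%s: cannot parse RDF/XML: %s",
                                       path, conditionMessage(e)),
                               "ontoscout_format_error")
                  })
  ns <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#",
          owl = "http://www.w3.org/2002/07/owl#",
          oio = "http://www.geneontology.org/formats/oboInOwl#")
  classes <- xml2::xml_find_all(doc, "//owl:Class[@rdf:about]", ns)
  ids <- character(); labels <- character()
  synonyms <- list(); parents <- list()
  for (cl in classes) {
    iri <- xml2::xml_attr(cl, "rdf:about", ns = ns)
    id <- normalize_term_id(iri, prefix_map)
    lab <- xml2::xml_text(xml2::xml_find_first(cl, "./rdfs:label", ns))
    syns <- xml2::xml_text(xml2::xml_find_all(
      cl, "./oio:hasExactSynonym | ./oio:hasRelatedSynonym", ns))
    sup <- xml2::xml_attr(
      xml2::xml_find_all(cl, "./rdfs:subClassOf[@rdf:resource]", ns),
      "rdf:resource", ns = ns)
    sup <- sup[!is.na(sup)]
    if (!id %in% ids) {
      ids <- c(ids, id)
      labels[id] <- if (is.na(lab)) id else lab
      synonyms[[id]] <- unique(syns)
      parents[[id]] <- normalize_term_id(sup, prefix_map)
    } else {
      synonyms[[id]] <- sorted_union(synonyms[[id]], syns)
      parents[[id]] <- unique(c(parents[[id]],
                                if (length(sup)) normalize_term_id(sup, prefix_map)))
    }
  }
  if (!length(ids)) {
    onto_error(sprintf("%s: no named owl:Class elements found", path),
               "ontoscout_format_error")
  }
  build_parsed_graph(ids, labels, synonyms, parents, tag, path)
}

build_parsed_graph <- function(ids, labels, synonyms, parents, tag, path) {
  drop_thing <- function(x) x[!x %in% c(VIRTUAL_ROOT, "owl:Thing")]
  ids <- drop_thing(ids)
  edges <- do.call(rbind, lapply(ids, function(id) {
    p <- drop_thing(intersect(parents[[id]], ids))
    if (!length(p)) return(NULL)
    data.frame(child = id, parent = p, stringsAsFactors = FALSE)
  }))
  terms <- data.frame(id = ids, label = unname(labels[ids]),
                      stringsAsFactors = FALSE)
  terms$synonyms <- I(unname(synonyms[ids]))
  terms$tags <- I(rep(list(tag), length(ids)))
  tryCatch(
    ontology_graph(terms, edges),
    ontoscout_cycle_error = function(e) {
      onto_error(sprintf("%s: %s", path, conditionMessage(e)),
                 "ontoscout_cycle_error", cycle = e$cycle)
    }
  )
}

#' Export the property graph
#'
#' Writes the graph as GraphML (`.graphml`/`.xml`) or as a structured JSON
#' dump (`.json`) with stable key order. Node records carry `id`, `label`
#' and `ontology_tags`; every edge is typed `subclass_of`. Re-importing an
#' export with [import_property_graph()] reproduces an isomorphic graph.
#'
#' @param g an `ontology_graph`.
#' @param path output file; the dialect is chosen by extension.
#' @return `path`, invisibly.
#' @export
export_property_graph <- function(g, path) {
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) {
    onto_error(sprintf("cannot write '%s': directory does not exist", path),
               "ontoscout_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    nodes <- lapply(g$ids, function(id) list(
      id = id, label = unname(g$labels[[id]]),
      ontology_tags = as.list(g$tags[[id]]),
      synonyms = as.list(g$synonyms[[id]])))
    edges <- lapply(seq_len(nrow(g$edges)), function(i) list(
      source = g$edges$child[i], target = g$edges$parent[i],
      type = "subclass_of"))
    jsonlite::write_json(list(root = g$root, nodes = nodes, edges = edges),
                         path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    write_graphml(g, path)
  }
  invisible(path)
}

write_graphml <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="label" for="node" attr.name="label" attr.type="string"/>')
  w('  <key id="ontology_tags" for="node" attr.name="ontology_tags" attr.type="string"/>')
  w('  <key id="synonyms" for="node" attr.name="synonyms" attr.type="string"/>')
  w('  <key id="type" for="edge" attr.name="type" attr.type="string"/>')
  w('  <graph id="ontology" edgedefault="directed">')
  for (id in g$ids) {
    w('    <node id="', esc(id), '">')
    w('      <data key="label">', esc(g$labels[[id]]), '</data>')
    w('      <data key="ontology_tags">',
      esc(paste(g$tags[[id]], collapse = "|")), '</data>')
    w('      <data key="synonyms">',
      esc(paste(g$synonyms[[id]], collapse = "|")), '</data>')
    w('    </node>')
  }
  for (i in seq_len(nrow(g$edges))) {
    w('    <edge source="', esc(g$edges$child[i]),
      '" target="', esc(g$edges$parent[i]), '">')
    w('      <data key="type">subclass_of</data>')
    w('    </edge>')
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

#' Import a property graph written by [export_property_graph()]
#'
#' @param path a `.graphml` or `.json` export.
#' @return an `ontology_graph`.
#' @export
import_property_graph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path)
    ids <- vapply(obj$nodes, `[[`, character(1), "id")
    keep <- ids != obj$root
    terms <- data.frame(
      id = ids[keep],
      label = vapply(obj$nodes, `[[`, character(1), "label")[keep],
      stringsAsFactors = FALSE)
    terms$synonyms <- I(lapply(obj$nodes[keep], function(n)
      unlist(n$synonyms) %||% character()))
    terms$tags <- I(lapply(obj$nodes[keep], function(n)
      unlist(n$ontology_tags) %||% character()))
    edges <- data.frame(
      child = vapply(obj$edges, `[[`, character(1), "source"),
      parent = vapply(obj$edges, `[[`, character(1), "target"),
      stringsAsFactors = FALSE)
    return(ontology_graph(terms, edges[edges$child != obj$root, , drop = FALSE],
                          root = obj$root))
  }
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  nodes <- xml2::xml_find_all(doc, "//g:node", ns)
  ids <- xml2::xml_attr(nodes, "id")
  dat <- function(node, key) {
    xml2::xml_text(xml2::xml_find_first(
      node, sprintf("./g:data[@key='%s']", key), ns))
  }
  labels <- vapply(nodes, dat, character(1), key = "label")
  split_bar <- function(x) {
    if (is.na(x) || !nzchar(x)) character()
    else strsplit(x, "|", fixed = TRUE)[[1]]
  }
  tags <- lapply(vapply(nodes, dat, character(1), key = "ontology_tags"), split_bar)
  syns <- lapply(vapply(nodes, dat, character(1), key = "synonyms"), split_bar)
  eg <- xml2::xml_find_all(doc, "//g:edge", ns)
  edges <- data.frame(child = xml2::xml_attr(eg, "source"),
                      parent = xml2::xml_attr(eg, "target"),
                      stringsAsFactors = FALSE)
  keep <- ids != VIRTUAL_ROOT
  terms <- data.frame(id = ids[keep], label = labels[keep],
                      stringsAsFactors = FALSE)
  terms$synonyms <- I(syns[keep])
  terms$tags <- I(tags[keep])
  ontology_graph(terms, edges[edges$child != VIRTUAL_ROOT, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
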