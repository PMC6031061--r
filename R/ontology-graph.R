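#' Ontology subclass graphs
#'
#' An `ontology_graph` is the simplified property-graph view of one or more
#' ontologies: one node per named class, one directed edge per asserted
#' subclass relation (child -> parent), and a single virtual root term with
#' the reserved id `"OWL:Thing"`. The graph is required to be acyclic and
#' every non-root term must reach the root along parent edges.
#'
#' @section Fields:
#' \describe{
#'   \item{ids}{character vector of all term ids (CURIE-normalized),
#'     including the root.}
#'   \item{labels}{named character vector, one human-readable label per id.}
#'   \item{synonyms}{named list of character vectors.}
#'   \item{tags}{named list of short uppercase ontology abbreviations (e.g.
#'     `"EFO"`); a class present in several source ontologies is a single
#'     node carrying every source tag.}
#'   \item{edges}{data.frame with columns `child`, `parent`.}
#'   \item{root}{id of the virtual root.}
#' }
#' @name ontology_graph
NULL

VIRTUAL_ROOT <- "OWL:Thing"

#' Construct an ontology graph
#'
#' Low-level constructor used by the parsers and the fixture generator.
#' Terms with no asserted parent are attached to the virtual root, which is
#' created if absent. Duplicate and self edges are rejected, and the graph
#' must be acyclic.
#'
#' @param terms data.frame with columns `id`, `label` and optional
#'   list-columns `synonyms`, `tags` (or character columns with `|`-separated
#'   values).
#' @param edges data.frame with character columns `child`, `parent`.
#' @param root id to use for the virtual root term.
#' @return an `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges = NULL, root = VIRTUAL_ROOT) {
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  ids <- as.character(terms$id)
  if (anyDuplicated(ids)) {
    onto_error(sprintf("duplicate term ids: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "ontoscout_format_error")
  }
  labels <- as.character(terms$label)
  labels[is.na(labels) | !nzchar(labels)] <- ids[is.na(labels) | !nzchar(labels)]
  names(labels) <- ids

  pull_listcol <- function(col) {
    if (is.null(terms[[col]])) {
      out <- rep(list(character()), length(ids))
    } else if (is.list(terms[[col]])) {
      out <- lapply(terms[[col]], function(x) as.character(x[nzchar(x)]))
    } else {
      out <- lapply(strsplit(as.character(terms[[col]]), "|", fixed = TRUE),
                    function(x) x[!is.na(x) & nzchar(x)])
    }
    names(out) <- ids
    out
  }
  synonyms <- pull_listcol("synonyms")
  tags <- pull_listcol("tags")

  if (any(edges$child == edges$parent)) {
    onto_error("self subclass edges are not allowed", "ontoscout_format_error")
  }
  edges <- unique(edges)
  unknown <- setdiff(c(edges$child, edges$parent), c(ids, root))
  if (length(unknown)) {
    onto_error(sprintf("edges reference unknown terms: %s",
                       paste(unknown, collapse = ", ")),
               "ontoscout_format_error")
  }

  ## attach the virtual root
  if (!root %in% ids) {
    ids <- c(root, ids)
    labels <- c(stats::setNames("Thing", root), labels)
    synonyms <- c(stats::setNames(list(character()), root), synonyms)
    tags <- c(stats::setNames(list(character()), root), tags)
  }
  orphans <- setdiff(ids, c(root, edges$child))
  if (length(orphans)) {
    edges <- rbind(edges, data.frame(child = orphans, parent = root,
                                     stringsAsFactors = FALSE))
  }
  if (any(edges$parent == root & edges$child == root)) {
    edges <- edges[!(edges$parent == root & edges$child == root), ]
  }
  g <- structure(
    list(ids = ids, labels = labels, synonyms = synonyms, tags = tags,
         edges = edges[order(edges$child, edges$parent), , drop = FALSE],
         root = root),
    class = "ontology_graph"
  )
  rownames(g$edges) <- NULL
  assert_acyclic(g)
  g
}

## igraph view of the subclass graph, edges child -> parent
as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = data.frame(name = g$ids))
}

assert_acyclic <- function(g) {
  ig <- as_igraph(g)
  if (!igraph::is_dag(ig)) {
    comp <- igraph::components(ig, mode = "strong")
    big <- which(comp$csize > 1)[1]
    cyc <- sort(g$ids[comp$membership == big])
    onto_error(sprintf("subclass graph contains a cycle: [%s]",
                       paste(cyc, collapse = ", ")),
               "ontoscout_cycle_error",
               cycle = cyc)
  }
  invisible(g)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms (incl. root), %d subclass edges\n",
              length(x$ids), nrow(x$edges)))
  tg <- sort(unique(unlist(x$tags)))
  if (length(tg)) cat("  ontologies:", paste(tg, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.ontology_graph <- function(x, ...) {
  sprintf("<ontology_graph: %d terms, %d edges>", length(x$ids), nrow(x$edges))
}

## children / parents adjacency as named lists of character vectors
graph_children <- function(g) {
  split(g$edges$child, factor(g$edges$parent, levels = g$ids))
}
graph_parents <- function(g) {
  split(g$edges$parent, factor(g$edges$child, levels = g$ids))
}

#' Merge ontology graphs under one virtual root
#'
#' Takes the union of vertices and edges of the input graphs. Classes with
#' equal (normalized) ids become a single node whose `tags` is the union of
#' the source-ontology abbreviations, so a shared class (e.g. a cell type
#' imported by two ontologies) is traversed as one node while its origin
#' remains traceable. Labels and synonyms are unioned as well (first label
#' wins).
#'
#' @param graphs list of `ontology_graph` objects (at least one).
#' @return a merged `ontology_graph`.
#' @export
merge_graphs <- function(graphs) {
  if (!length(graphs)) {
    onto_error("merge_graphs needs at least one graph", "ontoscout_format_error")
  }
  stopifnot(all(vapply(graphs, inherits, logical(1), "ontology_graph")))
  root <- graphs[[1]]$root
  ids <- character(); labels <- character()
  synonyms <- list(); tags <- list()
  for (g in graphs) {
    new <- setdiff(g$ids, ids)
    ids <- c(ids, new)
    labels[new] <- g$labels[new]
    synonyms[new] <- g$synonyms[new]
    tags[new] <- g$tags[new]
    shared <- setdiff(intersect(g$ids, ids), new)
    for (id in shared) {
      synonyms[[id]] <- sorted_union(synonyms[[id]], g$synonyms[[id]])
      tags[[id]] <- sorted_union(tags[[id]], g$tags[[id]])
    }
  }
  edges <- unique(do.call(rbind, lapply(graphs, `[[`, "edges")))
  ## drop root-attachment edges that are superseded by a real parent elsewhere
  has_real_parent <- unique(edges$child[edges$parent != root])
  edges <- edges[!(edges$parent == root & edges$child %in% has_real_parent), ]
  nonroot <- setdiff(ids, root)
  terms <- data.frame(id = nonroot, label = unname(labels[nonroot]),
                      stringsAsFactors = FALSE)
  terms$synonyms <- I(unname(synonyms[nonroot]))
  terms$tags <- I(unname(tags[nonroot]))
  ontology_graph(terms,
                 edges = edges[edges$child != root, , drop = FALSE],
                 root = root)
}

#' Graph measures: distance to root and subtree depth
#'
#' `distance` is the length of the shortest path from a term to the root
#' along parent edges (the root has distance 0). `subtree_depth` is the
#' longest downward path from a term to any of its descendants (leaves have
#' depth 0); it drives the treemap color encoding.
#'
#' @param g an `ontology_graph`.
#' @return list with named integer vectors `distance` and `subtree_depth`.
#' @export
compute_measures <- function(g) {
  ig <- as_igraph(g)
  d <- igraph::distances(ig, v = g$ids, to = g$root, mode = "out")[, 1]
  if (any(!is.finite(d))) {
    onto_error(sprintf("terms cannot reach the root: %s",
                       paste(g$ids[!is.finite(d)], collapse = ", ")),
               "ontoscout_format_error")
  }
  distance <- stats::setNames(as.integer(d), g$ids)

  ## longest downward path, children before parents
  topo <- names(igraph::topo_sort(ig, mode = "out"))  # children first
  ch <- graph_children(g)
  depth <- stats::setNames(integer(length(g$ids)), g$ids)
  for (t in topo) {
    kids <- ch[[t]]
    depth[[t]] <- if (length(kids)) 1L + max(depth[kids]) else 0L
  }
  list(distance = distance, subtree_depth = depth)
}
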