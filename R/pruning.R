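#' Pruning the annotation term graph
#'
#' Most of an ontology is never used for annotation, so the merged graph is
#' reduced to an *exploration graph* in two steps:
#'
#' 1. [restrict_to_used()] hides every term whose transitive dataset set is
#'    empty (size 0), re-linking retained children past removed ancestors.
#' 2. [collapse_redundant_parents()] removes ancestors that carry no extra
#'    information: a non-root term with exactly one retained child whose
#'    dataset set equals its own is absorbed into that child. The surviving
#'    hierarchy is a strict containment set hierarchy: along every retained
#'    edge (child, parent) with a non-root parent, `S_child` is a proper
#'    subset of `S_parent`.
#'
#' Pruning never changes the transitive set of a retained term; sets are
#' computed on the full graph and preserved. Absorbed ancestors are recorded
#' per retained term in `provenance`, so breadcrumb paths can still display
#' the full ontological lineage.
#'
#' @name pruning
NULL

#' Hide unused annotation terms
#'
#' Retains exactly the terms with transitive size >= 1 plus the virtual
#' root. Edges between retained terms are kept; a retained child whose
#' retained ancestors are only reachable through removed terms is re-linked
#' to its nearest retained ancestor(s).
#'
#' @param g an `ontology_graph`.
#' @param index the `annotation_index` built on `g`.
#' @return an `ontology_graph` over the used terms.
#' @export
restrict_to_used <- function(g, index) {
  used <- names(index$transitive)
  keep <- c(g$root, intersect(g$ids, used))
  par <- graph_parents(g)
  keep_set <- structure(rep(TRUE, length(keep)), names = keep)

  ## nearest retained ancestors of a term, walking through removed ones
  memo <- new.env(parent = emptyenv())
  nearest_retained <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    out <- character()
    for (p in par[[t]]) {
      if (isTRUE(keep_set[p])) out <- c(out, p)
      else out <- c(out, nearest_retained(p))
    }
    out <- sort(unique(out))
    memo[[t]] <- out
    out
  }
  edges <- do.call(rbind, lapply(setdiff(keep, g$root), function(t) {
    anc <- nearest_retained(t)
    if (!length(anc)) return(NULL)
    data.frame(child = t, parent = anc, stringsAsFactors = FALSE)
  }))
  terms <- data.frame(id = setdiff(keep, g$root),
                      label = unname(g$labels[setdiff(keep, g$root)]),
                      stringsAsFactors = FALSE)
  terms$synonyms <- I(unname(g$synonyms[terms$id]))
  terms$tags <- I(unname(g$tags[terms$id]))
  ontology_graph(terms, edges, root = g$root)
}

#' Collapse redundant equal-set ancestors
#'
#' Repeatedly removes any non-root term `p` that has a retained child `c`
#' with `S_p == S_c`: such a parent describes exactly the same datasets as
#' its child and carries no extra information. All of `p`'s children are
#' re-linked to `p`'s parents and `p` (plus the ancestors it had already
#' absorbed) is appended to the provenance of the equal-set child — the
#' deepest one, ties broken by id, so the most specific term of an
#' equal-set chain is the one kept. Candidates are processed in decreasing
#' distance from the root, making the output deterministic. A parent whose
#' set equals the union of two or more proper-subset children is retained:
#' removing it would disconnect siblings, and every such edge already
#' satisfies strict containment. At the fixpoint every retained edge with a
#' non-root parent satisfies `S_child` strictly contained in `S_parent`.
#'
#' @param g an `ontology_graph` already restricted to used terms.
#' @param index the `annotation_index` built on the original graph.
#' @return an `exploration_graph`.
#' @export
collapse_redundant_parents <- function(g, index) {
  edges <- g$edges
  ids <- g$ids
  provenance <- stats::setNames(rep(list(character()), length(ids)), ids)
  sets <- index$transitive

  same_set <- function(a, b) {
    sa <- sets[[a]] %||% character(); sb <- sets[[b]] %||% character()
    length(sa) == length(sb) && all(sa == sb)
  }
  measures <- compute_measures(g)
  ## live adjacency, updated as terms are absorbed
  kids <- split(edges$child, factor(edges$parent, levels = ids))
  pars <- split(edges$parent, factor(edges$child, levels = ids))
  alive <- stats::setNames(rep(TRUE, length(ids)), ids)
  order_ids <- ids[order(-measures$distance[ids], ids)]  # deepest parents first
  repeat {
    removed_any <- FALSE
    for (p in order_ids) {
      if (!alive[[p]] || p == g$root) next
      ch <- kids[[p]]
      if (!length(ch)) next
      eq <- ch[vapply(ch, function(x) same_set(p, x), logical(1))]
      if (!length(eq)) next
      ## absorb p into its deepest equal-set child (tie: smallest id)
      eq <- eq[order(-measures$distance[eq], eq)]
      absorber <- eq[[1]]
      provenance[[absorber]] <- c(provenance[[absorber]], p, provenance[[p]])
      provenance[[p]] <- NULL
      gp <- pars[[p]]
      ## relink every child of p to p's parents, dropping the * -> p edges
      for (c2 in ch) {
        pars[[c2]] <- sort(unique(c(setdiff(pars[[c2]], p), gp)))
      }
      for (q in gp) {
        kids[[q]] <- sort(unique(c(setdiff(kids[[q]], p), ch)))
      }
      alive[[p]] <- FALSE
      kids[[p]] <- character(); pars[[p]] <- character()
      removed_any <- TRUE
    }
    if (!removed_any) break
  }
  ids <- ids[alive[ids]]
  edges <- do.call(rbind, lapply(ids, function(ch2) {
    ps <- pars[[ch2]]
    if (!length(ps)) return(NULL)
    data.frame(child = ch2, parent = ps, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }

  keep <- setdiff(ids, g$root)
  terms <- data.frame(id = keep, label = unname(g$labels[keep]),
                      stringsAsFactors = FALSE)
  terms$synonyms <- I(unname(g$synonyms[keep]))
  terms$tags <- I(unname(g$tags[keep]))
  pruned <- ontology_graph(terms, edges[edges$child != g$root, , drop = FALSE],
                           root = g$root)
  new_exploration_graph(pruned, index, provenance[pruned$ids])
}

new_exploration_graph <- function(pruned, index, provenance) {
  sizes <- term_size(index, pruned$ids)
  sizes[pruned$root] <- length(index$universe)
  structure(list(
    graph = pruned,
    sizes = sizes[pruned$ids],
    transitive = c(stats::setNames(list(index$universe), pruned$root),
                   index$transitive[intersect(names(index$transitive),
                                              setdiff(pruned$ids, pruned$root))]),
    measures = compute_measures(pruned),
    provenance = provenance
  ), class = "exploration_graph")
}

#' @export
print.exploration_graph <- function(x, ...) {
  cat(sprintf("<exploration_graph> %d retained terms + root, %d edges\n",
              length(x$graph$ids) - 1L, nrow(x$graph$edges)))
  n_abs <- sum(vapply(x$provenance, length, integer(1)))
  cat(sprintf("  absorbed ancestors recorded: %d; max distance: %d\n",
              n_abs, max(x$measures$distance)))
  invisible(x)
}

#' @export
summary.exploration_graph <- function(object, ...) {
  ids <- setdiff(object$graph$ids, object$graph$root)
  df <- data.frame(term_id = ids,
                   label = unname(object$graph$labels[ids]),
                   size = unname(object$sizes[ids]),
                   distance = unname(object$measures$distance[ids]),
                   depth = unname(object$measures$subtree_depth[ids]),
                   stringsAsFactors = FALSE)
  df[order(-df$size, df$label, df$term_id), ]
}

#' Retained terms of an exploration graph (root excluded)
#' @param eg an `exploration_graph`.
#' @export
retained_terms <- function(eg) setdiff(eg$graph$ids, eg$graph$root)

#' Build the exploration graph from a repository and ontology
#'
#' Pipeline composition: annotation closure, hiding of unused terms,
#' collapse of redundant equal-set ancestors, and recomputation of graph
#' measures on the pruned graph. Deterministic for fixed inputs.
#'
#' @param g the merged `ontology_graph`.
#' @param repo a `repository`.
#' @return list with elements `eg` (the `exploration_graph`) and `index`
#'   (the `annotation_index`, including the unresolved-annotations report).
#' @export
build_exploration_graph <- function(g, repo) {
  index <- build_annotation_index(repo, g)
  used <- restrict_to_used(g, index)
  eg <- collapse_redundant_parents(used, index)
  list(eg = eg, index = index)
}
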