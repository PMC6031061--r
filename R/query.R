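#' Query expressions
#'
#' A query combines a free-text part and a Boolean annotation-term part.
#' The term part has three disjoint sets — `or`, `and`, `not` — plus an
#' optional `root` term that restricts both the visible graph and the
#' result set to a subtree.
#'
#' Evaluation order (NOT is an absolute exclusion): the AND terms are
#' intersected first, the OR union is intersected with that (or with the
#' universe when there are no AND terms), the NOT union is subtracted last,
#' and the root term's set is intersected at the end.
#'
#' @name query
NULL

#' Construct a term query
#'
#' @param or,and,not character vectors of term ids; a term may appear in at
#'   most one of the three sets.
#' @param root optional term id restricting the result to a subtree.
#' @return a `term_query`.
#' @export
term_query <- function(or = character(), and = character(),
                       not = character(), root = NULL) {
  or <- unique(as.character(or)); and <- unique(as.character(and))
  not <- unique(as.character(not))
  dup <- c(intersect(or, and), intersect(or, not), intersect(and, not))
  if (length(dup)) {
    onto_error(sprintf("term(s) in more than one query state: %s",
                       paste(unique(dup), collapse = ", ")),
               "ontoscout_query_error")
  }
  structure(list(or = or, and = and, not = not, root = root),
            class = "term_query")
}

#' Construct a text query
#'
#' @param raw query string (empty string means "everything").
#' @param expand_synonyms expand query tokens with ontology synonyms of
#'   matching term labels (e.g. "mouse" also matches "mice").
#' @return a `text_query`.
#' @export
text_query <- function(raw = "", expand_synonyms = TRUE) {
  structure(list(raw = as.character(raw)[1],
                 expand_synonyms = isTRUE(expand_synonyms)),
            class = "text_query")
}

#' Construct a combined query expression
#'
#' @param text a `text_query` (or a plain string).
#' @param terms a `term_query`.
#' @return a `query_expression`.
#' @export
query_expression <- function(text = text_query(), terms = term_query()) {
  if (is.character(text)) text <- text_query(text)
  stopifnot(inherits(text, "text_query"), inherits(terms, "term_query"))
  structure(list(text = text, terms = terms), class = "query_expression")
}

#' Canonical query string
#'
#' Serializes a query expression to the canonical CLI syntax: free text
#' followed by `+term:` (and), `~term:` (or), `-term:` (not) and `root:`
#' clauses, each set in sorted order.
#'
#' @param q a `query_expression`.
#' @return a single string.
#' @export
format_query <- function(q) {
  clause <- function(prefix, ids) {
    if (!length(ids)) character() else paste0(prefix, sort(ids))
  }
  parts <- c(
    if (nzchar(q$text$raw)) shQuote(q$text$raw, type = "cmd"),
    clause("+term:", q$terms$and),
    clause("~term:", q$terms$or),
    clause("-term:", q$terms$not),
    if (!is.null(q$terms$root)) paste0("root:", q$terms$root))
  paste(parts, collapse = " ")
}

#' Parse the canonical query string
#'
#' Grammar: whitespace-separated clauses; `+term:ID`, `~term:ID`,
#' `-term:ID`, `root:ID`; double-quoted or bare words form the free-text
#' part.
#'
#' @param s query string.
#' @return a `query_expression`.
#' @export
parse_query <- function(s) {
  s <- as.character(s)[1]
  toks <- regmatches(s, gregexpr('"[^"]*"|\\S+', s))[[1]]
  and <- or <- not <- character(); root <- NULL; words <- character()
  pos <- 1L
  for (tk in toks) {
    clause_id <- function(prefix) {
      id <- sub(prefix, "", tk)
      if (!nzchar(id)) {
        onto_error(sprintf("malformed clause '%s' at position %d", tk, pos),
                   "ontoscout_query_parse_error")
      }
      id
    }
    if (grepl("^\\+term:", tk)) and <- c(and, clause_id("^\\+term:"))
    else if (grepl("^~term:", tk)) or <- c(or, clause_id("^~term:"))
    else if (grepl("^-term:", tk)) not <- c(not, clause_id("^-term:"))
    else if (grepl("^root:", tk)) root <- clause_id("^root:")
    else words <- c(words, gsub('^"|"$', "", tk))
    pos <- pos + nchar(tk) + 1L
  }
  query_expression(text_query(paste(words, collapse = " ")),
                   term_query(or = or, and = and, not = not, root = root))
}

## ---------------------------------------------------------------------------
## Text search

## expanded token sets: each query token becomes itself plus the tokens of
## synonyms of ontology terms whose label (or a synonym) matches the token.
expand_tokens <- function(tokens, g) {
  lapply(tokens, function(tok) {
    hits <- vapply(g$ids, function(id) {
      tok %in% tokenize(g$labels[[id]])[[1]] ||
        tok %in% unlist(tokenize(g$synonyms[[id]]))
    }, logical(1))
    extra <- unlist(c(tokenize(g$labels[g$ids[hits]]),
                      lapply(g$ids[hits], function(id)
                        unlist(tokenize(g$synonyms[[id]])))))
    sorted_union(tok, extra)
  })
}

## per-dataset token bags by field
dataset_fields <- function(repo) {
  ids <- repo$datasets$id
  att_text <- vapply(ids, function(id) {
    paste(repo$annotations$text_value[repo$annotations$dataset_id == id],
          collapse = " ")
  }, character(1))
  list(title = stats::setNames(tokenize(repo$datasets$title), ids),
       description = stats::setNames(tokenize(repo$datasets$description), ids),
       attributes = stats::setNames(tokenize(att_text), ids))
}

#' Free-text search over dataset metadata
#'
#' Case-insensitive conjunctive token search over title, description and
#' attribute text values: a dataset matches when every query token (or one
#' of its synonym expansions) occurs in some field. Matching datasets are
#' ranked by a BM25-style score with field weights (title 3, description 1,
#' attribute text 1); ties are broken by dataset id. An empty query returns
#' the whole repository in id order.
#'
#' @param q a `text_query` (or plain string).
#' @param repo a `repository`.
#' @param g an `ontology_graph`, used for synonym expansion (optional when
#'   `expand_synonyms` is off).
#' @return a `result_set` carrying relevance scores.
#' @export
text_search <- function(q, repo, g = NULL) {
  if (is.character(q)) q <- text_query(q)
  tokens <- tokenize(q$raw)[[1]]
  if (!length(tokens)) {
    return(result_set(sort(repo$datasets$id), query_expression(q)))
  }
  groups <- if (q$expand_synonyms && !is.null(g)) expand_tokens(tokens, g)
            else as.list(tokens)
  fields <- dataset_fields(repo)
  ids <- repo$datasets$id
  weights <- c(title = 3, description = 1, attributes = 1)

  ## tf per token-group, field and dataset
  tf <- function(group, field, id) sum(fields[[field]][[id]] %in% group)
  matches <- vapply(ids, function(id) {
    all(vapply(groups, function(gr)
      any(vapply(names(weights), function(f) tf(gr, f, id) > 0, logical(1))),
      logical(1)))
  }, logical(1))
  hit_ids <- ids[matches]
  if (!length(hit_ids)) return(result_set(character(), query_expression(q)))

  ## BM25-flavoured score: idf * tf / (tf + k1), summed over fields with
  ## weights; document-length normalization omitted (metadata records are
  ## short and uniform).
  k1 <- 1.2
  n_docs <- length(ids)
  score <- vapply(hit_ids, function(id) {
    s <- 0
    for (gi in seq_along(groups)) {
      df_tok <- sum(vapply(ids, function(d)
        any(vapply(names(weights), function(f) tf(groups[[gi]], f, d) > 0,
                   logical(1))), logical(1)))
      idf <- log((n_docs - df_tok + 0.5) / (df_tok + 0.5) + 1)
      for (f in names(weights)) {
        tfv <- tf(groups[[gi]], f, id)
        s <- s + weights[[f]] * idf * tfv / (tfv + k1)
      }
    }
    s
  }, numeric(1))
  ord <- order(-score, hit_ids)
  result_set(hit_ids[ord], query_expression(q),
             scores = stats::setNames(score[ord], hit_ids[ord]))
}

#' Keyword-in-context snippet
#'
#' Returns the first matched token of the query in the dataset's title,
#' description or attribute text, with up to `window` characters of
#' context on each side. The match is wrapped in `[` `]`; truncated ends
#' carry an ellipsis. When the match came from a synonym expansion, the
#' snippet centers the synonym token actually present in the text, not the
#' query token. Returns `""` when nothing matches.
#'
#' @param dataset a dataset (from [get_dataset()]).
#' @param q a `text_query` (or plain string).
#' @param window characters of context per side (default 40).
#' @param g optional `ontology_graph` for synonym expansion.
#' @return a snippet string.
#' @export
kwic_snippet <- function(dataset, q, window = 40, g = NULL) {
  if (is.character(q)) q <- text_query(q)
  tokens <- tokenize(q$raw)[[1]]
  if (!length(tokens)) return("")
  groups <- if (q$expand_synonyms && !is.null(g)) expand_tokens(tokens, g)
            else as.list(tokens)
  texts <- c(dataset$title, dataset$description,
             dataset$attributes$text_value)
  for (txt in texts) {
    if (is.na(txt) || !nzchar(txt)) next
    low <- tolower(txt)
    for (gr in groups) {
      for (tok in gr) {
        m <- regexpr(paste0("(?<![a-z0-9])", tok, "(?![a-z0-9])"), low,
                     perl = TRUE)
        if (m > 0) {
          start <- as.integer(m); len <- attr(m, "match.length")
          from <- max(1L, start - window)
          to <- min(nchar(txt), start + len - 1L + window)
          out <- paste0(
            if (from > 1L) "…" else "",
            substr(txt, from, start - 1L),
            "[", substr(txt, start, start + len - 1L), "]",
            substr(txt, start + len, to),
            if (to < nchar(txt)) "…" else "")
          return(out)
        }
      }
    }
  }
  ""
}

## ---------------------------------------------------------------------------
## Term queries

#' Evaluate a Boolean annotation-term query
#'
#' Pure set algebra over the transitive term sets: base is the
#' intersection over the AND terms of their sets (universe when none),
#' intersected with the union over the OR terms (skipped when none); the
#' union over the NOT terms is subtracted; the root term's set, when set,
#' is intersected last.
#'
#' @param tq a `term_query`.
#' @param index an `annotation_index`.
#' @return a `result_set` (dataset ids in sorted order).
#' @export
evaluate_term_query <- function(tq, index) {
  ## a term known to the graph but never used resolves to the empty set;
  ## a term unknown to the graph is an error
  known <- unique(c(index$graph_terms, names(index$transitive)))
  resolve <- function(terms) {
    bad <- setdiff(terms, known)
    if (length(bad)) {
      onto_error(sprintf("unresolvable query term(s): %s",
                         paste(bad, collapse = ", ")),
                 "ontoscout_query_error")
    }
    lapply(terms, term_set, index = index)
  }
  base <- index$universe
  and_sets <- resolve(tq$and)
  for (s in and_sets) base <- intersect(base, s)
  if (length(tq$or)) {
    base <- intersect(base, sorted_union(unlist(resolve(tq$or))))
  }
  if (length(tq$not)) {
    base <- setdiff(base, unlist(resolve(tq$not)))
  }
  if (!is.null(tq$root)) {
    base <- intersect(base, resolve(tq$root)[[1]])
  }
  result_set(sort(base), query_expression(terms = tq))
}

#' Toggle a term's query state
#'
#' Cycles a term through the four query states
#' `none -> or -> and -> not -> none`, moving it between the sets of the
#' query accordingly.
#'
#' @param term a term id.
#' @param tq the current `term_query`.
#' @return the updated `term_query`.
#' @export
toggle_query_state <- function(term, tq) {
  state <- if (term %in% tq$or) "or" else if (term %in% tq$and) "and"
           else if (term %in% tq$not) "not" else "none"
  or <- setdiff(tq$or, term); and <- setdiff(tq$and, term)
  not <- setdiff(tq$not, term)
  switch(state,
         none = term_query(or = c(or, term), and = and, not = not, root = tq$root),
         or   = term_query(or = or, and = c(and, term), not = not, root = tq$root),
         and  = term_query(or = or, and = and, not = c(not, term), root = tq$root),
         not  = term_query(or = or, and = and, not = not, root = tq$root))
}

#' Root the exploration view at a term
#'
#' Restricts the visible graph to the term and its descendants and adds the
#' term as `root` to the query, so retrieved datasets are simultaneously
#' restricted to `S_term`. Un-root by calling with `term = NULL`, which
#' restores the full view and removes the restriction.
#'
#' @param term a retained term id, or `NULL` to un-root.
#' @param eg an `exploration_graph`.
#' @param tq the current `term_query`.
#' @return list with `view` (an `exploration_graph` restricted to the
#'   subtree; the original graph when un-rooting), `query` (updated
#'   `term_query`) and `breadcrumb` (data.frame from [breadcrumb_path()]).
#' @export
root_at <- function(term, eg, tq = term_query()) {
  if (is.null(term)) {
    tq$root <- NULL
    return(list(view = eg, query = tq,
                breadcrumb = breadcrumb_path(eg$graph$root, eg)))
  }
  if (!term %in% eg$graph$ids) {
    onto_error(sprintf("term '%s' is not retained in the exploration graph", term),
               "ontoscout_query_error")
  }
  ig <- as_igraph(eg$graph)
  desc <- names(igraph::subcomponent(ig, term, mode = "in"))  # term + descendants
  keep <- c(eg$graph$root, desc)
  sub_edges <- eg$graph$edges[eg$graph$edges$child %in% desc &
                                eg$graph$edges$parent %in% desc, , drop = FALSE]
  ## the subtree root attaches to the virtual root inside the view
  terms <- data.frame(id = desc, label = unname(eg$graph$labels[desc]),
                      stringsAsFactors = FALSE)
  terms$synonyms <- I(unname(eg$graph$synonyms[desc]))
  terms$tags <- I(unname(eg$graph$tags[desc]))
  sub <- ontology_graph(terms, sub_edges, root = eg$graph$root)
  view <- structure(list(
    graph = sub,
    sizes = eg$sizes[sub$ids],
    transitive = eg$transitive[intersect(names(eg$transitive), sub$ids)],
    measures = compute_measures(sub),
    provenance = eg$provenance[intersect(names(eg$provenance), sub$ids)]
  ), class = "exploration_graph")
  tq$root <- term
  list(view = view, query = tq, breadcrumb = breadcrumb_path(term, eg))
}

#' Evaluate a combined text + term query
#'
#' The result is the intersection of the free-text result and the Boolean
#' term result, ordered by the text relevance ranking (id order when the
#' text part is empty).
#'
#' @param q a `query_expression` (or canonical query string).
#' @param repo a `repository`.
#' @param eg an `exploration_graph` (used for synonym expansion context).
#' @param index an `annotation_index`.
#' @return a `result_set`.
#' @export
evaluate <- function(q, repo, eg, index) {
  if (is.character(q)) q <- parse_query(q)
  txt <- text_search(q$text, repo, eg$graph)
  trm <- evaluate_term_query(q$terms, index)
  ids <- txt$ids[txt$ids %in% trm$ids]
  result_set(ids, q, scores = txt$scores[ids])
}

## ---------------------------------------------------------------------------
## Data cart

#' Data carts
#'
#' An insertion-ordered, duplicate-free collection of saved datasets for
#' comparing results across searches without memorizing them.
#'
#' @param ids initial dataset ids (optional).
#' @return a `data_cart`.
#' @export
data_cart <- function(ids = character()) {
  structure(list(saved = unique(as.character(ids))), class = "data_cart")
}

#' @rdname data_cart
#' @param cart a `data_cart`.
#' @param repo the `repository` the ids must belong to.
#' @export
cart_add <- function(cart, ids, repo) {
  bad <- setdiff(ids, repo$datasets$id)
  if (length(bad)) {
    onto_error(sprintf("unknown dataset id(s): %s", paste(bad, collapse = ", ")),
               "ontoscout_lookup_error")
  }
  cart$saved <- unique(c(cart$saved, as.character(ids)))
  cart
}

#' @rdname data_cart
#' @export
cart_remove <- function(cart, ids) {
  bad <- setdiff(ids, cart$saved)
  if (length(bad)) {
    onto_error(sprintf("dataset(s) not in cart: %s", paste(bad, collapse = ", ")),
               "ontoscout_lookup_error")
  }
  cart$saved <- setdiff(cart$saved, ids)
  cart
}

#' @rdname data_cart
#' @export
cart_list <- function(cart) cart$saved

#' @export
print.data_cart <- function(x, ...) {
  cat(sprintf("<data_cart> %d saved dataset(s)\n", length(x$saved)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Highlighting

#' Direct and indirect annotation terms of a dataset
#'
#' Maps the dataset's asserted terms to their retained representatives
#' (an asserted term absorbed during pruning is represented by the retained
#' term that carries it in its provenance) and returns the retained
#' ancestors as the indirect set. In the interface, direct terms are drawn
#' filled and indirect terms outlined.
#'
#' @param id a dataset id.
#' @param repo a `repository`.
#' @param eg an `exploration_graph`.
#' @return list with sorted character vectors `direct` and `indirect`.
#' @export
highlight_terms <- function(id, repo, eg) {
  d <- get_dataset(repo, id)
  asserted <- unique(d$attributes$term_id[nzchar(d$attributes$term_id)])
  if (!length(asserted)) return(list(direct = character(), indirect = character()))
  ## provenance lookup: absorbed ancestor -> retained representative
  absorbed <- stats::setNames(
    rep(names(eg$provenance), vapply(eg$provenance, length, integer(1))),
    unlist(eg$provenance))
  direct <- vapply(asserted, function(t) {
    if (t %in% eg$graph$ids) t
    else if (t %in% names(absorbed)) unname(absorbed[[t]])
    else NA_character_
  }, character(1))
  direct <- sort(unique(direct[!is.na(direct)]))
  if (!length(direct)) return(list(direct = character(), indirect = character()))
  ig <- as_igraph(eg$graph)
  anc <- unique(unlist(lapply(direct, function(t)
    names(igraph::subcomponent(ig, t, mode = "out")))))
  indirect <- sort(setdiff(setdiff(anc, direct), eg$graph$root))
  list(direct = direct, indirect = indirect)
}
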