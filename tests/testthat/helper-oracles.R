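# Brute-force oracles, deliberately naive and independent of the package's
# graph algorithms: recursion over raw edge tables only.

# all ancestors of `term` (term excluded), by recursive parent walking
oracle_ancestors <- function(edges, term) {
  ps <- edges$parent[edges$child == term]
  out <- ps
  for (p in ps) out <- c(out, oracle_ancestors(edges, p))
  unique(out)
}

# all descendants of `term` (term excluded)
oracle_descendants <- function(edges, term) {
  cs <- edges$child[edges$parent == term]
  out <- cs
  for (ch in cs) out <- c(out, oracle_descendants(edges, ch))
  unique(out)
}

# per-term transitive dataset sets by per-dataset ancestor-set union
oracle_closure <- function(repo, g) {
  ann <- repo$annotations[nzchar(repo$annotations$term_id), , drop = FALSE]
  ann <- ann[ann$term_id %in% g$ids, , drop = FALSE]
  sets <- list()
  for (i in seq_len(nrow(ann))) {
    terms <- unique(c(ann$term_id[i], oracle_ancestors(g$edges, ann$term_id[i])))
    for (t in terms) {
      sets[[t]] <- sort(unique(c(sets[[t]], ann$dataset_id[i])))
    }
  }
  sets
}

# dataset x term incidence matrix after ancestor closure
oracle_incidence <- function(repo, g) {
  sets <- oracle_closure(repo, g)
  ds <- sort(repo$datasets$id)
  terms <- sort(names(sets))
  m <- matrix(0L, length(ds), length(terms), dimnames = list(ds, terms))
  for (t in terms) m[sets[[t]], t] <- 1L
  m
}

# shortest distance to root by enumeration of all upward paths
oracle_distance <- function(edges, term, root) {
  if (term == root) return(0L)
  ps <- edges$parent[edges$child == term]
  1L + min(vapply(ps, oracle_distance, integer(1), edges = edges, root = root))
}

# longest downward path by enumeration
oracle_subtree_depth <- function(edges, term) {
  cs <- edges$child[edges$parent == term]
  if (!length(cs)) return(0L)
  1L + max(vapply(cs, oracle_subtree_depth, integer(1), edges = edges))
}

# cycle detection by exhaustive DFS from every node
oracle_has_cycle <- function(edges) {
  nodes <- unique(c(edges$child, edges$parent))
  reaches_self <- function(start, cur, seen) {
    ps <- edges$parent[edges$child == cur]
    for (p in ps) {
      if (p == start) return(TRUE)
      if (!p %in% seen && reaches_self(start, p, c(seen, p))) return(TRUE)
    }
    FALSE
  }
  any(vapply(nodes, function(n) reaches_self(n, n, n), logical(1)))
}

# exhaustive per-dataset predicate evaluation of a term query
oracle_term_query <- function(tq, repo, g) {
  sets <- oracle_closure(repo, g)
  in_set <- function(d, t) d %in% (sets[[t]] %||% character())
  keep <- vapply(sort(repo$datasets$id), function(d) {
    ok_and <- all(vapply(tq$and, in_set, logical(1), d = d))
    ok_or <- !length(tq$or) || any(vapply(tq$or, in_set, logical(1), d = d))
    ok_not <- !any(vapply(tq$not, in_set, logical(1), d = d))
    ok_root <- is.null(tq$root) || in_set(d, tq$root)
    ok_and && ok_or && ok_not && ok_root
  }, logical(1))
  sort(repo$datasets$id)[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small random fixture shared by the property tests
random_fixture <- function(seed, n_terms = 30, n_datasets = 25) {
  generate_fixture(fixture_spec(
    n_terms = n_terms, max_depth = 5, polyhierarchy_fraction = 0.2,
    n_datasets = n_datasets, used_term_fraction = 0.4,
    annotations_per_dataset = c(1, 3), seed = seed))
}
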