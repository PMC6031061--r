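#' Result sets
#'
#' A `result_set` is the ordered list of dataset ids retrieved by a query
#' (text, term or combined), with no duplicates, together with the query
#' that produced it (optional) and per-dataset relevance scores when the
#' result came from text search.
#'
#' @param ids ordered character vector of dataset ids.
#' @param query the `query_expression` that produced it, if any.
#' @param scores optional named numeric relevance scores.
#' @return a `result_set`.
#' @export
result_set <- function(ids, query = NULL, scores = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    onto_error("result sets may not contain duplicate dataset ids",
               "ontoscout_validation_error")
  }
  structure(list(ids = ids, query = query, scores = scores),
            class = "result_set")
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set> %d datasets\n", length(x$ids)))
  if (length(x$ids)) {
    shown <- utils::head(x$ids, 10)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$ids) > 10) "...\n" else "\n")
  }
  invisible(x)
}

#' @export
length.result_set <- function(x) length(x$ids)

#' Per-term precision for a result set
#'
#' The fraction of retrieved datasets that are annotated (directly or
#' transitively) with the term:
#' `|retrieved n S_t| / |retrieved|`. High precision means the term
#' describes many of the datasets just retrieved.
#'
#' @param term a term id.
#' @param result a `result_set` (must be non-empty).
#' @param index an `annotation_index`.
#' @return a fraction in `[0, 1]`.
#' @export
precision <- function(term, result, index) {
  if (!length(result$ids)) {
    onto_error("precision is undefined for an empty result set",
               "ontoscout_undefined_metric")
  }
  length(intersect(result$ids, term_set(index, term))) / length(result$ids)
}

#' Per-term recall for a result set
#'
#' The fraction of all datasets annotated with the term, across the entire
#' repository, that were retrieved:
#' `|retrieved n S_t| / |S_t|`. Recall is the "information scent" signal:
#' low recall for a term says more datasets carrying that attribute are
#' available than the current query surfaced.
#'
#' @inheritParams precision
#' @export
recall <- function(term, result, index) {
  s <- term_set(index, term)
  if (!length(s)) {
    onto_error(sprintf("recall is undefined for unused term '%s' (size 0)", term),
               "ontoscout_undefined_metric")
  }
  length(intersect(result$ids, s)) / length(s)
}

#' Precision and recall for every retained term
#'
#' Computes the statistics table underlying the exploration view: for each
#' retained term its size, precision and recall given the current result
#' set, plus its distance to the root and subtree depth. The virtual root
#' is excluded from the table (it trivially covers everything). Terms whose
#' recall would be undefined are flagged with `NA`, never silently 0.
#'
#' @param result a non-empty `result_set`.
#' @param eg an `exploration_graph`.
#' @param index an `annotation_index`.
#' @return data.frame with columns
#'   `term_id, label, size, precision, recall, distance, depth`, ordered by
#'   decreasing precision (ties by label then id).
#' @export
compute_all_stats <- function(result, eg, index) {
  if (!length(result$ids)) {
    onto_error("statistics are undefined for an empty result set",
               "ontoscout_undefined_metric")
  }
  ids <- retained_terms(eg)
  n_ret <- length(result$ids)
  inter <- vapply(ids, function(t)
    length(intersect(result$ids, eg$transitive[[t]])), integer(1))
  size <- unname(eg$sizes[ids])
  df <- data.frame(
    term_id = ids,
    label = unname(eg$graph$labels[ids]),
    size = size,
    precision = unname(inter) / n_ret,
    recall = ifelse(size > 0, unname(inter) / size, NA_real_),
    distance = unname(eg$measures$distance[ids]),
    depth = unname(eg$measures$subtree_depth[ids]),
    stringsAsFactors = FALSE)
  df <- df[order(-df$precision, df$label, df$term_id), ]
  rownames(df) <- NULL
  df
}

#' Write a term-statistics table as TSV
#'
#' @param stats data.frame from [compute_all_stats()].
#' @param path output path.
#' @export
write_stats <- function(stats, path) {
  write_tsv(stats, path)
}
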