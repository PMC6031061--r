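#' Dataset repositories
#'
#' A `repository` models a collection of datasets, each an atomic unit with
#' surrogate fields (title, ownership, sharing), a free-text description and
#' a list of attribute values. An attribute value has a name (e.g.
#' `organism`), a free-text value and optionally a direct ontology-term
#' annotation.
#'
#' Internally the repository is two data.frames: `datasets`
#' (`id, title, description, ownership, sharing`) and `annotations`
#' (`dataset_id, attribute_name, text_value, term_id`; `term_id` may be
#' `""` for annotation-free attributes).
#'
#' @param datasets data.frame with columns
#'   `id, title, description, ownership, sharing`.
#' @param annotations data.frame with columns
#'   `dataset_id, attribute_name, text_value, term_id`.
#' @return a `repository` object.
#' @export
repository <- function(datasets, annotations = NULL) {
  req <- c("id", "title", "description", "ownership", "sharing")
  missing_cols <- setdiff(req, names(datasets))
  if (length(missing_cols)) {
    onto_error(sprintf("datasets table lacks columns: %s",
                       paste(missing_cols, collapse = ", ")),
               "ontoscout_schema_error")
  }
  datasets <- datasets[req]
  for (col in req) datasets[[col]] <- as.character(datasets[[col]])
  if (anyDuplicated(datasets$id)) {
    onto_error("duplicate dataset ids in repository", "ontoscout_validation_error")
  }
  if (any(!nzchar(datasets$id))) {
    onto_error("dataset ids must be non-empty", "ontoscout_validation_error")
  }
  if (any(!nzchar(datasets$title))) {
    onto_error("dataset titles must be non-empty", "ontoscout_validation_error")
  }
  if (is.null(annotations)) {
    annotations <- data.frame(dataset_id = character(),
                              attribute_name = character(),
                              text_value = character(),
                              term_id = character(), stringsAsFactors = FALSE)
  }
  areq <- c("dataset_id", "attribute_name", "text_value", "term_id")
  missing_cols <- setdiff(areq, names(annotations))
  if (length(missing_cols)) {
    onto_error(sprintf("annotations table lacks columns: %s",
                       paste(missing_cols, collapse = ", ")),
               "ontoscout_schema_error")
  }
  annotations <- annotations[areq]
  for (col in areq) {
    annotations[[col]] <- as.character(annotations[[col]])
    annotations[[col]][is.na(annotations[[col]])] <- ""
  }
  bad <- setdiff(unique(annotations$dataset_id), datasets$id)
  if (length(bad)) {
    onto_error(sprintf("annotations reference unknown datasets: %s",
                       paste(bad, collapse = ", ")),
               "ontoscout_validation_error")
  }
  empty_attr <- !nzchar(annotations$text_value) & !nzchar(annotations$term_id)
  if (any(empty_attr)) {
    onto_error("attribute rows need a text value or a term id (or both)",
               "ontoscout_validation_error")
  }
  rownames(datasets) <- NULL
  rownames(annotations) <- NULL
  structure(list(datasets = datasets, annotations = annotations),
            class = "repository")
}

#' @export
print.repository <- function(x, ...) {
  n_ann <- sum(nzchar(x$annotations$term_id))
  cat(sprintf("<repository> %d datasets, %d attribute rows (%d term-annotated)\n",
              nrow(x$datasets), nrow(x$annotations), n_ann))
  invisible(x)
}

#' Number of datasets in a repository
#' @param repo a `repository`.
#' @export
n_datasets <- function(repo) nrow(repo$datasets)

#' Look up one dataset
#'
#' @param repo a `repository`.
#' @param id dataset id.
#' @return list with the dataset's fields and an `attributes` data.frame.
#' @export
get_dataset <- function(repo, id) {
  i <- match(id, repo$datasets$id)
  if (is.na(i)) {
    onto_error(sprintf("unknown dataset id: %s", id), "ontoscout_lookup_error")
  }
  out <- as.list(repo$datasets[i, ])
  out$attributes <- repo$annotations[repo$annotations$dataset_id == id, -1,
                                     drop = FALSE]
  rownames(out$attributes) <- NULL
  out
}

#' Read a repository manifest
#'
#' The manifest is a UTF-8 TSV (LF or CRLF) with header columns
#' `dataset_id, title, description, ownership, sharing, attribute_name,
#' text_value, term_id` and one row per attribute value (datasets repeat
#' their surrogate fields across rows; a dataset with no attributes may
#' appear as a single row with empty attribute fields). A `.json` manifest
#' with the same fields (`datasets` array, each with an `attributes` array)
#' is accepted as well.
#'
#' @param path manifest file.
#' @return a `repository`.
#' @export
load_repository <- function(path) {
  if (!file.exists(path)) {
    onto_error(sprintf("manifest not found: %s", path), "ontoscout_io_error")
  }
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- jsonlite::read_json(path)
    ds <- do.call(rbind, lapply(obj$datasets, function(d) {
      data.frame(id = d$id, title = d$title,
                 description = d$description %||% "",
                 ownership = d$ownership %||% "",
                 sharing = d$sharing %||% "", stringsAsFactors = FALSE)
    }))
    ann <- do.call(rbind, lapply(obj$datasets, function(d) {
      if (!length(d$attributes)) return(NULL)
      do.call(rbind, lapply(d$attributes, function(a) {
        data.frame(dataset_id = d$id,
                   attribute_name = a$attribute_name %||% "",
                   text_value = a$text_value %||% "",
                   term_id = a$term_id %||% "", stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(ds)) {
      ds <- data.frame(id = character(), title = character(),
                       description = character(), ownership = character(),
                       sharing = character(), stringsAsFactors = FALSE)
    }
    return(repository(ds, ann))
  }
  tab <- read_tsv(path)
  req <- c("dataset_id", "title", "description", "ownership", "sharing",
           "attribute_name", "text_value", "term_id")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    onto_error(sprintf("%s: manifest lacks required columns: %s", path,
                       paste(missing_cols, collapse = ", ")),
               "ontoscout_schema_error")
  }
  for (col in req) tab[[col]][is.na(tab[[col]])] <- ""
  ## surrogate fields must be consistent within a dataset_id
  first <- !duplicated(tab$dataset_id)
  ds <- data.frame(id = tab$dataset_id[first], title = tab$title[first],
                   description = tab$description[first],
                   ownership = tab$ownership[first],
                   sharing = tab$sharing[first], stringsAsFactors = FALSE)
  conflict <- tapply(tab$title, tab$dataset_id,
                     function(x) length(unique(x)) > 1L)
  if (any(conflict)) {
    onto_error(sprintf("conflicting titles for dataset(s): %s",
                       paste(names(conflict)[conflict], collapse = ", ")),
               "ontoscout_validation_error")
  }
  has_attr <- nzchar(tab$attribute_name) | nzchar(tab$text_value) |
    nzchar(tab$term_id)
  ann <- data.frame(dataset_id = tab$dataset_id[has_attr],
                    attribute_name = tab$attribute_name[has_attr],
                    text_value = tab$text_value[has_attr],
                    term_id = tab$term_id[has_attr], stringsAsFactors = FALSE)
  ann$term_id[nzchar(ann$term_id)] <-
    normalize_term_id(ann$term_id[nzchar(ann$term_id)])
  repository(ds, ann)
}

#' Write a repository manifest (TSV dialect)
#'
#' Inverse of [load_repository()]; datasets without attributes are written
#' as a single row with empty attribute fields.
#'
#' @param repo a `repository`.
#' @param path output TSV path.
#' @export
write_repository <- function(repo, path) {
  ds <- repo$datasets
  ann <- repo$annotations
  if (!nrow(ds)) {
    empty <- data.frame(dataset_id = character(), title = character(),
                        description = character(), ownership = character(),
                        sharing = character(), attribute_name = character(),
                        text_value = character(), term_id = character(),
                        stringsAsFactors = FALSE)
    return(write_tsv(empty, path))
  }
  rows <- lapply(ds$id, function(id) {
    d <- ds[ds$id == id, ]
    a <- ann[ann$dataset_id == id, , drop = FALSE]
    if (!nrow(a)) {
      a <- data.frame(dataset_id = id, attribute_name = "", text_value = "",
                      term_id = "", stringsAsFactors = FALSE)
    }
    data.frame(dataset_id = id, title = d$title, description = d$description,
               ownership = d$ownership, sharing = d$sharing,
               attribute_name = a$attribute_name, text_value = a$text_value,
               term_id = a$term_id, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Build the transitive annotation index
#'
#' For every ontology term `t` this computes the direct set (datasets
#' carrying `t` as an explicit annotation) and the transitive set `S_t`
#' (datasets annotated with `t` or any of its descendants) — the set
#' representation of the term. Sets are dataset sets, not multisets: a
#' dataset annotated with two subclasses of `t` counts once in `S_t`.
#'
#' Annotation terms absent from the graph do not abort the build; they are
#' collected in the `unresolved` report (`dataset_id, term_id,
#' attribute_name`) and skipped.
#'
#' @param repo a `repository`.
#' @param g the merged `ontology_graph`.
#' @return an `annotation_index`: list with `direct`, `transitive` (named
#'   lists of sorted dataset-id vectors), `universe` (all dataset ids) and
#'   `unresolved` (data.frame).
#' @export
build_annotation_index <- function(repo, g) {
  ann <- repo$annotations[nzchar(repo$annotations$term_id), , drop = FALSE]
  known <- ann$term_id %in% g$ids
  unresolved <- data.frame(dataset_id = ann$dataset_id[!known],
                           term_id = ann$term_id[!known],
                           attribute_name = ann$attribute_name[!known],
                           stringsAsFactors = FALSE)
  ann <- ann[known, , drop = FALSE]

  direct <- lapply(split(ann$dataset_id, ann$term_id), function(x) sort(unique(x)))
  ig <- as_igraph(g)
  topo <- names(igraph::topo_sort(ig, mode = "out"))  # children before parents
  ch <- graph_children(g)
  transitive <- list()
  for (t in topo) {
    s <- unlist(transitive[ch[[t]]], use.names = FALSE)
    if (!is.null(direct[[t]])) s <- c(s, direct[[t]])
    s <- sort(unique(s))
    if (length(s)) transitive[[t]] <- s  # absent entry == empty set
  }
  structure(list(direct = direct, transitive = transitive,
                 universe = sort(repo$datasets$id), unresolved = unresolved,
                 graph_terms = g$ids),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("<annotation_index> %d datasets; %d directly used terms; %d terms with non-empty S_t; %d unresolved annotation rows\n",
              length(x$universe), length(x$direct), length(x$transitive),
              nrow(x$unresolved)))
  invisible(x)
}

#' Transitive set of a term
#'
#' @param index an `annotation_index`.
#' @param term a term id.
#' @return sorted character vector of dataset ids (empty if unused).
#' @export
term_set <- function(index, term) {
  index$transitive[[term]] %||% character()
}

#' Term sizes
#'
#' The size of a term is the cardinality of its transitive dataset set
#' `|S_t|`; unused terms have size 0 (and are absent from the returned
#' vector unless named in `terms`).
#'
#' @param index an `annotation_index`.
#' @param terms optional term ids to report (defaults to all terms with
#'   non-empty sets).
#' @return named integer vector of sizes.
#' @export
term_size <- function(index, terms = NULL) {
  sizes <- vapply(index$transitive, length, integer(1))
  if (is.null(terms)) return(sizes)
  out <- stats::setNames(integer(length(terms)), terms)
  hit <- intersect(terms, names(sizes))
  out[hit] <- sizes[hit]
  out
}
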