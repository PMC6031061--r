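#' Synthetic ontologies and repositories
#'
#' The generator emulates the regime real annotated repositories live in:
#' multi-level (optionally polyhierarchic) subclass DAGs in which only a
#' small fraction of terms is ever used for annotation, and datasets
#' annotated at varying depths. Generation is deterministic given the
#' seed; fixtures are emitted as OBO + manifest TSV text and re-loaded
#' through the package's own parsers, so every run also exercises the
#' loader path.
#'
#' @param n_terms number of ontology terms (excluding the virtual root).
#' @param max_depth maximum rank (distance from root) a term may sit at.
#' @param polyhierarchy_fraction fraction of terms given a second parent.
#' @param n_datasets number of datasets.
#' @param used_term_fraction fraction of terms used for direct annotation.
#' @param annotations_per_dataset integer range `c(lo, hi)` of direct
#'   annotations per dataset.
#' @param seed RNG seed.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 60, max_depth = 6,
                         polyhierarchy_fraction = 0.15,
                         n_datasets = 40, used_term_fraction = 0.3,
                         annotations_per_dataset = c(1, 4), seed = 1) {
  spec <- list(n_terms = as.integer(n_terms), max_depth = as.integer(max_depth),
               polyhierarchy_fraction = polyhierarchy_fraction,
               n_datasets = as.integer(n_datasets),
               used_term_fraction = used_term_fraction,
               annotations_per_dataset = as.integer(annotations_per_dataset),
               seed = as.integer(seed))
  fr <- c(spec$polyhierarchy_fraction, spec$used_term_fraction)
  if (any(fr < 0 | fr > 1)) {
    onto_error("fractions must lie in [0, 1]", "ontoscout_validation_error")
  }
  if (spec$n_terms < 1 || spec$max_depth < 1 || spec$n_datasets < 0) {
    onto_error("n_terms and max_depth must be >= 1, n_datasets >= 0",
               "ontoscout_validation_error")
  }
  if (any(spec$annotations_per_dataset < 0) ||
      spec$annotations_per_dataset[2] < spec$annotations_per_dataset[1]) {
    onto_error("annotations_per_dataset must be a non-decreasing range",
               "ontoscout_validation_error")
  }
  n_used <- max(1L, round(spec$used_term_fraction * spec$n_terms))
  if (spec$used_term_fraction > 0 && n_used > spec$n_terms) {
    onto_error("more used terms requested than terms exist",
               "ontoscout_validation_error")
  }
  structure(spec, class = "fixture_spec")
}

## a small word bank for dataset titles/descriptions
.fixture_words <- c("profiling", "expression", "cells", "tissue", "cohort",
                    "study", "analysis", "treatment", "control", "primary",
                    "culture", "sequencing", "assay", "samples", "screen")

#' Generate a synthetic ontology and repository
#'
#' Random DAG construction assigns each term a rank in `1..max_depth`
#' (rank-1 terms attach to the virtual root) and samples each term's parent
#' from strictly lower ranks, which guarantees acyclicity by construction.
#' A `polyhierarchy_fraction` of terms receives a second parent. Datasets
#' draw their direct annotations from the designated used-term subset.
#'
#' @param spec a `fixture_spec`.
#' @return list with `graph` (an `ontology_graph`), `repo` (a
#'   `repository`) and `used_terms` (the term ids designated for direct
#'   annotation).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_terms
    ids <- sprintf("SYN:%04d", seq_len(n))
    labels <- sprintf("synthetic term %04d", seq_len(n))
    ranks <- sort(c(seq_len(min(spec$max_depth, n)),  # every rank inhabited
                    if (n > spec$max_depth)
                      sample(spec$max_depth, n - spec$max_depth, replace = TRUE)))
    edges <- list()
    for (i in seq_len(n)) {
      if (ranks[i] == 1L) next
      lower <- which(ranks < ranks[i])
      p1 <- lower[sample.int(length(lower), 1L)]
      edges[[length(edges) + 1L]] <-
        data.frame(child = ids[i], parent = ids[p1], stringsAsFactors = FALSE)
      if (length(lower) > 1L &&
          stats::runif(1) < spec$polyhierarchy_fraction) {
        p2 <- setdiff(lower, p1)[sample.int(length(lower) - 1L, 1L)]
        edges[[length(edges) + 1L]] <-
          data.frame(child = ids[i], parent = ids[p2], stringsAsFactors = FALSE)
      }
    }
    ## synonyms on a few terms so synonym search has something to find
    synonyms <- rep(list(character()), n)
    with_syn <- sample.int(n, max(1L, n %/% 10L))
    for (i in with_syn) synonyms[[i]] <- sprintf("alias %04d", i)

    terms <- data.frame(id = ids, label = labels, stringsAsFactors = FALSE)
    terms$synonyms <- I(synonyms)
    terms$tags <- I(rep(list("SYN"), n))
    graph <- ontology_graph(terms, do.call(rbind, edges))

    n_used <- if (spec$used_term_fraction == 0) 0L
              else max(1L, round(spec$used_term_fraction * n))
    used <- if (n_used) sort(ids[sample.int(n, n_used)]) else character()

    ds_ids <- sprintf("DS%04d", seq_len(spec$n_datasets))
    ds <- data.frame(
      id = ds_ids,
      title = vapply(ds_ids, function(d)
        paste(d, paste(sample(.fixture_words, 3), collapse = " ")), character(1)),
      description = vapply(ds_ids, function(d)
        paste(sample(.fixture_words, 6, replace = TRUE), collapse = " "),
        character(1)),
      ownership = "lab", sharing = "public", stringsAsFactors = FALSE)
    ann <- NULL
    if (length(used) && spec$n_datasets > 0 &&
        spec$annotations_per_dataset[2] > 0) {
      rng <- spec$annotations_per_dataset
      ann <- do.call(rbind, lapply(ds_ids, function(d) {
        k <- if (rng[1] == rng[2]) rng[1]
             else sample(seq(rng[1], rng[2]), 1L)
        if (k == 0L) return(NULL)
        picked <- sample(used, min(k, length(used)))
        data.frame(dataset_id = d, attribute_name = "annotation",
                   text_value = graph$labels[picked], term_id = picked,
                   stringsAsFactors = FALSE)
      }))
    }
    list(graph = graph, repo = repository(ds, ann), used_terms = used)
  })
}

#' Write a fixture to disk
#'
#' Emits `ontology.obo` and `manifest.tsv` (plus `expected.json` with a few
#' derived quantities) into `dir`. Emitting fixtures as OBO exercises the
#' same loader path that real ontologies take.
#'
#' @param fx list from [generate_fixture()] or [named_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(fx$graph, file.path(dir, "ontology.obo"))
  write_repository(fx$repo, file.path(dir, "manifest.tsv"))
  idx <- build_annotation_index(fx$repo, fx$graph)
  jsonlite::write_json(
    list(n_terms = length(fx$graph$ids) - 1L,
         n_datasets = n_datasets(fx$repo),
         n_used_terms = length(idx$transitive)),
    file.path(dir, "expected.json"), auto_unbox = TRUE)
  invisible(dir)
}

## Serialize an ontology graph as an OBO 1.4 flat file (root excluded; root
## attachment is implicit for parentless terms).
write_obo <- function(g, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.4", ""), con)
  par <- graph_parents(g)
  for (id in setdiff(g$ids, g$root)) {
    lines <- c("[Term]",
               paste0("id: ", id),
               paste0("name: ", g$labels[[id]]))
    for (s in g$synonyms[[id]]) {
      lines <- c(lines, sprintf('synonym: "%s" EXACT []', s))
    }
    for (p in setdiff(par[[id]], g$root)) {
      lines <- c(lines, paste0("is_a: ", p, " ! ", g$labels[[p]]))
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

## helper: build a fixture from term/edge/dataset tables through the
## OBO + TSV writers and the package parsers (loader round-trip)
fixture_from_tables <- function(terms, edges, datasets, annotations, tag) {
  g0 <- ontology_graph(terms, edges)
  repo0 <- repository(datasets, annotations)
  dir <- tempfile("fixture")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  write_obo(g0, file.path(dir, "ontology.obo"))
  write_repository(repo0, file.path(dir, "manifest.tsv"))
  list(graph = load_ontology(file.path(dir, "ontology.obo"), tag),
       repo = load_repository(file.path(dir, "manifest.tsv")))
}

#' Named worked-scenario fixtures
#'
#' Small, fully deterministic fixtures reproducing the canonical worked
#' scenarios used throughout the tests:
#'
#' * `mammalia_chain` — 10 datasets, all directly annotated *human*, under
#'   the chain human < Homo < Primates < Mammalia < Vertebrata; every
#'   ancestor of *human* has the identical dataset set and is absorbed by
#'   pruning.
#' * `leukocyte_scenario` — a cell-type branch (native cell with somatic,
#'   animal and precursor cell subgroups; leukocyte and its subtypes below
#'   somatic cell): 12 leukocyte-subtype datasets of which 7 also carry a
#'   precursor-cell annotation, 5 precursor-only datasets and 3
#'   organism-only datasets. No free text mentions "leukocyte", so text
#'   search alone finds nothing even though 12 annotated datasets exist.
#' * `fig5_quadrants` — 4 datasets annotated with human / hepatocyte /
#'   fibroblast / p53 / fibrosis / RNA-Seq realizing the four qualitative
#'   precision-recall cases under simple searches.
#' * `taxonomy_prune` — human / mouse / zebrafish chains below a common
#'   ancestor, with single-child equal-set inner terms that pruning must
#'   remove while keeping the branching ancestors.
#'
#' @param name one of `"mammalia_chain"`, `"leukocyte_scenario"`,
#'   `"fig5_quadrants"`, `"taxonomy_prune"`.
#' @return list with `graph` and `repo` (loaded through the OBO/TSV
#'   parsers).
#' @export
named_fixture <- function(name) {
  switch(
    name,
    mammalia_chain = fixture_mammalia(),
    leukocyte_scenario = fixture_leukocyte(),
    fig5_quadrants = fixture_fig5(),
    taxonomy_prune = fixture_taxonomy(),
    onto_error(sprintf("unknown fixture '%s'", name), "ontoscout_lookup_error")
  )
}

fixture_mammalia <- function() {
  terms <- data.frame(
    id = c("TAX:9606", "TAX:9605", "TAX:9443", "TAX:40674", "TAX:7742"),
    label = c("human", "Homo", "Primates", "Mammalia", "Vertebrata"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("TAX:9606", "TAX:9605", "TAX:9443", "TAX:40674"),
    parent = c("TAX:9605", "TAX:9443", "TAX:40674", "TAX:7742"),
    stringsAsFactors = FALSE)
  ids <- sprintf("DS%02d", 1:10)
  datasets <- data.frame(
    id = ids, title = paste("human study", 1:10),
    description = paste("expression profiling of human samples, study", 1:10),
    ownership = "lab", sharing = "public", stringsAsFactors = FALSE)
  annotations <- data.frame(
    dataset_id = ids, attribute_name = "organism", text_value = "human",
    term_id = "TAX:9606", stringsAsFactors = FALSE)
  fixture_from_tables(terms, edges, datasets, annotations, "TAX")
}

fixture_leukocyte <- function() {
  terms <- data.frame(
    id = c("CL:0000003", "CL:0002371", "CL:0000548", "CL:0000011",
           "CL:0000738", "CL:0000084", "CL:0000236", "CL:0000235",
           "CL:0000037", "TAX:10090"),
    label = c("native cell", "somatic cell", "animal cell", "precursor cell",
              "leukocyte", "T cell", "B cell", "macrophage",
              "hematopoietic stem cell", "mouse"),
    stringsAsFactors = FALSE)
  terms$synonyms <- I(list(character(), character(), character(), character(),
                           character(), character(), character(), character(),
                           character(), "mice"))
  edges <- data.frame(
    child = c("CL:0002371", "CL:0000548", "CL:0000011", "CL:0000738",
              "CL:0000738", "CL:0000084", "CL:0000236", "CL:0000235",
              "CL:0000037"),
    parent = c("CL:0000003", "CL:0000003", "CL:0000003", "CL:0002371",
               "CL:0000548", "CL:0000738", "CL:0000738", "CL:0000738",
               "CL:0000011"),
    stringsAsFactors = FALSE)
  subtype <- rep(c("CL:0000084", "CL:0000236", "CL:0000235"), length.out = 12)
  subtype_label <- c("CL:0000084" = "T cell", "CL:0000236" = "B cell",
                     "CL:0000235" = "macrophage")
  ids <- sprintf("DS%02d", 1:20)
  datasets <- data.frame(
    id = ids,
    title = c(paste("immune cell study", 1:12),
              paste("stem cell study", 1:5),
              paste("organism survey", 1:3)),
    description = c(
      paste("profiling of", subtype_label[subtype],
            "populations in mice, replicate", 1:12),
      paste("hematopoietic stem cell differentiation time course", 1:5),
      paste("whole-organism expression atlas in mouse, part", 1:3)),
    ownership = "lab", sharing = "public", stringsAsFactors = FALSE)
  ann <- rbind(
    data.frame(dataset_id = ids[1:12], attribute_name = "cell type",
               text_value = unname(subtype_label[subtype]), term_id = subtype,
               stringsAsFactors = FALSE),
    ## 7 of the 12 leukocyte datasets also carry a precursor-cell annotation
    data.frame(dataset_id = ids[1:7], attribute_name = "cell type",
               text_value = "hematopoietic stem cell", term_id = "CL:0000037",
               stringsAsFactors = FALSE),
    data.frame(dataset_id = ids[13:17], attribute_name = "cell type",
               text_value = "hematopoietic stem cell", term_id = "CL:0000037",
               stringsAsFactors = FALSE),
    data.frame(dataset_id = ids, attribute_name = "organism",
               text_value = "mouse", term_id = "TAX:10090",
               stringsAsFactors = FALSE))
  fixture_from_tables(terms, edges, datasets, ann, "CL")
}

fixture_fig5 <- function() {
  terms <- data.frame(
    id = c("TAX:9606", "CL:0000182", "CL:0000057", "GENE:TP53",
           "DOID:3770", "OBI:0001271"),
    label = c("human", "hepatocyte", "fibroblast", "p53", "fibrosis",
              "RNA-Seq"),
    stringsAsFactors = FALSE)
  edges <- NULL  # flat: all six attach to the virtual root
  ids <- sprintf("DS%d", 1:4)
  datasets <- data.frame(
    id = ids,
    title = c("human hepatocyte p53 RNA-Seq study",
              "human fibroblast p53 RNA-Seq study A",
              "human fibroblast p53 RNA-Seq study B",
              "human fibroblast fibrosis microarray study"),
    description = c(
      "p53 binding in human hepatocyte cultures assayed by RNA-Seq",
      "p53 pathway activity in human fibroblast lines by RNA-Seq",
      "p53 knockdown in human fibroblast culture profiled with RNA-Seq",
      "fibrosis progression markers in human fibroblast biopsies"),
    ownership = "lab", sharing = "public", stringsAsFactors = FALSE)
  mk <- function(ds, attr, label, term)
    data.frame(dataset_id = ds, attribute_name = attr, text_value = label,
               term_id = term, stringsAsFactors = FALSE)
  ann <- rbind(
    mk(ids, "organism", "human", "TAX:9606"),
    mk(ids[1], "cell type", "hepatocyte", "CL:0000182"),
    mk(ids[2:4], "cell type", "fibroblast", "CL:0000057"),
    mk(ids[1:3], "gene", "p53", "GENE:TP53"),
    mk(ids[4], "disease", "fibrosis", "DOID:3770"),
    mk(ids[1:3], "technology", "RNA-Seq", "OBI:0001271"))
  fixture_from_tables(terms, edges, datasets, ann, "MIX")
}

fixture_taxonomy <- function() {
  ## chains below the last common ancestor with collapsible inner terms:
  ## euteleostomi > Mammalia > Euarchontoglires > Primates > human
  ##                         > Rodentia > Mus > mouse
  ##              > Actinopterygii > Danio > zebrafish
  terms <- data.frame(
    id = c("TAX:117571", "TAX:40674", "TAX:314146", "TAX:9443", "TAX:9606",
           "TAX:9989", "TAX:10088", "TAX:10090",
           "TAX:7898", "TAX:7954", "TAX:7955"),
    label = c("Euteleostomi", "Mammalia", "Euarchontoglires", "Primates",
              "human", "Rodentia", "Mus", "mouse",
              "Actinopterygii", "Danio", "zebrafish"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("TAX:40674", "TAX:314146", "TAX:9443", "TAX:9606",
              "TAX:9989", "TAX:10088", "TAX:10090",
              "TAX:7898", "TAX:7954", "TAX:7955"),
    parent = c("TAX:117571", "TAX:40674", "TAX:314146", "TAX:9443",
               "TAX:40674", "TAX:9989", "TAX:10088",
               "TAX:117571", "TAX:7898", "TAX:7954"),
    stringsAsFactors = FALSE)
  org <- c(rep("TAX:9606", 5), rep("TAX:10090", 4), rep("TAX:7955", 3))
  lab <- c("TAX:9606" = "human", "TAX:10090" = "mouse", "TAX:7955" = "zebrafish")
  ids <- sprintf("DS%02d", seq_along(org))
  datasets <- data.frame(
    id = ids, title = paste(lab[org], "study", seq_along(org)),
    description = paste("expression study in", lab[org]),
    ownership = "lab", sharing = "public", stringsAsFactors = FALSE)
  annotations <- data.frame(
    dataset_id = ids, attribute_name = "organism",
    text_value = unname(lab[org]), term_id = org, stringsAsFactors = FALSE)
  fixture_from_tables(terms, edges, datasets, annotations, "TAX")
}
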