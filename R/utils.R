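## Internal helpers shared across modules.

#' @keywords internal
onto_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ontoscout_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Tokenize free text
#'
#' Lowercases and splits on non-alphanumeric characters. No stemming; the
#' result is deterministic and locale-independent, which keeps search
#' behaviour predictable across systems.
#'
#' @param x character vector.
#' @return list of character vectors, one per element of `x`.
#' @keywords internal
tokenize <- function(x) {
  x <- tolower(as.character(x))
  out <- strsplit(x, "[^a-z0-9]+")
  lapply(out, function(tok) tok[nzchar(tok)])
}

#' Default CURIE prefix map
#'
#' Maps common OBO Library / OLS IRI stems to CURIE prefixes. Users can extend
#' or override this via the `prefix_map` argument of the loaders.
#'
#' @return named character vector, names are IRI stems, values CURIE prefixes.
#' @export
default_prefix_map <- function() {
  c(
    "http://purl.obolibrary.org/obo/" = "obo",
    "http://www.ebi.ac.uk/efo/" = "EFO",
    "http://www.w3.org/2002/07/owl#" = "OWL"
  )
}

#' Normalize a term identifier to CURIE form
#'
#' Identifiers already in `PREFIX:LOCALID` form are returned unchanged. Full
#' IRIs are mapped through the prefix map; OBO-style IRIs
#' (`.../obo/GO_0008150`) become `GO:0008150`. Unknown IRIs fall back to the
#' full IRI so that identity is never lost. Normalization is idempotent.
#'
#' @param ids character vector of CURIEs or IRIs.
#' @param prefix_map named character vector, see [default_prefix_map()].
#' @return character vector of normalized ids.
#' @export
normalize_term_id <- function(ids, prefix_map = default_prefix_map()) {
  ids <- as.character(ids)
  if (any(!nzchar(ids))) {
    onto_error("term identifiers must be non-empty", "ontoscout_id_error")
  }
  is_iri <- grepl("^https?://", ids)
  out <- ids
  if (any(is_iri)) {
    out[is_iri] <- vapply(ids[is_iri], function(iri) {
      for (stem in names(prefix_map)) {
        if (startsWith(iri, stem)) {
          local <- substring(iri, nchar(stem) + 1L)
          if (prefix_map[[stem]] == "obo") {
            # OBO Library pattern: PREFIX_LOCALID after the stem
            if (grepl("^[A-Za-z]+_[^_]+", local)) {
              return(sub("_", ":", local))
            }
            return(iri)
          }
          return(paste0(prefix_map[[stem]], ":", local))
        }
      }
      iri
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

## Stable set helpers: results sorted so downstream output is deterministic.
sorted_union <- function(...) sort(unique(c(...)))

## write a data.frame as UTF-8 TSV with header, LF endings
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
}

## Run an expression with a locally-seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
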