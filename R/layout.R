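#' Layout geometry for the exploration view
#'
#' Both visualizations are computed as pure geometry/ordering data so any
#' renderer (SVG, canvas, print) can draw them; no pixels are produced
#' here.
#'
#' * The treemap tiles the unit square with one rectangle per term; sibling
#'   areas are proportional to term sizes *relative to the sibling group*
#'   (not to the root — a term under two parents is tiled under each), and
#'   the color level of a rectangle is the term's subtree depth, so darker
#'   tiles promise deeper structure underneath.
#' * The node-link layout places terms in columns indexed by their distance
#'   to the root in the pruned graph, sorts each column (precision
#'   descending by default) and counts links whose partner falls outside
#'   the visible window.
#'
#' Coordinates are in the unit square, origin top-left, y growing downward,
#' rectangles half-open `[x, x+w) x [y, y+h)`.
#'
#' @name layout
NULL

#' Squarified treemap layout
#'
#' Tiles the unit square with the retained children of `root`, recursing to
#' `depth` levels. Sibling rectangles get area proportional to term size
#' within the sibling group (sizes are normalized by the sibling sum, which
#' with polyhierarchy overlap means areas are comparable among siblings but
#' not across the whole plot). Uses the squarified algorithm: siblings are
#' laid out in size-descending order (ties by label then id) into rows,
#' each row accepted while it does not worsen the worst aspect ratio.
#' Terminal rectangles (no children at the next level) are flagged
#' `terminal` — the renderer draws them without a border.
#'
#' @param eg an `exploration_graph`.
#' @param root term to root the treemap at (default: the virtual root).
#' @param depth number of visible levels (>= 1).
#' @return a `treemap_layout`: list with `root_term`, `visible_depth`,
#'   `breadcrumb` and `nodes` (nested list of nodes with `term`, `label`,
#'   `rect = c(x, y, w, h)`, `area_fraction`, `color_level`, `terminal`,
#'   `children`).
#' @export
treemap_layout <- function(eg, root = NULL, depth = 2L) {
  root <- root %||% eg$graph$root
  if (!root %in% eg$graph$ids) {
    onto_error(sprintf("unknown treemap root '%s'", root), "ontoscout_layout_error")
  }
  if (depth < 1L) {
    onto_error("treemap depth must be >= 1", "ontoscout_layout_error")
  }
  if (root != eg$graph$root && !is.na(eg$sizes[root]) && eg$sizes[root] == 0) {
    onto_error(sprintf("cannot root the treemap at size-0 term '%s'", root),
               "ontoscout_layout_error")
  }
  ch <- graph_children(eg$graph)
  build <- function(term, rect, frac, level) {
    node <- list(term = term, label = unname(eg$graph$labels[[term]]),
                 rect = rect, area_fraction = frac,
                 color_level = unname(eg$measures$subtree_depth[[term]]),
                 terminal = length(ch[[term]]) == 0L,
                 children = list())
    if (level < depth && length(ch[[term]])) {
      kids <- ch[[term]]
      sizes <- eg$sizes[kids]
      ord <- order(-sizes, eg$graph$labels[kids], kids)
      kids <- kids[ord]; sizes <- as.numeric(sizes[ord])
      keep <- sizes > 0
      kids <- kids[keep]; sizes <- sizes[keep]
      if (length(kids)) {
        fr <- sizes / sum(sizes)
        rects <- squarify(fr, rect)
        node$children <- lapply(seq_along(kids), function(i)
          build(kids[i], rects[[i]], fr[i], level + 1L))
      }
    }
    node
  }
  structure(list(root_term = root, visible_depth = as.integer(depth),
                 breadcrumb = breadcrumb_path(root, eg),
                 nodes = build(root, c(x = 0, y = 0, w = 1, h = 1), 1.0, 0L)),
            class = "treemap_layout")
}

#' @export
print.treemap_layout <- function(x, ...) {
  count <- function(n) 1L + sum(vapply(n$children, count, integer(1)))
  cat(sprintf("<treemap_layout> root %s, depth %d, %d rectangles\n",
              x$root_term, x$visible_depth, count(x$nodes) - 1L))
  invisible(x)
}

## Squarified tiling (Bruls, Huizing & van Wijk): lay fractions (summing to
## 1, descending) into rows along the shorter side of the remaining
## rectangle; a row is closed when adding the next item would worsen its
## worst aspect ratio. Returns a list of c(x, y, w, h) covering `rect`
## exactly.
squarify <- function(fracs, rect) {
  total_area <- rect[["w"]] * rect[["h"]]
  areas <- fracs * total_area
  rects <- vector("list", length(areas))
  i <- 1L
  x <- rect[["x"]]; y <- rect[["y"]]; w <- rect[["w"]]; h <- rect[["h"]]
  worst <- function(row, side) {
    s <- sum(row)
    mx <- max(row); mn <- min(row)
    max(side^2 * mx / s^2, s^2 / (side^2 * mn))
  }
  idx <- 1L
  while (idx <= length(areas)) {
    side <- min(w, h)
    row <- areas[idx]
    j <- idx + 1L
    while (j <= length(areas) &&
           worst(c(row, areas[j]), side) <= worst(row, side)) {
      row <- c(row, areas[j]); j <- j + 1L
    }
    s <- sum(row)
    if (w >= h) {
      ## vertical strip of width s/h on the left
      strip_w <- s / h
      yy <- y
      for (a in row) {
        hh <- a / strip_w
        rects[[i]] <- c(x = x, y = yy, w = strip_w, h = hh)
        yy <- yy + hh; i <- i + 1L
      }
      x <- x + strip_w; w <- w - strip_w
    } else {
      strip_h <- s / w
      xx <- x
      for (a in row) {
        ww <- a / strip_h
        rects[[i]] <- c(x = xx, y = y, w = ww, h = strip_h)
        xx <- xx + ww; i <- i + 1L
      }
      y <- y + strip_h; h <- h - strip_h
    }
    idx <- j
  }
  rects
}

#' Layered node-link layout
#'
#' Places every retained term in the column given by its distance to the
#' root in the pruned graph, orders each column by the sort key (numeric
#' keys descending, `name` ascending; ties by label then id), attaches the
#' precision/recall bar values from the statistics table, and counts, for
#' each visible term, the incoming (parent-side) and outgoing (child-side)
#' links whose partner lies outside the visible window.
#'
#' @param eg an `exploration_graph`.
#' @param stats data.frame from [compute_all_stats()].
#' @param sort_key one of `"precision"`, `"recall"`, `"name"`, `"size"`
#'   (default `"precision"`, the most informative initial ordering since
#'   recall starts out at 1 for the whole repository).
#' @param window optional list/vector `(first_column, n_columns,
#'   rows_per_column)` defining the visible area; default shows everything.
#' @return a `nodelink_layout`: list with `columns` (list of ordered term
#'   id vectors, index = distance), `sort_key`, `bars` (data.frame
#'   `term_id, precision, recall`), `hidden_links` (data.frame
#'   `term_id, hidden_in, hidden_out`) and `window`.
#' @export
nodelink_layout <- function(eg, stats, sort_key = "precision", window = NULL) {
  keys <- c("precision", "recall", "name", "size")
  if (!sort_key %in% keys) {
    onto_error(sprintf("unknown sort key '%s' (use one of %s)", sort_key,
                       paste(keys, collapse = ", ")),
               "ontoscout_layout_error")
  }
  ids <- retained_terms(eg)
  dist <- eg$measures$distance[ids]
  srow <- stats[match(ids, stats$term_id), ]
  keyval <- switch(sort_key,
                   precision = -srow$precision,
                   recall = -srow$recall,
                   size = -as.numeric(eg$sizes[ids]),
                   name = NULL)
  labs <- unname(eg$graph$labels[ids])
  ord <- if (is.null(keyval)) order(labs, ids) else order(keyval, labs, ids)
  ids_o <- ids[ord]; dist_o <- dist[ord]
  max_d <- if (length(ids)) max(dist_o) else 0L
  columns <- lapply(seq_len(max_d), function(d) ids_o[dist_o == d])

  if (is.null(window)) {
    window <- c(first_column = 1L, n_columns = max(1L, max_d),
                rows_per_column = max(1L, max(c(1L, lengths(columns)))))
  } else {
    window <- stats::setNames(as.integer(window[1:3]),
                              c("first_column", "n_columns", "rows_per_column"))
  }
  visible <- character()
  last_col <- min(max_d, window[["first_column"]] + window[["n_columns"]] - 1L)
  vis_cols <- if (last_col >= window[["first_column"]])
    seq(window[["first_column"]], last_col) else integer()
  vis_cols <- vis_cols[vis_cols >= 1L]
  for (d in vis_cols) {
    visible <- c(visible, utils::head(columns[[d]], window[["rows_per_column"]]))
  }
  e <- eg$graph$edges
  e <- e[e$parent != eg$graph$root, , drop = FALSE]
  hid <- do.call(rbind, lapply(visible, function(t) {
    parents <- e$parent[e$child == t]
    children <- e$child[e$parent == t]
    data.frame(term_id = t,
               hidden_in = sum(!parents %in% visible),
               hidden_out = sum(!children %in% visible),
               stringsAsFactors = FALSE)
  }))
  if (is.null(hid)) {
    hid <- data.frame(term_id = character(), hidden_in = integer(),
                      hidden_out = integer(), stringsAsFactors = FALSE)
  }
  structure(list(
    columns = columns, sort_key = sort_key,
    bars = data.frame(term_id = ids_o,
                      precision = srow$precision[ord],
                      recall = srow$recall[ord], stringsAsFactors = FALSE),
    hidden_links = hid, window = window
  ), class = "nodelink_layout")
}

#' @export
print.nodelink_layout <- function(x, ...) {
  cat(sprintf("<nodelink_layout> %d columns (sorted by %s), %d terms\n",
              length(x$columns), x$sort_key, sum(lengths(x$columns))))
  invisible(x)
}

#' Breadcrumb path from the absolute root to a term
#'
#' The shortest retained path from the virtual root to the term (ties
#' between equal-length paths broken lexicographically by parent id), with
#' the ancestors each retained term absorbed during pruning interleaved as
#' display-only entries — so the breadcrumb shows the full ontological
#' lineage even where the containment hierarchy was collapsed.
#'
#' @param term a retained term id.
#' @param eg an `exploration_graph`.
#' @return data.frame with columns `term_id`, `label`, `display_only`
#'   (TRUE for absorbed ancestors), ordered root first.
#' @export
breadcrumb_path <- function(term, eg) {
  g <- eg$graph
  if (!term %in% g$ids) {
    onto_error(sprintf("unknown term '%s'", term), "ontoscout_layout_error")
  }
  par <- graph_parents(g)
  ## walk upward choosing, among parents of minimal distance, the
  ## lexicographically smallest — yields the unique shortest path chosen
  ## deterministically
  path <- term
  cur <- term
  while (cur != g$root) {
    ps <- par[[cur]]
    d <- eg$measures$distance[ps]
    best <- sort(ps[d == min(d)])[1]
    path <- c(best, path)
    cur <- best
  }
  rows <- list()
  for (t in path) {
    prov <- eg$provenance[[t]] %||% character()
    ## provenance is stored nearest-absorbed-first; display root-ward first
    for (p in rev(prov)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = p, label = p, display_only = TRUE, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = t, label = unname(g$labels[[t]]), display_only = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a layout to JSON
#'
#' Writes treemap or node-link layouts as JSON with stable key order, for
#' consumption by renderers.
#'
#' @param layout a `treemap_layout` or `nodelink_layout`.
#' @param path output path.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(unclass_deep(layout), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
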