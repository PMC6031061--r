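collect_nodes <- function(node) {
  c(list(node), do.call(c, lapply(node$children, collect_nodes)))
}

test_that("sibling areas are proportional to term sizes", {
  ## three siblings sized 2,1,1 under one parent
  terms <- data.frame(id = c("T:a", "T:b", "T:c"),
                      label = c("alpha", "beta", "gamma"),
                      stringsAsFactors = FALSE)
  g <- ontology_graph(terms)
  ds <- data.frame(id = sprintf("D%d", 1:4), title = "t", description = "",
                   ownership = "", sharing = "", stringsAsFactors = FALSE)
  ann <- data.frame(dataset_id = ds$id, attribute_name = "x", text_value = "v",
                    term_id = c("T:a", "T:a", "T:b", "T:c"),
                    stringsAsFactors = FALSE)
  b <- build_exploration_graph(g, repository(ds, ann))
  tm <- treemap_layout(b$eg, depth = 1)
  kids <- tm$nodes$children
  fr <- stats::setNames(vapply(kids, `[[`, numeric(1), "area_fraction"),
                        vapply(kids, `[[`, character(1), "term"))
  expect_equal(unname(fr[c("T:a", "T:b", "T:c")]), c(0.5, 0.25, 0.25))
  areas <- vapply(kids, function(k) k$rect[["w"]] * k$rect[["h"]], numeric(1))
  expect_equal(sort(areas, decreasing = TRUE), c(0.5, 0.25, 0.25))
})

test_that("a single child tiles its parent exactly, at area fraction 1", {
  fx <- named_fixture("mammalia_chain")
  b <- build_exploration_graph(fx$graph, fx$repo)
  tm <- treemap_layout(b$eg, depth = 1)
  expect_length(tm$nodes$children, 1L)
  expect_equal(tm$nodes$children[[1]]$area_fraction, 1.0)
  expect_equal(unname(tm$nodes$children[[1]]$rect), c(0, 0, 1, 1))
})

test_that("the treemap recurses to exactly the requested depth", {
  fx <- named_fixture("taxonomy_prune")  # 3 retained levels below the root
  b <- build_exploration_graph(fx$graph, fx$repo)
  depth_of <- function(node) {
    if (!length(node$children)) return(0L)
    1L + max(vapply(node$children, depth_of, integer(1)))
  }
  tm2 <- treemap_layout(b$eg, depth = 2)
  expect_identical(depth_of(tm2$nodes), 2L)
  tm1 <- treemap_layout(b$eg, depth = 1)
  expect_identical(depth_of(tm1$nodes), 1L)
  expect_error(treemap_layout(b$eg, depth = 0), class = "ontoscout_layout_error")
  expect_error(treemap_layout(b$eg, root = "TAX:none"),
               class = "ontoscout_layout_error")
})

test_that("child rectangles tile their parent within 1e-9", {
  for (seed in c(2, 9, 14)) {
    fx <- random_fixture(seed, n_terms = 40, n_datasets = 30)
    b <- build_exploration_graph(fx$graph, fx$repo)
    tm <- treemap_layout(b$eg, depth = 3)
    check <- function(node) {
      if (!length(node$children)) return(invisible())
      pr <- node$rect
      areas <- vapply(node$children, function(k)
        k$rect[["w"]] * k$rect[["h"]], numeric(1))
      expect_equal(sum(areas), pr[["w"]] * pr[["h"]], tolerance = 1e-9)
      ## children stay inside the parent
      for (k in node$children) {
        expect_gte(k$rect[["x"]], pr[["x"]] - 1e-9)
        expect_gte(k$rect[["y"]], pr[["y"]] - 1e-9)
        expect_lte(k$rect[["x"]] + k$rect[["w"]], pr[["x"]] + pr[["w"]] + 1e-9)
        expect_lte(k$rect[["y"]] + k$rect[["h"]], pr[["y"]] + pr[["h"]] + 1e-9)
      }
      ## no pairwise overlap
      n <- length(node$children)
      if (n > 1) {
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
          a <- node$children[[i]]$rect; bb <- node$children[[j]]$rect
          ox <- min(a[["x"]] + a[["w"]], bb[["x"]] + bb[["w"]]) -
            max(a[["x"]], bb[["x"]])
          oy <- min(a[["y"]] + a[["h"]], bb[["y"]] + bb[["h"]]) -
            max(a[["y"]], bb[["y"]])
          expect_true(ox <= 1e-9 || oy <= 1e-9)
        }
      }
      for (k in node$children) check(k)
    }
    check(tm$nodes)
  }
})

test_that("squarified rows are no worse than a plain slice layout", {
  worst_aspect <- function(rects) {
    max(vapply(rects, function(r) max(r[["w"]] / r[["h"]], r[["h"]] / r[["w"]]),
               numeric(1)))
  }
  fr <- c(6, 5, 4, 3, 2, 1) / 21
  sq <- ontoscout:::squarify(fr, c(x = 0, y = 0, w = 1, h = 1))
  slice <- lapply(cumsum(c(0, fr[-length(fr)])), function(x0) NULL)
  slice <- lapply(seq_along(fr), function(i)
    c(x = sum(fr[seq_len(i - 1)]), y = 0, w = fr[i], h = 1))
  expect_lte(worst_aspect(sq), worst_aspect(slice))
  ## color level is the subtree depth of the term
  fx <- named_fixture("taxonomy_prune")
  b <- build_exploration_graph(fx$graph, fx$repo)
  tm <- treemap_layout(b$eg, depth = 3)
  for (node in collect_nodes(tm$nodes)) {
    expect_identical(node$color_level,
                     unname(b$eg$measures$subtree_depth[node$term]))
  }
})

test_that("node-link columns partition terms by pruned-graph distance", {
  fx <- random_fixture(4)
  b <- build_exploration_graph(fx$graph, fx$repo)
  st <- compute_all_stats(result_set(fx$repo$datasets$id), b$eg, b$index)
  nl <- nodelink_layout(b$eg, st)
  placed <- unlist(nl$columns)
  expect_setequal(placed, retained_terms(b$eg))
  for (d in seq_along(nl$columns)) {
    for (t in nl$columns[[d]]) {
      expect_identical(unname(b$eg$measures$distance[t]), d)
    }
  }
  ## default sort: precision descending within each column
  for (col in nl$columns) {
    p <- st$precision[match(col, st$term_id)]
    expect_true(all(diff(p) <= 0))
  }
  expect_identical(nl$sort_key, "precision")
  expect_error(nodelink_layout(b$eg, st, sort_key = "bogus"),
               class = "ontoscout_layout_error")
})

test_that("hidden-link counts match a brute-force edge scan", {
  fx <- named_fixture("taxonomy_prune")
  b <- build_exploration_graph(fx$graph, fx$repo)
  st <- compute_all_stats(result_set(fx$repo$datasets$id), b$eg, b$index)
  ## full window: no hidden links
  nl <- nodelink_layout(b$eg, st)
  expect_true(all(nl$hidden_links$hidden_in == 0))
  expect_true(all(nl$hidden_links$hidden_out == 0))
  ## hide the last column: every edge into it must be counted at its
  ## visible partner
  nl2 <- nodelink_layout(b$eg, st, window = c(1, 2, 10))
  visible <- unlist(nl2$columns[1:2])
  e <- b$eg$graph$edges
  e <- e[e$parent != b$eg$graph$root, , drop = FALSE]
  for (i in seq_len(nrow(nl2$hidden_links))) {
    t <- nl2$hidden_links$term_id[i]
    expect_identical(nl2$hidden_links$hidden_out[i],
                     sum(e$parent == t & !(e$child %in% visible)))
    expect_identical(nl2$hidden_links$hidden_in[i],
                     sum(e$child == t & !(e$parent %in% visible)))
  }
  total_hidden <- sum(nl2$hidden_links$hidden_out) +
    sum(nl2$hidden_links$hidden_in)
  crossing <- sum(xor(e$child %in% visible, e$parent %in% visible))
  expect_identical(total_hidden, crossing)
})

test_that("breadcrumbs run root-first and interleave absorbed ancestors", {
  fx <- named_fixture("taxonomy_prune")
  b <- build_exploration_graph(fx$graph, fx$repo)
  ## term at distance 1 -> [root, term]
  bc <- breadcrumb_path("TAX:117571", b$eg)
  expect_identical(bc$term_id[!bc$display_only],
                   c("OWL:Thing", "TAX:117571"))
  ## absorbed lineage of human appears as display-only entries, in
  ## root-ward order
  bch <- breadcrumb_path("TAX:9606", b$eg)
  expect_identical(bch$term_id[!bch$display_only],
                   c("OWL:Thing", "TAX:117571", "TAX:40674", "TAX:9606"))
  expect_identical(bch$term_id[bch$display_only],
                   c("TAX:314146", "TAX:9443"))
  ## display-only ancestors directly precede the term that absorbed them
  expect_identical(utils::tail(bch$term_id, 3),
                   c("TAX:314146", "TAX:9443", "TAX:9606"))
  expect_error(breadcrumb_path("TAX:none", b$eg),
               class = "ontoscout_layout_error")
})

test_that("diamond breadcrumbs take the shortest path, ties lexicographic", {
  terms <- data.frame(id = c("T:a", "T:b", "T:d"), label = c("a", "b", "d"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = c("T:d", "T:d"), parent = c("T:a", "T:b"),
                      stringsAsFactors = FALSE)
  g <- ontology_graph(terms, edges)
  ds <- data.frame(id = c("D1", "D2", "D3"), title = "t", description = "",
                   ownership = "", sharing = "", stringsAsFactors = FALSE)
  ann <- data.frame(dataset_id = ds$id, attribute_name = "x", text_value = "v",
                    term_id = c("T:d", "T:a", "T:b"), stringsAsFactors = FALSE)
  b <- build_exploration_graph(g, repository(ds, ann))
  bc <- breadcrumb_path("T:d", b$eg)
  ## both paths have length 2; the lexicographically smaller parent wins
  expect_identical(bc$term_id, c("OWL:Thing", "T:a", "T:d"))
})

test_that("layouts serialize to JSON", {
  fx <- named_fixture("taxonomy_prune")
  b <- build_exploration_graph(fx$graph, fx$repo)
  st <- compute_all_stats(result_set(fx$repo$datasets$id), b$eg, b$index)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_layout(treemap_layout(b$eg, depth = 2), p1)
  write_layout(nodelink_layout(b$eg, st), p2)
  expect_true(jsonlite::validate(paste(readLines(p1), collapse = "\n")))
  expect_true(jsonlite::validate(paste(readLines(p2), collapse = "\n")))
})
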