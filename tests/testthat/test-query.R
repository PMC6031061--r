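leuko <- local({
  fx <- named_fixture("leukocyte_scenario")
  b <- build_exploration_graph(fx$graph, fx$repo)
  list(fx = fx, eg = b$eg, idx = b$index)
})

test_that("synonym expansion lets 'mouse' match descriptions saying only 'mice'", {
  repo <- repository(
    data.frame(id = "D1", title = "immune atlas",
               description = "profiling of splenocytes in mice",
               ownership = "", sharing = "", stringsAsFactors = FALSE),
    data.frame(dataset_id = "D1", attribute_name = "organism",
               text_value = "", term_id = "TAX:10090", stringsAsFactors = FALSE))
  terms <- data.frame(id = "TAX:10090", label = "mouse", stringsAsFactors = FALSE)
  terms$synonyms <- I(list("mice"))
  g <- ontology_graph(terms)
  hit <- text_search(text_query("mouse", expand_synonyms = TRUE), repo, g)
  expect_identical(hit$ids, "D1")
  miss <- text_search(text_query("mouse", expand_synonyms = FALSE), repo, g)
  expect_length(miss, 0L)
})

test_that("text search is conjunctive, ranked, and returns all on empty query", {
  fx <- named_fixture("fig5_quadrants")
  expect_identical(text_search("", fx$repo, fx$graph)$ids,
                   sort(fx$repo$datasets$id))
  ## conjunctive: all tokens must match
  expect_identical(text_search("human hepatocyte p53", fx$repo, fx$graph)$ids,
                   "DS1")
  ## a token found nowhere in free text retrieves nothing, even though
  ## annotated subtypes exist
  expect_length(text_search("leukocyte", leuko$fx$repo, leuko$fx$graph), 0L)
  ## deterministic tie-break by id
  r <- text_search("human", fx$repo, fx$graph)
  expect_identical(r$ids, sort(r$ids)[order(-r$scores[sort(r$ids)],
                                            sort(r$ids))])
})

test_that("KWIC snippets mark the match and respect boundaries", {
  d <- list(title = "study", description = paste(
    "long preamble text before the keyword appears somewhere in the middle",
    "of this description and then trails on"), attributes = data.frame(
      text_value = character()))
  s <- kwic_snippet(d, "keyword", window = 10)
  expect_match(s, "\\[keyword\\]")
  expect_true(startsWith(s, "…"))
  expect_true(endsWith(s, "…"))
  ## match at string start: no leading ellipsis
  d2 <- list(title = "keyword first here", description = "",
             attributes = data.frame(text_value = character()))
  s2 <- kwic_snippet(d2, "keyword", window = 5)
  expect_false(startsWith(s2, "…"))
  expect_true(startsWith(s2, "[keyword]"))
  ## no match -> empty snippet
  expect_identical(kwic_snippet(d2, "absent"), "")
  ## synonym match centers the synonym token, verified against a naive scan
  terms <- data.frame(id = "TAX:10090", label = "mouse", stringsAsFactors = FALSE)
  terms$synonyms <- I(list("mice"))
  g <- ontology_graph(terms)
  d3 <- list(title = "atlas", description = "profiled in mice at scale",
             attributes = data.frame(text_value = character()))
  s3 <- kwic_snippet(d3, text_query("mouse"), window = 50, g = g)
  expect_match(s3, "\\[mice\\]", fixed = FALSE)
  naive_pos <- regexpr("mice", d3$description, fixed = TRUE)
  expect_identical(sub("\\].*$", "", sub("^.*\\[", "", s3)),
                   substr(d3$description, naive_pos, naive_pos + 3))
})

test_that("Boolean term queries implement the documented set algebra", {
  idx <- leuko$idx
  ## and native cell, not precursor cell -> the five native-not-precursor sets
  r <- evaluate_term_query(term_query(and = "CL:0000003", not = "CL:0000011"), idx)
  expect_length(r, 5L)
  expect_identical(r$ids, sprintf("DS%02d", 8:12))
  ## leukocyte alone -> all 12
  expect_length(evaluate_term_query(term_query(and = "CL:0000738"), idx), 12L)
  ## empty query -> whole universe
  expect_identical(evaluate_term_query(term_query(), idx)$ids, idx$universe)
  ## unresolvable term errors by name
  err <- expect_error(evaluate_term_query(term_query(and = "CL:none"), idx),
                      class = "ontoscout_query_error")
  expect_match(conditionMessage(err), "CL:none")
  ## not-only query = universe minus union of not-sets
  rn <- evaluate_term_query(term_query(not = "CL:0000011"), idx)
  expect_setequal(rn$ids, setdiff(idx$universe, term_set(idx, "CL:0000011")))
})

test_that("term-query evaluation matches exhaustive per-dataset predicates", {
  for (seed in 1:8) {
    fx <- random_fixture(seed, n_datasets = 20)
    idx <- build_annotation_index(fx$repo, fx$graph)
    used <- names(idx$transitive)
    if (length(used) < 4) next
    set.seed(seed)
    picks <- sample(used, 4)
    tq <- term_query(or = picks[1:2], and = picks[3], not = picks[4])
    expect_identical(evaluate_term_query(tq, idx)$ids,
                     oracle_term_query(tq, fx$repo, fx$graph))
    tq2 <- term_query(or = picks[1:2])
    expect_identical(evaluate_term_query(tq2, idx)$ids,
                     oracle_term_query(tq2, fx$repo, fx$graph))
  }
})

test_that("query states cycle none -> or -> and -> not -> none", {
  tq <- term_query()
  t1 <- toggle_query_state("T:x", tq)
  expect_identical(t1$or, "T:x")
  t2 <- toggle_query_state("T:x", t1)
  expect_identical(t2$and, "T:x")
  t3 <- toggle_query_state("T:x", t2)
  expect_identical(t3$not, "T:x")
  t4 <- toggle_query_state("T:x", t3)
  expect_identical(t4, tq)  # cycle of length 4
  expect_error(term_query(or = "T:x", and = "T:x"),
               class = "ontoscout_query_error")
})

test_that("rooting restricts graph and result set; un-rooting restores them", {
  rooted <- root_at("CL:0000738", leuko$eg)
  expect_true(all(rooted$view$graph$ids %in%
                    c(leuko$eg$graph$root, "CL:0000738", "CL:0000084",
                      "CL:0000236", "CL:0000235")))
  r <- evaluate_term_query(rooted$query, leuko$idx)
  expect_true(all(r$ids %in% term_set(leuko$idx, "CL:0000738")))
  ## rooting at a leaf gives a single-node view
  leaf <- root_at("CL:0000084", leuko$eg)
  expect_identical(setdiff(leaf$view$graph$ids, leaf$view$graph$root),
                   "CL:0000084")
  ## un-root restores the original view and result set
  unrooted <- root_at(NULL, leuko$eg, rooted$query)
  expect_identical(unrooted$view$graph$ids, leuko$eg$graph$ids)
  expect_identical(evaluate_term_query(unrooted$query, leuko$idx)$ids,
                   evaluate_term_query(term_query(), leuko$idx)$ids)
  expect_error(root_at("CL:gone", leuko$eg), class = "ontoscout_query_error")
  ## rooting then querying equals querying with root_term added
  tq <- term_query(not = "CL:0000011")
  expect_identical(
    evaluate_term_query(root_at("CL:0000738", leuko$eg, tq)$query, leuko$idx)$ids,
    evaluate_term_query(term_query(not = "CL:0000011", root = "CL:0000738"),
                        leuko$idx)$ids)
})

test_that("combined text+term evaluation intersects both constraint sets", {
  q <- query_expression("mouse", term_query(and = "CL:0000003",
                                            not = "CL:0000011"))
  r <- evaluate(q, leuko$fx$repo, leuko$eg, leuko$idx)
  expect_identical(sort(r$ids), sprintf("DS%02d", 8:12))
  ## subset laws
  txt <- text_search(q$text, leuko$fx$repo, leuko$eg$graph)
  trm <- evaluate_term_query(q$terms, leuko$idx)
  expect_true(all(r$ids %in% txt$ids))
  expect_true(all(r$ids %in% trm$ids))
  ## empty text + empty terms -> whole repository
  r0 <- evaluate(query_expression(), leuko$fx$repo, leuko$eg, leuko$idx)
  expect_identical(r0$ids, leuko$idx$universe)
  ## random fixture: combined result equals brute-force per-dataset filter
  fx <- random_fixture(17, n_datasets = 20)
  b <- build_exploration_graph(fx$graph, fx$repo)
  used <- names(b$index$transitive)
  tq <- term_query(and = used[1])
  word <- tokenize(fx$repo$datasets$description[1])[[1]][1]
  rr <- evaluate(query_expression(word, tq), fx$repo, b$eg, b$index)
  brute <- intersect(text_search(word, fx$repo, fx$graph)$ids,
                     oracle_term_query(tq, fx$repo, fx$graph))
  expect_setequal(rr$ids, brute)
})

test_that("canonical query strings parse, format and round-trip", {
  q <- parse_query('"native cells" +term:CL:0000003 -term:CL:0000011 root:CL:0000738')
  expect_identical(q$terms$and, "CL:0000003")
  expect_identical(q$terms$not, "CL:0000011")
  expect_identical(q$terms$root, "CL:0000738")
  expect_identical(q$text$raw, "native cells")
  q2 <- parse_query(format_query(q))
  expect_identical(q2$terms, q$terms)
  err <- expect_error(parse_query("+term:"), class = "ontoscout_query_parse_error")
  expect_match(conditionMessage(err), "position")
})

test_that("the data cart deduplicates, preserves order and validates ids", {
  repo <- leuko$fx$repo
  cart <- data_cart()
  cart <- cart_add(cart, c("DS03", "DS01", "DS02"), repo)
  cart <- cart_add(cart, "DS01", repo)  # duplicate ignored
  expect_identical(cart_list(cart), c("DS03", "DS01", "DS02"))
  cart <- cart_add(cart, sprintf("DS%02d", 8:12), repo)
  expect_length(cart_list(cart), 8L)
  cart <- cart_remove(cart, "DS01")
  expect_false("DS01" %in% cart_list(cart))
  expect_error(cart_remove(cart, "DS99x"), class = "ontoscout_lookup_error")
  expect_error(cart_add(cart, "nope", repo), class = "ontoscout_lookup_error")
})

test_that("dataset highlighting separates direct and indirect terms", {
  fx <- named_fixture("mammalia_chain")
  b <- build_exploration_graph(fx$graph, fx$repo)
  h <- highlight_terms("DS01", fx$repo, b$eg)
  expect_identical(h$direct, "TAX:9606")
  expect_length(h$indirect, 0L)  # all ancestors were absorbed into human
  ## unannotated dataset -> both empty
  repo <- fx$repo
  repo$annotations <- repo$annotations[repo$annotations$dataset_id != "DS02", ]
  h2 <- highlight_terms("DS02", repo, b$eg)
  expect_length(h2$direct, 0L)
  expect_length(h2$indirect, 0L)
  ## two terms sharing an ancestor: ancestor listed once in indirect
  h3 <- highlight_terms("DS01", leuko$fx$repo, leuko$eg)
  expect_setequal(h3$direct, c("CL:0000084", "CL:0000037", "TAX:10090"))
  expect_identical(sum(h3$indirect == "CL:0000003"), 1L)
  expect_true("CL:0000738" %in% h3$indirect)
})
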