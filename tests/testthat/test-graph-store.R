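graph_fixture <- function(seed = 6L, n = 60L, ...) {
  fix <- small_fixture(seed = seed, n = n, ...)
  net <- fixture_network(fix)
  tox <- if (sum(fix$compounds$category == "drug") >= 2)
    all_pairs_toxicity(fix$side_effects) else NULL
  scores <- ecsd_table(fix$abundance)
  list(fix = fix, net = net, tox = tox,
       graph = assemble_graph(net, fix$compounds, tox, fix$enzyme_map,
                              fix$uses, scores))
}

test_that("assembled graph has one node per entity and deduplicated edges", {
  # 5 compounds / 2 enzymes / 1 use -> 8 nodes
  spec <- fixture_spec(n_compounds = 5L, n_clusters = 1L, seed = 44L)
  cmp <- generate_compounds(spec)
  sims <- pairwise_similarity(cmp)
  net <- flag_significant_edges(detect_communities(build_network(sims, 0)))
  em <- data.frame(ec_number = c("1.1.1.1", "2.2.2.2", "1.1.1.1"),
                   compound_id = c("cmpd_001", "cmpd_002", "cmpd_003"))
  uses <- data.frame(compound_id = c("cmpd_001", "cmpd_002"), use = "analgesic")
  g <- assemble_graph(net, cmp, NULL, em, uses)
  expect_equal(nrow(g$nodes), 8L)
  expect_equal(sort(unique(g$nodes$label)), c("Compound", "Enzyme", "Use"))
  # relationship conservation after deduplication
  expect_equal(sum(g$relationships$type == "METABOLIZED_BY"), 3L)
  expect_equal(sum(g$relationships$type == "HAS_USE"), 2L)
  expect_equal(sum(g$relationships$type == "SUBSTRUCTURE_SIMILARITY"), nrow(net$edges))
  expect_false(anyDuplicated(g$relationships[, c("start", "end", "type")]) > 0)

  # dangling references are skipped and counted
  em_bad <- rbind(em, data.frame(ec_number = "9.9.9.9", compound_id = "ghost"))
  expect_message(g2 <- assemble_graph(net, cmp, NULL, em_bad, uses),
                 "unresolvable|unknown")
  expect_equal(g2$skipped, 1L)
  expect_equal(nrow(g2$nodes), 8L)
})

test_that("ecsd scores attach to enzyme nodes", {
  gf <- graph_fixture()
  en <- gf$graph$nodes[gf$graph$nodes$label == "Enzyme", ]
  sc <- ecsd_table(gf$fix$abundance)$scores
  expect_equal(en$ecsd, sc$ecsd[match(en$node_id, sc$ec_number)])
})

test_that("significant_neighbors matches a full-scan oracle and ranks by score", {
  gf <- graph_fixture(seed = 6L, n = 100L)
  g <- gf$graph
  net <- gf$net
  ids <- gf$fix$compounds$compound_id
  for (id in sample(ids, 15)) {
    res <- significant_neighbors(g, id)
    sig <- net$edges[net$edges$significant &
                       (net$edges$id1 == id | net$edges$id2 == id), ]
    want <- ifelse(sig$id1 == id, sig$id2, sig$id1)
    expect_setequal(res$compound_id, want)
    if (nrow(res) > 1) {
      expect_true(all(diff(res$score) <= 0))
      ties <- which(diff(res$score) == 0)
      for (t in ties) expect_true(res$compound_id[t] < res$compound_id[t + 1])
    }
  }
  expect_error(significant_neighbors(g, "ghost"), class = "ctg_input_error")
})

test_that("dual_neighbors intersects structure and toxicity and is anti-monotone", {
  gf <- graph_fixture(seed = 16L, n = 80L, category_proportions = c(drug = 1))
  g <- gf$graph
  id <- gf$fix$compounds$compound_id[1]
  base <- dual_neighbors(g, id, 0, 0)
  s_n <- significant_neighbors(g, id)$compound_id
  tox <- gf$tox
  t_n <- c(tox$id2[tox$id1 == id], tox$id1[tox$id2 == id])
  expect_setequal(base$compound_id, intersect(s_n, t_n))
  for (ms in c(0.5, 0.8)) for (mt in c(0.3, 0.7)) {
    r <- dual_neighbors(g, id, ms, mt)
    expect_true(all(r$compound_id %in% base$compound_id))
    expect_true(all(r$score >= ms & r$tox_score >= mt))
  }
})

test_that("dual_neighbors surfaces a planted high-structure/high-toxicity partner", {
  # two drugs engineered with near-identical fingerprints and identical
  # side-effect profiles inside a background fixture
  spec <- fixture_spec(n_compounds = 30L, category_proportions = c(drug = 1),
                       seed = 55L)
  fix <- generate_fixture(spec)
  fps <- attr(fix$compounds, "fingerprints")
  fps[["cmpd_002"]] <- fps[["cmpd_001"]]
  cmp <- as_compound_table(fix$compounds, fps)
  prof <- fix$side_effects
  prof[["cmpd_002"]] <- prof[["cmpd_001"]]
  net <- fixture_network(list(compounds = cmp))
  tox <- all_pairs_toxicity(prof)
  g <- assemble_graph(net, cmp, tox)
  res <- dual_neighbors(g, "cmpd_001", min_struct = 0.99, min_tox = 0.99)
  expect_equal(res$compound_id, "cmpd_002")
})

test_that("substrate_pool_scan stays inside the community and flags substrates", {
  gf <- graph_fixture(seed = 26L, n = 100L)
  g <- gf$graph
  net <- gf$net
  em <- gf$fix$enzyme_map
  ec <- em$ec_number[1]
  seeds <- sample(gf$fix$compounds$compound_id, 10)
  for (id in seeds) {
    res <- substrate_pool_scan(g, ec, id)
    # full-scan oracle
    comm <- net$membership[[id]]
    sig <- net$edges[net$edges$significant &
                       (net$edges$id1 == id | net$edges$id2 == id), ]
    other <- ifelse(sig$id1 == id, sig$id2, sig$id1)
    other <- other[net$membership[other] == comm]
    expect_setequal(res$compound_id, other)
    known <- em$compound_id[em$ec_number == ec]
    expect_equal(res$known_substrate, res$compound_id %in% known)
    expect_equal(res$category,
                 gf$fix$compounds$category[match(res$compound_id,
                                                 gf$fix$compounds$compound_id)])
  }
  expect_error(substrate_pool_scan(g, "no.such.ec", seeds[1]),
               class = "ctg_input_error")
})

test_that("export/import round trips both formats with identical content", {
  gf <- graph_fixture(seed = 36L, n = 40L)
  g <- gf$graph

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  back <- import_graph(gml, "graphml")
  expect_equal(back$nodes[order(back$nodes$node_id), ],
               g$nodes[order(g$nodes$node_id), ], ignore_attr = TRUE)
  ord <- function(r) r[order(r$type, r$start, r$end), ]
  expect_equal(ord(back$relationships), ord(g$relationships), ignore_attr = TRUE)

  dir <- withr::local_tempdir()
  export_graph(g, dir, "csv")
  csv <- import_graph(dir, "csv")
  expect_equal(ord(csv$relationships), ord(g$relationships), ignore_attr = TRUE)
  expect_equal(nrow(utils::read.csv(file.path(dir, "nodes.csv"))), nrow(g$nodes))

  # queries agree between in-memory and re-imported graphs
  id <- g$nodes$node_id[g$nodes$label == "Compound"][1]
  expect_equal(significant_neighbors(back, id), significant_neighbors(g, id))
  expect_equal(significant_neighbors(csv, id), significant_neighbors(g, id))
})
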