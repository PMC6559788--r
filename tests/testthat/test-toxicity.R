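profiles4 <- list(d1 = c("c1", "c2"), d2 = c("c1", "c3"),
                  d3 = c("c2", "c3"), d4 = c("c3", "c4"))

test_that("concept frequency and rarity weights follow their definitions", {
  f <- concept_frequency(profiles4)
  expect_equal(unname(f["c1"]), 0.5)
  expect_equal(unname(f["c3"]), 0.75)
  expect_error(concept_frequency(list()), class = "ctg_input_error")

  all_drugs <- list(a = "x", b = "x")
  expect_equal(unname(concept_frequency(all_drugs)["x"]), 1)
  expect_equal(unname(rarity_weights(c(x = 1))["x"]), 0)
  expect_equal(unname(rarity_weights(c(x = 0.5))["x"]), -log(0.5), tolerance = 1e-12)
  expect_error(rarity_weights(c(x = 0)), class = "ctg_input_error")

  # monotone decreasing in frequency
  f <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(rarity_weights(stats::setNames(f, paste0("f", f)))) < 1e-15))

  # brute-force count oracle on synthetic profiles
  set.seed(23)
  vocab <- sprintf("v%02d", 1:25)
  prof <- lapply(1:100, function(i) sample(vocab, sample(1:8, 1)))
  names(prof) <- sprintf("d%03d", 1:100)
  f <- concept_frequency(prof)
  for (cc in names(f))
    expect_equal(unname(f[cc]),
                 sum(vapply(prof, function(p) cc %in% p, logical(1))) / 100)
})

test_that("concept co-occurrence is drug-set Tanimoto", {
  co <- concept_cooccurrence(profiles4)
  # c1 in {d1,d2}, c2 in {d1,d3}: share d1 of {d1,d2,d3} -> 1/3
  expect_equal(co["c1", "c2"], 1 / 3)
  # c2 in {d1,d3}, c3 in {d2,d3,d4}: share d3 of 4 -> 0.25
  expect_equal(co["c2", "c3"], 0.25)
  expect_true(isSymmetric(co))
  expect_equal(unname(diag(co)), rep(1, 4))

  ident <- concept_cooccurrence(list(a = c("x", "y"), b = c("x", "y"), c = "z"))
  expect_equal(ident["x", "y"], 1)   # identical drug sets
  expect_equal(ident["x", "z"], 0)   # never co-listed
  # {d1,d2,d3} vs {d2,d3,d4} -> 0.5
  p <- list(d1 = "a", d2 = c("a", "b"), d3 = c("a", "b"), d4 = "b")
  expect_equal(concept_cooccurrence(p)["a", "b"], 0.5)
})

test_that("concept tree is ultrametric UPGMA on 1 - cooccurrence", {
  # two concepts, corr 0 -> branch lengths 0.5 each
  co <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- build_concept_tree(co)
  expect_equal(sort(tr$edge.length), c(0.5, 0.5))

  # corr 1 -> merge at height 0
  co1 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(build_concept_tree(co1)$edge.length, c(0, 0))

  # 4-concept case against a hand-run UPGMA trace:
  # d(AB)=0.2, d(CD)=0.4, all cross distances 0.8
  # merge AB at 0.2 (heights 0.1), CD at 0.4 (heights 0.2),
  # then {AB}x{CD} at mean 0.8 (root height 0.4)
  cc <- 1 - matrix(c(0, .2, .8, .8,
                     .2, 0, .8, .8,
                     .8, .8, 0, .4,
                     .8, .8, .4, 0), 4, byrow = TRUE,
                   dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_concept_tree(cc)
  depth <- ape::node.depth.edgelength(tr)
  expect_equal(unname(depth[1:4]), rep(0.4, 4), tolerance = 1e-12)  # ultrametric
  tip_edge <- tr$edge.length[match(1:4, tr$edge[, 2])]
  names(tip_edge) <- tr$tip.label
  expect_equal(unname(tip_edge[c("A", "B")]), c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(unname(tip_edge[c("C", "D")]), c(0.2, 0.2), tolerance = 1e-12)
})

test_that("GSC weights distribute branch lengths and down-weight redundancy", {
  # symmetric two-leaf tree -> equal weights
  t0 <- ape::read.tree(text = "(A:1,B:1);")
  w0 <- gsc_weights(t0)
  expect_equal(w0$gsc_weight, c(1, 1))

  # hand trace ((A:1,B:1):1,C:2): raw A=1.5 B=1.5 C=2, sum = 5
  t1 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  w1 <- gsc_weights(t1)
  expect_equal(w1$raw_weight[match(c("A", "B", "C"), w1$concept_id)],
               c(1.5, 1.5, 2.0))
  expect_equal(sum(w1$raw_weight), sum(t1$edge.length))

  # duplicating a leaf at distance 0 halves its weight, leaves others alone
  t2 <- ape::read.tree(text = "(((A:0,A2:0):1,B:1):1,C:2);")
  w2 <- gsc_weights(t2)
  g <- function(w, id) w$raw_weight[w$concept_id == id]
  expect_equal(g(w2, "A"), g(w1, "A") / 2)
  expect_equal(g(w2, "A2"), g(w1, "A") / 2)
  expect_equal(g(w2, "B"), g(w1, "B"))
  expect_equal(g(w2, "C"), g(w1, "C"))

  # conservation on random trees: sum(raw) == total branch length
  set.seed(31)
  for (i in 1:20) {
    tr <- ape::rtree(sample(3:12, 1))
    w <- gsc_weights(tr)
    expect_equal(sum(w$raw_weight), sum(tr$edge.length), tolerance = 1e-10)
    expect_equal(mean(w$gsc_weight), 1, tolerance = 1e-10)
  }
})

test_that("toxicity similarity matches hand-computed worked case and bounds", {
  prof <- list(d1 = c("c1", "c2"), d2 = c("c1", "c2"), d3 = c("c3", "c4"))
  w <- concept_weights(prof)
  # identical profiles -> 1, disjoint -> 0
  expect_equal(toxicity_similarity(prof$d1, prof$d2, w)$normalized_score, 1)
  expect_equal(toxicity_similarity(prof$d1, prof$d3, w)$raw_score, 0)
  expect_equal(toxicity_similarity(prof$d1, prof$d3, w)$normalized_score, 0)

  # three-drug worked case with hand-computed weights
  prof2 <- list(d1 = c("c1", "c2"), d2 = c("c1", "c3"), d3 = c("c2", "c3"))
  w2 <- concept_weights(prof2)
  # every concept appears in 2/3 drugs -> rarity -ln(2/3) everywhere; the
  # co-occurrence matrix is symmetric so GSC weights are all equal (=1)
  expect_equal(w2$combined_weight, rep(-log(2 / 3), 3), tolerance = 1e-10)
  ts <- toxicity_similarity(prof2$d1, prof2$d2, w2)
  expect_equal(ts$raw_score, -log(2 / 3), tolerance = 1e-10)
  expect_equal(ts$normalized_score, 0.5, tolerance = 1e-10)  # 1 shared of 2 vs 2

  # profiles weighted only by ubiquitous concepts error out
  ubiq <- list(a = "x", b = "x")
  expect_error(toxicity_similarity("x", "x", concept_weights(ubiq)),
               class = "ctg_input_error")
  expect_error(toxicity_similarity("zz", "c1", w2), class = "ctg_input_error")
})

test_that("all_pairs_toxicity enumerates pairs, is symmetric and deterministic", {
  set.seed(13)
  vocab <- sprintf("v%02d", 1:20)
  prof <- lapply(1:30, function(i) sort(sample(vocab, sample(2:6, 1))))
  names(prof) <- sprintf("d%02d", 1:30)
  tox <- all_pairs_toxicity(prof)
  expect_equal(nrow(tox), choose(30, 2))
  w <- concept_weights(prof)
  # brute-force double loop oracle + symmetry
  for (k in sample(nrow(tox), 40)) {
    a <- prof[[tox$id1[k]]]; b <- prof[[tox$id2[k]]]
    expect_equal(tox$score[k], toxicity_similarity(a, b, w)$normalized_score)
    expect_equal(tox$score[k], toxicity_similarity(b, a, w)$normalized_score)
  }
  expect_true(all(tox$score >= 0 & tox$score <= 1))
  # byte-identical weight tables on identical inputs
  expect_identical(concept_weights(prof), concept_weights(prof))
  four <- all_pairs_toxicity(prof[1:4])
  expect_equal(nrow(four), 6L)
})

test_that("adding an exact-duplicate concept never raises pair similarity", {
  set.seed(19)
  vocab <- sprintf("v%02d", 1:12)
  prof <- lapply(1:15, function(i) sort(sample(vocab, sample(2:5, 1))))
  names(prof) <- sprintf("d%02d", 1:15)
  base <- all_pairs_toxicity(prof)
  # duplicate concept v01 as v01dup wherever v01 occurs
  prof2 <- lapply(prof, function(p) if ("v01" %in% p) c(p, "v01dup") else p)
  dup <- all_pairs_toxicity(prof2)
  # the duplicated leaf's own weight halves exactly; pair scores can still
  # shift at second order because the extra leaf enters the size-weighted
  # average-linkage means of later merges, so allow a small tolerance
  expect_true(all(dup$score <= base$score + 1e-3))
  expect_lt(mean(pmax(dup$score - base$score, 0)), 1e-4)
})
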