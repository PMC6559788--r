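test_that("randomization preserves node count, edge count and labels", {
  fix <- small_fixture(seed = 4L, n = 50L)
  net <- fixture_network(fix)
  for (s in 1:20) {
    rnd <- randomize_network(net, seed = s)
    expect_equal(rnd$nodes, net$nodes)
    expect_equal(nrow(rnd$edges), nrow(net$edges))
    expect_equal(sort(rnd$edges$score), sort(net$edges$score))
    expect_true(all(rnd$edges$id1 != rnd$edges$id2))
    expect_false(anyDuplicated(paste(rnd$edges$id1, rnd$edges$id2)) > 0)
  }
  # complete graph randomizes to itself
  ids <- letters[1:5]
  cmb <- t(combn(ids, 2))
  full <- build_network(data.frame(id1 = cmb[, 1], id2 = cmb[, 2], score = 0.5), 0)
  rnd <- randomize_network(full, seed = 1)
  expect_setequal(paste(rnd$edges$id1, rnd$edges$id2),
                  paste(full$edges$id1, full$edges$id2))
})

test_that("randomized edges are uniform over node pairs", {
  ids <- sprintf("n%03d", 1:30)
  cmb <- t(combn(ids, 2))
  sel <- seq_len(100)
  net <- build_network(data.frame(id1 = cmb[sel, 1], id2 = cmb[sel, 2],
                                  score = 0.5), 0)
  m <- 100; npairs <- choose(30, 2)
  hit <- 0
  nseeds <- 400
  probe <- c("n001 n002", "n010 n020", "n005 n029")
  counts <- numeric(length(probe))
  for (s in seq_len(nseeds)) {
    rnd <- randomize_network(net, seed = s)
    key <- paste(rnd$edges$id1, rnd$edges$id2)
    counts <- counts + probe %in% key
  }
  p_expect <- m / npairs
  se <- sqrt(p_expect * (1 - p_expect) / nseeds)
  for (cc in counts / nseeds)
    expect_lt(abs(cc - p_expect), 3.5 * se + 1e-9)
})

test_that("superclass agreement counts match a brute-force tally", {
  fix <- small_fixture(seed = 8L, n = 70L, superclass_alignment = 1)
  net <- fixture_network(fix)
  agr <- superclass_agreement(net, fix$compounds, bin_width = 0.05)
  sc <- fix$compounds$superclass[match(net$edges$id1, fix$compounds$compound_id)]
  sc2 <- fix$compounds$superclass[match(net$edges$id2, fix$compounds$compound_id)]
  expect_equal(sum(agr$matched) + sum(agr$unmatched), nrow(net$edges))
  expect_equal(sum(agr$matched), sum(sc == sc2))
  for (b in which(agr$matched + agr$unmatched > 0)) {
    inbin <- net$edges$score >= agr$bin_low[b] &
      (net$edges$score < agr$bin_high[b] | (agr$bin_high[b] == 1 & net$edges$score == 1))
    expect_equal(agr$matched[b], sum((sc == sc2)[inbin]))
  }
  # all edges in one superclass: matched fraction 1 in occupied bins
  uni <- fix$compounds
  uni$superclass <- "only"
  agr1 <- superclass_agreement(net, uni)
  expect_true(all(agr1$matched_fraction[agr1$matched + agr1$unmatched > 0] == 1))
  expect_true(all(is.na(agr1$ratio[agr1$matched > 0])))

  # aligned planted clusters: matched fraction non-decreasing over occupied bins
  occ <- agr[agr$matched + agr$unmatched > 3, ]
  expect_true(all(diff(occ$matched_fraction) >= -0.1))
})

test_that("rank-sum test separates planted structure from randomized networks", {
  fix <- small_fixture(seed = 12L, n = 80L, superclass_alignment = 0.9)
  net <- fixture_network(fix)
  rnd <- randomize_network(net, seed = 1L)
  res <- compare_to_random(net, rnd, fix$compounds)
  expect_false(res$inconclusive)
  expect_lt(res$p_value, 0.01)

  # identical samples: p approximately 1
  self <- compare_to_random(net, net, fix$compounds)
  expect_gt(self$p_value, 0.95)

  # statistic equals the independent rank-sum implementation
  em <- chemtoxgraph:::edge_superclass_match(net, fix$compounds)
  em2 <- chemtoxgraph:::edge_superclass_match(rnd, fix$compounds)
  ref <- suppressWarnings(stats::wilcox.test(as.numeric(em$matched),
                                             as.numeric(em2$matched)))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  # degenerate all-tied samples are reported inconclusive
  uni <- fix$compounds
  uni$superclass <- "only"
  expect_true(compare_to_random(net, rnd, uni)$inconclusive)
})

test_that("structure-toxicity regression recovers exact and planted slopes", {
  # exact linear relation
  pairs <- data.frame(id1 = sprintf("a%02d", 1:20), id2 = sprintf("b%02d", 1:20))
  x <- seq(0.05, 1, length.out = 20)
  struct <- cbind(pairs, score = x)
  tox <- cbind(pairs, score = 0.5 * x)
  res <- suppressWarnings(structure_toxicity_regression(struct, tox))
  expect_equal(res$slope, 0.5, tolerance = 1e-12)
  expect_equal(res$r, 1, tolerance = 1e-12)

  # independent noise: slope CI covers 0 in >= 90/100 runs at n = 200
  cover0 <- 0
  for (s in 1:100) {
    set.seed(s)
    xs <- runif(200); ys <- runif(200)
    st <- data.frame(id1 = sprintf("p%03d", 1:200), id2 = sprintf("q%03d", 1:200),
                     score = xs)
    tx <- st; tx$score <- ys
    fit <- structure_toxicity_regression(st, tx)
    ci <- stats::confint(fit$fit)[2, ]
    cover0 <- cover0 + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(cover0, 90)

  expect_error(structure_toxicity_regression(struct[1:2, ], tox[1:2, ]),
               class = "ctg_input_error")
  const <- struct; const$score <- 0.5
  expect_error(structure_toxicity_regression(const, tox),
               class = "ctg_domain_error")
})

test_that("regression and rank-sum results are invariant to row order", {
  fix <- small_fixture(seed = 30L, n = 50L, category_proportions = c(drug = 1))
  net <- fixture_network(fix)
  tox <- all_pairs_toxicity(fix$side_effects)
  struct <- net$edges
  r1 <- structure_toxicity_regression(struct, tox)
  set.seed(2)
  r2 <- structure_toxicity_regression(struct[sample(nrow(struct)), ],
                                      tox[sample(nrow(tox)), ])
  expect_equal(r1$slope, r2$slope)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("category self-similarity uses the empirical-CDF sup difference", {
  fix <- small_fixture(seed = 14L, n = 60L)
  # same compounds under both labels -> statistic 0
  both <- fix$compounds
  res <- category_self_similarity(both, unique(both$category)[1],
                                  unique(both$category)[1])
  expect_equal(res$statistic, 0)

  # oracle check across fixtures
  ecdf_sup <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(g) - ecdf(b)(g)))
  }
  for (s in 1:10) {
    fx <- small_fixture(seed = s + 100L, n = 40L)
    cats <- names(which(table(fx$compounds$category) >= 2))
    if (length(cats) < 2) next
    res <- category_self_similarity(fx$compounds, cats[1], cats[2])
    within_scores <- function(cat) {
      ids <- fx$compounds$compound_id[fx$compounds$category == cat]
      sub <- fx$compounds[fx$compounds$compound_id %in% ids, ]
      sub <- as_compound_table(sub, attr(fx$compounds, "fingerprints")[ids])
      pairwise_similarity(sub)$score
    }
    expect_equal(res$statistic, ecdf_sup(within_scores(cats[1]), within_scores(cats[2])),
                 tolerance = 1e-12)
  }
  one <- fix$compounds[1, , drop = FALSE]
  expect_error(category_self_similarity(fix$compounds, "nope", "drug"),
               class = "ctg_input_error")
})

test_that("validation report writes parameters and per-bin agreement", {
  fix <- small_fixture(seed = 2L, n = 40L)
  net <- fixture_network(fix)
  agr <- superclass_agreement(net, fix$compounds)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_validation_report(agr, path, parameters = list(seed = 2, bin_width = 0.05))
  lines <- readLines(path)
  expect_match(lines[1], "^# seed=2")
  tab <- read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), nrow(agr))
})
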