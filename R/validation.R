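# Network validation: superclass agreement vs a randomized network,
# structure-toxicity regression, and category self-similarity.

#' Randomize a network preserving node count, edge count and labels
#'
#' Draws the same number of edges uniformly at random among unordered node
#' pairs without replacement; node annotations are untouched and the
#' original edge-score multiset is reassigned to the new edges in seeded
#' random order, so scores are independent of endpoints. Degrees are not
#' preserved (a degree-preserving rewiring is available via
#' `degree_preserving = TRUE` for sensitivity analysis).
#'
#' @param net a `similarity_network`.
#' @param seed integer seed.
#' @param degree_preserving rewire keeping the degree sequence instead of
#'   drawing uniform pairs (default `FALSE`).
#' @return A `similarity_network` with randomized edges (no communities or
#'   significance flags).
#' @export
randomize_network <- function(net, seed = 1L, degree_preserving = FALSE) {
  stopifnot(inherits(net, "similarity_network"))
  n <- length(net$nodes)
  m <- nrow(net$edges)
  npairs <- n * (n - 1) / 2
  if (m > npairs)
    ctg_error("edge count exceeds the number of node pairs", "ctg_input_error")
  set.seed(as.integer(seed))
  if (degree_preserving) {
    g <- as_igraph(net)
    g <- igraph::rewire(g, igraph::keeping_degseq(niter = 20 * max(m, 1L)))
    el <- igraph::as_edgelist(g)
    pair <- canonical_pair(el[, 1L], el[, 2L])
  } else {
    ut <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    sel <- ut[sample(npairs, m), , drop = FALSE]
    pair <- canonical_pair(net$nodes[sel[, 1L]], net$nodes[sel[, 2L]])
  }
  edges <- data.frame(id1 = pair[, "id1"], id2 = pair[, "id2"],
                      score = sample(net$edges$score), stringsAsFactors = FALSE)
  edges <- edges[order(edges$id1, edges$id2), , drop = FALSE]
  edges$community <- rep(NA_integer_, nrow(edges))
  edges$zscore <- rep(NA_real_, nrow(edges))
  edges$significant <- rep(FALSE, nrow(edges))
  rownames(edges) <- NULL
  structure(list(nodes = net$nodes, edges = edges, membership = NULL,
                 communities = NULL,
                 parameters = c(net$parameters, list(randomized_seed = as.integer(seed)))),
            class = "similarity_network")
}

edge_superclass_match <- function(net, compounds) {
  i1 <- match(net$edges$id1, compounds$compound_id)
  i2 <- match(net$edges$id2, compounds$compound_id)
  s1 <- compounds$superclass[i1]
  s2 <- compounds$superclass[i2]
  ok <- !is.na(s1) & !is.na(s2)
  data.frame(score = net$edges$score[ok], matched = s1[ok] == s2[ok])
}

#' Superclass agreement by similarity bin
#'
#' For edges whose endpoints both carry a superclass annotation, counts per
#' similarity bin how many pairs share the annotation. The
#' matched:unmatched ratio is `NA` when no unmatched pair falls in a bin;
#' the matched fraction is always defined for occupied bins.
#'
#' @param net a `similarity_network` (real or randomized).
#' @param compounds a `compound_table` with `superclass` annotations
#'   (`NA` allowed; such nodes are excluded).
#' @param bin_width similarity bin width (default 0.05).
#' @return `data.frame`: `bin_low`, `bin_high`, `matched`, `unmatched`,
#'   `matched_fraction`, `ratio`.
#' @export
superclass_agreement <- function(net, compounds, bin_width = 0.05) {
  em <- edge_superclass_match(net, compounds)
  edges_all <- seq(0, 1, by = bin_width)
  edges_lo <- edges_all[-length(edges_all)]
  edges_hi <- edges_all[-1L]
  bin <- pmin(findInterval(em$score, edges_all, rightmost.closed = TRUE),
              length(edges_lo))
  rows <- lapply(seq_along(edges_lo), function(b) {
    sel <- bin == b
    matched <- sum(em$matched[sel])
    unmatched <- sum(sel) - matched
    data.frame(bin_low = edges_lo[b], bin_high = edges_hi[b],
               matched = matched, unmatched = unmatched,
               matched_fraction = if (any(sel)) matched / sum(sel) else NA_real_,
               ratio = if (unmatched > 0) matched / unmatched else NA_real_)
  })
  do.call(rbind, rows)
}

#' Rank-sum comparison of real vs randomized superclass agreement
#'
#' Two-sided Wilcoxon rank-sum test on the edge-level superclass match
#' indicators of the real network against those of the randomized network:
#' if substructure similarity carries chemical ontology, connected pairs
#' share their superclass far more often in the real network than under
#' randomization with the same nodes, edges and labels.
#'
#' @param net a `similarity_network`.
#' @param random a randomized network from [randomize_network()].
#' @param compounds a `compound_table` with superclass annotations.
#' @return List with `statistic`, `p_value`, `n_real`, `n_random`,
#'   `inconclusive` (`TRUE` when either sample is empty or all values tie).
#' @export
compare_to_random <- function(net, random, compounds) {
  x <- as.numeric(edge_superclass_match(net, compounds)$matched)
  y <- as.numeric(edge_superclass_match(random, compounds)$matched)
  if (!length(x) || !length(y) || length(unique(c(x, y))) == 1L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_real = length(x), n_random = length(y), inconclusive = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_real = length(x), n_random = length(y), inconclusive = FALSE)
}

#' Regress toxicity similarity on substructure similarity
#'
#' Ordinary least squares over drug pairs present in both edge sets
#' (structure-linked pairs with a toxicity score).
#'
#' @param struct_edges `data.frame` with `id1`, `id2`, `score` (structure).
#' @param tox_edges `data.frame` with `id1`, `id2`, `score` (toxicity,
#'   normalised).
#' @return List with `slope`, `intercept`, `r` (Pearson), `p_value`, `n`,
#'   and the fitted `lm` object as `fit`.
#' @export
structure_toxicity_regression <- function(struct_edges, tox_edges) {
  key_s <- paste(struct_edges$id1, struct_edges$id2)
  key_t <- paste(tox_edges$id1, tox_edges$id2)
  common <- intersect(key_s, key_t)
  if (length(common) < 3L)
    ctg_error("need at least three pairs present in both edge sets", "ctg_input_error")
  x <- struct_edges$score[match(common, key_s)]
  y <- tox_edges$score[match(common, key_t)]
  if (stats::var(x) == 0)
    ctg_error("zero variance in substructure similarity", "ctg_domain_error")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]), intercept = unname(stats::coef(fit)[1L]),
       r = unname(sign(stats::coef(fit)[2L]) * sqrt(sm$r.squared)),
       p_value = sm$coefficients[2L, 4L], n = length(common), fit = fit)
}

#' Compare within-category self-similarity distributions
#'
#' Two-sample Kolmogorov-Smirnov test between the distributions of
#' within-category pairwise Tanimoto scores of two compound categories.
#'
#' @param compounds a `compound_table`.
#' @param category_a,category_b category labels to compare.
#' @return List with `statistic`, `p_value`, `n_a`, `n_b` (pair counts).
#' @export
category_self_similarity <- function(compounds, category_a, category_b) {
  within_scores <- function(cat) {
    ids <- compounds$compound_id[compounds$category == cat]
    if (length(ids) < 2L)
      ctg_error(sprintf("category '%s' has fewer than two compounds", cat),
                "ctg_input_error")
    fps <- attr(compounds, "fingerprints")[ids]
    sub <- as_compound_table(compounds[compounds$compound_id %in% ids, , drop = FALSE], fps)
    pairwise_similarity(sub)$score
  }
  a <- within_scores(category_a)
  b <- within_scores(category_b)
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_a = length(a), n_b = length(b))
}

#' Write a validation report TSV
#'
#' Per-bin agreement plus regression and test summaries, with seed and
#' parameters echoed in a header comment.
#'
#' @param agreement output of [superclass_agreement()].
#' @param regression output of [structure_toxicity_regression()] (optional).
#' @param rank_sum output of [compare_to_random()] (optional).
#' @param path output path.
#' @param parameters named list echoed in the header.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(agreement, path, regression = NULL,
                                    rank_sum = NULL, parameters = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", paste(names(parameters), unlist(parameters),
                                   sep = "=", collapse = " ")), con)
  if (!is.null(regression))
    writeLines(sprintf("# regression slope=%g r=%g p=%g n=%d",
                       regression$slope, regression$r, regression$p_value,
                       regression$n), con)
  if (!is.null(rank_sum))
    writeLines(sprintf("# rank_sum W=%g p=%g", rank_sum$statistic,
                       rank_sum$p_value), con)
  utils::write.table(agreement, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
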