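# Side-effect-based toxicity similarity.
#
# Each drug is a set of side-effect concepts. A concept's weight combines
# (i) a rarity score, -ln of the fraction of drugs listing it, and (ii) a
# Gerstein-Sonnhammer-Chothia (GSC) tree weight that down-weights concepts
# whose drug sets are redundant with other concepts. Pairwise toxicity
# similarity sums combined weights over shared concepts, normalised
# cosine-style to [0, 1].

#' Read side-effect profiles from a SIDER-like TSV
#'
#' Expects columns `compound_id`, `concept_id`, `concept_name` (the name
#' column is optional).
#'
#' @param path TSV file path.
#' @return Named list of character vectors: per-drug sets of concept ids.
#' @export
read_side_effects <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("compound_id", "concept_id") %in% names(df)))
    ctg_error("side-effect table needs compound_id and concept_id columns",
              "ctg_format_error")
  lapply(split(df$concept_id, df$compound_id), unique)
}

#' Concept frequency across drug side-effect lists
#'
#' @param profiles named list of per-drug concept-id sets.
#' @return Named numeric vector: fraction of drugs listing each concept,
#'   in `(0, 1]`.
#' @export
concept_frequency <- function(profiles) {
  if (!length(profiles))
    ctg_error("no side-effect profiles supplied", "ctg_input_error")
  counts <- table(unlist(lapply(profiles, unique), use.names = FALSE))
  f <- as.numeric(counts) / length(profiles)
  names(f) <- names(counts)
  f[order(names(f))]
}

#' Rarity weights from concept frequencies
#'
#' Information-content form: `-ln(frequency)`. A concept listed by every
#' drug carries no information and gets weight 0.
#'
#' @param frequencies named numeric vector in `(0, 1]`.
#' @return Named numeric vector of non-negative rarity weights.
#' @export
rarity_weights <- function(frequencies) {
  if (any(frequencies <= 0 | frequencies > 1))
    ctg_error("frequencies must lie in (0, 1]", "ctg_input_error")
  w <- -log(frequencies)
  names(w) <- names(frequencies)
  w
}

#' Concept co-occurrence (Tanimoto over drug sets)
#'
#' For two concepts, the number of drugs listing both relative to the number
#' listing either.
#'
#' @param profiles named list of per-drug concept-id sets.
#' @return Symmetric matrix of co-occurrence values in `[0, 1]`, unit
#'   diagonal, concepts ordered lexicographically.
#' @export
concept_cooccurrence <- function(profiles) {
  concepts <- sort(unique(unlist(profiles, use.names = FALSE)))
  if (length(concepts) < 2L)
    ctg_error("need at least two concepts", "ctg_input_error")
  # drugs x concepts incidence
  inc <- vapply(concepts, function(cc)
    vapply(profiles, function(p) cc %in% p, logical(1L)), logical(length(profiles)))
  inc <- matrix(as.numeric(inc), nrow = length(profiles),
                dimnames = list(names(profiles), concepts))
  inter <- crossprod(inc)
  n <- diag(inter)
  uni <- outer(n, n, "+") - inter
  corr <- ifelse(uni == 0, 0, inter / uni)
  dimnames(corr) <- list(concepts, concepts)
  corr
}

#' Build an ultrametric concept tree by average-linkage clustering
#'
#' Agglomerates concepts on the distance `1 - cooccurrence` (UPGMA); node
#' heights are half the merge distance so the tree is ultrametric with leaf
#' depth equal to half the largest merge distance. Concepts are ordered
#' lexicographically before clustering so equal-distance merges break ties
#' deterministically.
#'
#' @param cooccurrence symmetric co-occurrence matrix from
#'   [concept_cooccurrence()].
#' @return An [ape::as.phylo()] tree with concept ids as tip labels; a
#'   single concept yields a degenerate one-leaf tree (class
#'   `concept_leaf`).
#' @export
build_concept_tree <- function(cooccurrence) {
  if (any(cooccurrence < 0 | cooccurrence > 1))
    ctg_error("co-occurrence values must lie in [0, 1]", "ctg_input_error")
  concepts <- sort(rownames(cooccurrence))
  if (length(concepts) < 2L)
    return(structure(list(tip.label = concepts), class = "concept_leaf"))
  d <- stats::as.dist(1 - cooccurrence[concepts, concepts])
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)   # halves hclust heights: ultrametric branch lengths
}

#' Gerstein-Sonnhammer-Chothia leaf weights
#'
#' Distributes each branch length among the leaves of its subtree: edges are
#' processed from the tips toward the root, and an edge's length is divided
#' among its subtree's leaves in proportion to their currently accumulated
#' weights (equally when all are still zero). Redundant leaves hanging close
#' together share their ancestral branch lengths and are down-weighted.
#' Before rescaling, the leaf weights sum to the total branch length of the
#' tree; returned weights are rescaled to mean 1.
#'
#' @param tree a `phylo` tree from [build_concept_tree()].
#' @return `data.frame` with columns `concept_id`, `raw_weight`,
#'   `gsc_weight` (mean 1).
#' @export
gsc_weights <- function(tree) {
  if (inherits(tree, "concept_leaf"))
    return(data.frame(concept_id = tree$tip.label, raw_weight = 1, gsc_weight = 1,
                      stringsAsFactors = FALSE))
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < -1e-12))
    ctg_error("negative branch length", "ctg_input_error")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # leaves under each node
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # node depths (edges from root) to order edge processing tips -> root
  depth <- numeric(nnode)
  root <- ntip + 1L
  ord <- order(tree$edge[, 1L])  # parent-sorted
  # compute depths via BFS from root
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  queue <- root
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (e in kids[[as.character(v)]]) {
      w <- tree$edge[e, 2L]
      depth[w] <- depth[v] + 1L
      queue <- c(queue, w)
    }
  }
  # fill descendant lists bottom-up
  for (v in order(depth[(ntip + 1L):nnode], decreasing = TRUE) + ntip) {
    ch <- tree$edge[tree$edge[, 1L] == v, 2L]
    desc[[v]] <- unlist(desc[ch])
  }
  weights <- numeric(ntip)
  # process edges with deeper child first (tips root-ward)
  edge_order <- order(depth[tree$edge[, 2L]], decreasing = TRUE)
  for (e in edge_order) {
    child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    leaves <- desc[[child]]
    cur <- weights[leaves]
    share <- if (sum(cur) == 0) rep(1 / length(leaves), length(leaves)) else cur / sum(cur)
    weights[leaves] <- weights[leaves] + len * share
  }
  out <- data.frame(concept_id = tree$tip.label, raw_weight = weights,
                    stringsAsFactors = FALSE)
  out <- out[order(out$concept_id), , drop = FALSE]
  out$gsc_weight <- if (mean(out$raw_weight) > 0)
    out$raw_weight / mean(out$raw_weight) else rep(1, nrow(out))
  rownames(out) <- NULL
  out
}

#' Combined concept weight table
#'
#' Convenience wrapper running frequency, rarity, co-occurrence, tree and
#' GSC steps; `combined_weight = rarity_weight * gsc_weight`.
#'
#' @param profiles named list of per-drug concept-id sets.
#' @return `data.frame` with columns `concept_id`, `frequency`,
#'   `rarity_weight`, `gsc_weight`, `combined_weight`.
#' @export
concept_weights <- function(profiles) {
  f <- concept_frequency(profiles)
  rw <- rarity_weights(f)
  gsc <- if (length(f) >= 2L) gsc_weights(build_concept_tree(concept_cooccurrence(profiles)))
         else data.frame(concept_id = names(f), raw_weight = 1, gsc_weight = 1)
  i <- match(names(f), gsc$concept_id)
  data.frame(concept_id = names(f), frequency = unname(f),
             rarity_weight = unname(rw), gsc_weight = gsc$gsc_weight[i],
             combined_weight = unname(rw) * gsc$gsc_weight[i],
             stringsAsFactors = FALSE)
}

self_weight <- function(concepts, weights) {
  sum(weights$combined_weight[match(concepts, weights$concept_id)])
}

#' Toxicity similarity of two drugs
#'
#' Raw score: sum of `combined_weight` over shared side-effect concepts.
#' Normalised score: raw divided by the geometric mean of the two drugs'
#' self-scores (cosine-style), bounded in `[0, 1]` with 1 exactly for
#' identical weighted concept sets and 0 for disjoint ones.
#'
#' @param a,b character vectors of concept ids (the two profiles).
#' @param weights weight table from [concept_weights()]; must cover every
#'   concept in both profiles.
#' @return List with `raw_score` and `normalized_score`.
#' @export
toxicity_similarity <- function(a, b, weights) {
  miss <- setdiff(c(a, b), weights$concept_id)
  if (length(miss))
    ctg_error(paste("concepts missing from weight table:",
                    paste(utils::head(miss, 5L), collapse = ", ")), "ctg_input_error")
  sa <- self_weight(unique(a), weights)
  sb <- self_weight(unique(b), weights)
  if (sa <= 0 || sb <= 0)
    ctg_error("profile has no positively weighted concepts", "ctg_input_error")
  shared <- intersect(a, b)
  raw <- if (length(shared)) self_weight(shared, weights) else 0
  list(raw_score = raw, normalized_score = min(1, raw / sqrt(sa * sb)))
}

#' All pairwise toxicity similarities
#'
#' @param profiles named list of per-drug concept-id sets.
#' @param weights optional weight table; computed from `profiles` when
#'   omitted.
#' @return `data.frame` with one row per unordered drug pair: `id1`, `id2`,
#'   `raw_score`, `score` (the normalised similarity).
#' @export
all_pairs_toxicity <- function(profiles, weights = NULL) {
  if (length(profiles) < 2L)
    ctg_error("need at least two profiles", "ctg_input_error")
  if (is.null(weights)) weights <- concept_weights(profiles)
  ids <- sort(names(profiles))
  combs <- utils::combn(ids, 2L)
  res <- apply(combs, 2L, function(p)
    toxicity_similarity(profiles[[p[1L]]], profiles[[p[2L]]], weights))
  data.frame(id1 = combs[1L, ], id2 = combs[2L, ],
             raw_score = vapply(res, `[[`, numeric(1L), "raw_score"),
             score = vapply(res, `[[`, numeric(1L), "normalized_score"),
             stringsAsFactors = FALSE)
}

#' Write a concept weight table or toxicity edge list to TSV
#' @param x `data.frame` from [concept_weights()] or [all_pairs_toxicity()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
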