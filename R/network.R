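# Substructure-similarity network: threshold filter, Walktrap communities,
# per-community Z-score edge significance.

#' Build a filtered substructure-similarity network
#'
#' Keeps exactly the compound pairs whose Tanimoto score reaches
#' `min_similarity`; pairs below the threshold are removed. All compounds
#' remain as nodes, possibly isolated.
#'
#' @param similarities `data.frame` with columns `id1`, `id2`, `score`
#'   (from [pairwise_similarity()]).
#' @param min_similarity edge-retention threshold in `[0, 1]` (default 0.3).
#' @param nodes optional character vector of node ids; defaults to the ids
#'   appearing in `similarities`.
#' @return A `similarity_network`: list with `nodes`, `edges` (columns
#'   `id1`, `id2`, `score`, `community`, `zscore`, `significant`),
#'   `membership`, `communities`, `parameters`.
#' @export
build_network <- function(similarities, min_similarity = 0.3, nodes = NULL) {
  if (!is.numeric(min_similarity) || length(min_similarity) != 1L ||
      is.na(min_similarity) || min_similarity < 0 || min_similarity > 1)
    ctg_error("min_similarity must be a single value in [0, 1]", "ctg_input_error")
  stopifnot(all(c("id1", "id2", "score") %in% names(similarities)))
  if (any(similarities$score < 0 | similarities$score > 1))
    ctg_error("similarity scores must lie in [0, 1]", "ctg_input_error")
  if (any(similarities$id1 == similarities$id2))
    ctg_error("self-pairs are not allowed", "ctg_input_error")
  nodes <- sort(unique(c(nodes, similarities$id1, similarities$id2)))
  pair <- canonical_pair(similarities$id1, similarities$id2)
  edges <- data.frame(id1 = pair[, "id1"], id2 = pair[, "id2"],
                      score = similarities$score, stringsAsFactors = FALSE)
  if (anyDuplicated(paste(edges$id1, edges$id2)))
    ctg_error("duplicate pairs in similarity table", "ctg_input_error")
  edges <- edges[edges$score >= min_similarity, , drop = FALSE]
  edges <- edges[order(edges$id1, edges$id2), , drop = FALSE]
  edges$community <- rep(NA_integer_, nrow(edges))
  edges$zscore <- rep(NA_real_, nrow(edges))
  edges$significant <- rep(FALSE, nrow(edges))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 membership = NULL, communities = NULL,
                 parameters = list(min_similarity = min_similarity)),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network: %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (!is.null(x$membership))
    cat(sprintf(", %d communities", length(unique(x$membership))))
  cat(sprintf(", %d significant edges>\n", sum(x$edges$significant)))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("id1", "id2", "score")], directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  igraph::E(g)$weight <- net$edges$score
  g
}

#' Detect communities by random walks (Walktrap)
#'
#' Runs the Walktrap agglomerative algorithm on the score-weighted network
#' and keeps the partition with maximum modularity. Isolated nodes each form
#' a singleton community. Community ids are renumbered deterministically by
#' the smallest member id so identical inputs always yield identical labels.
#'
#' @param net a `similarity_network` from [build_network()].
#' @param walk_length random-walk length (default 4, the algorithm's
#'   canonical choice).
#' @param seed integer seed recorded in the network parameters and set
#'   before clustering.
#' @return The network with `membership`, `communities` and per-edge
#'   `community` filled in (edges crossing communities keep `NA`).
#' @export
detect_communities <- function(net, walk_length = 4L, seed = 1L) {
  stopifnot(inherits(net, "similarity_network"))
  if (walk_length < 1) ctg_error("walk_length must be >= 1", "ctg_input_error")
  membership <- integer(0)
  if (length(net$nodes)) {
    g <- as_igraph(net)
    deg <- igraph::degree(g)
    connected <- names(deg)[deg > 0]
    membership <- rep(NA_integer_, length(net$nodes))
    names(membership) <- net$nodes
    if (length(connected)) {
      sub <- igraph::induced_subgraph(g, connected)
      set.seed(as.integer(seed))
      wt <- igraph::cluster_walktrap(sub, weights = igraph::E(sub)$weight,
                                     steps = walk_length)
      membership[igraph::V(sub)$name] <- igraph::membership(wt)
    }
    # singleton communities for isolated nodes
    iso <- is.na(membership)
    if (any(iso))
      membership[iso] <- seq_len(sum(iso)) + max(membership, 0L, na.rm = TRUE)
    # renumber by smallest member id for determinism across igraph versions
    first_member <- vapply(split(names(membership), membership),
                           function(m) min(m), character(1L))
    relabel <- integer(length(first_member))
    relabel[order(first_member)] <- seq_along(first_member)
    names(relabel) <- names(first_member)
    membership <- unname(relabel[as.character(membership)])
    names(membership) <- net$nodes
  }
  net$membership <- membership
  same <- !is.na(membership[net$edges$id1]) &
    membership[net$edges$id1] == membership[net$edges$id2]
  net$edges$community <- ifelse(same, membership[net$edges$id1], NA_integer_)
  net$edges$zscore <- rep(NA_real_, nrow(net$edges))
  net$edges$significant <- rep(FALSE, nrow(net$edges))
  net$parameters$walk_length <- walk_length
  net$parameters$seed <- as.integer(seed)
  net$communities <- community_stats(net)
  net
}

community_stats <- function(net, z_threshold = net$parameters$z_threshold %||% NA_real_) {
  m <- net$membership
  ids <- sort(unique(m))
  stats <- lapply(ids, function(cid) {
    members <- names(m)[m == cid]
    sc <- net$edges$score[!is.na(net$edges$community) & net$edges$community == cid]
    data.frame(community = cid, n_members = length(members), n_edges = length(sc),
               edge_mean = if (length(sc)) mean(sc) else NA_real_,
               edge_sd = if (length(sc) >= 2L) stats::sd(sc) else NA_real_,
               threshold = if (length(sc) >= 2L && !is.na(z_threshold))
                 mean(sc) + z_threshold * stats::sd(sc) else NA_real_)
  })
  do.call(rbind, stats)
}

#' Flag significant edges by per-community Z-score
#'
#' Within each community the Z-score of an edge is
#' `(score - edge_mean) / edge_sd` over that community's internal edges
#' (sample standard deviation). An edge is significant when its Z-score is
#' at least `z_threshold` (one-sided upper: similarity significance rewards
#' high overlap). Inter-community edges are retained but never significant;
#' communities with fewer than two internal edges or zero spread yield no
#' significant edges.
#'
#' @param net a `similarity_network` with communities assigned.
#' @param z_threshold Z-score cut-off (default 1).
#' @return The network with `zscore` and `significant` filled in and
#'   per-community `edge_mean` / `edge_sd` / `threshold` recorded.
#' @export
flag_significant_edges <- function(net, z_threshold = 1) {
  stopifnot(inherits(net, "similarity_network"))
  if (is.null(net$membership))
    ctg_error("run detect_communities() first", "ctg_input_error")
  net$parameters$z_threshold <- z_threshold
  net$edges$zscore <- NA_real_
  net$edges$significant <- FALSE
  for (cid in unique(stats::na.omit(net$edges$community))) {
    sel <- which(!is.na(net$edges$community) & net$edges$community == cid)
    if (length(sel) < 2L) next
    sc <- net$edges$score[sel]
    s <- stats::sd(sc)
    if (s == 0) next
    z <- (sc - mean(sc)) / s
    net$edges$zscore[sel] <- z
    net$edges$significant[sel] <- z >= z_threshold
  }
  net$communities <- community_stats(net, z_threshold)
  net
}

#' Write a similarity network as GraphML plus an edge-list TSV mirror
#'
#' Node attributes: `category`, `superclass`, `community`; edge attributes:
#' `score`, `zscore`, `significant`.
#'
#' @param net a `similarity_network`.
#' @param path output GraphML path; the TSV mirror is written alongside with
#'   extension `.tsv`.
#' @param compounds optional `compound_table` supplying node annotations.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, compounds = NULL) {
  stopifnot(inherits(net, "similarity_network"))
  g <- as_igraph(net)
  if (!is.null(net$membership))
    igraph::V(g)$community <- unname(net$membership[igraph::V(g)$name])
  if (!is.null(compounds)) {
    i <- match(igraph::V(g)$name, compounds$compound_id)
    igraph::V(g)$category <- compounds$category[i]
    igraph::V(g)$superclass <- compounds$superclass[i]
  }
  igraph::E(g)$zscore <- ifelse(is.na(net$edges$zscore), NaN, net$edges$zscore)
  igraph::E(g)$significant <- as.integer(net$edges$significant)
  igraph::write_graph(g, path, format = "graphml")
  tsv <- sub("\\.graphml$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  utils::write.table(net$edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
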