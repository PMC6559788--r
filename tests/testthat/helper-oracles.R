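# Independent oracles and small generators used across the suite.

# set-arithmetic Tanimoto over dense logical vectors, independent of the
# package's sparse-index implementation
tanimoto_oracle <- function(a, b) {
  av <- as.logical(fp_bits(a))
  bv <- as.logical(fp_bits(b))
  u <- sum(av | bv)
  if (u == 0) 0 else sum(av & bv) / u
}

random_fingerprint <- function(density = 0.2) {
  fingerprint(which(runif(881) < density) - 1L)
}

# Simpson dominance through pair-counting combinatorics (independent code
# path from the n(n-1)/(N(N-1)) implementation)
simpson_oracle <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  sum(choose(counts, 2)) / choose(N, 2)
}

# small fixture shared by network/validation/graph tests
small_fixture <- function(seed = 17L, n = 60L, ...) {
  generate_fixture(fixture_spec(n_compounds = n, seed = seed, ...))
}

# similarity network with communities and significance flags for a fixture
fixture_network <- function(fix, min_similarity = 0.3, z_threshold = 1) {
  sims <- pairwise_similarity(fix$compounds)
  net <- build_network(sims, min_similarity, nodes = fix$compounds$compound_id)
  net <- detect_communities(net, seed = 1L)
  flag_significant_edges(net, z_threshold)
}
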