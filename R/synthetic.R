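# Seeded synthetic fixtures.
#
# Generators plant the statistical structure each pipeline stage assumes:
# fingerprint clusters with tunable within-cluster bit sharing and noise,
# superclass labels aligned with clusters, side-effect concepts coupled to
# cluster membership, within-cluster enzyme sharing, and species-abundance
# tables with tunable evenness. One global seed expands to per-stage child
# seeds through a counter scheme so adding a stage never perturbs earlier
# stages' draws. Fingerprints are statistical stand-ins, not valid
# molecules.

#' Specification for a synthetic fixture
#'
#' Defaults are chosen as a small but realistic regime for this kind of
#' data: clearly separated substructure clusters (within-cluster Tanimoto
#' far above the 0.3 edge threshold, between-cluster below it), strong but
#' imperfect superclass-cluster alignment, and moderately uneven species
#' abundances.
#'
#' @param n_compounds number of compounds (default 200).
#' @param n_clusters number of planted substructure clusters (default 4).
#' @param shared_bit_fraction fraction of the 881 bits set in each cluster
#'   template (default 0.25).
#' @param bit_flip_noise per-bit flip probability applied to each member's
#'   copy of its template (default 0.02).
#' @param category_proportions named proportions over
#'   `drug`/`food`/`endogenous` (default 0.4/0.4/0.2).
#' @param superclass_alignment probability a compound carries its cluster's
#'   superclass rather than a random other one (default 0.9).
#' @param n_concepts side-effect vocabulary size (default 30).
#' @param concepts_per_drug side-effect concepts drawn per drug (default 6).
#' @param coupling structure-toxicity coupling strength in `[0, 1]`: the
#'   probability each concept draw comes from the drug's cluster-specific
#'   pool rather than the whole vocabulary (default 0.8). 0 gives
#'   independence.
#' @param n_enzymes number of EC numbers (default 10).
#' @param enzyme_sharing probability that a within-cluster compound pair
#'   shares its cluster's enzyme (default 0.8).
#' @param background_ec_rate probability a compound additionally carries one
#'   uniformly random enzyme (default 0.02).
#' @param n_species species pool size for abundance tables (default 20).
#' @param evenness Dirichlet concentration controlling abundance evenness;
#'   large values approach equal abundances (default 5).
#' @param abundance_total individuals per enzyme abundance table
#'   (default 1000).
#' @param seed global integer seed (default 1).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_compounds = 200L, n_clusters = 4L,
                         shared_bit_fraction = 0.25, bit_flip_noise = 0.02,
                         category_proportions = c(drug = 0.4, food = 0.4, endogenous = 0.2),
                         superclass_alignment = 0.9,
                         n_concepts = 30L, concepts_per_drug = 6L, coupling = 0.8,
                         n_enzymes = 10L, enzyme_sharing = 0.8,
                         background_ec_rate = 0.02,
                         n_species = 20L, evenness = 5, abundance_total = 1000L,
                         seed = 1L) {
  spec <- list(n_compounds = as.integer(n_compounds), n_clusters = as.integer(n_clusters),
               shared_bit_fraction = shared_bit_fraction, bit_flip_noise = bit_flip_noise,
               category_proportions = category_proportions,
               superclass_alignment = superclass_alignment,
               n_concepts = as.integer(n_concepts),
               concepts_per_drug = as.integer(concepts_per_drug),
               coupling = coupling, n_enzymes = as.integer(n_enzymes),
               enzyme_sharing = enzyme_sharing, background_ec_rate = background_ec_rate,
               n_species = as.integer(n_species), evenness = evenness,
               abundance_total = as.integer(abundance_total), seed = as.integer(seed))
  probs <- c(spec$shared_bit_fraction, spec$bit_flip_noise, spec$superclass_alignment,
             spec$coupling, spec$enzyme_sharing, spec$background_ec_rate,
             spec$category_proportions)
  if (any(probs < 0 | probs > 1))
    ctg_error("all probabilities must lie in [0, 1]", "ctg_input_error")
  if (any(c(spec$n_compounds, spec$n_clusters, spec$n_concepts, spec$n_enzymes,
            spec$n_species) < 1L))
    ctg_error("counts must be positive", "ctg_input_error")
  if (spec$n_clusters > spec$n_compounds)
    ctg_error("more clusters than compounds", "ctg_input_error")
  structure(spec, class = "fixture_spec")
}

# stage counters for the child-seed scheme
.STAGE <- c(compounds = 1L, side_effects = 2L, enzyme_map = 3L,
            abundance = 4L, descriptors = 5L)

#' Generate a synthetic compound table with planted clusters
#'
#' Each cluster gets a random template bit set of
#' `round(881 * shared_bit_fraction)` bits; members copy the template and
#' flip every bit independently at `bit_flip_noise`. Categories follow the
#' configured proportions; each compound's superclass matches its cluster's
#' with probability `superclass_alignment`. Planted cluster labels are
#' attached as attribute `truth`.
#'
#' @param spec a [fixture_spec()].
#' @return A `compound_table` with attribute `truth` (`data.frame`:
#'   `compound_id`, `cluster`).
#' @export
generate_compounds <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(child_seed(spec$seed, .STAGE[["compounds"]]))
  n <- spec$n_compounds; k <- spec$n_clusters
  ids <- sprintf("cmpd_%03d", seq_len(n))
  cluster <- rep(seq_len(k), length.out = n)
  ntemplate <- max(1L, round(FP_NBITS * spec$shared_bit_fraction))
  templates <- lapply(seq_len(k), function(i) sample.int(FP_NBITS, ntemplate) - 1L)
  fps <- vector("list", n)
  for (i in seq_len(n)) {
    bits <- integer(FP_NBITS)
    bits[templates[[cluster[i]]] + 1L] <- 1L
    flip <- stats::runif(FP_NBITS) < spec$bit_flip_noise
    bits[flip] <- 1L - bits[flip]
    fps[[i]] <- fingerprint(which(bits == 1L) - 1L)
  }
  names(fps) <- ids
  cats <- sample(names(spec$category_proportions), n, replace = TRUE,
                 prob = spec$category_proportions)
  super_of_cluster <- sprintf("superclass_%02d", seq_len(k))
  superclass <- vapply(seq_len(n), function(i) {
    if (k == 1L || stats::runif(1) < spec$superclass_alignment)
      super_of_cluster[cluster[i]]
    else sample(super_of_cluster[-cluster[i]], 1L)
  }, character(1L))
  df <- data.frame(compound_id = ids, name = paste0("compound ", seq_len(n)),
                   category = cats, superclass = superclass, stringsAsFactors = FALSE)
  out <- as_compound_table(df, fps)
  attr(out, "truth") <- data.frame(compound_id = ids, cluster = cluster,
                                   stringsAsFactors = FALSE)
  out
}

#' Generate cluster-coupled synthetic side-effect profiles
#'
#' Drugs draw `concepts_per_drug` concepts; each draw comes from the drug's
#' cluster-specific concept pool with probability `coupling` and uniformly
#' from the whole vocabulary otherwise, so concept-set similarity rises with
#' fingerprint similarity at the configured strength; `coupling = 0` gives
#' independence. Every drug receives at least one concept.
#'
#' @param spec a [fixture_spec()].
#' @param compounds output of [generate_compounds()].
#' @return Named list of per-drug concept-id sets (drugs only).
#' @export
generate_side_effects <- function(spec, compounds) {
  stopifnot(inherits(spec, "fixture_spec"))
  truth <- attr(compounds, "truth")
  if (spec$concepts_per_drug > spec$n_concepts)
    ctg_error("vocabulary smaller than the per-drug draw", "ctg_input_error")
  set.seed(child_seed(spec$seed, .STAGE[["side_effects"]]))
  vocab <- sprintf("concept_%02d", seq_len(spec$n_concepts))
  pool_size <- max(2L, min(spec$concepts_per_drug + 1L,
                           spec$n_concepts %/% spec$n_clusters))
  pools <- lapply(seq_len(spec$n_clusters), function(i) sample(vocab, pool_size))
  drugs <- compounds$compound_id[compounds$category == "drug"]
  profiles <- lapply(drugs, function(id) {
    cl <- truth$cluster[truth$compound_id == id]
    draws <- vapply(seq_len(spec$concepts_per_drug), function(j) {
      if (stats::runif(1) < spec$coupling) sample(pools[[cl]], 1L)
      else sample(vocab, 1L)
    }, character(1L))
    out <- unique(draws)
    if (!length(out)) out <- sample(vocab, 1L)
    sort(out)
  })
  names(profiles) <- drugs
  profiles
}

#' Generate a synthetic compound-enzyme map with within-cluster sharing
#'
#' Each cluster owns one EC number; a member carries it with probability
#' `sqrt(enzyme_sharing)`, so an independent within-cluster pair shares the
#' enzyme with probability `enzyme_sharing`. Each compound additionally
#' carries one uniformly random enzyme with probability
#' `background_ec_rate`, providing rare between-cluster sharing.
#'
#' @param spec a [fixture_spec()].
#' @param compounds output of [generate_compounds()].
#' @return `data.frame` with columns `ec_number`, `compound_id`.
#' @export
generate_enzyme_map <- function(spec, compounds) {
  stopifnot(inherits(spec, "fixture_spec"))
  truth <- attr(compounds, "truth")
  set.seed(child_seed(spec$seed, .STAGE[["enzyme_map"]]))
  ecs <- sprintf("3.2.1.%d", seq_len(spec$n_enzymes))
  cluster_ec <- ecs[rep(seq_len(min(spec$n_enzymes, spec$n_clusters)),
                        length.out = spec$n_clusters)]
  q <- sqrt(spec$enzyme_sharing)
  rows <- list()
  for (i in seq_len(nrow(compounds))) {
    id <- compounds$compound_id[i]
    cl <- truth$cluster[truth$compound_id == id]
    if (stats::runif(1) < q)
      rows[[length(rows) + 1L]] <- data.frame(ec_number = cluster_ec[cl],
                                              compound_id = id, stringsAsFactors = FALSE)
    if (stats::runif(1) < spec$background_ec_rate)
      rows[[length(rows) + 1L]] <- data.frame(ec_number = sample(ecs, 1L),
                                              compound_id = id, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(ec_number = character(), compound_id = character(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' Generate synthetic physiochemical descriptors
#'
#' Twelve numeric descriptors in six groups (geometry, functional groups,
#' aromaticity, amino acid composition, polarity, hydrophobicity), drawn
#' around cluster-specific means so descriptor differences are informative
#' about shared metabolism in the planted data.
#'
#' @param spec a [fixture_spec()].
#' @param compounds output of [generate_compounds()].
#' @return `data.frame`: `compound_id` plus one column per descriptor.
#' @export
generate_descriptors <- function(spec, compounds) {
  stopifnot(inherits(spec, "fixture_spec"))
  truth <- attr(compounds, "truth")
  set.seed(child_seed(spec$seed, .STAGE[["descriptors"]]))
  groups <- c("geometry", "functional_groups", "aromaticity",
              "amino_acid_composition", "polarity", "hydrophobicity")
  cols <- as.vector(outer(groups, 1:2, paste, sep = "_"))
  centers <- matrix(stats::rnorm(spec$n_clusters * length(cols), sd = 2),
                    nrow = spec$n_clusters)
  cl <- truth$cluster[match(compounds$compound_id, truth$compound_id)]
  vals <- centers[cl, , drop = FALSE] +
    matrix(stats::rnorm(nrow(compounds) * length(cols)), nrow = nrow(compounds))
  out <- data.frame(compound_id = compounds$compound_id, vals, stringsAsFactors = FALSE)
  names(out) <- c("compound_id", cols)
  out
}

#' Generate a species-abundance table for one enzyme
#'
#' Species proportions are Dirichlet-distributed with concentration
#' `evenness` (larger is more even) and multiplied into `abundance_total`
#' individuals. When `target_ecsd` is given, counts are instead solved so
#' the resulting ECs_D is within 0.02 of the target: one dominant species
#' takes a share `a` and the remaining `k - 1` split the rest evenly, `a`
#' solved from the dominance formula.
#'
#' @param spec a [fixture_spec()].
#' @param enzyme_id EC number for the table (default "3.2.1.1").
#' @param target_ecsd optional target in `[0, 1 - 1/n_species]`.
#' @return An [enzyme_abundance()].
#' @export
generate_abundance <- function(spec, enzyme_id = "3.2.1.1", target_ecsd = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(child_seed(spec$seed, .STAGE[["abundance"]]) +
             sum(utf8ToInt(enzyme_id)))
  k <- spec$n_species
  N <- spec$abundance_total
  species <- sprintf("species_%02d", seq_len(k))
  if (is.null(target_ecsd)) {
    p <- stats::rgamma(k, shape = spec$evenness)
    p <- p / sum(p)
    counts <- stats::rmultinom(1L, N, p)[, 1L]
    return(enzyme_abundance(enzyme_id, stats::setNames(counts, species)))
  }
  max_ecsd <- 1 - (N / k - 1) / (N - 1)   # even allocation, finite N
  if (target_ecsd < 0 || target_ecsd > max_ecsd + 0.02)
    ctg_error(sprintf("target_ecsd %.3f unreachable with %d species (max %.3f)",
                      target_ecsd, k, max_ecsd), "ctg_domain_error")
  if (target_ecsd < 1e-9)
    return(enzyme_abundance(enzyme_id, stats::setNames(N, species[1L])))
  dom <- function(a) {
    c1 <- a * N; c2 <- (1 - a) * N / (k - 1)
    (c1 * (c1 - 1) + (k - 1) * c2 * (c2 - 1)) / (N * (N - 1))
  }
  target_d <- 1 - target_ecsd
  lo <- 1 / k; hi <- 1
  a <- stats::uniroot(function(a) dom(a) - target_d, c(lo, hi),
                      tol = 1e-10, extendInt = "upX")$root
  counts <- c(round(a * N), rep(round((1 - a) * N / (k - 1)), k - 1L))
  counts[1L] <- counts[1L] + (N - sum(counts))   # keep the total exact
  counts <- counts[counts > 0]
  enzyme_abundance(enzyme_id, stats::setNames(counts, species[seq_along(counts)]))
}

#' Generate and write a complete fixture
#'
#' Produces every input table the pipeline consumes, writes them in the TSV
#' dialects the readers expect, and records the planted truths (cluster
#' labels, coupling, sharing probability, seed) in a `truth.json` sidecar.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed); `NULL` returns the
#'   in-memory fixture without writing.
#' @return List with `compounds`, `side_effects`, `enzyme_map`,
#'   `descriptors`, `abundance` (list of [enzyme_abundance()]), `truth`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  compounds <- generate_compounds(spec)
  side_effects <- generate_side_effects(spec, compounds)
  enzyme_map <- generate_enzyme_map(spec, compounds)
  descriptors <- generate_descriptors(spec, compounds)
  ecs <- sprintf("3.2.1.%d", seq_len(spec$n_enzymes))
  abundance <- lapply(ecs, function(ec) generate_abundance(spec, ec))
  names(abundance) <- ecs
  tr <- attr(compounds, "truth")
  drugs <- compounds$compound_id[compounds$category == "drug"]
  uses <- data.frame(compound_id = drugs,
                     use = sprintf("use_%02d",
                                   tr$cluster[match(drugs, tr$compound_id)]),
                     stringsAsFactors = FALSE)
  truth <- list(cluster = attr(compounds, "truth"),
                coupling = spec$coupling, enzyme_sharing = spec$enzyme_sharing,
                seed = spec$seed)
  fix <- list(compounds = compounds, side_effects = side_effects,
              enzyme_map = enzyme_map, descriptors = descriptors,
              abundance = abundance, uses = uses, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_compounds(compounds, file.path(dir, "compounds.tsv"))
    se <- data.frame(
      compound_id = rep(names(side_effects), lengths(side_effects)),
      concept_id = unlist(side_effects, use.names = FALSE), stringsAsFactors = FALSE)
    se$concept_name <- sub("concept", "side effect", se$concept_id)
    utils::write.table(se, file.path(dir, "side_effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(enzyme_map, file.path(dir, "enzyme_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(descriptors, file.path(dir, "descriptors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ab <- do.call(rbind, lapply(abundance, function(tb)
      data.frame(ec_number = tb$enzyme_id, species_id = names(tb$counts),
                 count = unname(tb$counts), stringsAsFactors = FALSE)))
    utils::write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(uses, file.path(dir, "uses.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  fix
}
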