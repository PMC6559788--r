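# Probability that a compound pair shares a metabolising enzyme.
#
# Pairs are labelled associated when the two compounds' EC sets intersect.
# Features are symmetric: the pair's Tanimoto similarity plus the absolute
# difference of each physiochemical descriptor. A radial-kernel margin
# classifier with Platt-style probability calibration turns the margin into
# P(associated); the binary problem is the degenerate single case of a
# one-vs-one decomposition.

#' Read a physiochemical descriptor table
#'
#' Expects a `compound_id` column plus one numeric column per descriptor.
#'
#' @param path TSV file path.
#' @return `data.frame` keyed by `compound_id`.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(df))
    ctg_error("descriptor table needs a compound_id column", "ctg_format_error")
  if (!all(vapply(df[setdiff(names(df), "compound_id")], is.numeric, logical(1L))))
    ctg_error("descriptor columns must be numeric", "ctg_format_error")
  df
}

#' Read a compound-enzyme map
#'
#' Expects columns `ec_number`, `compound_id`. Rows whose compound is
#' missing from `compounds` (when given) are logged and skipped.
#'
#' @param path TSV file path.
#' @param compounds optional `compound_table` for id resolution.
#' @return `data.frame` with columns `ec_number`, `compound_id`.
#' @export
read_enzyme_map <- function(path, compounds = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("ec_number", "compound_id") %in% names(df)))
    ctg_error("enzyme map needs ec_number and compound_id columns", "ctg_format_error")
  df <- unique(df[, c("ec_number", "compound_id")])
  if (!is.null(compounds)) {
    bad <- !df$compound_id %in% compounds$compound_id
    if (any(bad)) {
      message(sprintf("skipping %d enzyme-map row(s) with unresolvable compound ids",
                      sum(bad)))
      df <- df[!bad, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

#' Label all compound pairs by shared-enzyme status
#'
#' A pair is `associated` when the two compounds are substrates of at least
#' one common EC number, `non-associated` otherwise.
#'
#' @param compounds a `compound_table`.
#' @param enzyme_map `data.frame` with `ec_number`, `compound_id`.
#' @return `data.frame` with columns `id1`, `id2`, `label` (factor,
#'   levels `associated`, `non_associated`).
#' @export
label_pairs <- function(compounds, enzyme_map) {
  if (!nrow(enzyme_map))
    ctg_error("enzyme map is empty", "ctg_input_error")
  ecs_of <- split(enzyme_map$ec_number, enzyme_map$compound_id)
  ids <- sort(compounds$compound_id)
  combs <- utils::combn(ids, 2L)
  shared <- vapply(seq_len(ncol(combs)), function(j) {
    e1 <- ecs_of[[combs[1L, j]]]
    e2 <- ecs_of[[combs[2L, j]]]
    !is.null(e1) && !is.null(e2) && length(intersect(e1, e2)) > 0L
  }, logical(1L))
  data.frame(id1 = combs[1L, ], id2 = combs[2L, ],
             label = factor(ifelse(shared, "associated", "non_associated"),
                            levels = c("associated", "non_associated")),
             stringsAsFactors = FALSE)
}

#' Symmetric pair features
#'
#' `[tanimoto similarity] ++ [|descriptor difference|]` for every labelled
#' pair; order-invariant by construction.
#'
#' @param pairs `data.frame` from [label_pairs()] (or any `id1`/`id2` table).
#' @param compounds a `compound_table`.
#' @param descriptors descriptor `data.frame` from [read_descriptors()] /
#'   [generate_descriptors()].
#' @return Numeric matrix, first column `tanimoto`.
#' @export
pair_features <- function(pairs, compounds, descriptors) {
  sims <- pairwise_similarity(compounds)
  key <- paste(sims$id1, sims$id2)
  sim <- sims$score[match(paste(pairs$id1, pairs$id2), key)]
  if (anyNA(sim))
    ctg_error("pair not found among compound similarities", "ctg_input_error")
  dcols <- setdiff(names(descriptors), "compound_id")
  d1 <- as.matrix(descriptors[match(pairs$id1, descriptors$compound_id), dcols])
  d2 <- as.matrix(descriptors[match(pairs$id2, descriptors$compound_id), dcols])
  if (anyNA(d1) || anyNA(d2))
    ctg_error("descriptors missing for some compounds", "ctg_input_error")
  out <- cbind(tanimoto = sim, abs(d1 - d2))
  colnames(out) <- c("tanimoto", paste0("d_", dcols))
  out
}

#' Train the shared-enzyme probability model
#'
#' Radial-kernel support-vector classifier with Platt-style probability
#' calibration. Features are standardised internally on the training data;
#' the kernel bandwidth follows the median heuristic on pairwise feature
#' distances; class imbalance is handled by down-sampling the majority
#' class to at most `max_ratio`:1 (seeded). Training is deterministic given
#' the seed.
#'
#' @param features numeric matrix from [pair_features()].
#' @param labels factor with levels `associated`, `non_associated`.
#' @param seed integer seed.
#' @param max_ratio majority:minority cap applied before fitting
#'   (default 5).
#' @return A `pair_svm` model.
#' @export
train_probability_model <- function(features, labels, seed = 1L, max_ratio = 5) {
  labels <- factor(labels, levels = c("associated", "non_associated"))
  if (nlevels(droplevels(labels)) < 2L)
    ctg_error("both labels must be present to train", "ctg_input_error")
  stopifnot(nrow(features) == length(labels))
  set.seed(as.integer(seed))
  tab <- table(labels)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  keep <- seq_along(labels)
  cap <- ceiling(max_ratio * min(tab))
  if (tab[majority] > cap) {
    maj_idx <- which(labels == majority)
    keep <- sort(c(which(labels == minority), sample(maj_idx, cap)))
  }
  x <- features[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  # median heuristic on a subsample of pairwise distances
  sub <- x[sample(nrow(x), min(nrow(x), 200L)), , drop = FALSE]
  sub <- scale(sub)
  sub[, attr(sub, "scaled:scale") == 0] <- 0
  med <- stats::median(stats::dist(sub))
  gamma <- if (is.finite(med) && med > 0) 1 / (2 * med^2) else 1 / ncol(x)
  set.seed(as.integer(seed))
  fit <- e1071::svm(x, y, kernel = "radial", gamma = gamma,
                    probability = TRUE, scale = TRUE)
  structure(list(fit = fit, gamma = gamma, seed = as.integer(seed),
                 levels = levels(y)), class = "pair_svm")
}

#' Predicted probability of sharing an enzyme
#'
#' @param object a `pair_svm` model.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return Numeric vector of `P(associated)` in `[0, 1]`.
#' @export
predict.pair_svm <- function(object, newdata, ...) {
  p <- attr(stats::predict(object$fit, newdata, probability = TRUE),
            "probabilities")
  unname(p[, "associated"])
}

#' Out-of-fold predicted probabilities by stratified cross-validation
#'
#' Five-fold (by default) stratified splits; the model, including its
#' internal standardisation, is refit on each training fold so no test
#' information leaks into the scaling.
#'
#' @param features numeric matrix from [pair_features()].
#' @param labels factor with levels `associated`, `non_associated`.
#' @param folds number of folds (default 5).
#' @param seed integer seed.
#' @param max_ratio passed to [train_probability_model()].
#' @return Numeric vector of out-of-fold `P(associated)`, aligned with rows.
#' @export
cross_validated_probabilities <- function(features, labels, folds = 5L, seed = 1L,
                                          max_ratio = 5) {
  labels <- factor(labels, levels = c("associated", "non_associated"))
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  out <- rep(NA_real_, length(labels))
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- train_probability_model(features[tr, , drop = FALSE], labels[tr],
                                     seed = child_seed(seed, f), max_ratio = max_ratio)
    out[!tr] <- predict(model, features[!tr, , drop = FALSE])
  }
  out
}

#' Mean predicted probability by similarity bin and label class
#'
#' Bin edges are uniform on `[0, 1]` over the pair's Tanimoto similarity;
#' per bin and label class the count and mean predicted probability are
#' reported (mean `NA` for empty cells).
#'
#' @param probabilities vector of `P(associated)` per pair.
#' @param features feature matrix whose first column is `tanimoto`.
#' @param labels factor of pair labels.
#' @param bins number of similarity bins (default 10).
#' @return `data.frame`: `bin_low`, `bin_high`, `class`, `n`,
#'   `mean_probability`.
#' @export
probability_vs_similarity_curve <- function(probabilities, features, labels,
                                            bins = 10L) {
  sim <- features[, "tanimoto"]
  edges <- seq(0, 1, length.out = bins + 1L)
  bin <- pmin(findInterval(sim, edges, rightmost.closed = TRUE), bins)
  labels <- factor(labels, levels = c("associated", "non_associated"))
  grid <- expand.grid(bin = seq_len(bins), class = levels(labels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- bin == grid$bin[i] & labels == grid$class[i]
    data.frame(bin_low = edges[grid$bin[i]], bin_high = edges[grid$bin[i] + 1L],
               class = grid$class[i], n = sum(sel),
               mean_probability = if (any(sel)) mean(probabilities[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
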