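# Enzyme-specific taxonomic dominance.
#
# For each enzyme (EC number) with species-level carrier counts n summing to
# N, the Simpson dominance is D = sum n(n-1) / (N(N-1)); the reported score
# is ECs_D = 1 - D. Values near 0 mark functions concentrated in few
# species; values near 1 mark taxonomically diverse functions.

#' Species-level abundance table for one enzyme
#'
#' @param enzyme_id EC number (dotted string).
#' @param counts named non-negative integer vector: individuals of each
#'   species carrying the enzyme. Zero-count species are ignored.
#' @return An `enzyme_abundance` object with `enzyme_id`, `counts`, `total`.
#' @export
enzyme_abundance <- function(enzyme_id, counts) {
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    ctg_error("counts must be uniquely named by species id", "ctg_input_error")
  if (any(counts < 0) || any(counts != round(counts)))
    ctg_error("counts must be non-negative integers", "ctg_input_error")
  counts <- counts[counts > 0]
  structure(list(enzyme_id = as.character(enzyme_id),
                 counts = counts, total = sum(counts)),
            class = "enzyme_abundance")
}

#' Simpson dominance of an enzyme's species distribution
#'
#' `D = sum_species n(n-1) / (N(N-1))`: the probability that two individuals
#' drawn without replacement carry the enzyme in the same species. Undefined
#' (error) when fewer than two individuals are present.
#'
#' @param table an [enzyme_abundance()].
#' @return Dominance in `[0, 1]`.
#' @export
simpson_dominance <- function(table) {
  stopifnot(inherits(table, "enzyme_abundance"))
  N <- table$total
  if (N < 2)
    ctg_error("dominance undefined for fewer than two individuals", "ctg_domain_error")
  n <- as.numeric(table$counts)
  sum(n * (n - 1)) / (N * (N - 1))
}

#' Enzyme-specific dominance score (ECs_D)
#'
#' One minus the Simpson dominance: near 0 for single-species functions,
#' near 1 for taxonomically diverse ones.
#'
#' @param table an [enzyme_abundance()].
#' @return List with `enzyme_id`, `dominance`, `ecsd`.
#' @export
ecsd <- function(table) {
  d <- simpson_dominance(table)
  list(enzyme_id = table$enzyme_id, dominance = d, ecsd = 1 - d)
}

#' Score a cohort of enzymes and classify by dominance
#'
#' Computes ECs_D per enzyme, the cohort mean and standard deviation over
#' scoreable enzymes, and labels enzymes falling below the cohort mean as
#' high-dominance / low-diversity. The classification threshold is always
#' the recomputed cohort mean, never a fixed constant. Enzymes with fewer
#' than two individuals are reported as not scoreable.
#'
#' @param tables list of [enzyme_abundance()] objects.
#' @return List with `scores` (`data.frame`: `ec_number`, `dominance`,
#'   `ecsd`, `scoreable`, `classification`), `mean`, `sd`, `band`
#'   (mean +/- 1 sd).
#' @export
ecsd_table <- function(tables) {
  stopifnot(length(tables) >= 1L)
  rows <- lapply(tables, function(tb) {
    stopifnot(inherits(tb, "enzyme_abundance"))
    if (tb$total >= 2) {
      s <- ecsd(tb)
      data.frame(ec_number = tb$enzyme_id, dominance = s$dominance,
                 ecsd = s$ecsd, scoreable = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(ec_number = tb$enzyme_id, dominance = NA_real_,
                 ecsd = NA_real_, scoreable = FALSE, stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  if (!any(df$scoreable))
    ctg_error("no scoreable enzyme (all N < 2)", "ctg_domain_error")
  m <- mean(df$ecsd[df$scoreable])
  s <- if (sum(df$scoreable) >= 2L) stats::sd(df$ecsd[df$scoreable]) else NA_real_
  df$classification <- ifelse(!df$scoreable, "not_scoreable",
                              ifelse(df$ecsd < m, "high_dominance", "diverse"))
  rownames(df) <- NULL
  list(scores = df, mean = m, sd = s,
       band = c(lower = m - s, upper = m + s))
}

#' Read a taxon-enzyme abundance TSV
#'
#' Expects columns `ec_number`, `species_id`, `count`.
#'
#' @param path TSV file path.
#' @return Named list of [enzyme_abundance()] objects, one per EC number.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  if (!all(c("ec_number", "species_id", "count") %in% names(df)))
    ctg_error("abundance table needs ec_number, species_id, count columns",
              "ctg_format_error")
  by_ec <- split(df, df$ec_number)
  out <- lapply(by_ec, function(d)
    enzyme_abundance(d$ec_number[1L], stats::setNames(d$count, d$species_id)))
  out[sort(names(out))]
}

#' Write ECs_D scores to TSV
#'
#' Columns `ec_number dominance ecsd classification`.
#'
#' @param scores result of [ecsd_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ecsd_tsv <- function(scores, path) {
  utils::write.table(scores$scores[, c("ec_number", "dominance", "ecsd", "classification")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
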