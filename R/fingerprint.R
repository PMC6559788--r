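# Substructure fingerprints and Tanimoto similarity.
#
# Compounds carry PubChem-style 881-bit binary substructure keys. A
# fingerprint is stored sparsely as the sorted vector of 0-based set-bit
# positions; the CACTVS wire format (base64 over a 4-byte big-endian bit
# count plus MSB-first bit-packed data) is supported for round-trip I/O.

FP_NBITS <- 881L

#' Construct a substructure fingerprint
#'
#' @param bits integer vector of 0-based set-bit positions (duplicates
#'   removed, order irrelevant), or a logical/0-1 vector of length 881.
#' @return An object of class `fingerprint`: sorted 0-based set-bit
#'   positions with attribute `nbits = 881`.
#' @examples
#' fp <- fingerprint(c(0, 5, 880))
#' popcount(fp)
#' @export
fingerprint <- function(bits = integer()) {
  if (is.logical(bits) || (length(bits) == FP_NBITS && all(bits %in% c(0, 1)))) {
    if (length(bits) != FP_NBITS)
      ctg_error("logical bit vector must have length 881", "ctg_dimension_error")
    bits <- which(as.logical(bits)) - 1L
  }
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 0L || max(bits) >= FP_NBITS))
    ctg_error("set-bit positions must lie in [0, 880]", "ctg_dimension_error")
  structure(bits, nbits = FP_NBITS, class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d bits, popcount %d>\n", attr(x, "nbits"), length(x)))
  invisible(x)
}

#' Number of set bits in a fingerprint
#' @param fp a [fingerprint()].
#' @return Integer popcount.
#' @export
popcount <- function(fp) {
  stopifnot(inherits(fp, "fingerprint"))
  length(unclass(fp))
}

#' Dense 0/1 representation of a fingerprint
#' @param fp a [fingerprint()].
#' @return Integer vector of length 881.
#' @export
fp_bits <- function(fp) {
  stopifnot(inherits(fp, "fingerprint"))
  v <- integer(FP_NBITS)
  v[unclass(fp) + 1L] <- 1L
  v
}

#' Decode a base64 CACTVS-encoded fingerprint
#'
#' The decoded byte stream must carry a 4-byte big-endian bit-length prefix
#' (always 881 here) followed by MSB-first bit-packed data whose trailing pad
#' bits are zero.
#'
#' @param encoded a base64 string.
#' @return A [fingerprint()].
#' @export
decode_cactvs <- function(encoded) {
  stopifnot(is.character(encoded), length(encoded) == 1L)
  raw <- tryCatch(jsonlite::base64_dec(encoded),
                  error = function(e) ctg_error("malformed base64 input", "ctg_format_error"))
  if (length(raw) < 4L)
    ctg_error("byte stream shorter than the 4-byte length prefix", "ctg_format_error")
  nbits <- sum(as.integer(raw[1:4]) * c(256^3, 256^2, 256, 1))
  if (nbits != FP_NBITS)
    ctg_error(sprintf("declared bit length %d, expected 881", nbits), "ctg_dimension_error")
  ndata <- ceiling(FP_NBITS / 8)
  if (length(raw) != 4L + ndata)
    ctg_error(sprintf("expected %d data bytes, found %d", ndata, length(raw) - 4L),
              "ctg_format_error")
  # rawToBits is LSB-first within each byte; flip to MSB-first
  m <- matrix(as.integer(rawToBits(raw[-(1:4)])), nrow = 8L)
  bits <- as.vector(m[8:1, , drop = FALSE])
  if (any(bits[(FP_NBITS + 1L):length(bits)] != 0L))
    ctg_error("nonzero pad bits after position 880", "ctg_format_error")
  fingerprint(which(bits[1:FP_NBITS] == 1L) - 1L)
}

#' Encode a fingerprint in the base64 CACTVS wire format
#'
#' Inverse of [decode_cactvs()]: `decode_cactvs(encode_cactvs(fp))` is the
#' identity.
#'
#' @param fp a [fingerprint()].
#' @return A base64 string.
#' @export
encode_cactvs <- function(fp) {
  stopifnot(inherits(fp, "fingerprint"))
  nbytes <- ceiling(FP_NBITS / 8)
  bits <- c(fp_bits(fp), integer(nbytes * 8L - FP_NBITS))
  m <- matrix(bits, nrow = 8L)
  data <- packBits(as.raw(as.vector(m[8:1, , drop = FALSE])), type = "raw")
  prefix <- as.raw(c(FP_NBITS %/% 256^3, (FP_NBITS %/% 256^2) %% 256,
                     (FP_NBITS %/% 256) %% 256, FP_NBITS %% 256))
  gsub("\n", "", jsonlite::base64_enc(c(prefix, data)), fixed = TRUE)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A n B| / |A u B|` over the set-bit sets. Defined as 0 when both
#' fingerprints are all-zero (the 0/0 case carries no substructure evidence).
#'
#' @param a,b [fingerprint()] objects.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(fingerprint(1:3), fingerprint(2:4))  # 0.5
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (attr(a, "nbits") != attr(b, "nbits"))
    ctg_error("fingerprint dimensions differ", "ctg_dimension_error")
  na <- length(unclass(a)); nb <- length(unclass(b))
  if (na == 0L && nb == 0L) return(0)
  ni <- length(intersect(unclass(a), unclass(b)))
  ni / (na + nb - ni)
}

#' All pairwise Tanimoto similarities for a compound set
#'
#' Computed through a dense bit-matrix cross product; one row per unordered
#' pair, keyed by the canonical (lexicographically ordered) pair.
#'
#' @param compounds a `compound_table` (see [read_compounds()]) or a named
#'   list of [fingerprint()] objects.
#' @return A `data.frame` with columns `id1`, `id2`, `score`.
#' @export
pairwise_similarity <- function(compounds) {
  fps <- compound_fingerprints(compounds)
  if (length(fps) < 2L)
    ctg_error("need at least two compounds", "ctg_input_error")
  if (anyDuplicated(names(fps)))
    ctg_error("duplicate compound ids", "ctg_input_error")
  ids <- names(fps)
  M <- vapply(fps, fp_bits, integer(FP_NBITS))      # 881 x n
  inter <- crossprod(M)                             # n x n set-bit overlaps
  pop <- diag(inter)
  uni <- outer(pop, pop, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  pair <- canonical_pair(ids[idx[, 1L]], ids[idx[, 2L]])
  out <- data.frame(id1 = pair[, "id1"], id2 = pair[, "id2"],
                    score = sim[idx], stringsAsFactors = FALSE)
  out[order(out$id1, out$id2), , drop = FALSE]
}

# Accept either a compound table or a plain named list of fingerprints.
compound_fingerprints <- function(compounds) {
  if (inherits(compounds, "compound_table")) return(attr(compounds, "fingerprints"))
  if (is.list(compounds) && all(vapply(compounds, inherits, TRUE, "fingerprint"))) {
    if (is.null(names(compounds)))
      ctg_error("fingerprint list must be named by compound id", "ctg_input_error")
    return(compounds)
  }
  ctg_error("expected a compound_table or named list of fingerprints", "ctg_input_error")
}

#' Read a compound table from TSV
#'
#' Expects a UTF-8 header `compound_id name category superclass fingerprint`.
#' The fingerprint column is auto-detected per row: either a base64 CACTVS
#' string or a comma-separated list of 0-based set-bit indices (an empty
#' index list denotes an all-zero fingerprint). Rows with a missing
#' fingerprint are dropped with a warning; real inputs are incomplete.
#'
#' @param path TSV file path.
#' @return A `compound_table`: a `data.frame` with columns `compound_id`,
#'   `name`, `category`, `superclass`, and an attribute `fingerprints`
#'   holding a named list of [fingerprint()] objects.
#' @export
read_compounds <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  need <- c("compound_id", "name", "category", "superclass", "fingerprint")
  if (!all(need %in% names(df)))
    ctg_error(paste("compound table missing columns:",
                    paste(setdiff(need, names(df)), collapse = ", ")),
              "ctg_format_error")
  if (anyDuplicated(df$compound_id))
    ctg_error("duplicate compound_id values", "ctg_input_error")
  bad_cat <- setdiff(unique(df$category), c("drug", "food", "endogenous", "other"))
  if (length(bad_cat))
    ctg_error(paste("unknown category:", paste(bad_cat, collapse = ", ")),
              "ctg_input_error")
  missing_fp <- is.na(df$fingerprint)
  if (any(missing_fp)) {
    warning(sprintf("dropping %d compound(s) without a fingerprint: %s",
                    sum(missing_fp),
                    paste(utils::head(df$compound_id[missing_fp], 5L), collapse = ", ")))
    df <- df[!missing_fp, , drop = FALSE]
  }
  fps <- lapply(df$fingerprint, parse_fingerprint_field)
  names(fps) <- df$compound_id
  as_compound_table(df[, c("compound_id", "name", "category", "superclass")], fps)
}

parse_fingerprint_field <- function(x) {
  if (grepl("^[0-9]+(,[0-9]+)*$", x) || x == "-") {
    if (x == "-") return(fingerprint())
    fingerprint(as.integer(strsplit(x, ",", fixed = TRUE)[[1L]]))
  } else {
    decode_cactvs(x)
  }
}

#' Assemble a compound table in memory
#'
#' @param df `data.frame` with columns `compound_id`, `name`, `category`,
#'   `superclass` (`NA` allowed for superclass).
#' @param fingerprints named list of [fingerprint()] objects covering every
#'   `compound_id`.
#' @return A `compound_table`.
#' @export
as_compound_table <- function(df, fingerprints) {
  stopifnot(all(df$compound_id %in% names(fingerprints)))
  rownames(df) <- NULL
  structure(df, fingerprints = fingerprints[df$compound_id],
            class = c("compound_table", "data.frame"))
}

#' Write a compound table to TSV
#'
#' Fingerprints are serialised in the base64 CACTVS format so the file round
#' trips through [read_compounds()].
#'
#' @param compounds a `compound_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  stopifnot(inherits(compounds, "compound_table"))
  fps <- attr(compounds, "fingerprints")
  out <- data.frame(compound_id = compounds$compound_id, name = compounds$name,
                    category = compounds$category, superclass = compounds$superclass,
                    fingerprint = vapply(fps, encode_cactvs, character(1L)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
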