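#' DICE similarity between two binary profiles
#'
#' `2 |A and B| / (|A| + |B|)` over two logical vectors interpreted as
#' presence/absence sets (here: which target-gene functions a miRNA hits).
#'
#' @param a,b logical vectors of equal length, not both all-`FALSE`.
#' @return similarity in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("profile lengths differ", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) stop("DICE undefined for two empty sets", call. = FALSE)
  2 * sum(a & b) / (na + nb)
}

#' Nei-style genetic distance from a similarity
#'
#' `D = -ln(S)`, the standard transform pairing, e.g., similarity 0.28 with
#' distance 1.27. Zero similarity maps to `Inf`; downstream clustering
#' substitutes a finite cap (see [similarity_pipeline()]).
#'
#' @param s similarity in `[0, 1]` (vectorized).
#' @return distance (>= 0, `Inf` when `s <= 0`).
#' @export
nei_distance <- function(s) {
  out <- ifelse(s <= 0, Inf, -log(s))
  out[s > 1 | s < 0] <- NA_real_
  if (any(is.na(out))) stop("similarity outside [0, 1]", call. = FALSE)
  out
}

#' DICE/Nei similarity analysis of a binary function matrix
#'
#' Computes all pairwise DICE similarities between the rows of a miRNA x
#' function-label boolean matrix, transforms them to Nei distances, and
#' clusters the distance matrix by UPGMA. Zero-similarity pairs have
#' infinite Nei distance; these are replaced by `inf_cap` (with a warning)
#' before clustering so the tree remains defined.
#'
#' @param matrix logical matrix, rows = miRNA ids, columns = function
#'   labels; every retained row must contain at least one `TRUE`.
#' @param inf_cap finite distance substituted for infinite entries.
#' @return a list of class `similarity_report`: `similarity` (S, unit
#'   diagonal), `distance` (D, possibly capped), `tree` (an `upgma_tree`),
#'   `newick`, `max_pair` and `min_pair` (off-diagonal extremes of S with
#'   their id pairs), `capped` (logical: any infinite distance replaced).
#' @export
similarity_pipeline <- function(matrix, inf_cap = 10.0) {
  m <- as.matrix(matrix) != 0
  n <- nrow(m)
  stopifnot(n >= 2L, !is.null(rownames(m)))
  empty <- rowSums(m) == 0L
  if (any(empty)) {
    stop("all-FALSE row(s): ", paste(rownames(m)[empty], collapse = ", "),
         call. = FALSE)
  }
  ids <- rownames(m)
  S <- diag(1, n); dimnames(S) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      S[i, j] <- S[j, i] <- dice(m[i, ], m[j, ])
    }
  }
  D <- nei_distance(S)
  diag(D) <- 0
  capped <- any(is.infinite(D))
  if (capped) {
    warning(sprintf(
      "zero-similarity pair(s): infinite Nei distance capped at %.1f", inf_cap))
    D[is.infinite(D)] <- inf_cap
  }
  tree <- upgma(D)
  off <- S; diag(off) <- NA
  mx <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  mn <- which(off == min(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  structure(list(
    similarity = S, distance = D, tree = tree, newick = to_newick(tree),
    max_pair = list(ids = ids[mx], value = max(off, na.rm = TRUE)),
    min_pair = list(ids = ids[mn], value = min(off, na.rm = TRUE)),
    capped = capped), class = "similarity_report")
}

#' Write a combined distance/similarity table
#'
#' Writes a square table with Nei distances in the upper-right triangle and
#' DICE similarities in the lower-left triangle (diagonal blank), the layout
#' conventionally used to print both matrices at once.
#'
#' @param report a `similarity_report`.
#' @param path output TSV path.
#' @param digits decimals for the printed values.
#' @export
write_similarity_table <- function(report, path, digits = 2) {
  S <- report$similarity; D <- report$distance
  n <- nrow(S)
  out <- matrix("", n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) out[i, j] <- formatC(D[i, j], format = "f", digits = digits)
      if (i > j) out[i, j] <- formatC(S[i, j], format = "f", digits = digits)
    }
  }
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}
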