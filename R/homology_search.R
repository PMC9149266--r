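#' Alignment scoring scheme
#'
#' Parameters of the Smith-Waterman local aligner. A gap run of length k
#' costs `gap_open + k * gap_extend`; both penalties are non-positive.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gap_open gap opening penalty (<= 0).
#' @param gap_extend per-base gap extension penalty (<= 0).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = -5,
                           gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' Smith-Waterman local alignment
#'
#' Exact affine-gap local alignment by dynamic programming. Input is DNA
#' (U is accepted and treated as T); `N` acts as a hard mask that no
#' alignment column may touch. Identity is computed as matches over all
#' aligned columns, gap columns counting as non-matches; coverage is the
#' fraction of the first ("query") sequence covered by the alignment.
#'
#' @param a,b sequences (single character strings).
#' @param scheme a [scoring_scheme()].
#' @return a list of class `alignment_hit` with elements `score`,
#'   `a_span`/`b_span` (1-based inclusive), `a_aln`/`b_aln` (gapped strings),
#'   `n_columns`, `n_matches`, `identity`, `coverage`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  if (length(a) != 1L || length(b) != 1L || nchar(a) == 0L || nchar(b) == 0L) {
    stop("local_align requires two non-empty sequences", call. = FALSE)
  }
  a <- as_dna(a); b <- as_dna(b)
  .check_alphabet(a, extra = "N"); .check_alphabet(b, extra = "N")
  r <- sw_align_cpp(a, b, scheme$match, scheme$mismatch,
                    scheme$gap_open, scheme$gap_extend)
  cols <- nchar(r$a_aln)
  if (cols > 0L) {
    av <- strsplit(r$a_aln, "")[[1]]
    bv <- strsplit(r$b_aln, "")[[1]]
    nm <- sum(av == bv & av != "-")
  } else {
    nm <- 0L
  }
  structure(list(
    score = r$score,
    a_span = c(r$a_start, r$a_end),
    b_span = c(r$b_start, r$b_end),
    a_aln = r$a_aln, b_aln = r$b_aln,
    n_columns = cols, n_matches = nm,
    identity = if (cols > 0) nm / cols else 0,
    coverage = if (cols > 0) (r$a_end - r$a_start + 1) / nchar(a) else 0
  ), class = "alignment_hit")
}

# mask a 1-based inclusive interval of a sequence with N
.mask_region <- function(seq, start, end) {
  paste0(substr(seq, 1, start - 1),
         strrep("N", end - start + 1),
         substr(seq, end + 1, nchar(seq)))
}

#' Scan genome scaffolds for homologs of known precursors
#'
#' Runs exact local alignment of every query against every scaffold on both
#' strands, iteratively masking each reported locus so that multiple copies
#' of a query in one scaffold are all found. Hits must reach `min_identity`
#' and `min_coverage`; hits whose scaffold intervals overlap reciprocally by
#' at least 50% are merged into one locus keeping the best score. Coordinates
#' are reported 1-based inclusive on the plus strand of the scaffold.
#'
#' @param queries named character vector of query (precursor) sequences.
#' @param scaffolds named character vector of genome scaffolds.
#' @param min_identity minimum alignment identity in `[0, 1]`.
#' @param min_coverage minimum query coverage in `[0, 1]`.
#' @param flank nucleotides of scaffold context appended to each side of the
#'   extracted candidate, clipped at scaffold ends.
#' @param scheme a [scoring_scheme()].
#' @param max_hits_per_pair safety cap on iterative masking.
#' @return a list with `hits` (data.frame: query_id, scaffold_id, start, end,
#'   strand, score, identity, coverage, locus_id) and `candidates` (named
#'   character vector of extracted candidate sequences, flanks included).
#' @export
scan_genome <- function(queries, scaffolds, min_identity = 0.85,
                        min_coverage = 0.8, flank = 20,
                        scheme = scoring_scheme(), max_hits_per_pair = 50L) {
  if (length(scaffolds) == 0L) stop("no scaffolds supplied", call. = FALSE)
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1, flank >= 0)
  if (is.null(names(queries)) || is.null(names(scaffolds))) {
    stop("queries and scaffolds must be named", call. = FALSE)
  }
  rows <- list()
  for (qi in names(queries)) {
    q <- as_dna(queries[[qi]])
    for (si in names(scaffolds)) {
      slen <- nchar(scaffolds[[si]])
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") as_dna(scaffolds[[si]]) else
          revcomp(as_dna(scaffolds[[si]]))
        for (it in seq_len(max_hits_per_pair)) {
          h <- local_align(q, subj, scheme)
          if (h$score <= 0 || h$coverage < min_coverage) break
          if (h$identity >= min_identity) {
            bs <- h$b_span
            if (strand == "+") {
              start <- bs[1]; end <- bs[2]
            } else {
              start <- slen - bs[2] + 1; end <- slen - bs[1] + 1
            }
            rows[[length(rows) + 1L]] <- data.frame(
              query_id = qi, scaffold_id = si, start = start, end = end,
              strand = strand, score = h$score, identity = h$identity,
              coverage = h$coverage, stringsAsFactors = FALSE)
          }
          subj <- .mask_region(subj, h$b_span[1], h$b_span[2])
        }
      }
    }
  }
  if (length(rows) == 0L) {
    hits <- data.frame(query_id = character(), scaffold_id = character(),
                       start = integer(), end = integer(),
                       strand = character(), score = numeric(),
                       identity = numeric(), coverage = numeric(),
                       locus_id = character(), stringsAsFactors = FALSE)
    return(list(hits = hits, candidates = character()))
  }
  hits <- do.call(rbind, rows)
  hits <- .merge_loci(hits)
  hits <- hits[order(hits$scaffold_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits$locus_id <- sprintf("%s_%d_%d", hits$scaffold_id, hits$start, hits$end)
  cand <- vapply(seq_len(nrow(hits)), function(k) {
    si <- hits$scaffold_id[k]
    s <- max(1L, hits$start[k] - flank)
    e <- min(nchar(scaffolds[[si]]), hits$end[k] + flank)
    sub <- substr(as_dna(scaffolds[[si]]), s, e)
    if (hits$strand[k] == "-") revcomp(sub) else sub
  }, character(1))
  names(cand) <- hits$locus_id
  list(hits = hits, candidates = cand)
}

# reciprocal >= 50% overlap on the same scaffold => one locus, best score kept
.merge_loci <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score)
  for (u in seq_along(ord)) {
    i <- ord[u]
    if (!keep[i]) next
    for (v in seq_along(ord)) {
      j <- ord[v]
      if (i == j || !keep[j]) next
      if (hits$scaffold_id[i] != hits$scaffold_id[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1
      if (ov <= 0) next
      li <- hits$end[i] - hits$start[i] + 1
      lj <- hits$end[j] - hits$start[j] + 1
      if (ov / li >= 0.5 && ov / lj >= 0.5) keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}
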