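#' Default duplex penalty weights
#'
#' Expectation penalties per alignment state: mismatch 1.0, G:U wobble 0.5,
#' each bulged base 2.0, Watson-Crick 0. Penalties at miRNA positions inside
#' the seed span (positions 2-13 from the miRNA 5' end by default) are
#' multiplied by `seed_factor`.
#'
#' @return named numeric vector with elements mismatch, gu, bulge.
#' @export
duplex_weights <- function() c(mismatch = 1.0, gu = 0.5, bulge = 2.0)

# pairing state of one miRNA base against one (antiparallel) site base
.pair_state <- function(m, s) {
  wc <- (m == "A" & s == "U") | (m == "U" & s == "A") |
        (m == "G" & s == "C") | (m == "C" & s == "G")
  gu <- (m == "G" & s == "U") | (m == "U" & s == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "mismatch"))
}

#' Build an ungapped miRNA:site duplex alignment
#'
#' The miRNA (5'->3') is paired antiparallel against a transcript site
#' (5'->3'), so miRNA position 1 pairs the last site base. Position i of the
#' returned state vector refers to miRNA position i from the 5' end.
#'
#' @param mirna miRNA sequence (RNA; T accepted).
#' @param site transcript site of the same length (RNA or DNA).
#' @return a list of class `duplex_alignment` with `states` (per-miRNA-
#'   position, in `WC`, `GU`, `mismatch`, `bulge`) and `site_bulges`
#'   (integer vector: an unpaired site base sits between miRNA positions k
#'   and k+1).
#' @export
duplex_align <- function(mirna, site) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  s <- rev(strsplit(as_rna(site), "")[[1]])
  if (length(m) != length(s)) {
    stop("ungapped duplex needs equal miRNA and site lengths", call. = FALSE)
  }
  structure(list(states = .pair_state(m, s), site_bulges = integer()),
            class = "duplex_alignment")
}

#' Expectation penalty of a duplex alignment
#'
#' Sums the per-state penalties (see [duplex_weights()]); penalties at miRNA
#' positions within `seed_span` are multiplied by `seed_factor`. A bulged
#' site base (entry k of `site_bulges`) is charged the bulge penalty, seed-
#' doubled when its 5'-flanking miRNA position k lies in the seed span.
#'
#' @param alignment a `duplex_alignment`.
#' @param seed_span integer pair, seed region in miRNA coordinates
#'   (inclusive; default `c(2, 13)`).
#' @param weights penalty weights, see [duplex_weights()].
#' @param seed_factor multiplier for penalties in the seed span.
#' @return expectation penalty (>= 0).
#' @export
score_duplex <- function(alignment, seed_span = c(2L, 13L),
                         weights = duplex_weights(), seed_factor = 2) {
  st <- alignment$states
  pen <- numeric(length(st))
  pen[st == "mismatch"] <- weights[["mismatch"]]
  pen[st == "GU"] <- weights[["gu"]]
  pen[st == "bulge"] <- weights[["bulge"]]
  pos <- seq_along(st)
  inseed <- pos >= seed_span[1] & pos <= seed_span[2]
  pen[inseed] <- pen[inseed] * seed_factor
  extra <- 0
  for (k in alignment$site_bulges) {
    w <- weights[["bulge"]]
    if (k >= seed_span[1] && k <= seed_span[2]) w <- w * seed_factor
    extra <- extra + w
  }
  sum(pen) + extra
}

#' Inhibition mode of a target site
#'
#' Plant miRNA convention: central complementarity decides the mode. The
#' site is classified as `translation` (translational repression) iff any
#' non-WC state, miRNA bulge, or adjacent site bulge occurs at the central
#' miRNA positions 9-11; otherwise `cleavage`.
#'
#' @param alignment a `duplex_alignment`.
#' @param central integer pair, central window (default `c(9, 11)`).
#' @return `"cleavage"` or `"translation"`.
#' @export
classify_inhibition <- function(alignment, central = c(9L, 11L)) {
  pos <- seq_along(alignment$states)
  cen <- pos >= central[1] & pos <= central[2]
  nonwc <- any(alignment$states[cen] != "WC") ||
    any(alignment$site_bulges >= central[1] & alignment$site_bulges < central[2])
  if (nonwc) "translation" else "cleavage"
}

# all candidate alignments of a miRNA against one window start:
# ungapped (site length L), one bulged site base (L+1), one bulged miRNA
# base (L-1); returns best (min expectation) alignment + site span length
.best_at_start <- function(mv, tv, start, seed_span, weights, seed_factor) {
  L <- length(mv)
  n <- length(tv)
  best <- NULL
  consider <- function(aln, span_len) {
    e <- score_duplex(aln, seed_span, weights, seed_factor)
    if (is.null(best) || e < best$expectation) {
      best <<- list(alignment = aln, expectation = e, span_len = span_len)
    }
  }
  # ungapped
  if (start + L - 1L <= n) {
    site <- tv[start:(start + L - 1L)]
    aln <- structure(list(states = .pair_state(mv, rev(site)),
                          site_bulges = integer()),
                     class = "duplex_alignment")
    consider(aln, L)
  }
  # one bulged site base: site has L+1 bases, base b (2..L) unpaired.
  # In antiparallel orientation a skipped site base at reversed index b sits
  # between miRNA positions b-1 and b.
  if (start + L <= n) {
    site <- tv[start:(start + L)]
    rs <- rev(site)
    for (b in 2:L) {
      aln <- structure(list(states = .pair_state(mv, rs[-b]),
                            site_bulges = b - 1L),
                       class = "duplex_alignment")
      consider(aln, L + 1L)
    }
  }
  # one bulged miRNA base (internal): site has L-1 bases
  if (start + L - 2L <= n && L >= 3L) {
    site <- tv[start:(start + L - 2L)]
    rs <- rev(site)
    for (b in 2:(L - 1L)) {
      st <- character(L)
      st[b] <- "bulge"
      st[-b] <- .pair_state(mv[-b], rs)
      aln <- structure(list(states = st, site_bulges = integer()),
                       class = "duplex_alignment")
      consider(aln, L - 1L)
    }
  }
  best
}

#' Scan transcripts for miRNA target sites
#'
#' Evaluates every transcript window against each miRNA: ungapped duplexes
#' plus variants with at most one single-base bulge on either strand. The
#' minimal-expectation alignment per window start is kept, overlapping
#' windows are collapsed to the best (ties to the leftmost), and sites with
#' expectation at most `cutoff` are reported sorted by expectation, then
#' transcript and position. Transcripts are scanned on the given (sense)
#' strand only.
#'
#' @param mirnas named character vector of mature miRNA sequences (RNA).
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum reported expectation (default 5.0).
#' @param seed_span,weights,seed_factor see [score_duplex()].
#' @return a data.frame with columns mirna_id, transcript_id, start, end,
#'   expectation, inhibition.
#' @export
scan_transcripts <- function(mirnas, transcripts, cutoff = 5.0,
                             seed_span = c(2L, 13L),
                             weights = duplex_weights(), seed_factor = 2) {
  stopifnot(cutoff >= 0)
  empty <- data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), inhibition = character(),
                      stringsAsFactors = FALSE)
  if (length(transcripts) == 0L) return(empty)
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  rows <- list()
  for (mi in names(mirnas)) {
    mv <- strsplit(as_rna(mirnas[[mi]]), "")[[1]]
    L <- length(mv)
    for (ti in names(transcripts)) {
      tv <- strsplit(as_rna(transcripts[[ti]]), "")[[1]]
      n <- length(tv)
      if (n < L - 1L) next
      cand <- list()
      for (s in seq_len(max(0L, n - L + 2L))) {
        b <- .best_at_start(mv, tv, s, seed_span, weights, seed_factor)
        if (is.null(b) || b$expectation > cutoff) next
        cand[[length(cand) + 1L]] <- list(
          start = s, end = s + b$span_len - 1L,
          expectation = b$expectation, alignment = b$alignment)
      }
      # collapse overlapping candidate spans to the best (ties -> leftmost)
      if (length(cand) > 0L) {
        ord <- order(vapply(cand, `[[`, numeric(1), "expectation"),
                     vapply(cand, `[[`, numeric(1), "start"))
        taken <- list()
        for (k in ord) {
          ck <- cand[[k]]
          overlaps <- any(vapply(taken, function(t)
            ck$start <= t$end && ck$end >= t$start, logical(1)))
          if (!overlaps) taken[[length(taken) + 1L]] <- ck
        }
        for (t in taken) {
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = mi, transcript_id = ti, start = t$start, end = t$end,
            expectation = t$expectation,
            inhibition = classify_inhibition(t$alignment),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$expectation, out$mirna_id, out$transcript_id,
                   out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
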