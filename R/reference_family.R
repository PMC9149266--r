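#' Construct a synthetic family of hairpin-forming reference precursors
#'
#' Builds miR166-style reference precursors for simulations: each member is
#' a random 5' arm ending in a GC clamp, an all-A loop, and the reverse
#' complement of the arm with a chosen number of substitutions placed in the
#' outer half of the 3' arm (outside the mature-duplex windows), so the
#' designed structure is a single long stem-loop. The GC clamp flanking the
#' loop makes alternative pairings that open the loop strictly unfavourable,
#' and an all-A loop cannot pair with itself. The mature reference for each
#' arm is the 21-nt window ending four bases short of the loop (mature
#' miRNAs sit a few bases away from the terminal loop, and keeping the
#' window off the loop junction keeps its duplex insensitive to
#' loop-adjacent rearrangements).
#'
#' @param n number of family members.
#' @param arm_len arm length in nt (>= 25).
#' @param loop_len loop length in nt.
#' @param n_arm_mismatches substitutions introduced in the outer 3' arm.
#' @param seed integer seed.
#' @return a list with `precursors` (named character vector, DNA) and
#'   `matures` (named character vector of 21-nt mature references, one per
#'   arm, names `<prec>-5p` / `<prec>-3p`).
#' @export
synthetic_precursor_family <- function(n = 3L, arm_len = 40L, loop_len = 12L,
                                       n_arm_mismatches = 2L, seed = 1L) {
  stopifnot(arm_len >= 25L, loop_len >= 3L, n_arm_mismatches >= 0L)
  set.seed(seed)
  precursors <- character(0)
  matures <- character(0)
  for (k in seq_len(n)) {
    arm5 <- paste0(.random_dna(arm_len - 4L), "GCGC")
    arm3 <- revcomp(arm5)
    if (n_arm_mismatches > 0L) {
      # outer half of the 3' arm = second half of the arm3 string
      cand <- seq.int(ceiling(arm_len / 2) + 11L, arm_len)
      pos <- sample(cand, min(n_arm_mismatches, length(cand)))
      v <- strsplit(arm3, "")[[1]]
      for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
      arm3 <- paste(v, collapse = "")
    }
    id <- sprintf("prec%02d", k)
    precursors[[id]] <- paste0(arm5, strrep("A", loop_len), arm3)
    matures[[paste0(id, "-5p")]] <- substr(arm5, arm_len - 24L, arm_len - 4L)
    matures[[paste0(id, "-3p")]] <- substr(arm3, 5L, 25L)
  }
  list(precursors = precursors, matures = matures)
}
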