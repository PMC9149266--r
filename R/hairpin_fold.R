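#' Fold an RNA into its minimum-energy nested structure
#'
#' Energy-weighted Nussinov dynamic program: the structure minimizing the sum
#' of base-pair energies over all nested (pseudoknot-free) structures with
#' hairpin loops of at least `min_loop` unpaired bases. Default pair energies
#' are GC -3.0, AU -2.0, GU -1.0 kcal/mol. This is a transparent, fully
#' enumerable stand-in for a nearest-neighbour thermodynamic folder: absolute
#' energies are not comparable to Turner-model values, so all downstream
#' energy thresholds are exposed as parameters. Ties in the traceback are
#' broken deterministically by preferring the pair with the smaller 5' index.
#'
#' @param seq RNA sequence (T accepted and mapped to U).
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @param energies named numeric vector with elements `gc`, `au`, `gu`
#'   (kcal/mol, all <= 0; set one to `NA` to disallow that pair type).
#' @return a list of class `fold_result`: `sequence`, `structure`
#'   (dot-bracket), `mfe`, and `pairs` (two-column matrix of 1-based pairs).
#' @export
fold_rna <- function(seq, min_loop = 3L,
                     energies = c(gc = -3.0, au = -2.0, gu = -1.0)) {
  stopifnot(length(seq) == 1L, min_loop >= 0)
  s <- as_rna(seq)
  .check_alphabet(s, what = "RNA sequence")
  e <- energies[c("gc", "au", "gu")]
  e[is.na(e)] <- 1 # positive = unpairable
  r <- nussinov_fold_cpp(s, as.integer(min_loop), e[["gc"]], e[["au"]], e[["gu"]])
  structure(list(sequence = s, structure = r$structure, mfe = r$mfe,
                 pairs = cbind(i = r$pair_i, j = r$pair_j)),
            class = "fold_result")
}

#' GC content of a sequence
#'
#' @param seq a DNA or RNA string.
#' @return fraction of G+C in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(length(seq) == 1L, nchar(seq) > 0L)
  v <- strsplit(toupper(seq), "")[[1]]
  mean(v %in% c("G", "C"))
}

#' Minimum folding free energy index (MFEI)
#'
#' MFEI = (|MFE| / length x 100) / (GC x 100), the dimensionless index used
#' to separate genuine miRNA precursors from tRNA/rRNA/mRNA folds (precursor
#' values are typically above ~0.85 while housekeeping RNAs fall lower).
#' Reported positive by convention although MFE itself is negative.
#'
#' @param mfe minimum folding free energy (kcal/mol, <= 0 for stable folds).
#' @param length sequence length in nucleotides (> 0).
#' @param gc GC fraction in `(0, 1]`.
#' @return the MFEI (dimensionless, >= 0).
#' @export
mfei <- function(mfe, length, gc) {
  stopifnot(length > 0)
  if (any(gc <= 0)) stop("MFEI undefined for GC = 0", call. = FALSE)
  (abs(mfe) / length * 100) / (gc * 100)
}

#' Extract the arms and loop of a hairpin structure
#'
#' For a structure with exactly one hairpin loop, the 5' arm spans from the
#' outermost paired base to the innermost 5' paired base (interior-loop and
#' bulge columns included), the loop is the unpaired stretch enclosed by the
#' innermost pair, and the 3' arm mirrors the 5' arm. Structures with more
#' than one hairpin loop are not simple stem-loops and are flagged. Lonely
#' pairs - pairs without a stacked neighbour - are disregarded when judging
#' the topology (the usual no-lonely-pairs convention): a pair-maximizing
#' folding model otherwise decorates every unpaired stretch with spurious
#' isolated pairs that would misclassify genuine stem-loops.
#'
#' @param fold a `fold_result` from [fold_rna()].
#' @return a list with `is_hairpin` (logical), and when `TRUE`: `arm5`,
#'   `loop`, `arm3` (1-based inclusive intervals `c(start, end)`).
#' @export
extract_arms <- function(fold) {
  stopifnot(inherits(fold, "fold_result"))
  p <- fold$pairs
  if (nrow(p) > 0L) {
    key <- paste(p[, "i"], p[, "j"])
    stacked <- (paste(p[, "i"] + 1L, p[, "j"] - 1L) %in% key) |
      (paste(p[, "i"] - 1L, p[, "j"] + 1L) %in% key)
    p <- p[stacked, , drop = FALSE]
  }
  if (nrow(p) == 0L) {
    return(list(is_hairpin = FALSE, reason = "no stacked base pairs"))
  }
  # hairpin loops = pairs enclosing no other pair
  inner <- vapply(seq_len(nrow(p)), function(k) {
    !any(p[, "i"] > p[k, "i"] & p[, "j"] < p[k, "j"])
  }, logical(1))
  if (sum(inner) > 1L) {
    return(list(is_hairpin = FALSE,
                reason = sprintf("%d hairpin loops, not a simple stem-loop",
                                 sum(inner))))
  }
  hi <- unname(p[inner, "i"]); hj <- unname(p[inner, "j"])
  list(is_hairpin = TRUE,
       arm5 = c(min(p[, "i"]), hi),
       loop = c(hi + 1L, hj - 1L),
       arm3 = c(hj, max(p[, "j"])))
}

#' Count mismatches between the mature-duplex arms
#'
#' NM is the number of mature-span positions not engaged in a WC or G:U pair
#' with the opposite mature span; unpaired and bulged positions each count
#' one. The two spans are counted separately and the larger count is
#' reported, so a perfect duplex gives 0 and fully unpaired spans give the
#' mature length.
#'
#' @param fold a `fold_result`.
#' @param mature5_span,mature3_span 1-based inclusive intervals
#'   `c(start, end)` of the mature miRNA and its star on opposite arms
#'   (the 5' span must precede the 3' span).
#' @return integer mismatch count.
#' @export
count_duplex_mismatches <- function(fold, mature5_span, mature3_span) {
  stopifnot(inherits(fold, "fold_result"))
  if (mature5_span[2] >= mature3_span[1]) {
    stop("mature spans must lie on opposite arms (5' span before 3' span)",
         call. = FALSE)
  }
  p <- fold$pairs
  partner <- integer(nchar(fold$sequence))
  if (nrow(p) > 0L) {
    partner[p[, "i"]] <- p[, "j"]
    partner[p[, "j"]] <- p[, "i"]
  }
  in_span <- function(x, span) x >= span[1] & x <= span[2]
  pos5 <- seq.int(mature5_span[1], mature5_span[2])
  pos3 <- seq.int(mature3_span[1], mature3_span[2])
  un5 <- sum(!(partner[pos5] > 0 & in_span(partner[pos5], mature3_span)))
  un3 <- sum(!(partner[pos3] > 0 & in_span(partner[pos3], mature5_span)))
  as.integer(max(un5, un3))
}

#' Place mature miRNAs on the precursor arms
#'
#' Slides each reference mature sequence along the precursor without gaps and
#' records, per arm, the reference with the fewest substitutions (ties broken
#' by reference order, then by leftmost window). A window is assigned to the
#' 5' or 3' arm by the position of its midpoint relative to the hairpin loop.
#' Matches are reported only when the mismatch count is at most
#' `max_mismatch`.
#'
#' @param precursor precursor sequence (RNA or DNA).
#' @param fold a `fold_result` for the precursor.
#' @param mature_refs named character vector of reference mature miRNAs
#'   (20-24 nt).
#' @param max_mismatch maximum substitutions to the best homolog.
#' @param locus_id name used to label annotations (`{locus}-5p`/`-3p`).
#' @return a data.frame with columns mature_id, arm, start, end, sequence,
#'   length, best_homolog, nm_to_homolog (0-2 rows).
#' @export
locate_mature <- function(precursor, fold, mature_refs, max_mismatch = 3L,
                          locus_id = "candidate") {
  stopifnot(length(mature_refs) >= 1L, !is.null(names(mature_refs)))
  rl <- nchar(mature_refs)
  if (any(rl < 20L | rl > 24L)) {
    stop("mature references must be 20-24 nt", call. = FALSE)
  }
  arms <- extract_arms(fold)
  if (!isTRUE(arms$is_hairpin)) {
    return(.empty_mature_df())
  }
  prec <- as_rna(precursor)
  n <- nchar(prec)
  loop_mid <- mean(arms$loop)
  pv <- strsplit(prec, "")[[1]]
  best <- list(`5p` = NULL, `3p` = NULL)
  for (ri in seq_along(mature_refs)) {
    ref <- strsplit(as_rna(mature_refs[[ri]]), "")[[1]]
    L <- length(ref)
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      mm <- sum(pv[s:(s + L - 1L)] != ref)
      if (mm > max_mismatch) next
      arm <- if (s + (L - 1) / 2 < loop_mid) "5p" else "3p"
      cur <- best[[arm]]
      if (is.null(cur) || mm < cur$nm) {
        best[[arm]] <- list(ref_id = names(mature_refs)[ri], nm = mm,
                            start = s, end = s + L - 1L, length = L)
      }
    }
  }
  out <- lapply(c("5p", "3p"), function(arm) {
    b <- best[[arm]]
    if (is.null(b)) return(NULL)
    data.frame(mature_id = sprintf("%s-%s", locus_id, arm), arm = arm,
               start = b$start, end = b$end,
               sequence = substr(prec, b$start, b$end), length = b$length,
               best_homolog = b$ref_id, nm_to_homolog = b$nm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) .empty_mature_df() else out
}

.empty_mature_df <- function() {
  data.frame(mature_id = character(), arm = character(), start = integer(),
             end = integer(), sequence = character(), length = integer(),
             best_homolog = character(), nm_to_homolog = integer(),
             stringsAsFactors = FALSE)
}

#' Characterize a candidate precursor
#'
#' Convenience wrapper combining [fold_rna()], [gc_content()], [mfei()],
#' [extract_arms()], [locate_mature()] and [count_duplex_mismatches()] into
#' one candidate record. NM is counted over the located mature spans when
#' both arms carry an annotation; when only one arm is annotated, the span
#' on the missing arm is the star span - the range of pairing partners of
#' the annotated span - and when neither arm is annotated both spans default
#' to the innermost 21-nt window of each arm.
#'
#' @param seq candidate sequence.
#' @param locus_id candidate label.
#' @param mature_refs optional named character vector of mature references.
#' @param max_mismatch passed to [locate_mature()].
#' @param min_loop,energies passed to [fold_rna()].
#' @return a list of class `hairpin_candidate` with fields `locus_id`,
#'   `fold`, `gc`, `mfei`, `is_hairpin`, `arm5`, `arm3`, `loop`, `nm`,
#'   `matures` (data.frame).
#' @export
characterize_hairpin <- function(seq, locus_id = "candidate",
                                 mature_refs = NULL, max_mismatch = 3L,
                                 min_loop = 3L,
                                 energies = c(gc = -3.0, au = -2.0, gu = -1.0)) {
  f <- fold_rna(seq, min_loop = min_loop, energies = energies)
  gc <- gc_content(f$sequence)
  mi <- if (gc > 0) mfei(f$mfe, nchar(f$sequence), gc) else NA_real_
  arms <- extract_arms(f)
  matures <- .empty_mature_df()
  nm <- NA_integer_
  if (isTRUE(arms$is_hairpin)) {
    if (!is.null(mature_refs)) {
      matures <- locate_mature(seq, f, mature_refs,
                               max_mismatch = max_mismatch,
                               locus_id = locus_id)
    }
    sp5 <- if (any(matures$arm == "5p")) {
      m <- matures[matures$arm == "5p", ][1, ]; c(m$start, m$end)
    } else NULL
    sp3 <- if (any(matures$arm == "3p")) {
      m <- matures[matures$arm == "3p", ][1, ]; c(m$start, m$end)
    } else NULL
    if (is.null(sp5) && !is.null(sp3)) {
      sp5 <- .star_span(f, sp3, arms$arm5)
    } else if (is.null(sp3) && !is.null(sp5)) {
      sp3 <- .star_span(f, sp5, arms$arm3)
    }
    if (is.null(sp5)) sp5 <- .innermost_window(arms$arm5, 21L, "5p")
    if (is.null(sp3)) sp3 <- .innermost_window(arms$arm3, 21L, "3p")
    if (!is.null(sp5) && !is.null(sp3) && sp5[2] < sp3[1]) {
      nm <- count_duplex_mismatches(f, sp5, sp3)
    }
  }
  structure(list(locus_id = locus_id, fold = f, gc = gc, mfei = mi,
                 is_hairpin = isTRUE(arms$is_hairpin),
                 arm5 = arms$arm5, arm3 = arms$arm3, loop = arms$loop,
                 nm = nm, matures = matures),
            class = "hairpin_candidate")
}

# star span: range of pairing partners of a mature span on the opposite arm
.star_span <- function(fold, span, opposite_arm) {
  p <- fold$pairs
  if (nrow(p) == 0L || is.null(opposite_arm)) return(NULL)
  partner <- integer(nchar(fold$sequence))
  partner[p[, "i"]] <- p[, "j"]
  partner[p[, "j"]] <- p[, "i"]
  prt <- partner[span[1]:span[2]]
  prt <- prt[prt >= opposite_arm[1] & prt <= opposite_arm[2]]
  if (length(prt) == 0L) return(NULL)
  c(min(prt), max(prt))
}

.innermost_window <- function(arm, len, side) {
  if (is.null(arm)) return(NULL)
  alen <- arm[2] - arm[1] + 1L
  len <- min(len, alen)
  if (side == "5p") c(arm[2] - len + 1L, arm[2]) else c(arm[1], arm[1] + len - 1L)
}

#' Screen candidate precursors against hairpin quality thresholds
#'
#' A candidate passes if it folds into a simple stem-loop, has at most
#' `max_nm` mature-duplex mismatches, MFEI at least `min_mfei`, and MFE at
#' most `max_mfe`. Rules are applied in that order and each rejection
#' carries the first failed rule. The defaults (NM <= 4, MFEI >= 0.85)
#' reflect the values typical of accepted miR166-class precursors; because
#' the folding model's absolute energies are model-specific, `max_mfe`
#' defaults to a permissive 0 and should be tightened by the caller if a
#' thermodynamic folder is plugged in.
#'
#' @param candidates a list of `hairpin_candidate` objects.
#' @param max_nm maximum mature-duplex mismatch count (inclusive).
#' @param min_mfei minimum MFEI (inclusive).
#' @param max_mfe maximum MFE in kcal/mol (inclusive).
#' @return a data.frame with columns locus_id, length, nm, mfe, gc, mfei,
#'   is_hairpin, accepted, reason.
#' @export
screen_candidates <- function(candidates, max_nm = 4L, min_mfei = 0.85,
                              max_mfe = 0) {
  stopifnot(is.finite(max_nm), is.finite(min_mfei), is.finite(max_mfe))
  rows <- lapply(candidates, function(cc) {
    stopifnot(inherits(cc, "hairpin_candidate"))
    reason <- ""
    if (!cc$is_hairpin) reason <- "not a simple stem-loop"
    else if (is.na(cc$nm) || cc$nm > max_nm) reason <- "nm"
    else if (is.na(cc$mfei) || cc$mfei < min_mfei) reason <- "mfei"
    else if (cc$fold$mfe > max_mfe) reason <- "mfe"
    data.frame(locus_id = cc$locus_id, length = nchar(cc$fold$sequence),
               nm = cc$nm, mfe = cc$fold$mfe, gc = cc$gc, mfei = cc$mfei,
               is_hairpin = cc$is_hairpin, accepted = reason == "",
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write fold results in Vienna-style text format
#'
#' One record per fold: a `>` header line, the sequence, and the dot-bracket
#' structure followed by the energy in parentheses.
#'
#' @param folds named list of `fold_result` objects.
#' @param path output file.
#' @export
write_vienna <- function(folds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(folds)) {
    f <- folds[[nm]]
    writeLines(c(paste0(">", nm), f$sequence,
                 sprintf("%s (%.2f)", f$structure, f$mfe)), con)
  }
  invisible(path)
}
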