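# Independent oracles used by the test suite. These deliberately avoid the
# package's DP code paths: structures and alignments are enumerated
# explicitly and scored from first principles.

oracle_pair_energy <- function(a, b, e = c(gc = -3, au = -2, gu = -1)) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) return(e[["gc"]])
  if (p %in% c("AU", "UA")) return(e[["au"]])
  if (p %in% c("GU", "UG")) return(e[["gu"]])
  NA_real_
}

# enumerate every nested structure (as a list of pair matrices) of seq
# with hairpin loops of >= min_loop unpaired bases
enumerate_structures <- function(seq, min_loop = 3) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i + 1 < min_loop + 2) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i, j - 1) # j unpaired
    for (k in i:(j - min_loop - 1)) {
      if (is.na(oracle_pair_energy(v[k], v[j]))) next
      left <- if (k > i) rec(i, k - 1) else list(list())
      right <- rec(k + 1, j - 1)
      for (L in left) for (R in right) {
        out[[length(out) + 1L]] <- c(L, R, list(c(k, j)))
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# minimum total pair energy over all nested structures, by full enumeration
oracle_mfe <- function(seq, min_loop = 3, e = c(gc = -3, au = -2, gu = -1)) {
  v <- strsplit(seq, "")[[1]]
  structs <- enumerate_structures(seq, min_loop)
  min(vapply(structs, function(s) {
    if (length(s) == 0) return(0)
    sum(vapply(s, function(p) oracle_pair_energy(v[p[1]], v[p[2]], e),
               numeric(1)))
  }, numeric(1)))
}

# exhaustive local alignment score: maximum over all monotone sets of
# matched index pairs, scoring affine gaps between consecutive pairs.
# Complete for the default scheme (a mismatch column always outscores a
# pair of adjacent opposite gaps).
oracle_local_score <- function(a, b, match = 2, mismatch = -1,
                               gap_open = -5, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  gapcost <- function(g) if (g == 0) 0 else gap_open + g * gap_extend
  subst <- function(i, j) if (av[i] == bv[j]) match else mismatch
  # best score of a matching starting with matched pair (i, j)
  from <- function(i, j) {
    best <- 0
    if (i < n && j < m) {
      for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
        ext <- gapcost(i2 - i - 1) + gapcost(j2 - j - 1) + from(i2, j2)
        if (ext > best) best <- ext
      }
    }
    subst(i, j) + best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- from(i, j)
    if (s > best) best <- s
  }
  best
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# fold_result from a hand-written dot-bracket string (for arm-parsing tests)
fold_from_db <- function(seq, db) {
  v <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (k in seq_along(v)) {
    if (v[k] == "(") stack <- c(stack, k)
    if (v[k] == ")") {
      pi <- c(pi, stack[length(stack)]); pj <- c(pj, k)
      stack <- stack[-length(stack)]
    }
  }
  ord <- order(pi)
  structure(list(sequence = seq, structure = db, mfe = NA_real_,
                 pairs = cbind(i = pi[ord], j = pj[ord])),
            class = "fold_result")
}

# heights of all internal nodes of an upgma_tree
.collect_heights <- function(tree) {
  rec <- function(node) {
    if (is.null(node$children)) return(numeric(0))
    c(node$height, unlist(lapply(node$children, rec)))
  }
  rec(tree$root)
}

# toy motif dictionary for promoter tests
toy_motifs <- function() {
  data.frame(
    name = c("boxA", "boxB", "boxC"),
    pattern = c("TGACGCA", "CCGGTTAA", "GATCNNGATC"),
    category = c("catA", "catB", "catC"),
    stringsAsFactors = FALSE)
}
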