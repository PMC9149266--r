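test_that("local alignment matches hand-checked examples", {
  h <- local_align("ACGT", "ACGT")
  expect_equal(h$score, 8)
  expect_equal(h$identity, 1.0)
  expect_equal(h$coverage, 1.0)

  h2 <- local_align("ACGTACGT", "ACGAACGT")
  expect_equal(h2$n_columns, 8L)
  expect_equal(h2$identity, 0.875)

  expect_error(local_align("", "ACGT"), "non-empty")
  expect_error(local_align("ACXT", "ACGT"), "non-IUPAC")
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(31)
  for (i in 1:25) {
    a <- random_dna(sample(4:15, 1))
    b <- random_dna(sample(4:15, 1))
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
})

test_that("forward alignment of a sequence to its reverse complement is imperfect", {
  set.seed(77)
  a <- random_dna(30)
  h <- local_align(a, revcomp(a))
  expect_lt(h$identity * h$coverage, 1.0)
})

test_that("DP score equals exhaustive enumeration on tiny pairs", {
  set.seed(13)
  for (i in 1:40) {
    a <- random_dna(sample(3:6, 1))
    b <- random_dna(sample(3:6, 1))
    expect_equal(local_align(a, b)$score, oracle_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("DP score matches an independent aligner on longer pairs", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(17)
  for (i in 1:60) {
    a <- random_dna(sample(5:12, 1))
    b <- random_dna(sample(5:12, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 1)
    expect_equal(local_align(a, b)$score, Biostrings::score(ref),
                 info = paste(a, b))
  }
})

test_that("genome scan recovers implanted loci with exact coordinates", {
  fam <- synthetic_precursor_family(n = 3, seed = 2)
  g <- generate_genome(fam$precursors, n_scaffolds = 2, scaffold_len = 1500,
                       n_implants = 3, mutation_rate = 0, seed = 4)
  sc <- scan_genome(fam$precursors, g$scaffolds, min_identity = 0.95,
                    flank = 0)
  expect_equal(nrow(sc$hits), 3L)
  truth <- g$truth[order(g$truth$scaffold_id, g$truth$start), ]
  expect_equal(sc$hits$start, truth$start)
  expect_equal(sc$hits$end, truth$end)
  expect_equal(sc$hits$strand, truth$strand)
  expect_true(all(sc$hits$identity == 1))
  # zero-mutation implants come back as the exact reference sequence
  for (k in seq_len(nrow(sc$hits))) {
    expect_identical(unname(sc$candidates[k]),
                     unname(fam$precursors[[truth$source_precursor_id[k]]]))
  }
})

test_that("minus-strand implants are reported on the plus reference frame", {
  fam <- synthetic_precursor_family(n = 1, seed = 6)
  set.seed(9)
  bg <- random_dna(600)
  prec <- fam$precursors[[1]]
  ins <- revcomp(prec)
  scaf <- paste0(substr(bg, 1, 99), ins,
                 substr(bg, 100 + nchar(ins), 600))
  sc <- scan_genome(fam$precursors, c(s1 = scaf), min_identity = 0.95,
                    flank = 0)
  expect_equal(nrow(sc$hits), 1L)
  expect_equal(sc$hits$strand, "-")
  expect_equal(sc$hits$start, 100L)
  expect_equal(sc$hits$end, 99L + nchar(ins))
  expect_identical(unname(sc$candidates[1]), unname(prec))
})

test_that("perfect-identity threshold excludes mutated implants", {
  fam <- synthetic_precursor_family(n = 2, seed = 8)
  g <- generate_genome(fam$precursors, n_scaffolds = 1, scaffold_len = 1200,
                       n_implants = 2, mutation_rate = 0.08, seed = 10)
  # every implant carries at least one substitution at this seed
  expect_true(all(g$truth$mutation_count >= 1))
  sc <- scan_genome(fam$precursors, g$scaffolds, min_identity = 1.0,
                    flank = 0)
  expect_equal(nrow(sc$hits), 0L)
})

test_that("raising the identity threshold never increases the hit count", {
  fam <- synthetic_precursor_family(n = 2, seed = 12)
  g <- generate_genome(fam$precursors, n_scaffolds = 1, scaffold_len = 1500,
                       n_implants = 3, mutation_rate = 0.05, seed = 14)
  counts <- vapply(c(0.5, 0.8, 0.9, 0.99),
                   function(mi) nrow(scan_genome(fam$precursors, g$scaffolds,
                                                 min_identity = mi,
                                                 flank = 0)$hits),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("scan fails without scaffolds and flanks are clipped at ends", {
  fam <- synthetic_precursor_family(n = 1, seed = 16)
  expect_error(scan_genome(fam$precursors, character()), "no scaffolds")

  prec <- fam$precursors[[1]]
  scaf <- c(s1 = paste0(prec, strrep("A", 50)))
  sc <- scan_genome(fam$precursors, scaf, min_identity = 0.95, flank = 30)
  expect_equal(sc$hits$start, 1L)
  # left flank clipped at the scaffold start, right flank fully available
  expect_equal(unname(nchar(sc$candidates[1])), nchar(prec) + 30L)
})
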