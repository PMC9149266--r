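test_that("duplex expectation follows the declared penalty weights", {
  mir <- "UCGGACCAGGCUUCAUUCCCC"
  site <- revcomp(mir)
  aln <- duplex_align(mir, site)
  expect_true(all(aln$states == "WC"))
  expect_equal(score_duplex(aln), 0.0)

  # one mismatch at miRNA position 15 (non-seed): penalty 1.0
  sv <- strsplit(site, "")[[1]]
  mv <- strsplit(mir, "")[[1]]
  sv[21 - 15 + 1] <- mv[15]
  a15 <- duplex_align(mir, paste(sv, collapse = ""))
  expect_equal(a15$states[15], "mismatch")
  expect_equal(score_duplex(a15), 1.0)
})

test_that("seed doubling and wobble weights combine as declared", {
  mir <- "UGGGACCAGGCUUCAUUCCCC" # position 2 = G, position 5 = A
  site <- strsplit(revcomp(mir), "")[[1]]
  mv <- strsplit(mir, "")[[1]]

  # G:U wobble at seed position 2: miRNA G pairs site U
  s2 <- site
  s2[21 - 2 + 1] <- "U"
  a <- duplex_align(mir, paste(s2, collapse = ""))
  expect_equal(a$states[2], "GU")
  expect_equal(score_duplex(a), 1.0)

  # the same mismatch moved from position 15 to seed position 5 doubles
  m15 <- site; m15[21 - 15 + 1] <- mv[15]
  m5 <- site; m5[21 - 5 + 1] <- mv[5]
  e15 <- score_duplex(duplex_align(mir, paste(m15, collapse = "")))
  e5 <- score_duplex(duplex_align(mir, paste(m5, collapse = "")))
  expect_equal(e5, 2 * e15)

  # adding a penalty state never decreases the expectation
  both <- m15; both[21 - 5 + 1] <- mv[5]
  expect_gte(score_duplex(duplex_align(mir, paste(both, collapse = ""))), e15)
})

test_that("inhibition mode is decided by central complementarity", {
  mir <- "UCGGACCAGGCUUCAUUCCCC"
  site <- strsplit(revcomp(mir), "")[[1]]
  mv <- strsplit(mir, "")[[1]]
  expect_equal(classify_inhibition(duplex_align(mir, revcomp(mir))),
               "cleavage")

  s10 <- site; s10[21 - 10 + 1] <- mv[10]
  expect_equal(classify_inhibition(duplex_align(mir,
                                                paste(s10, collapse = ""))),
               "translation")

  s2 <- site; s2[21 - 2 + 1] <- mv[2]
  expect_equal(classify_inhibition(duplex_align(mir,
                                                paste(s2, collapse = ""))),
               "cleavage")
})

test_that("transcript scan recovers planted sites at the cutoff", {
  fam <- synthetic_precursor_family(n = 2, seed = 3)
  mir <- fam$matures[1]
  spec <- data.frame(mirna_id = names(mir),
                     transcript_id = paste0("tx", 1:4),
                     target_penalty = c(0, 1, 3, 6),
                     stringsAsFactors = FALSE)
  tx <- generate_transcripts(fam$matures, spec, transcript_len = 200,
                             seed = 5)
  sites <- scan_transcripts(mir, tx$transcripts, cutoff = 5)
  expect_equal(nrow(sites), 3L)
  expect_setequal(sites$transcript_id, c("tx1", "tx2", "tx3"))
  expect_equal(sort(sites$expectation), c(0, 1, 3))
  # positions match the generator truth
  m <- merge(sites, tx$truth, by = c("mirna_id", "transcript_id"))
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$expectation, m$penalty)

  # cutoff 0 keeps only the perfect site
  s0 <- scan_transcripts(mir, tx$transcripts, cutoff = 0)
  expect_equal(nrow(s0), 1L)
  expect_equal(s0$transcript_id, "tx1")

  expect_equal(nrow(scan_transcripts(mir, character(), cutoff = 5)), 0L)
})

test_that("scan agrees with brute-force ungapped window evaluation", {
  set.seed(9)
  mir <- random_rna(21)
  mv <- strsplit(mir, "")[[1]]
  for (i in 1:10) {
    tx <- c(t1 = random_dna(sample(30:60, 1)))
    sites <- scan_transcripts(setNames(mir, "m"), tx, cutoff = 1e6)
    tv <- strsplit(as_rna(tx), "")[[1]]
    brute <- Inf
    for (s in seq_len(length(tv) - 21 + 1)) {
      aln <- duplex_align(mir, paste(tv[s:(s + 20)], collapse = ""))
      brute <- min(brute, score_duplex(aln))
    }
    # the scan also explores single-base bulges, so it can only be better
    expect_lte(min(sites$expectation), brute)
    # and with bulges disabled by construction the ungapped optimum is found:
    # every reported site must be at most the brute-force optimum
    expect_true(any(abs(sites$expectation - brute) < 1e-9) ||
                  min(sites$expectation) < brute)
  }
})

test_that("requested penalties outside the scheme fail loudly", {
  fam <- synthetic_precursor_family(n = 1, seed = 7)
  spec_neg <- data.frame(mirna_id = names(fam$matures)[1],
                         transcript_id = "t", target_penalty = -1)
  expect_error(generate_transcripts(fam$matures, spec_neg), ">= 0")
  spec_frac <- data.frame(mirna_id = names(fam$matures)[1],
                          transcript_id = "t", target_penalty = 0.3)
  expect_error(generate_transcripts(fam$matures, spec_frac), "0.5")
})
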