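test_that("zero-mutation implants are identical to their reference", {
  fam <- synthetic_precursor_family(n = 1, arm_len = 40, seed = 7)
  g <- generate_genome(fam$precursors, n_scaffolds = 1, scaffold_len = 1000,
                       n_implants = 1, mutation_rate = 0, seed = 7)
  t <- g$truth
  expect_equal(t$mutation_count, 0L)
  implanted <- substr(g$scaffolds[[t$scaffold_id]], t$start, t$end)
  if (t$strand == "-") implanted <- revcomp(implanted)
  expect_identical(implanted, unname(fam$precursors[[1]]))
})

test_that("observed implant divergence matches the mutation rate", {
  fam <- synthetic_precursor_family(n = 3, seed = 1)
  g <- generate_genome(fam$precursors, n_scaffolds = 2, scaffold_len = 2000,
                       n_implants = 5, mutation_rate = 0.05, seed = 1)
  expect_equal(nrow(g$truth), 5L)
  L <- nchar(fam$precursors[[1]])
  total <- sum(g$truth$mutation_count)
  # binomial 3-sigma band around 5% of all implanted bases
  nbase <- 5 * L
  expect_lt(abs(total - 0.05 * nbase), 3 * sqrt(nbase * 0.05 * 0.95) + 1)
  # divergence recomputed against the truth agrees with the recorded count
  for (k in seq_len(nrow(g$truth))) {
    t <- g$truth[k, ]
    obs <- substr(g$scaffolds[[t$scaffold_id]], t$start, t$end)
    if (t$strand == "-") obs <- revcomp(obs)
    ref <- fam$precursors[[t$source_precursor_id]]
    diffs <- sum(strsplit(obs, "")[[1]] != strsplit(ref, "")[[1]])
    expect_equal(diffs, t$mutation_count)
  }
})

test_that("near-total mutation leaves nothing recoverable at 90% identity", {
  fam <- synthetic_precursor_family(n = 1, seed = 2)
  g <- generate_genome(fam$precursors, n_scaffolds = 1, scaffold_len = 800,
                       n_implants = 1, mutation_rate = 0.999, seed = 2)
  sc <- scan_genome(fam$precursors, g$scaffolds, min_identity = 0.9,
                    flank = 0)
  expect_equal(nrow(sc$hits), 0L)
})

test_that("generation is deterministic and implants never overlap", {
  fam <- synthetic_precursor_family(n = 2, seed = 3)
  g1 <- generate_genome(fam$precursors, n_scaffolds = 2, scaffold_len = 1200,
                        n_implants = 6, mutation_rate = 0.1, seed = 31)
  g2 <- generate_genome(fam$precursors, n_scaffolds = 2, scaffold_len = 1200,
                        n_implants = 6, mutation_rate = 0.1, seed = 31)
  expect_identical(g1, g2)
  t <- g1$truth
  for (sid in unique(t$scaffold_id)) {
    iv <- t[t$scaffold_id == sid, , drop = FALSE]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1) expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
  }
  # impossible placement fails explicitly
  expect_error(
    generate_genome(fam$precursors, n_scaffolds = 1, scaffold_len = 100,
                    n_implants = 5, mutation_rate = 0, seed = 1,
                    max_tries = 20),
    "overlap|exceed")
})

test_that("promoter generator refuses impossible specifications", {
  motifs <- toy_motifs()
  spec <- matrix(TRUE, 1, 1, dimnames = list("p1", "catMissing"))
  expect_error(generate_promoters(spec, motifs), "catMissing")
  spec2 <- matrix(TRUE, 1, 1, dimnames = list("p1", "catB"))
  expect_error(generate_promoters(spec2, motifs, promoter_len = 4),
               "longest motif")
  badmotifs <- data.frame(name = "bad", pattern = "ACQT", category = "catB")
  expect_error(generate_promoters(spec2, badmotifs, promoter_len = 100),
               "non-IUPAC")
})

test_that("generated Ct tables include the reference in every sample", {
  des <- qpcr_design(treatments = list(x = c(0, 2)), genes = "g",
                     fold_profile = data.frame(gene = "g", treatment = "x",
                                               timepoint_h = 2, fold = 2),
                     n_bio = 2, n_tech = 2, noise_sd = 0.1)
  ct <- generate_ct_table(des, seed = 5)
  cells <- unique(ct[, c("treatment", "timepoint_h", "replicate_bio")])
  for (k in seq_len(nrow(cells))) {
    sub <- merge(ct, cells[k, ])
    expect_true("U6" %in% sub$gene)
    expect_equal(sum(sub$gene == "g"), 2L)
  }
  # determinism
  expect_identical(ct, generate_ct_table(des, seed = 5))
  # a missing control timepoint is rejected at design time
  expect_error(qpcr_design(treatments = list(x = c(2, 4)), genes = "g",
                           fold_profile = data.frame(gene = "g",
                                                     treatment = "x",
                                                     timepoint_h = 2,
                                                     fold = 2)),
               "control")
})

test_that("designs validate fold positivity and control folds", {
  expect_error(qpcr_design(treatments = list(x = 0), genes = "g",
                           fold_profile = data.frame(gene = "g",
                                                     treatment = "x",
                                                     timepoint_h = 2,
                                                     fold = -2)),
               "> 0")
  expect_error(qpcr_design(treatments = list(x = 0), genes = "g",
                           fold_profile = data.frame(gene = "g",
                                                     treatment = "x",
                                                     timepoint_h = 0,
                                                     fold = 2)),
               "must be 1")
})
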