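test_that("motif scanning reports both strands with 1-based positions", {
  motifs <- data.frame(name = "toy", pattern = "TGACG", category = "catX",
                       stringsAsFactors = FALSE)
  h <- scan_promoter("AATGACGA", motifs)
  expect_equal(nrow(h), 1L)
  expect_equal(h$pos, 3L)
  expect_equal(h$strand, "+")

  # reverse-complement occurrence
  h2 <- scan_promoter("TCGTCA", motifs)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$pos, 2L)

  # IUPAC degeneracy
  mdeg <- data.frame(name = "ebox", pattern = "CANNTG", category = "catY",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(scan_promoter("TTCAGGTGTT", mdeg,
                                  both_strands = FALSE)), 1L)

  expect_error(scan_promoter("ACGTQ", motifs), "non-IUPAC")
})

test_that("presence matrix is category-level presence with all-FALSE rows", {
  motifs <- toy_motifs()
  proms <- c(p1 = paste0(strrep("T", 20), "TGACGCA", strrep("T", 20)),
             p2 = strrep("T", 50))
  hits <- scan_promoters(proms, motifs)
  m <- presence_matrix(hits, names(proms), unique(motifs$category))
  expect_true(m["p1", "catA"])
  expect_false(any(m["p2", ]))
  expect_false(m["p1", "catB"])

  badhits <- hits
  badhits$category <- "nope"
  expect_error(presence_matrix(badhits, names(proms), "catA"), "unknown")
})

test_that("prevalence summary reproduces the published element-table arithmetic", {
  m <- load_element_matrix()
  s <- prevalence_summary(m)
  expect_equal(s$percent[s$category == "gibberellin"], 77.8)
  expect_equal(s$percent[s$category == "methyl_jasmonate"], 66.7)
  expect_equal(s$count[s$category == "drought"], 4L)
  expect_equal(s$count[s$category == "low_temperature"], 3L)
  expect_equal(s$count[s$category == "defense_stress"], 2L)
  expect_equal(s$count[s$category == "anaerobic"], 9L)
  expect_true(all(s$n == 9L))
})

test_that("prevalence of a category union is at least that of each member", {
  m <- load_element_matrix()
  u <- m[, "drought"] | m[, "low_temperature"]
  expect_gte(mean(u), mean(m[, "drought"]))
  expect_gte(mean(u), mean(m[, "low_temperature"]))
})

test_that("all-FALSE summary and half-up rounding", {
  m0 <- matrix(FALSE, 4, 2, dimnames = list(paste0("p", 1:4), c("x", "y")))
  s <- prevalence_summary(m0)
  expect_true(all(s$percent == 0))
  expect_equal(round_half_up(7 / 9 * 100, 1), 77.8)
  expect_equal(round_half_up(0.25 * 100, 1), 25.0)
  expect_equal(round_half_up(1 / 16 * 100, 1), 6.3) # half-up at the tie
})

test_that("generated promoters reproduce their element specification exactly", {
  motifs <- toy_motifs()
  spec <- matrix(c(TRUE, FALSE, TRUE,
                   FALSE, TRUE, FALSE,
                   FALSE, FALSE, FALSE), 3, 3, byrow = TRUE,
                 dimnames = list(paste0("p", 1:3),
                                 c("catA", "catB", "catC")))
  g <- generate_promoters(spec, motifs, promoter_len = 300, seed = 11)
  hits <- scan_promoters(g$promoters, motifs)
  got <- presence_matrix(hits, rownames(spec), colnames(spec))
  expect_identical(got, spec)
  # all-FALSE promoter contains no dictionary motif at all
  expect_equal(nrow(hits[hits$promoter == "p3", ]), 0L)
})

test_that("planted-site truth matches the scanner's positions", {
  motifs <- toy_motifs()[1, , drop = FALSE] # single non-degenerate motif
  spec <- matrix(TRUE, 1, 1, dimnames = list("p1", "catA"))
  g <- generate_promoters(spec, motifs, promoter_len = 120, seed = 3)
  hits <- scan_promoters(g$promoters, motifs)
  expect_true(all(g$truth$pos %in% hits$pos))
  expect_equal(g$truth$promoter, "p1")
})

test_that("presence matrix is invariant under reverse-complementing promoters", {
  motifs <- toy_motifs()
  spec <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE), 2, 3,
                 dimnames = list(c("p1", "p2"),
                                 c("catA", "catB", "catC")))
  g <- generate_promoters(spec, motifs, promoter_len = 300, seed = 19)
  rc <- vapply(g$promoters, revcomp, character(1))
  m1 <- presence_matrix(scan_promoters(g$promoters, motifs),
                        names(g$promoters), colnames(spec))
  m2 <- presence_matrix(scan_promoters(rc, motifs),
                        names(rc), colnames(spec))
  expect_identical(m1, m2)
})

test_that("full-scale generation round-trips the bundled element matrix", {
  spec <- load_element_matrix()
  motifs <- load_motif_dictionary()
  g <- generate_promoters(spec, motifs, promoter_len = 600, seed = 23)
  expect_length(g$promoters, 9L)
  hits <- scan_promoters(g$promoters, motifs)
  got <- presence_matrix(hits, rownames(spec), colnames(spec))
  expect_identical(got, spec)
})
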