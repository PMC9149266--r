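test_that("minimum-energy fold matches hand-checked examples", {
  f <- fold_rna("GGGAAACCC", min_loop = 3)
  expect_identical(f$structure, "(((...)))")
  expect_equal(f$mfe, -9.0)

  f2 <- fold_rna("AAAAAA")
  expect_identical(f2$structure, "......")
  expect_equal(f2$mfe, 0.0)

  # below the minimal foldable length: all-dots, energy zero
  f3 <- fold_rna("GAC")
  expect_identical(f3$structure, "...")
  expect_equal(f3$mfe, 0.0)

  expect_error(fold_rna("ACGX"), "non-IUPAC")
})

test_that("DP energy equals full-enumeration minimum on short strings", {
  set.seed(101)
  for (i in 1:40) {
    s <- random_rna(sample(5:14, 1))
    expect_equal(fold_rna(s)$mfe, oracle_mfe(s), info = s)
  }
})

test_that("pair-energy model is symmetric under complementation when G:U is disabled", {
  # with wobble pairs off, complementing every base maps GC<->CG and AU<->UA
  # pairs onto each other, so the optimum energy is unchanged
  e <- c(gc = -3, au = -2, gu = NA)
  comp <- function(s) chartr("ACGU", "UGCA", s)
  set.seed(7)
  for (i in 1:20) {
    s <- random_rna(sample(6:14, 1))
    expect_equal(fold_rna(s, energies = e)$mfe,
                 fold_rna(comp(s), energies = e)$mfe, info = s)
  }
})

test_that("gc_content and mfei follow their definitions", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AUAU"), 0.0)
  expect_equal(gc_content("GAUC"), 0.5)

  expect_equal(mfei(-50, 100, 0.50), 1.00)
  expect_equal(mfei(0, 100, 0.5), 0.0)
  expect_error(mfei(-10, 100, 0), "GC")

  # round trip through the published precursor row: MFE -51.70 over 114 nt
  # at MFEI 1.08 implies GC ~ 0.420; feeding that GC back must return 1.08
  gc_star <- abs(-51.70) / 114 / 1.08
  expect_equal(round(mfei(-51.70, 114, gc_star), 2), 1.08)
  expect_equal(round(gc_star, 3), 0.420)
})

test_that("MFEI is invariant to duplicating sequence at fixed MFE/length and GC", {
  expect_equal(mfei(-40, 80, 0.44), mfei(-80, 160, 0.44))
})

test_that("arm extraction parses hairpin topologies", {
  a <- extract_arms(fold_from_db("GGGAAACCC", "(((...)))"))
  expect_true(a$is_hairpin)
  expect_equal(a$arm5, c(1, 3))
  expect_equal(a$loop, c(4, 6))
  expect_equal(a$arm3, c(7, 9))

  # interior loop columns belong to the arms
  b <- extract_arms(fold_from_db("GGAAGGAAACCAACC", "((..((...))..))"))
  expect_true(b$is_hairpin)
  expect_equal(b$arm5, c(1, 6))
  expect_equal(b$loop, c(7, 9))
  expect_equal(b$arm3, c(10, 15))

  # two stacked hairpins: not a simple stem-loop
  c <- extract_arms(fold_from_db("GGAAACCGGAAACC", "((...))((...))"))
  expect_false(c$is_hairpin)

  # a lonely pair inside an unpaired stretch does not create a second loop
  d <- extract_arms(fold_from_db("GGGAAAGAAACAAACCC",
                                 "(((...(...)...)))"))
  expect_true(d$is_hairpin)
  expect_equal(d$arm5, c(1, 3))
})

test_that("duplex mismatch counting over mature spans", {
  # perfect 21-bp duplex
  arm <- "GCGAUCGUAGCUAGCUAGGCC"
  hp <- paste0(arm, "AAAA", revcomp(as_dna(arm)))
  f <- fold_rna(hp)
  expect_equal(count_duplex_mismatches(f, c(1, 21), c(26, 46)), 0L)

  # fully unpaired spans count the whole mature length
  f2 <- fold_from_db(strrep("A", 50), strrep(".", 50))
  expect_equal(count_duplex_mismatches(f2, c(1, 21), c(30, 50)), 21L)

  expect_error(count_duplex_mismatches(f, c(1, 21), c(10, 30)), "opposite")
})

test_that("engineered unpaired columns are counted as mismatches", {
  # purine-only arm so neither strand can self-pair; break three A:U pairs
  # by turning the star base into C (A:C cannot pair, nor wobble)
  arm <- "GAGGAGGAGAAGGAGAGGAGG"
  star <- strsplit(as_rna(revcomp(as_dna(arm))), "")[[1]]
  for (k in c(2, 8, 16)) star[22 - k] <- "C"
  hp <- paste0(arm, "AAAA", paste(star, collapse = ""))
  f <- fold_rna(hp)
  nm <- count_duplex_mismatches(f, c(1, 21), c(26, 46))
  expect_equal(nm, 3L)
})

test_that("mature placement finds the closest reference homolog", {
  fam <- synthetic_precursor_family(n = 1, seed = 5)
  prec <- fam$precursors[[1]]
  f <- fold_rna(prec)
  refs <- fam$matures
  ann <- locate_mature(prec, f, refs, locus_id = "cand")
  expect_setequal(ann$arm, c("5p", "3p"))
  expect_equal(ann$nm_to_homolog, c(0L, 0L))
  expect_equal(ann$mature_id, c("cand-5p", "cand-3p"))
  expect_equal(unique(ann$length), 21L)

  # two engineered substitutions in the 3p reference are counted exactly
  r3 <- strsplit(refs[[2]], "")[[1]]
  r3[c(4, 9)] <- vapply(r3[c(4, 9)],
                        function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  refs2 <- refs
  refs2[[2]] <- paste(r3, collapse = "")
  ann2 <- locate_mature(prec, f, refs2, locus_id = "cand")
  expect_equal(ann2$nm_to_homolog[ann2$arm == "3p"], 2L)

  # a strict threshold excludes the mutated reference
  ann3 <- locate_mature(prec, f, refs2[2], max_mismatch = 0L)
  expect_equal(nrow(ann3[ann3$arm == "3p", ]), 0L)
})

test_that("candidate screen applies thresholds in order with reasons", {
  fam <- synthetic_precursor_family(n = 2, seed = 11)
  cands <- lapply(names(fam$precursors), function(id)
    characterize_hairpin(fam$precursors[[id]], locus_id = id,
                         mature_refs = fam$matures))
  scr <- screen_candidates(cands)
  expect_true(all(scr$accepted))

  # boundary is inclusive: nm = 4 passes at max_nm = 4, fails at 3
  fake <- cands[[1]]
  fake$nm <- 4L
  expect_true(screen_candidates(list(fake), max_nm = 4L)$accepted)
  s2 <- screen_candidates(list(fake), max_nm = 3L)
  expect_false(s2$accepted)
  expect_equal(s2$reason, "nm")

  # mfei rule carries its name
  s3 <- screen_candidates(cands, min_mfei = 99)
  expect_true(all(s3$reason == "mfei"))

  # tightening any threshold never grows the accepted set
  a1 <- sum(screen_candidates(cands, min_mfei = 0.85)$accepted)
  a2 <- sum(screen_candidates(cands, min_mfei = 1.2)$accepted)
  expect_lte(a2, a1)
})

test_that("shuffled sequences are usually rejected by the screen", {
  fam <- synthetic_precursor_family(n = 1, seed = 21)
  v <- strsplit(fam$precursors[[1]], "")[[1]]
  set.seed(33)
  rejected <- 0L
  for (i in 1:10) {
    shuf <- paste(sample(v), collapse = "")
    cc <- characterize_hairpin(shuf, locus_id = "shuf",
                               mature_refs = fam$matures)
    if (!screen_candidates(list(cc))$accepted) rejected <- rejected + 1L
  }
  expect_gte(rejected, 8L)
})

test_that("vienna-format writer emits header, sequence and structure lines", {
  f <- fold_rna("GGGAAACCC")
  path <- withr::local_tempfile(fileext = ".txt")
  write_vienna(list(x1 = f), path)
  lines <- readLines(path)
  expect_equal(lines[1], ">x1")
  expect_equal(lines[2], "GGGAAACCC")
  expect_match(lines[3], "^\\(\\(\\(\\.\\.\\.\\)\\)\\) \\(-9.00\\)$")
})
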