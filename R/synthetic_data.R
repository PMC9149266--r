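#' Generate a synthetic genome with implanted precursor copies
#'
#' Builds scaffolds of i.i.d. uniform A/C/G/T background and implants copies
#' of reference precursor hairpins at recorded loci. Each implant is a
#' reference precursor with independent per-base substitution probability
#' `mutation_rate`; strands are drawn uniformly and minus-strand implants
#' are inserted as the reverse complement. Implant intervals never overlap;
#' placement is re-drawn on collision and generation fails explicitly after
#' bounded retries. The same seed reproduces the output byte for byte.
#'
#' @param reference_precursors named character vector of precursor
#'   sequences (DNA or RNA; stored as DNA).
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_len length of each scaffold (> max precursor length).
#' @param n_implants total implants, assigned to precursors round-robin.
#' @param mutation_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @param max_tries placement retries before failing.
#' @return a list with `scaffolds` (named character vector) and `truth`
#'   (data.frame: implant_id, scaffold_id, start, end, strand,
#'   source_precursor_id, mutation_count).
#' @export
generate_genome <- function(reference_precursors, n_scaffolds = 2L,
                            scaffold_len = 2000L, n_implants = 5L,
                            mutation_rate = 0.05, seed = 1L,
                            max_tries = 1000L) {
  stopifnot(length(reference_precursors) >= 1L,
            !is.null(names(reference_precursors)),
            mutation_rate >= 0, mutation_rate < 1)
  refs <- vapply(reference_precursors, as_dna, character(1))
  if (scaffold_len <= max(nchar(refs))) {
    stop("scaffold_len must exceed the longest precursor", call. = FALSE)
  }
  set.seed(seed)
  scaffolds <- setNames(
    vapply(seq_len(n_scaffolds), function(i) .random_dna(scaffold_len),
           character(1)),
    sprintf("scaffold%02d", seq_len(n_scaffolds)))
  placed <- lapply(names(scaffolds), function(x) NULL)
  names(placed) <- names(scaffolds)
  truth <- list()
  for (k in seq_len(n_implants)) {
    ref_id <- names(refs)[(k - 1L) %% length(refs) + 1L]
    ref <- refs[[ref_id]]
    L <- nchar(ref)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      si <- names(scaffolds)[sample.int(n_scaffolds, 1L)]
      start <- sample.int(scaffold_len - L + 1L, 1L)
      end <- start + L - 1L
      clash <- any(vapply(placed[[si]], function(iv)
        start <= iv[2] && end >= iv[1], logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place implant without overlap", call. = FALSE)
    v <- strsplit(ref, "")[[1]]
    mut <- runif(L) < mutation_rate
    if (any(mut)) {
      v[mut] <- vapply(v[mut], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    strand <- sample(c("+", "-"), 1L)
    ins <- paste(v, collapse = "")
    if (strand == "-") ins <- revcomp(ins)
    scaffolds[[si]] <- paste0(substr(scaffolds[[si]], 1, start - 1), ins,
                              substr(scaffolds[[si]], end + 1, scaffold_len))
    placed[[si]] <- c(placed[[si]], list(c(start, end)))
    truth[[k]] <- data.frame(
      implant_id = sprintf("implant%02d", k), scaffold_id = si,
      start = start, end = end, strand = strand,
      source_precursor_id = ref_id, mutation_count = as.integer(sum(mut)),
      stringsAsFactors = FALSE)
  }
  list(scaffolds = scaffolds,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(implant_id = character(), scaffold_id = character(),
                    start = integer(), end = integer(), strand = character(),
                    source_precursor_id = character(),
                    mutation_count = integer(), stringsAsFactors = FALSE))
}

# concrete instantiation of an IUPAC degenerate pattern
.iupac_expand <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

.instantiate_motif <- function(pattern) {
  v <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(v, function(b) {
    ch <- .iupac_expand[[b]]
    if (length(ch) == 1L) ch else sample(ch, 1L)
  }, character(1)), collapse = "")
}

#' Generate promoter sequences realizing an element-presence matrix
#'
#' For every `TRUE` cell of the specification matrix, at least one concrete
#' occurrence of a motif of that category is planted at a recorded position
#' and strand; `FALSE` cells are guaranteed motif-free for their category.
#' Each promoter is drawn from the uniform background and then repaired:
#' chance background occurrences of unwanted-category motifs are disrupted
#' by point substitutions outside the planted sites, and the whole promoter
#' is re-drawn if a clean configuration is not reached. The generated set is
#' verified by re-scanning before it is returned, so the round trip through
#' [scan_promoters()] + [presence_matrix()] reproduces the specification
#' exactly.
#'
#' @param element_spec logical matrix, promoters x categories.
#' @param motifs motif dictionary (see [load_motif_dictionary()]); every
#'   category that is `TRUE` anywhere must have at least one motif.
#' @param promoter_len promoter length in bp (>= longest motif).
#' @param seed integer seed.
#' @param max_attempts re-draws per promoter before failing.
#' @return a list with `promoters` (named character vector) and `truth`
#'   (data.frame: promoter, category, motif, pos, strand of planted sites).
#' @export
generate_promoters <- function(element_spec, motifs, promoter_len = 1600L,
                               seed = 1L, max_attempts = 200L) {
  .iupac_check(motifs$pattern, "motif pattern")
  spec <- as.matrix(element_spec) != 0
  cats <- colnames(spec)
  need <- cats[colSums(spec) > 0]
  missing <- setdiff(need, motifs$category)
  if (length(missing) > 0L) {
    stop("no motif for category: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (promoter_len < max(nchar(motifs$pattern))) {
    stop("promoter_len shorter than the longest motif", call. = FALSE)
  }
  dict_cats <- intersect(unique(motifs$category), cats)
  set.seed(seed)
  promoters <- character(0)
  truth <- list()
  for (p in rownames(spec)) {
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      res <- .try_promoter(setNames(spec[p, ], colnames(spec)), motifs,
                           promoter_len, dict_cats)
      if (!is.null(res)) {
        promoters[[p]] <- res$seq
        if (nrow(res$truth) > 0L) {
          truth[[p]] <- cbind(promoter = p, res$truth,
                              stringsAsFactors = FALSE)
        }
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("could not realize element spec for promoter ", p, call. = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(promoter = character(), category = character(),
               motif = character(), pos = integer(), strand = character(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  # verification round trip
  hits <- scan_promoters(promoters, motifs)
  got <- presence_matrix(hits[hits$category %in% cats, , drop = FALSE],
                         rownames(spec), cats)
  if (!identical(unname(got), unname(spec))) {
    stop("internal error: generated promoters do not reproduce the spec",
         call. = FALSE)
  }
  list(promoters = promoters, truth = truth)
}

# one attempt at a single promoter; NULL on failure
.try_promoter <- function(spec_row, motifs, promoter_len, dict_cats) {
  seq <- .random_dna(promoter_len)
  planted <- list() # intervals
  truth <- list()
  for (cat in names(spec_row)[spec_row]) {
    cand <- motifs[motifs$category == cat, , drop = FALSE]
    mrow <- cand[sample.int(nrow(cand), 1L), ]
    inst <- .instantiate_motif(mrow$pattern)
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "-") revcomp(inst) else inst
    L <- nchar(ins)
    pos <- NA
    for (try in 1:50) {
      s <- sample.int(promoter_len - L + 1L, 1L)
      e <- s + L - 1L
      if (!any(vapply(planted, function(iv) s <= iv[2] && e >= iv[1],
                      logical(1)))) { pos <- s; break }
    }
    if (is.na(pos)) return(NULL)
    seq <- paste0(substr(seq, 1, pos - 1), ins,
                  substr(seq, pos + L, promoter_len))
    planted[[length(planted) + 1L]] <- c(pos, pos + L - 1L)
    truth[[length(truth) + 1L]] <- data.frame(
      category = cat, motif = mrow$name, pos = pos, strand = strand,
      stringsAsFactors = FALSE)
  }
  # repair chance occurrences of unwanted-category motifs
  unwanted_cats <- names(spec_row)[!spec_row]
  unwanted_cats <- intersect(unwanted_cats, dict_cats)
  sub <- motifs[motifs$category %in% unwanted_cats, , drop = FALSE]
  for (iter in 1:50) {
    if (nrow(sub) == 0L) break
    h <- scan_promoter(seq, sub)
    if (nrow(h) == 0L) break
    hit <- h[1, ]
    w <- nchar(sub$pattern[match(hit$motif, sub$name)])
    cols <- seq.int(hit$pos, hit$pos + w - 1L)
    free <- cols[!vapply(cols, function(c)
      any(vapply(planted, function(iv) c >= iv[1] && c <= iv[2],
                 logical(1))), logical(1))]
    if (length(free) == 0L) return(NULL) # overlaps a planted site; re-draw
    c0 <- if (length(free) == 1L) free else sample(free, 1L)
    old <- substr(seq, c0, c0)
    newb <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(seq, c0, c0) <- newb
  }
  if (nrow(sub) > 0L && nrow(scan_promoter(seq, sub)) > 0L) return(NULL)
  # planted categories must still be present (repair never touches them)
  list(seq = seq,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(category = character(), motif = character(),
                    pos = integer(), strand = character(),
                    stringsAsFactors = FALSE))
}

#' Generate transcripts with planted miRNA target sites
#'
#' Each requested site is the reverse complement of the miRNA with
#' controlled substitutions chosen so that the duplex scores exactly the
#' requested expectation penalty under [score_duplex()]: whole-point amounts
#' are realized by non-seed mismatches (1.0 each) and, when those run out,
#' seed mismatches (2.0); a half-point remainder uses a G:U wobble.
#' Planted sites never overlap; background is uniform.
#'
#' @param mirnas named character vector of mature miRNAs (RNA).
#' @param site_spec data.frame with columns mirna_id, transcript_id,
#'   target_penalty (each penalty >= 0 and a multiple of 0.5).
#' @param transcript_len transcript length (every transcript in the spec).
#' @param seed integer seed.
#' @param seed_span,weights,seed_factor scoring configuration, see
#'   [score_duplex()].
#' @return a list with `transcripts` (named character vector, DNA) and
#'   `truth` (data.frame: transcript_id, mirna_id, start, end, penalty).
#' @export
generate_transcripts <- function(mirnas, site_spec, transcript_len = 300L,
                                 seed = 1L, seed_span = c(2L, 13L),
                                 weights = duplex_weights(),
                                 seed_factor = 2) {
  stopifnot(all(c("mirna_id", "transcript_id", "target_penalty") %in%
                  names(site_spec)))
  if (any(site_spec$target_penalty < 0)) {
    stop("target penalties must be >= 0", call. = FALSE)
  }
  if (any(abs(site_spec$target_penalty * 2 -
                round(site_spec$target_penalty * 2)) > 1e-9)) {
    stop("target penalties must be multiples of 0.5", call. = FALSE)
  }
  set.seed(seed)
  tids <- unique(site_spec$transcript_id)
  transcripts <- setNames(
    vapply(tids, function(i) .random_dna(transcript_len), character(1)), tids)
  occupied <- lapply(tids, function(x) NULL)
  names(occupied) <- tids
  truth <- list()
  for (k in seq_len(nrow(site_spec))) {
    mid <- site_spec$mirna_id[k]
    tid <- site_spec$transcript_id[k]
    pen <- site_spec$target_penalty[k]
    m <- as_rna(mirnas[[mid]])
    site <- .site_with_penalty(m, pen, seed_span, weights, seed_factor)
    L <- nchar(site)
    pos <- NA
    for (try in 1:200) {
      s <- sample.int(transcript_len - L + 1L, 1L)
      e <- s + L - 1L
      if (!any(vapply(occupied[[tid]], function(iv)
        s <= iv[2] && e >= iv[1], logical(1)))) { pos <- s; break }
    }
    if (is.na(pos)) stop("could not place target site without overlap",
                         call. = FALSE)
    transcripts[[tid]] <- paste0(substr(transcripts[[tid]], 1, pos - 1),
                                 as_dna(site),
                                 substr(transcripts[[tid]], pos + L,
                                        transcript_len))
    occupied[[tid]] <- c(occupied[[tid]], list(c(pos, pos + L - 1L)))
    truth[[k]] <- data.frame(transcript_id = tid, mirna_id = mid,
                             start = pos, end = pos + L - 1L, penalty = pen,
                             stringsAsFactors = FALSE)
  }
  list(transcripts = transcripts, truth = do.call(rbind, truth))
}

# build a site (5'->3', RNA) whose ungapped duplex with the miRNA scores
# exactly `pen`; substituting the site base at the position pairing miRNA
# position i to the *same* base as the miRNA gives a mismatch for any base
.site_with_penalty <- function(mirna, pen, seed_span, weights, seed_factor) {
  mv <- strsplit(mirna, "")[[1]]
  L <- length(mv)
  pos <- seq_len(L)
  inseed <- pos >= seed_span[1] & pos <= seed_span[2]
  nonseed <- pos[!inseed]
  seedpos <- pos[inseed]
  w_mm <- weights[["mismatch"]]; w_gu <- weights[["gu"]]
  edits <- list() # list of (mirna_pos, type)
  remaining <- pen
  used <- integer(0)
  # half-point remainder: one non-seed G:U (falls back to a seed G:U when
  # the seed doubling makes it integral)
  frac <- remaining - floor(remaining / w_mm) * w_mm
  if (abs(frac - w_gu) < 1e-9) {
    guable <- nonseed[mv[nonseed] %in% c("G", "U")]
    if (length(guable) == 0L) {
      stop("penalty not achievable: no non-seed G/U position for a wobble",
           call. = FALSE)
    }
    p <- guable[1]
    edits[[length(edits) + 1L]] <- list(pos = p, type = "gu")
    used <- c(used, p)
    remaining <- remaining - w_gu
  } else if (abs(frac) > 1e-9) {
    stop("penalty not achievable with the declared weights", call. = FALSE)
  }
  # whole points: non-seed mismatches first, then seed mismatches (doubled);
  # an odd leftover uses a seed G:U (0.5 * seed_factor)
  avail_ns <- setdiff(nonseed, used)
  n_ns <- min(length(avail_ns), floor(remaining / w_mm + 1e-9))
  k_seed <- (remaining - n_ns * w_mm) / (w_mm * seed_factor)
  if (abs(k_seed - round(k_seed)) > 1e-9) {
    # leftover not a multiple of the doubled mismatch: spend one seed wobble
    guable <- seedpos[mv[seedpos] %in% c("G", "U")]
    if (length(guable) == 0L) {
      stop("penalty not achievable: no seed G/U position for a wobble",
           call. = FALSE)
    }
    edits[[length(edits) + 1L]] <- list(pos = guable[1], type = "gu")
    used <- c(used, guable[1])
    remaining <- remaining - w_gu * seed_factor
    avail_ns <- setdiff(nonseed, used)
    n_ns <- min(length(avail_ns), floor(remaining / w_mm + 1e-9))
    k_seed <- (remaining - n_ns * w_mm) / (w_mm * seed_factor)
  }
  if (k_seed < -1e-9 || abs(k_seed - round(k_seed)) > 1e-9 ||
      round(k_seed) > length(setdiff(seedpos, used))) {
    stop("penalty not achievable with the declared weights", call. = FALSE)
  }
  for (p in avail_ns[seq_len(n_ns)]) {
    edits[[length(edits) + 1L]] <- list(pos = p, type = "mm")
    used <- c(used, p)
  }
  for (p in setdiff(seedpos, used)[seq_len(round(k_seed))]) {
    edits[[length(edits) + 1L]] <- list(pos = p, type = "mm")
  }
  # start from the exact reverse complement and apply edits
  sv <- strsplit(revcomp(mirna), "")[[1]] # site 5'->3'; pos i <-> site L-i+1
  for (e in edits) {
    si <- L - e$pos + 1L
    mb <- mv[e$pos]
    sv[si] <- if (e$type == "mm") mb else if (mb == "G") "U" else "G"
  }
  site <- paste(sv, collapse = "")
  got <- score_duplex(duplex_align(mirna, site), seed_span, weights,
                      seed_factor)
  if (abs(got - pen) > 1e-9) {
    stop("internal error: realized penalty ", got, " != requested ", pen,
         call. = FALSE)
  }
  site
}

#' Describe a stem-loop RT-qPCR experiment design
#'
#' Collects the treatments, timepoints, true fold-change profile, replicate
#' structure and noise level used by [generate_ct_table()]. Every treatment
#' must include the 0-h control; unspecified (gene, treatment, timepoint)
#' cells have true fold 1.
#'
#' @param treatments named list: treatment label -> numeric vector of
#'   timepoints in hours (0 must be present).
#' @param genes character vector of target gene labels.
#' @param fold_profile data.frame with columns gene, treatment,
#'   timepoint_h, fold (every fold > 0; control cells must be 1).
#' @param n_bio,n_tech biological and technical replicates (>= 1).
#' @param noise_sd Gaussian noise SD on the Ct scale.
#' @param reference reference gene label.
#' @param ct_base named numeric vector of baseline Ct per target gene
#'   (recycled from a default of 25 when omitted).
#' @param ref_ct baseline Ct of the reference gene.
#' @param sample_shift_sd SD of the per-sample Ct shift shared by all genes
#'   of one (treatment, timepoint, bio) cell; cancels in the dCt.
#' @return a list of class `qpcr_design`.
#' @export
qpcr_design <- function(treatments, genes, fold_profile, n_bio = 3L,
                        n_tech = 3L, noise_sd = 0.2, reference = "U6",
                        ct_base = NULL, ref_ct = 18,
                        sample_shift_sd = 0.5) {
  stopifnot(is.list(treatments), length(treatments) >= 1L,
            n_bio >= 1L, n_tech >= 1L, noise_sd >= 0)
  for (trt in names(treatments)) {
    if (!0 %in% treatments[[trt]]) {
      stop("treatment '", trt, "' lacks the 0-h control timepoint",
           call. = FALSE)
    }
  }
  stopifnot(all(c("gene", "treatment", "timepoint_h", "fold") %in%
                  names(fold_profile)))
  if (any(fold_profile$fold <= 0)) stop("fold values must be > 0",
                                        call. = FALSE)
  ctrl <- fold_profile$timepoint_h == 0 & fold_profile$fold != 1
  if (any(ctrl)) stop("control (0 h) fold must be 1", call. = FALSE)
  if (is.null(ct_base)) ct_base <- setNames(rep(25, length(genes)), genes)
  structure(list(treatments = treatments, genes = genes,
                 fold_profile = fold_profile, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), noise_sd = noise_sd,
                 reference = reference, ct_base = ct_base, ref_ct = ref_ct,
                 sample_shift_sd = sample_shift_sd),
            class = "qpcr_design")
}

#' Generate a synthetic Ct record table
#'
#' Emulates stem-loop RT-qPCR against a small-RNA reference gene: within
#' each (treatment, timepoint, biological replicate) sample, all genes share
#' one random sample shift (pipetting/input amount; it cancels in the dCt),
#' the target Ct is lowered by log2(true fold) relative to its baseline, and
#' every technical replicate adds independent Gaussian noise on the Ct
#' scale. With `noise_sd = 0` the 2^-ddCt analysis recovers the planted
#' folds exactly.
#'
#' @param design a [qpcr_design()].
#' @param seed integer seed.
#' @return a data.frame with columns sample, treatment, timepoint_h, gene,
#'   replicate_bio, replicate_tech, ct.
#' @export
generate_ct_table <- function(design, seed = 1L) {
  stopifnot(inherits(design, "qpcr_design"))
  set.seed(seed)
  fp <- design$fold_profile
  lookup <- function(g, trt, tp) {
    hit <- fp$gene == g & fp$treatment == trt & fp$timepoint_h == tp
    if (any(hit)) fp$fold[hit][1] else 1
  }
  rows <- list()
  for (trt in names(design$treatments)) {
    for (tp in design$treatments[[trt]]) {
      for (b in seq_len(design$n_bio)) {
        shift <- rnorm(1, 0, design$sample_shift_sd)
        sample_id <- sprintf("%s_%gh_b%d", trt, tp, b)
        for (g in c(design$reference, design$genes)) {
          base <- if (g == design$reference) design$ref_ct else
            design$ct_base[[g]] - log2(lookup(g, trt, tp))
          for (tech in seq_len(design$n_tech)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample = sample_id, treatment = trt, timepoint_h = tp,
              gene = g, replicate_bio = b, replicate_tech = tech,
              ct = base + shift + rnorm(1, 0, design$noise_sd),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default synthetic qPCR design
#'
#' Six target miRNAs across freezing, cold, heat, drought and salt
#' treatments with the timepoint grids and fold-change magnitudes typical of
#' abiotic-stress miRNA studies (e.g. rapid ~19- and ~29-fold induction of
#' two family members at 2 h of freezing, ~38-fold heat induction, severalfold
#' cold and salt responses, and drought repression), three biological x
#' three technical replicates, and 0.2-cycle Ct noise.
#'
#' @return a `qpcr_design`.
#' @export
default_qpcr_design <- function() {
  genes <- c("miR166a", "miR166d-5p", "miR166e-3p", "miR166f-5p",
             "miR166h-3p", "miR166i-3p")
  treatments <- list(
    freezing = c(0, 0.5, 1, 2, 4, 6),
    cold = c(0, 2, 4, 6, 9, 12, 24),
    heat = c(0, 0.5, 1, 1.5, 2, 3),
    drought = c(0, 1, 2, 6, 9, 12, 24),
    salt = c(0, 1, 2, 6, 9, 12, 24))
  fp <- rbind(
    data.frame(gene = "miR166h-3p", treatment = "freezing",
               timepoint_h = 2, fold = 18.6),
    data.frame(gene = "miR166i-3p", treatment = "freezing",
               timepoint_h = 2, fold = 28.6),
    data.frame(gene = "miR166a", treatment = "heat",
               timepoint_h = 2, fold = 38.1),
    data.frame(gene = "miR166a", treatment = "cold",
               timepoint_h = 9, fold = 4.1),
    data.frame(gene = "miR166e-3p", treatment = "cold",
               timepoint_h = 9, fold = 10.2),
    data.frame(gene = "miR166i-3p", treatment = "cold",
               timepoint_h = 9, fold = 3.9),
    data.frame(gene = "miR166d-5p", treatment = "cold",
               timepoint_h = 24, fold = 12.8),
    data.frame(gene = "miR166f-5p", treatment = "cold",
               timepoint_h = 4, fold = 15.4),
    data.frame(gene = "miR166h-3p", treatment = "cold",
               timepoint_h = 12, fold = 8.5),
    data.frame(gene = "miR166d-5p", treatment = "salt",
               timepoint_h = 6, fold = 6.9),
    data.frame(gene = "miR166d-5p", treatment = "salt",
               timepoint_h = 9, fold = 6.0),
    expand.grid(gene = genes, treatment = "drought", timepoint_h = 12,
                fold = 0.3, stringsAsFactors = FALSE))
  qpcr_design(treatments = treatments, genes = genes, fold_profile = fp)
}
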