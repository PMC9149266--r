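#' Load the bundled cis-element motif dictionary
#'
#' A small editable TSV of named promoter cis-regulatory elements (ABRE,
#' MBS, LTR, ARE, GARE-motif, P-box, TCA-element, TGACG-motif, CGTCA-motif,
#' AuxRR-core, TGA-box, TGA-element, TC-rich) with IUPAC consensus strings
#' and their response category (abscisic acid, drought inducibility,
#' low-temperature, anaerobic induction, ...). Consensus strings follow the
#' public PlantCARE motif descriptions; they are defaults intended to be
#' replaced when a project has its own motif set.
#'
#' @param path optional path to a custom dictionary TSV with columns
#'   `name`, `pattern`, `category`.
#' @return a data.frame with columns name, pattern, category.
#' @export
load_motif_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_element_motifs.tsv",
                        package = "mirfam", mustWork = TRUE)
  }
  d <- read_tsv_file(path)
  stopifnot(all(c("name", "pattern", "category") %in% names(d)))
  .iupac_check(d$pattern, "motif pattern")
  d
}

#' Load the bundled promoter element-presence matrix
#'
#' The 9-promoter x 9-category boolean matrix of phytohormone- and
#' defense-related cis-elements detected in the upstream regions of the nine
#' blueberry miR166 loci, transcribed from the published element table. Rows
#' are promoters, columns are response categories.
#'
#' @param path optional path to a custom matrix TSV (first column promoter
#'   id, remaining columns 0/1 per category).
#' @return a logical matrix with promoter rownames and category colnames.
#' @export
load_element_matrix <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mir166_promoter_elements.tsv",
                        package = "mirfam", mustWork = TRUE)
  }
  d <- read_tsv_file(path)
  m <- as.matrix(d[, -1, drop = FALSE]) == 1
  rownames(m) <- d[[1]]
  m
}

#' Scan a promoter for cis-element motifs
#'
#' Reports every exact IUPAC-degenerate match of every dictionary motif on
#' both strands, with 1-based start positions on the plus strand;
#' overlapping hits are allowed. A minus-strand hit at position p means the
#' reverse complement of the motif starts at p on the given sequence.
#'
#' @param seq promoter sequence (DNA).
#' @param motifs data.frame with columns name, pattern, category
#'   (see [load_motif_dictionary()]).
#' @param both_strands scan the minus strand as well (default `TRUE`).
#' @return a data.frame with columns motif, category, pos, strand.
#' @export
scan_promoter <- function(seq, motifs, both_strands = TRUE) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  .check_alphabet(seq, extra = "N", what = "promoter sequence")
  .iupac_check(motifs$pattern, "motif pattern")
  subj <- Biostrings::DNAString(as_dna(seq))
  rows <- list()
  for (k in seq_len(nrow(motifs))) {
    pats <- list(`+` = motifs$pattern[k])
    if (both_strands) pats[["-"]] <- revcomp(as_dna(motifs$pattern[k]))
    for (strand in names(pats)) {
      m <- Biostrings::matchPattern(Biostrings::DNAString(as_dna(pats[[strand]])),
                                    subj, fixed = FALSE)
      if (length(m) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motifs$name[k], category = motifs$category[k],
          pos = Biostrings::start(m), strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(motif = character(), category = character(),
                      pos = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$motif, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters
#'
#' @param promoters named character vector of promoter sequences.
#' @param motifs motif dictionary data.frame.
#' @param both_strands scan the minus strand as well.
#' @return a data.frame with columns promoter, motif, category, pos, strand.
#' @export
scan_promoters <- function(promoters, motifs, both_strands = TRUE) {
  stopifnot(!is.null(names(promoters)))
  rows <- lapply(names(promoters), function(p) {
    h <- scan_promoter(promoters[[p]], motifs, both_strands = both_strands)
    if (nrow(h) == 0L) return(NULL)
    cbind(promoter = p, h, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(promoter = character(), motif = character(),
                      category = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the promoters x categories presence matrix
#'
#' A cell is `TRUE` iff the promoter carries at least one hit of any motif
#' in that category.
#'
#' @param hits data.frame from [scan_promoters()].
#' @param promoter_ids character vector of all promoter ids (so promoters
#'   without hits appear as all-`FALSE` rows).
#' @param categories character vector of category names in report order.
#' @return logical matrix promoters x categories.
#' @export
presence_matrix <- function(hits, promoter_ids, categories) {
  if (nrow(hits) > 0L && !all(hits$category %in% categories)) {
    bad <- setdiff(unique(hits$category), categories)
    stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- matrix(FALSE, length(promoter_ids), length(categories),
              dimnames = list(promoter_ids, categories))
  if (nrow(hits) > 0L) {
    for (k in seq_len(nrow(hits))) {
      m[hits$promoter[k], hits$category[k]] <- TRUE
    }
  }
  m
}

#' Per-category prevalence summary of a presence matrix
#'
#' Counts how many promoters carry each element category and reports the
#' percentage (half-up rounding to one decimal, so 7/9 prints as 77.8).
#' Categories are reported in the matrix column order.
#'
#' @param matrix logical presence matrix (promoters x categories).
#' @return a data.frame with columns category, count, n, percent.
#' @export
prevalence_summary <- function(matrix) {
  n <- nrow(matrix)
  stopifnot(n >= 1L)
  counts <- colSums(matrix)
  data.frame(category = colnames(matrix), count = as.integer(counts), n = n,
             percent = round_half_up(counts / n * 100, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
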