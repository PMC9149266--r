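#' p-distance between two aligned sequences
#'
#' Proportion of differing columns among columns where both sequences carry a
#' residue; columns with a gap (`-` or `.`) in either sequence are excluded
#' from both numerator and denominator.
#'
#' @param a,b aligned sequences of equal length.
#' @return distance in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned lengths differ", call. = FALSE)
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  gap <- c("-", ".")
  ok <- !(av %in% gap) & !(bv %in% gap)
  if (!any(ok)) stop("no comparable (gap-free) columns", call. = FALSE)
  mean(av[ok] != bv[ok])
}

#' Pairwise p-distance matrix from an alignment
#'
#' @param alignment named character vector of aligned sequences.
#' @return symmetric matrix of p-distances with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  n <- length(alignment)
  stopifnot(n >= 2L, !is.null(names(alignment)))
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- p_distance(alignment[[i]], alignment[[j]])
    }
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Arithmetic-mean UPGMA: iteratively merges the closest pair of clusters,
#' with inter-cluster distances updated as size-weighted averages and node
#' heights equal to half the merge distance, so the output tree is
#' ultrametric. Ties are broken by the lexicographically smallest pair of
#' cluster labels, a cluster's label being its smallest leaf label; children
#' of each node are ordered by label, which canonicalizes the Newick string.
#'
#' @param d symmetric distance matrix with row/column names, zero diagonal.
#' @return a list of class `upgma_tree` with the recursive `root` node
#'   (fields `leaves`, `height`, `children`, `label`) and `labels`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2L, !is.null(rownames(d)))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric",
                                       call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  labs <- rownames(d)
  nodes <- lapply(labs, function(l) list(leaves = l, height = 0,
                                         children = NULL, label = l))
  sizes <- rep(1L, n)
  act <- seq_len(n)
  dm <- d
  while (length(act) > 1L) {
    # closest active pair; ties by smallest (label_i, label_j) sorted pair
    best <- NULL
    for (ui in seq_along(act)[-length(act)]) {
      for (uj in seq.int(ui + 1L, length(act))) {
        i <- act[ui]; j <- act[uj]
        dij <- dm[i, j]
        key <- sort(c(nodes[[i]]$label, nodes[[j]]$label))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    ch <- list(nodes[[i]], nodes[[j]])
    ch <- ch[order(vapply(ch, `[[`, character(1), "label"))]
    newnode <- list(leaves = sort(c(nodes[[i]]$leaves, nodes[[j]]$leaves)),
                    height = h, children = ch,
                    label = min(nodes[[i]]$label, nodes[[j]]$label))
    # size-weighted average update
    for (k in act) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <-
        (sizes[i] * dm[i, k] + sizes[j] * dm[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    nodes[[i]] <- newnode
    act <- act[act != j]
  }
  structure(list(root = nodes[[act]], labels = labs), class = "upgma_tree")
}

.fmt_num <- function(x) {
  format(x, digits = 15, trim = TRUE, scientific = FALSE)
}

.newick_node <- function(node, parent_height, supports = NULL) {
  bl <- .fmt_num(parent_height - node$height)
  if (is.null(node$children)) {
    return(paste0(node$leaves, ":", bl))
  }
  inner <- paste(vapply(node$children, .newick_node, character(1),
                        parent_height = node$height, supports = supports),
                 collapse = ",")
  sup <- ""
  if (!is.null(supports)) {
    key <- paste(node$leaves, collapse = "|")
    if (!is.null(supports[[key]])) sup <- .fmt_num(supports[[key]])
  }
  paste0("(", inner, ")", sup, ":", bl)
}

#' Render an UPGMA tree as rooted Newick
#'
#' Branch lengths are in the distance units of the input matrix; optional
#' bootstrap supports (percent) appear as internal node labels.
#'
#' @param tree an `upgma_tree`.
#' @param supports optional named list mapping a node's sorted-leaf key
#'   (labels joined by `|`) to a support percentage.
#' @return a Newick string terminated by `;`.
#' @export
to_newick <- function(tree, supports = NULL) {
  stopifnot(inherits(tree, "upgma_tree"))
  root <- tree$root
  inner <- paste(vapply(root$children, .newick_node, character(1),
                        parent_height = root$height, supports = supports),
                 collapse = ",")
  sup <- ""
  if (!is.null(supports)) {
    key <- paste(root$leaves, collapse = "|")
    if (!is.null(supports[[key]])) sup <- .fmt_num(supports[[key]])
  }
  paste0("(", inner, ")", sup, ";")
}

# all internal-node leaf sets (clusters) of a tree, root excluded
.clusters <- function(node, acc = NULL, is_root = TRUE) {
  if (is.null(node$children)) return(acc)
  if (!is_root) acc <- c(acc, paste(node$leaves, collapse = "|"))
  for (ch in node$children) acc <- .clusters(ch, acc, is_root = FALSE)
  acc
}

#' Leaf-to-root height differences of an UPGMA tree
#'
#' @param tree an `upgma_tree`.
#' @return named numeric vector of root-to-leaf path lengths.
#' @export
leaf_depths <- function(tree) {
  depths <- function(node) {
    if (is.null(node$children)) return(setNames(0, node$leaves))
    unlist(lapply(node$children,
                  function(ch) depths(ch) + (node$height - ch$height)))
  }
  depths(tree$root)
}

#' UPGMA tree with bootstrap support from an alignment
#'
#' Builds the base tree from the full alignment via p-distance + UPGMA, then
#' resamples alignment columns with replacement `n_replicates` times; the
#' support of an internal node is the percentage of replicate trees
#' containing the same set of leaves as a cluster. Replicates whose resampled
#' columns give an undefined distance (no comparable columns for some pair)
#' are redrawn.
#'
#' @param alignment named character vector of aligned sequences.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed for column resampling.
#' @return a list of class `bootstrap_tree`: `tree` (the base `upgma_tree`),
#'   `supports` (named list keyed by sorted-leaf key, percent), `newick`
#'   (Newick with supports as internal labels), `n_replicates`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 100L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  ncol <- nchar(alignment[[1]])
  if (ncol < 2L) stop("alignment must have >= 2 columns", call. = FALSE)
  if (any(nchar(alignment) != ncol)) stop("ragged alignment", call. = FALSE)
  base <- upgma(p_distance_matrix(alignment))
  keys <- .clusters(base$root)
  counts <- setNames(rep(0L, length(keys)), keys)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  set.seed(seed)
  done <- 0L
  guard <- 0L
  while (done < n_replicates && guard < n_replicates * 20L) {
    guard <- guard + 1L
    idx <- sample.int(ncol, ncol, replace = TRUE)
    sub <- mat[, idx, drop = FALSE]
    aln <- setNames(apply(sub, 1L, paste, collapse = ""), rownames(mat))
    t <- tryCatch(upgma(p_distance_matrix(aln)), error = function(e) NULL)
    if (is.null(t)) next
    done <- done + 1L
    rk <- .clusters(t$root)
    hit <- keys %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  if (done < n_replicates) {
    stop("could not complete bootstrap replicates (degenerate alignment)",
         call. = FALSE)
  }
  supports <- as.list(100 * counts / n_replicates)
  structure(list(tree = base, supports = supports,
                 newick = to_newick(base, supports = supports),
                 n_replicates = n_replicates),
            class = "bootstrap_tree")
}

#' Right-pad sequences into a rectangular pseudo-alignment
#'
#' Convenience utility for near-equal-length small RNAs: sequences are
#' right-padded with gaps to a common width. The canonical input to the
#' phylogeny functions is a pre-aligned FASTA produced by a dedicated
#' aligner; this helper only regularizes lengths.
#'
#' @param seqs named character vector.
#' @return named character vector of equal-length strings.
#' @export
pad_align <- function(seqs) {
  w <- max(nchar(seqs))
  setNames(vapply(seqs, function(s)
    paste0(s, strrep("-", w - nchar(s))), character(1)), names(seqs))
}
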