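#' Per-sample delta-Ct against the reference gene
#'
#' Technical replicates are averaged first; within each
#' (treatment, timepoint, biological replicate) cell,
#' `dCt = mean Ct(gene) - mean Ct(reference)`. The reference gene (e.g. U6
#' for small-RNA assays) must be present in every cell where the target was
#' measured.
#'
#' @param records data.frame with columns treatment, timepoint_h, gene,
#'   replicate_bio, replicate_tech, ct (the schema written by
#'   [generate_ct_table()]).
#' @param gene target gene label.
#' @param reference reference gene label.
#' @return a data.frame with columns treatment, timepoint_h, replicate_bio,
#'   delta_ct.
#' @export
delta_ct <- function(records, gene, reference) {
  need <- c("treatment", "timepoint_h", "gene", "replicate_bio", "ct")
  stopifnot(all(need %in% names(records)))
  tg <- records[records$gene == gene, , drop = FALSE]
  rf <- records[records$gene == reference, , drop = FALSE]
  if (nrow(tg) == 0L) stop("no records for gene ", gene, call. = FALSE)
  agg <- function(d) {
    a <- aggregate(ct ~ treatment + timepoint_h + replicate_bio, d, mean)
    a
  }
  at <- agg(tg); ar <- agg(rf)
  m <- merge(at, ar, by = c("treatment", "timepoint_h", "replicate_bio"),
             all.x = TRUE, suffixes = c("_gene", "_ref"))
  miss <- is.na(m$ct_ref)
  if (any(miss)) {
    cell <- m[which(miss)[1], ]
    stop(sprintf("missing reference '%s' in cell (%s, %g h, bio %s)",
                 reference, cell$treatment, cell$timepoint_h,
                 cell$replicate_bio), call. = FALSE)
  }
  data.frame(treatment = m$treatment, timepoint_h = m$timepoint_h,
             replicate_bio = m$replicate_bio,
             delta_ct = m$ct_gene - m$ct_ref, stringsAsFactors = FALSE)
}

#' Fold changes by the 2^-ddCt method
#'
#' Within each treatment, `ddCt(bio, t) = dCt(bio, t) - mean dCt(control)`
#' where the control is the `control_timepoint` (0 h by default), and the
#' per-replicate fold change is `eff^-ddCt` with amplification efficiency
#' `eff = 2` (perfect doubling). Mean and SD are taken over biological
#' replicates, so the control timepoint has mean fold 1 exactly in the
#' zero-noise limit.
#'
#' @param dct output of [delta_ct()].
#' @param control_timepoint timepoint (hours) serving as the control.
#' @param efficiency amplification efficiency (default 2).
#' @return a data.frame with columns treatment, timepoint_h, mean_fold,
#'   sd_fold, n_bio, plus per-replicate folds in attribute `"folds"`.
#' @export
fold_change <- function(dct, control_timepoint = 0, efficiency = 2) {
  out <- list()
  folds <- list()
  for (trt in unique(dct$treatment)) {
    d <- dct[dct$treatment == trt, , drop = FALSE]
    ctrl <- d[d$timepoint_h == control_timepoint, , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      stop(sprintf("treatment '%s' has no control timepoint %g h",
                   trt, control_timepoint), call. = FALSE)
    }
    base <- mean(ctrl$delta_ct)
    for (tp in sort(unique(d$timepoint_h))) {
      dd <- d[d$timepoint_h == tp, , drop = FALSE]
      f <- efficiency^(-(dd$delta_ct - base))
      out[[length(out) + 1L]] <- data.frame(
        treatment = trt, timepoint_h = tp, mean_fold = mean(f),
        sd_fold = if (length(f) > 1L) sd(f) else 0, n_bio = length(f),
        stringsAsFactors = FALSE)
      folds[[length(folds) + 1L]] <- data.frame(
        treatment = trt, timepoint_h = tp, replicate_bio = dd$replicate_bio,
        fold = f, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "folds") <- do.call(rbind, folds)
  res
}

#' Compact letter display from Tukey's HSD
#'
#' One-way ANOVA on log2 fold change per biological replicate, with group =
#' timepoint, followed by Tukey's honest significant difference over all
#' pairs at level `alpha`. Letters are assigned greedily from the group with
#' the highest mean: a group joins an existing letter class only if it is
#' not significantly different from every member; groups sharing a letter
#' are not significantly different.
#'
#' @param folds per-replicate fold table (attribute `"folds"` of
#'   [fold_change()]) for one gene and one treatment: columns timepoint_h,
#'   replicate_bio, fold.
#' @param alpha significance level (default 0.05).
#' @return a data.frame with columns timepoint_h, mean_log2_fold, letters.
#' @export
tukey_letters <- function(folds, alpha = 0.05) {
  stopifnot(all(c("timepoint_h", "fold") %in% names(folds)))
  cnt <- table(folds$timepoint_h)
  if (length(cnt) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(cnt < 2L)) {
    stop("each group needs >= 2 biological replicates", call. = FALSE)
  }
  d <- data.frame(y = log2(folds$fold),
                  g = factor(folds$timepoint_h,
                             levels = sort(unique(folds$timepoint_h))))
  fit <- aov(y ~ g, data = d)
  tk <- TukeyHSD(fit)$g
  pmat <- matrix(1, nlevels(d$g), nlevels(d$g),
                 dimnames = list(levels(d$g), levels(d$g)))
  for (r in rownames(tk)) {
    pr <- strsplit(r, "-", fixed = TRUE)[[1]]
    pmat[pr[1], pr[2]] <- pmat[pr[2], pr[1]] <- tk[r, "p adj"]
  }
  pmat[is.na(pmat)] <- 1 # zero residual variance: no evidence of difference
  means <- tapply(d$y, d$g, mean)
  ord <- names(sort(means, decreasing = TRUE))
  classes <- list() # each: character vector of member groups
  for (g in ord) {
    placed <- FALSE
    for (k in seq_along(classes)) {
      if (all(pmat[g, classes[[k]]] >= alpha)) {
        classes[[k]] <- c(classes[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- g
  }
  lab <- setNames(rep("", nlevels(d$g)), levels(d$g))
  for (k in seq_along(classes)) {
    for (g in classes[[k]]) lab[g] <- paste0(lab[g], letters[k])
  }
  data.frame(timepoint_h = as.numeric(levels(d$g)),
             mean_log2_fold = as.numeric(means[levels(d$g)]),
             letters = unname(lab[levels(d$g)]), stringsAsFactors = FALSE)
}

#' Full qPCR analysis of a Ct table
#'
#' Runs [delta_ct()], [fold_change()] and (when every timepoint has at least
#' two biological replicates) [tukey_letters()] for each target gene and
#' treatment in a Ct record table.
#'
#' @param records Ct record table (see [delta_ct()] for the schema).
#' @param reference reference gene label.
#' @param control_timepoint control timepoint in hours.
#' @param alpha significance level for the letter display.
#' @param efficiency amplification efficiency.
#' @return a data.frame with columns gene, treatment, timepoint_h,
#'   mean_fold, sd_fold, n_bio, letters.
#' @export
analyze_qpcr <- function(records, reference = "U6", control_timepoint = 0,
                         alpha = 0.05, efficiency = 2) {
  genes <- setdiff(unique(records$gene), reference)
  out <- list()
  for (g in genes) {
    dct <- delta_ct(records, g, reference)
    fc <- fold_change(dct, control_timepoint, efficiency)
    folds <- attr(fc, "folds")
    fc$letters <- NA_character_
    for (trt in unique(fc$treatment)) {
      ft <- folds[folds$treatment == trt, , drop = FALSE]
      lt <- tryCatch(tukey_letters(ft, alpha), error = function(e) NULL)
      if (!is.null(lt)) {
        idx <- fc$treatment == trt
        fc$letters[idx] <- lt$letters[match(fc$timepoint_h[idx],
                                            lt$timepoint_h)]
      }
    }
    out[[g]] <- cbind(gene = g, fc, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
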