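#' Default pipeline configuration
#'
#' A fully synthetic end-to-end run: a simulated genome with three implanted
#' reference precursors, discovery and hairpin screening, phylogenetics of
#' the reference matures, promoters realizing the bundled element matrix,
#' planted target sites, a DICE/Nei similarity analysis, and a synthetic
#' qPCR experiment. All stage seeds are derived deterministically from the
#' single root `seed`.
#'
#' @param seed root integer seed.
#' @param outdir output directory.
#' @return a nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, outdir = "mirfam_run") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = c("simulate", "discover", "phylo", "promoter", "target",
               "funcsim", "qpcr"),
    paths = list(genome = NULL, precursors = NULL, matures = NULL,
                 promoters = NULL, transcripts = NULL,
                 function_matrix = NULL, ct_table = NULL),
    simulate = list(n_family = 3L, n_scaffolds = 2L, scaffold_len = 2000L,
                    n_implants = 3L, mutation_rate = 0.05,
                    promoter_len = 400L, transcript_len = 300L),
    discover = list(min_identity = 0.85, min_coverage = 0.8, flank = 0L,
                    max_nm = 4L, min_mfei = 0.85, max_mfe = 0,
                    max_mismatch = 3L),
    phylo = list(bootstrap = 100L),
    target = list(cutoff = 5.0),
    qpcr = list(reference = "U6", alpha = 0.05))
}

#' Validate a pipeline configuration
#'
#' Exhaustive field checks; never mutates state. Returns a character vector
#' of error messages naming the offending fields (empty when the
#' configuration is valid).
#'
#' @param config a configuration list (see [default_pipeline_config()]).
#' @return character vector of errors; `character(0)` when valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1 &&
        config$seed == round(config$seed), "seed: must be a single integer")
  chk(is.character(config$outdir) && length(config$outdir) == 1,
      "outdir: must be a single path")
  known <- c("simulate", "discover", "phylo", "promoter", "target",
             "funcsim", "qpcr")
  chk(all(config$stages %in% known),
      paste0("stages: unknown stage(s) ",
             paste(setdiff(config$stages, known), collapse = ", ")))
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if ("simulate" %in% config$stages) {
    s <- config$simulate
    chk(num(s$n_implants) && s$n_implants >= 0, "simulate.n_implants")
    chk(num(s$mutation_rate) && s$mutation_rate >= 0 && s$mutation_rate < 1,
        "simulate.mutation_rate: must be in [0, 1)")
    chk(num(s$scaffold_len) && s$scaffold_len > 0, "simulate.scaffold_len")
  }
  if ("discover" %in% config$stages) {
    d <- config$discover
    chk(num(d$min_identity) && d$min_identity >= 0 && d$min_identity <= 1,
        "discover.min_identity: must be in [0, 1]")
    chk(num(d$min_coverage) && d$min_coverage >= 0 && d$min_coverage <= 1,
        "discover.min_coverage: must be in [0, 1]")
    chk(num(d$flank) && d$flank >= 0, "discover.flank")
    chk(num(d$min_mfei), "discover.min_mfei: must be numeric")
    chk(num(d$max_nm) && d$max_nm >= 0, "discover.max_nm")
    if (!"simulate" %in% config$stages) {
      chk(is.character(config$paths$genome) &&
            file.exists(config$paths$genome),
          "paths.genome: file required when discovery is enabled")
      chk(is.character(config$paths$precursors) &&
            file.exists(config$paths$precursors),
          "paths.precursors: file required when discovery is enabled")
    }
  }
  if ("phylo" %in% config$stages) {
    chk(num(config$phylo$bootstrap) && config$phylo$bootstrap >= 1,
        "phylo.bootstrap: must be >= 1")
  }
  if ("target" %in% config$stages) {
    chk(num(config$target$cutoff) && config$target$cutoff >= 0,
        "target.cutoff: must be >= 0")
  }
  if ("qpcr" %in% config$stages) {
    chk(num(config$qpcr$alpha) && config$qpcr$alpha > 0 &&
          config$qpcr$alpha <= 1, "qpcr.alpha: must be in (0, 1]")
  }
  errs
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing fields fall back to
#'   [default_pipeline_config()] values.
#' @return a configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_pipeline_config()
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]])) {
        merge_in(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  merge_in(config, user)
}

.stage_seed <- function(root, stage) {
  offsets <- c(simulate = 11L, discover = 23L, phylo = 37L, promoter = 53L,
               target = 71L, funcsim = 89L, qpcr = 101L)
  (as.integer(root) * 1009L + offsets[[stage]]) %% 2147483647L
}

.log_line <- function(stage, level, msg) {
  message(sprintf("[%s] %s %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, stage, msg))
}

.write_summary <- function(outdir, stage, summary) {
  jsonlite::write_json(summary, file.path(outdir, paste0(stage, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, discover, phylo,
#' promoter, target, funcsim, qpcr); each stage writes its TSV/FASTA/Newick
#' outputs and a machine-readable JSON summary into `config$outdir`.
#' Identical configuration and seed give identical outputs. Configuration
#' errors are reported before any stage runs; a stage failure aborts with
#' the stage name and cause.
#'
#' @param config a configuration list, see [default_pipeline_config()].
#' @return (invisibly) a named list of per-stage summaries.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  errs <- validate_config(config)
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  state <- list()
  for (stage in config$stages) {
    .log_line(stage, "INFO", "starting")
    res <- tryCatch(
      switch(stage,
             simulate = .stage_simulate(config, state),
             discover = .stage_discover(config, state),
             phylo = .stage_phylo(config, state),
             promoter = .stage_promoter(config, state),
             target = .stage_target(config, state),
             funcsim = .stage_funcsim(config, state),
             qpcr = .stage_qpcr(config, state)),
      error = function(e) {
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)
      })
    state <- res$state
    summaries[[stage]] <- res$summary
    .write_summary(outdir, stage, res$summary)
    .log_line(stage, "INFO", "done")
  }
  jsonlite::write_json(summaries, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summaries)
}

.stage_simulate <- function(config, state) {
  s <- config$simulate
  seed <- .stage_seed(config$seed, "simulate")
  fam <- synthetic_precursor_family(n = s$n_family, seed = seed)
  gen <- generate_genome(fam$precursors, n_scaffolds = s$n_scaffolds,
                         scaffold_len = s$scaffold_len,
                         n_implants = s$n_implants,
                         mutation_rate = s$mutation_rate, seed = seed + 1L)
  spec <- load_element_matrix()
  motifs <- load_motif_dictionary()
  prom <- generate_promoters(spec, motifs, promoter_len = s$promoter_len,
                             seed = seed + 2L)
  m1 <- names(fam$matures)[1]
  m2 <- names(fam$matures)[min(2L, length(fam$matures))]
  site_spec <- data.frame(
    mirna_id = c(rep(m1, 4), m2, m2, m2),
    transcript_id = c(paste0("tx", 1:4), "tx1", "tx2", "tx5"),
    target_penalty = c(0, 1, 3, 6, 0, 2, 1), stringsAsFactors = FALSE)
  tx <- generate_transcripts(fam$matures, site_spec,
                             transcript_len = s$transcript_len,
                             seed = seed + 3L)
  ct <- generate_ct_table(default_qpcr_design(), seed = seed + 4L)
  outdir <- config$outdir
  write_fasta(gen$scaffolds, file.path(outdir, "scaffolds.fasta"))
  write_fasta(fam$precursors, file.path(outdir, "reference_precursors.fasta"))
  write_fasta(fam$matures, file.path(outdir, "reference_matures.fasta"))
  write_fasta(prom$promoters, file.path(outdir, "promoters.fasta"))
  write_fasta(tx$transcripts, file.path(outdir, "transcripts.fasta"))
  write_tsv_file(gen$truth, file.path(outdir, "implant_truth.tsv"))
  write_tsv_file(tx$truth, file.path(outdir, "target_truth.tsv"))
  write_tsv_file(ct, file.path(outdir, "ct_table.tsv"))
  state$family <- fam
  state$genome <- gen
  state$promoters <- prom$promoters
  state$transcripts <- tx$transcripts
  state$target_truth <- tx$truth
  state$ct <- ct
  list(state = state,
       summary = list(stage = "simulate", seed = seed,
                      n_scaffolds = length(gen$scaffolds),
                      n_implants = nrow(gen$truth),
                      n_promoters = length(prom$promoters),
                      n_transcripts = length(tx$transcripts),
                      n_ct_records = nrow(ct)))
}

.stage_discover <- function(config, state) {
  d <- config$discover
  if (is.null(state$genome)) {
    scaffolds <- read_fasta(config$paths$genome)
    precursors <- read_fasta(config$paths$precursors)
    matures <- if (!is.null(config$paths$matures))
      read_fasta(config$paths$matures) else NULL
  } else {
    scaffolds <- state$genome$scaffolds
    precursors <- state$family$precursors
    matures <- state$family$matures
  }
  scan <- scan_genome(precursors, scaffolds, min_identity = d$min_identity,
                      min_coverage = d$min_coverage, flank = d$flank)
  cands <- lapply(names(scan$candidates), function(id)
    characterize_hairpin(scan$candidates[[id]], locus_id = id,
                         mature_refs = matures,
                         max_mismatch = d$max_mismatch))
  screen <- if (length(cands) > 0L) {
    screen_candidates(cands, max_nm = d$max_nm, min_mfei = d$min_mfei,
                      max_mfe = d$max_mfe)
  } else {
    data.frame()
  }
  outdir <- config$outdir
  write_tsv_file(scan$hits, file.path(outdir, "homology_hits.tsv"))
  if (length(scan$candidates) > 0L) {
    write_fasta(scan$candidates, file.path(outdir, "candidates.fasta"))
    write_tsv_file(screen, file.path(outdir, "hairpin_screen.tsv"))
    folds <- lapply(cands, function(cc) cc$fold)
    names(folds) <- vapply(cands, `[[`, character(1), "locus_id")
    write_vienna(folds, file.path(outdir, "candidates_fold.txt"))
    matures_df <- do.call(rbind, lapply(cands, function(cc)
      if (nrow(cc$matures) > 0L) cc$matures else NULL))
    if (!is.null(matures_df)) {
      write_tsv_file(matures_df, file.path(outdir, "mature_annotations.tsv"))
    }
  }
  state$candidates <- cands
  state$screen <- screen
  list(state = state,
       summary = list(stage = "discover", n_hits = nrow(scan$hits),
                      n_candidates = length(cands),
                      n_accepted = if (nrow(screen)) sum(screen$accepted)
                                   else 0L,
                      min_identity = d$min_identity,
                      min_coverage = d$min_coverage))
}

.stage_phylo <- function(config, state) {
  seed <- .stage_seed(config$seed, "phylo")
  seqs <- if (!is.null(state$family)) as_rna(state$family$matures) else
    as_rna(read_fasta(config$paths$matures))
  aln <- pad_align(seqs)
  bt <- bootstrap_support(aln, n_replicates = config$phylo$bootstrap,
                          seed = seed)
  writeLines(bt$newick, file.path(config$outdir, "mature_upgma.nwk"))
  dm <- p_distance_matrix(aln)
  write_tsv_file(data.frame(id = rownames(dm), dm, check.names = FALSE),
                 file.path(config$outdir, "mature_pdistance.tsv"))
  state$tree <- bt
  list(state = state,
       summary = list(stage = "phylo", seed = seed, n_leaves = length(aln),
                      n_replicates = bt$n_replicates,
                      mean_support = mean(unlist(bt$supports))))
}

.stage_promoter <- function(config, state) {
  motifs <- load_motif_dictionary()
  proms <- if (!is.null(state$promoters)) state$promoters else
    read_fasta(config$paths$promoters)
  hits <- scan_promoters(proms, motifs)
  cats <- unique(motifs$category)
  mat <- presence_matrix(hits, names(proms), cats)
  summ <- prevalence_summary(mat)
  outdir <- config$outdir
  write_tsv_file(hits, file.path(outdir, "promoter_hits.tsv"))
  write_tsv_file(data.frame(promoter = rownames(mat), mat + 0,
                            check.names = FALSE),
                 file.path(outdir, "element_presence.tsv"))
  write_tsv_file(summ, file.path(outdir, "element_prevalence.tsv"))
  state$presence <- mat
  list(state = state,
       summary = list(stage = "promoter", n_promoters = nrow(mat),
                      n_hits = nrow(hits),
                      full_prevalence_categories =
                        summ$category[summ$count == summ$n]))
}

.stage_target <- function(config, state) {
  mirnas <- if (!is.null(state$family)) state$family$matures else
    read_fasta(config$paths$matures)
  tx <- if (!is.null(state$transcripts)) state$transcripts else
    read_fasta(config$paths$transcripts)
  sites <- scan_transcripts(mirnas, tx, cutoff = config$target$cutoff)
  write_tsv_file(sites, file.path(config$outdir, "target_sites.tsv"))
  state$sites <- sites
  list(state = state,
       summary = list(stage = "target", cutoff = config$target$cutoff,
                      n_sites = nrow(sites)))
}

.stage_funcsim <- function(config, state) {
  if (!is.null(config$paths$function_matrix)) {
    d <- read_tsv_file(config$paths$function_matrix)
    m <- as.matrix(d[, -1, drop = FALSE]) != 0
    rownames(m) <- d[[1]]
  } else {
    # derive a binary function matrix from predicted target sites:
    # function label = targeted transcript
    sites <- state$sites
    if (is.null(sites) || nrow(sites) == 0L) {
      stop("no target sites available for the similarity analysis")
    }
    ids <- unique(sites$mirna_id)
    labs <- unique(sites$transcript_id)
    m <- matrix(FALSE, length(ids), length(labs),
                dimnames = list(ids, labs))
    for (k in seq_len(nrow(sites))) {
      m[sites$mirna_id[k], sites$transcript_id[k]] <- TRUE
    }
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2L) {
    summary <- list(stage = "funcsim", n_mirnas = nrow(m),
                    note = "fewer than two miRNAs with functions; skipped")
    return(list(state = state, summary = summary))
  }
  rep <- similarity_pipeline(m)
  outdir <- config$outdir
  write_similarity_table(rep, file.path(outdir, "similarity_table.tsv"))
  writeLines(rep$newick, file.path(outdir, "funcsim_upgma.nwk"))
  state$funcsim <- rep
  list(state = state,
       summary = list(stage = "funcsim", n_mirnas = nrow(m),
                      max_similarity = rep$max_pair$value,
                      min_similarity = rep$min_pair$value))
}

.stage_qpcr <- function(config, state) {
  ct <- if (!is.null(state$ct)) state$ct else
    read_tsv_file(config$paths$ct_table)
  res <- analyze_qpcr(ct, reference = config$qpcr$reference,
                      alpha = config$qpcr$alpha)
  write_tsv_file(res, file.path(config$outdir, "qpcr_fold_changes.tsv"))
  state$qpcr <- res
  list(state = state,
       summary = list(stage = "qpcr", n_genes = length(unique(res$gene)),
                      n_treatments = length(unique(res$treatment)),
                      max_mean_fold = max(res$mean_fold)))
}
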