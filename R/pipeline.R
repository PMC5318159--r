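#' Pipeline configuration
#'
#' One declarative object holding every analysis constant: call threshold,
#' coverage and read-count filters, window geometries, boundary flank, and the
#' simulation parameters used when no fixture directory is given. All
#' downstream stages read their constants from here.
#'
#' @param fixture_dir Fixture directory from [write_fixture()]; `NULL`
#'   simulates a study instead.
#' @param seed Master seed (simulation and bootstraps).
#' @param unpaired_threshold Reactivity call threshold.
#' @param min_mean DMS coverage filter, mean reads/nt.
#' @param min_reads Footprint read-count filter.
#' @param continuity_window,continuity_step Operon continuity window geometry, nt.
#' @param boundary_flank Half-width of boundary folding windows, nt.
#' @param directionality_window Up/downstream window for directionality, nt.
#' @param boundary_scan_window Rolling Gini window across boundaries, nt.
#' @param n_boundary_pairs Pairs folded for boundary statistics (folding a
#'   500 nt window is the pipeline's most expensive step).
#' @param beta Inverse temperature of the internal folding engine.
#' @param sim List of overrides passed to [simulate_study()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fixture_dir = NULL, seed = 1,
                            unpaired_threshold = 0.2, min_mean = 15,
                            min_reads = 128L, continuity_window = 80L,
                            continuity_step = 40L, boundary_flank = 250L,
                            directionality_window = 60L,
                            boundary_scan_window = 300L,
                            n_boundary_pairs = 12L, beta = 2, sim = list()) {
  structure(
    list(fixture_dir = fixture_dir, seed = seed,
         unpaired_threshold = unpaired_threshold, min_mean = min_mean,
         min_reads = as.integer(min_reads),
         continuity_window = as.integer(continuity_window),
         continuity_step = as.integer(continuity_step),
         boundary_flank = as.integer(boundary_flank),
         directionality_window = as.integer(directionality_window),
         boundary_scan_window = as.integer(boundary_scan_window),
         n_boundary_pairs = as.integer(n_boundary_pairs), beta = beta,
         sim = sim),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates signal processing, structure scoring, expression, operon-pair
#' calling and boundary statistics over a fixture or a simulated study:
#' discontinuous-gene flags, per-ORF Gini table with coverage filter, TE
#' table, same-message pair calling with TE ratios and the overlap-class K-S
#' test, replicate reproducibility (when a second DMS replicate is present),
#' TE-vs-structure correlation, and (optionally) constrained-folding
#' directionality and metagene profiles over a subset of boundaries.
#'
#' @param config A [pipeline_config()].
#' @param run_boundary Compute the folding-based boundary statistics.
#' @return A list of class `ribostruct_report` with a `tables` list, the
#'   `config`, a `config_hash` and a `log` of stage messages. Re-running with
#'   the same config reproduces every table exactly.
#' @export
run_pipeline <- function(config = pipeline_config(), run_boundary = TRUE) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  bundle <- if (!is.null(config$fixture_dir)) {
    note("input: fixture ", config$fixture_dir)
    read_fixture(config$fixture_dir)
  } else {
    note("input: simulate_study(seed = ", config$seed, ")")
    do.call(simulate_study, c(list(seed = config$seed), config$sim))
  }
  ann <- bundle$annotation
  tracks <- bundle$tracks

  disc <- flag_discontinuous_genes(tracks$mrna, ann)
  note("discontinuous genes flagged: ", sum(disc$flagged))

  gini_tbl <- orf_gini_table(tracks$dms, ann, min_mean = config$min_mean)
  note("ORFs passing coverage filter: ", sum(gini_tbl$included))

  cfg <- correction_config(min_reads = config$min_reads)
  expr <- expression_table(tracks$ribo, tracks$mrna, ann, cfg,
                           discontinuous = disc$orf_id[disc$flagged])
  note("ORFs with TE: ", sum(!is.na(expr$te)))

  pairs <- same_message_pairs(tracks$mrna, ann,
                              window = config$continuity_window,
                              step = config$continuity_step)
  pairs <- classify_overlap(pairs)
  ratios <- adjacent_te_ratios(pairs[pairs$same_message, ], expr)
  ks <- compare_te_ratio_classes(ratios)
  note("same-message pairs: ", sum(pairs$same_message), "/", nrow(pairs))

  repro <- NULL
  if (!is.null(tracks$dms_rep2)) {
    repro <- reproducibility_curve(tracks$dms, tracks$dms_rep2, ann,
                                   cutoffs = c(1, 2, 5, 10, 15, 25, 50))
    note("reproducibility curve computed over 7 cutoffs")
  } else {
    note("no second DMS replicate: reproducibility skipped")
  }

  joined <- left_join(expr, gini_tbl[, c("orf_id", "gini", "included")],
                      by = "orf_id")
  sub <- joined[!is.na(joined$te) & !is.na(joined$gini) & joined$included, ]
  te_structure <- if (nrow(sub) >= 5) {
    spearman_bootstrap(sub$gini, log(sub$te), seed = config$seed)
  } else {
    NULL
  }
  if (!is.null(te_structure)) {
    note("TE vs Gini: rho = ", format(te_structure$rho, digits = 3),
         " over ", te_structure$n, " ORFs")
  }

  directionality <- metagene <- NULL
  if (run_boundary) {
    cand <- pairs[pairs$same_message & pairs$spacing > 0, ]
    cand <- head(cand, config$n_boundary_pairs)
    if (nrow(cand)) {
      probs <- boundary_pair_probs(ann, cand, dms_track = tracks$dms,
                                   flank = config$boundary_flank,
                                   beta = config$beta,
                                   threshold = config$unpaired_threshold)
      directionality <- boundary_directionality(
        ann, cand, probs = probs, window = config$directionality_window
      )
      metagene <- metagene_pairing(ann, cand, probs = probs)
      note("boundary statistics over ", length(probs$probs), " pairs")
    } else {
      note("no eligible boundary pairs: folding stage skipped")
    }
  } else {
    note("boundary stage disabled")
  }

  out <- structure(
    list(
      tables = list(
        gini = gini_tbl, expression = expr, pairs = pairs,
        te_ratios = ratios, te_ratio_ks = ks, discontinuous = disc,
        reproducibility = repro, te_structure = te_structure,
        directionality = directionality, metagene = metagene
      ),
      config = config,
      config_hash = rlang::hash(config),
      log = log
    ),
    class = "ribostruct_report"
  )
  out
}

#' @export
print.ribostruct_report <- function(x, ...) {
  cat("<ribostruct_report> config ", x$config_hash, "\n", sep = "")
  cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a pipeline report to TSV files
#'
#' Each table is written with a `# config_hash:` provenance header.
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_pipeline_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(report$tables)) {
    tbl <- report$tables[[nm]]
    if (is.null(tbl)) next
    if (inherits(tbl, "spearman_boot")) tbl <- tidy(tbl)
    path <- file.path(outdir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", report$config_hash), con)
    suppressWarnings(write.table(as.data.frame(tbl), con, sep = "\t",
                                 quote = FALSE, row.names = FALSE))
    close(con)
    paths <- c(paths, path)
  }
  writeLines(c(paste0("# config_hash: ", report$config_hash), report$log),
             file.path(outdir, "stages.log"))
  invisible(paths)
}
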