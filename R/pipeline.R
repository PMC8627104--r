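# Orchestration: the iterative scaffolding pipeline. Each round rebuilds the
# contact matrix against the *current* scaffolds (coordinates lifted through
# the SAT document, always from the original alignments), constructs and
# prunes the mutual-N-best graph, and composes the resulting paths; after the
# last round the spanning-coverage misjoin stage breaks weak joins.

#' Run one scaffolding iteration
#'
#' @param doc a `sat_document` (first round: singleton paths per contig).
#' @param pairs pair data.frame (or SAM/BAM path(s)) of Hi-C alignments
#'   against the original contigs.
#' @param params from [scaffold_params()].
#' @param verbose log pair-filter and join counts via `message()`.
#' @return the updated `sat_document` (unchanged if no joins were possible).
#' @export
run_iteration <- function(doc, pairs, params = scaffold_params(),
                          verbose = TRUE) {
  pairs <- read_hic_pairs(pairs)
  cm <- build_contact_matrix(pairs, doc, params)
  if (verbose)
    message("pairs by filter: ",
            paste(names(cm$stats), as.integer(cm$stats), sep = "=",
                  collapse = " "))
  if (cm$n_counted == 0) {
    warning("no qualified inter-scaffold read pairs; document unchanged")
    return(doc)
  }
  nb <- n_best_neighbors(cm, params)
  g <- prune_scaffold_graph(build_scaffold_graph(nb))
  paths <- extract_scaffold_paths(g)
  if (verbose)
    message(sprintf("%d surviving edges, %d scaffold paths",
                    nrow(g$edges), length(paths)))
  compose_scaffolds(doc, paths)
}

#' Run the full iterative scaffolding pipeline
#'
#' `iterations` rounds of [run_iteration()], then misjoin detection and
#' breaking, then (optionally) SAT/AGP/FASTA emission under `output_dir`.
#'
#' @param assembly FASTA path, `DNAStringSet`, or a named numeric vector of
#'   contig lengths (no sequence output possible in the latter case).
#' @param alignments SAM/BAM path(s) or a pair data.frame.
#' @param output_dir directory for outputs (`scaffolds_iter<k>.sat`,
#'   `scaffolds_final.sat`, `scaffolds.agp`, `scaffolds.fa`, `breaks.tsv`);
#'   `NULL` for no file output.
#' @param iterations number of scaffolding rounds (default 3).
#' @param params from [scaffold_params()].
#' @param break_percent misjoin threshold p, percent (default 30).
#' @param gap_len gap size between members, bp (default 200).
#' @param verbose log progress.
#' @return list with `doc` (final, post-break), `prebreak_doc`, `decisions`
#'   (break table) and `metrics` (per-iteration scaffold count and N50).
#' @export
run_pipeline <- function(assembly, alignments, output_dir = NULL,
                         iterations = 3, params = scaffold_params(),
                         break_percent = 30, gap_len = 200, verbose = TRUE) {
  stopifnot(iterations >= 1)
  doc <- if (inherits(assembly, "sat_document")) assembly
  else if (is.numeric(assembly)) sat_from_lengths(assembly, gap_len = gap_len)
  else sat_from_fasta(assembly, gap_len = gap_len)
  pairs <- read_hic_pairs(alignments)
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  metrics <- list()
  for (k in seq_len(iterations)) {
    if (verbose) message("iteration ", k)
    doc <- run_iteration(doc, pairs, params, verbose = verbose)
    m <- assembly_metrics(doc)
    metrics[[k]] <- data.frame(iteration = k, scaffolds = m$count,
                               n50 = m$n50)
    if (verbose)
      message(sprintf("  %d scaffolds, N50 %s", m$count,
                      format(m$n50, big.mark = ",")))
    if (!is.null(output_dir))
      write_sat(doc, file.path(output_dir, sprintf("scaffolds_iter%d.sat", k)))
  }
  prof <- spanning_coverage(pairs, doc, q = params$q)
  decisions <- detect_breaks(collect_maxima(prof, doc), p = break_percent)
  final <- apply_breaks(doc, decisions)
  if (verbose)
    message(sprintf("misjoin stage: %d of %d joins broken",
                    sum(decisions$broken), nrow(decisions)))
  if (!is.null(output_dir)) {
    write_sat(final, file.path(output_dir, "scaffolds_final.sat"))
    write_agp(sat_to_agp(final), file.path(output_dir, "scaffolds.agp"))
    if (!is.null(final$sequences))
      Biostrings::writeXStringSet(scaffold_fasta(final),
                                  file.path(output_dir, "scaffolds.fa"),
                                  width = 60)
    utils::write.table(decisions, file.path(output_dir, "breaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(doc = final, prebreak_doc = doc, decisions = decisions,
       metrics = do.call(rbind, metrics))
}
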