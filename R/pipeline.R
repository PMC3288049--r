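#' Run the full simulation stage: library prep, sequencing, Model Assembly
#'
#' Executes the complete chain — expression, reverse transcription,
#' fragmentation, size selection, subsampling, flow-cycle sequencing — and
#' builds the Model Assembly from the origin-tagged reads. All stage seeds
#' are derived from the single `seed`, so a rerun with the same inputs is
#' byte-identical. Outputs written to `out_dir`: `reads.fasta`,
#' `origins.tsv`, `ma.fasta`, `ma_placements.tsv` and `manifest.json`
#' (recording seeds, parameters and per-stage counts).
#'
#' @param annotation A [transcriptome()].
#' @param out_dir Output directory (created if missing).
#' @param lib_config A [library_config()].
#' @param seq_config A [sequencer_config()].
#' @param seed Global integer seed (overrides `lib_config$seed`).
#' @param verbose Emit per-stage counts.
#' @return Invisibly, a list with `reads`, `ma` (unfiltered Model
#'   Assembly), `library` (profile/fragments/counts) and `paths`.
#' @export
run_simulation <- function(annotation, out_dir,
                           lib_config = library_config(),
                           seq_config = sequencer_config(),
                           seed = lib_config$seed, verbose = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lib_config$seed <- as.integer(seed)
  ok <- FALSE
  paths <- file.path(out_dir, c("reads.fasta", "origins.tsv", "ma.fasta",
                                "ma_placements.tsv", "manifest.json"))
  names(paths) <- c("reads", "origins", "ma", "placements", "manifest")
  on.exit(if (!ok) unlink(paths), add = TRUE)

  lib <- simulate_library(annotation, lib_config, verbose = verbose)
  reads <- sequence_library(lib$fragments, annotation, seq_config,
                            seed = seed + 4L)
  if (verbose)
    message(sprintf("sequenced %d reads, mean length %.1f bp", nrow(reads),
                    mean(nchar(reads$sequence))))
  ma <- build_model_assembly(reads, annotation)
  if (verbose)
    message(sprintf("model assembly: %d contigs", length(ma$contigs)))

  write_reads_fasta(reads, paths[["reads"]])
  utils::write.table(
    reads[, c("read_id", "transcript_id", "gene_id", "start", "end",
              "strand")],
    paths[["origins"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_assembly(ma, paths[["ma"]], paths[["placements"]])
  manifest <- list(
    seed = seed,
    stage_seeds = list(expression = seed, reverse_transcription = seed + 1L,
                       fragmentation = seed + 2L, subsampling = seed + 3L,
                       sequencing = seed + 4L),
    library_config = lib_config[setdiff(names(lib_config), "seed")],
    sequencer_config = unclass(seq_config),
    counts = c(as.list(lib$counts), reads = nrow(reads),
               ma_contigs = length(ma$contigs))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  ok <- TRUE
  invisible(list(reads = reads, ma = ma, library = lib, paths = paths))
}

#' Evaluate an assembly against a reference
#'
#' Applies the standard contig filter, then computes the full report
#' family: basic metrics and threshold counts, containment specificity and
#' sensitivity against the reference, and — when reads / placements are
#' supplied — mapping ambiguity and chimera statistics. The chimera section
#' is skipped with a note when placements are unavailable (as for
#' assemblers that do not expose read tracing).
#'
#' @param x An [assembly()] to evaluate.
#' @param reference A [transcriptome()] or [assembly()] (e.g. the Model
#'   Assembly) to compare against.
#' @param reads Optional `simulated_reads` for the ambiguity section.
#' @param annotation Optional [transcriptome()] for the chimera AS split
#'   (defaults to `reference` when that is a transcriptome).
#' @param params A [containment_params()].
#' @param min_len,drop_singletons Contig filter settings (see
#'   [filter_assembly()]).
#' @param backend Alignment backend for containment and mapping.
#' @return A list of class `assembly_evaluation` with elements `metrics`,
#'   `threshold_counts`, `specificity`, `sensitivity`, `ambiguity` (or
#'   NULL), `chimera` (or NULL) and `filtered` (the filtered assembly).
#' @export
evaluate_assembly <- function(x, reference, reads = NULL, annotation = NULL,
                              params = containment_params(),
                              min_len = 100L, drop_singletons = TRUE,
                              backend = "builtin") {
  if (length(x$contigs) == 0L) stop("empty assembly")
  ref_ids <- names(seqs_of(reference))
  clash <- intersect(names(x$contigs), ref_ids)
  if (length(clash) > 0L)
    stop("assembly and reference share sequence ids (e.g. '", clash[1L],
         "'); rename one side")
  filtered <- filter_assembly(x, min_len, drop_singletons)
  if (length(filtered$contigs) == 0L)
    stop("no contigs survive the length/singleton filter")
  if (is.null(annotation) && inherits(reference, "transcriptome"))
    annotation <- reference
  res <- list(
    metrics = compute_metrics(filtered),
    threshold_counts = cumulative_length_counts(filtered),
    specificity = specificity(filtered, reference, params, backend),
    sensitivity = sensitivity(reference, filtered, params, backend),
    ambiguity = NULL, chimera = NULL,
    filtered = filtered
  )
  if (!is.null(reads))
    res$ambiguity <- map_reads_to_contigs(reads, filtered, params, backend)
  if (!is.null(filtered$placements) && !is.null(reads) &&
      !is.null(annotation)) {
    res$chimera <- chimera_stats(filtered$placements, reads, annotation)
  } else {
    message("placements, reads or annotation unavailable; ",
            "chimera section skipped")
  }
  class(res) <- "assembly_evaluation"
  res
}

#' @export
print.assembly_evaluation <- function(x, ...) {
  cat("== Assembly metrics ==\n"); print(x$metrics)
  cat("Contigs longer than (bp):",
      paste(sprintf("%s: %d", names(x$threshold_counts),
                    x$threshold_counts), collapse = ", "), "\n")
  cat("== Containment ==\n")
  print(x$specificity); print(x$sensitivity)
  if (!is.null(x$ambiguity)) { cat("== Ambiguity ==\n"); print(x$ambiguity) }
  if (!is.null(x$chimera)) { cat("== Chimeras ==\n"); print(x$chimera) }
  invisible(x)
}

#' Write an evaluation to a set of TSV reports
#'
#' One file per report family (`metrics.tsv`, `threshold_counts.tsv`,
#' `containment.tsv`, `ambiguity.tsv`, `chimera.tsv`) plus a one-row
#' `summary.tsv`.
#'
#' @param ev An `assembly_evaluation`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_evaluation <- function(ev, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- character(0L)
  f <- file.path(out_dir, "metrics.tsv")
  write_metrics(ev$metrics, f); p <- c(p, f)
  f <- file.path(out_dir, "threshold_counts.tsv")
  utils::write.table(
    data.frame(threshold = names(ev$threshold_counts),
               contigs_longer = as.integer(ev$threshold_counts)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- c(p, f)
  f <- file.path(out_dir, "containment.tsv")
  utils::write.table(
    data.frame(
      measure = c("specificity", "sensitivity"),
      absolute = c(sprintf("%d/%d", ev$specificity$contained,
                           ev$specificity$total),
                   sprintf("%d/%d", ev$sensitivity$contained,
                           ev$sensitivity$total)),
      relative_pct = c(ev$specificity$percent, ev$sensitivity$percent)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- c(p, f)
  if (!is.null(ev$ambiguity)) {
    f <- file.path(out_dir, "ambiguity.tsv")
    a <- ev$ambiguity
    utils::write.table(
      data.frame(statistic = c("contigs_hit", "contigs_total",
                               "reads_mapped", "reads_total", "reads_multi"),
                 value = c(a$contigs_hit, a$contigs_total, a$reads_mapped,
                           a$reads_total, a$reads_multi)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    p <- c(p, f)
  }
  if (!is.null(ev$chimera)) {
    f <- file.path(out_dir, "chimera.tsv")
    ch <- ev$chimera
    utils::write.table(
      data.frame(statistic = c("non_chimeric_abs", "n_contigs",
                               "non_chimeric_rel",
                               "mean_misplaced_fraction_AS",
                               "mean_misplaced_fraction_nonAS"),
                 value = c(ch$non_chimeric_abs, ch$n_contigs,
                           ch$non_chimeric_rel,
                           ch$mean_misplaced_fraction_AS,
                           ch$mean_misplaced_fraction_nonAS)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    p <- c(p, f)
  }
  invisible(p)
}
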