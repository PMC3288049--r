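#' Read-to-contig mapping ambiguity
#'
#' Aligns reads back to assembled contigs and aggregates redundancy
#' statistics: how many contigs attract at least one read, how many reads
#' map at all, and how many map to multiple contigs (multiple hits above
#' the e-value threshold — intrinsic redundancy of the assembly).
#'
#' @param reads A `simulated_reads` data.frame (needs `read_id`,
#'   `sequence`).
#' @param assembly An [assembly()].
#' @param params A [containment_params()]; only `evalue_max` gates mapping
#'   (a read maps to a contig iff any local hit passes it).
#' @param backend Alignment backend, as in [align_all()].
#' @param best_hit_only Count each read only for its single best-scoring
#'   contig (default FALSE: any passing hit counts).
#' @return A list of class `ambiguity_report`: `contigs_hit`,
#'   `contigs_total`, `reads_mapped`, `reads_total`, `reads_multi`, and the
#'   per-read contig sets (`mapping`).
#' @export
map_reads_to_contigs <- function(reads, assembly,
                                 params = containment_params(),
                                 backend = "builtin",
                                 best_hit_only = FALSE) {
  if (length(assembly$contigs) == 0L) stop("empty assembly")
  queries <- setNames(reads$sequence, reads$read_id)
  hits <- align_all(queries, assembly$contigs, params, backend)
  hits <- hits[hits$evalue < params$evalue_max, , drop = FALSE]
  if (best_hit_only && nrow(hits) > 0L) {
    hits <- hits[order(hits$query_id, -hits$score), , drop = FALSE]
    hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  }
  key <- paste(hits$query_id, hits$subject_id)
  hits <- hits[!duplicated(key), , drop = FALSE]
  mapping <- split(hits$subject_id, hits$query_id)
  n_per_read <- lengths(mapping)
  structure(list(
    contigs_hit = length(unique(hits$subject_id)),
    contigs_total = length(assembly$contigs),
    reads_mapped = length(mapping),
    reads_total = nrow(reads),
    reads_multi = sum(n_per_read >= 2L),
    mapping = mapping
  ), class = "ambiguity_report")
}

#' @export
print.ambiguity_report <- function(x, ...) {
  cat(sprintf("Contigs hit                      %d / %d\n",
              x$contigs_hit, x$contigs_total))
  cat(sprintf("Reads mapped (out of %d)     %d\n", x$reads_total,
              x$reads_mapped))
  cat(sprintf("Reads mapped to multiple contigs %d\n", x$reads_multi))
  invisible(x)
}

#' Parse read placements from an ACE assembly file
#'
#' Reads the `CO` (contig) and `RD` (read) records of an ACE file and
#' returns one placement per read occurrence; a read appearing under
#' several contigs yields several placements. Trailing direction suffixes
#' on read names (`.f`/`.r`/`.fN`/`.rN`, or `/1`, `/2`) are stripped.
#'
#' @param path ACE file path.
#' @return data.frame with columns `read_id`, `contig_id`.
#' @export
parse_ace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty ACE file: ", path)
  co <- grepl("^CO ", lines)
  rd <- grepl("^RD ", lines)
  if (!any(co)) stop("no CO record in ACE file: ", path)
  bad <- which(rd)[which(rd) < which(co)[1L]]
  if (length(bad) > 0L)
    stop("malformed ACE file: RD record before any CO record at line ",
         bad[1L])
  contig_at <- cumsum(co)
  contig_names <- vapply(strsplit(lines[co], " ", fixed = TRUE), `[[`,
                         character(1L), 2L)
  read_names <- vapply(strsplit(lines[rd], " ", fixed = TRUE), `[[`,
                       character(1L), 2L)
  read_names <- sub("(\\.[fr][0-9]*|/[12])$", "", read_names)
  data.frame(read_id = read_names,
             contig_id = contig_names[contig_at[rd]],
             stringsAsFactors = FALSE)
}

#' Chimera statistics from read provenance
#'
#' For every contig, the majority origin transcript of its member reads is
#' determined (ties broken lexicographically and reported); reads whose
#' origin transcript differs are misplaced, and a contig is chimeric iff
#' any member is misplaced (equivalently, iff its misplaced fraction is
#' positive). Contigs are split by the alternative-splicing status of the
#' majority transcript's gene, and the average misplaced-read proportion is
#' reported per class (unweighted over contigs). A gene-level misplaced
#' fraction (origin gene differs from majority gene) is carried as a
#' secondary column for interpretation.
#'
#' @param placements data.frame with columns `read_id`, `contig_id` (reads
#'   placed in several contigs count in each).
#' @param read_origins data.frame with columns `read_id`, `transcript_id`
#'   (and optionally `gene_id`), e.g. a `simulated_reads` table or parsed
#'   headers.
#' @param annotation A [transcriptome()] (for gene membership and AS
#'   status).
#' @return A list of class `chimera_report`: `per_contig` data.frame
#'   (`contig_id`, `n_reads`, `majority_transcript_id`,
#'   `misplaced_fraction`, `misplaced_gene_fraction`, `is_chimeric`,
#'   `as_status`), plus summary fields `n_contigs`, `non_chimeric_abs`,
#'   `non_chimeric_rel`, `mean_misplaced_fraction_AS`,
#'   `mean_misplaced_fraction_nonAS`.
#' @export
chimera_stats <- function(placements, read_origins, annotation) {
  idx <- match(placements$read_id, read_origins$read_id)
  if (anyNA(idx))
    stop("placed read with unknown origin: ",
         placements$read_id[is.na(idx)][1L])
  tx <- read_origins$transcript_id[idx]
  tx2gene <- setNames(annotation$transcripts$gene_id,
                      annotation$transcripts$transcript_id)
  unknown_tx <- !(tx %in% names(tx2gene))
  if (any(unknown_tx))
    stop("read ", placements$read_id[unknown_tx][1L],
         " originates from transcript absent from the annotation: ",
         tx[unknown_tx][1L])
  as_gene <- is_alternatively_spliced(annotation)
  by_contig <- split(tx, placements$contig_id)
  per <- lapply(names(by_contig), function(cid) {
    t <- by_contig[[cid]]
    tab <- table(t)
    top <- max(tab)
    winners <- sort(names(tab)[tab == top])
    if (length(winners) > 1L)
      message("contig ", cid, ": majority tie among {",
              paste(winners, collapse = ", "),
              "}; broken lexicographically")
    maj <- winners[1L]
    maj_gene <- tx2gene[[maj]]
    mis <- sum(t != maj)
    mis_gene <- sum(tx2gene[t] != maj_gene)
    data.frame(contig_id = cid, n_reads = length(t),
               majority_transcript_id = maj,
               misplaced_fraction = mis / length(t),
               misplaced_gene_fraction = mis_gene / length(t),
               is_chimeric = mis > 0L,
               as_status = if (as_gene[[maj_gene]]) "AS" else "non-AS",
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  n <- nrow(per)
  nc <- sum(!per$is_chimeric)
  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  structure(list(
    per_contig = per,
    n_contigs = n,
    non_chimeric_abs = nc,
    non_chimeric_rel = nc / n,
    mean_misplaced_fraction_AS =
      mean_or_na(per$misplaced_fraction[per$as_status == "AS"]),
    mean_misplaced_fraction_nonAS =
      mean_or_na(per$misplaced_fraction[per$as_status == "non-AS"])
  ), class = "chimera_report")
}

#' @export
print.chimera_report <- function(x, ...) {
  cat(sprintf("Non-chimeric contigs             %d / %d (%.1f%%)\n",
              x$non_chimeric_abs, x$n_contigs, 100 * x$non_chimeric_rel))
  cat(sprintf("Avg proportion misplaced, AS     %s\n",
              if (is.na(x$mean_misplaced_fraction_AS)) "NA" else
                sprintf("%.2f%%", 100 * x$mean_misplaced_fraction_AS)))
  cat(sprintf("Avg proportion misplaced, non-AS %s\n",
              if (is.na(x$mean_misplaced_fraction_nonAS)) "NA" else
                sprintf("%.2f%%", 100 * x$mean_misplaced_fraction_nonAS)))
  invisible(x)
}
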