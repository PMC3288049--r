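#' Assembly container
#'
#' Generic container for any contig set — an external assembler's output or
#' the Model Assembly — with optional read placements.
#'
#' @param contigs Named character vector of contig sequences (unique,
#'   non-empty ids and sequences).
#' @param placements Optional data.frame with columns `read_id`,
#'   `contig_id`; a read may be placed in several contigs.
#' @param source_label Free-text provenance label.
#' @param ma_info Optional data.frame of positional metadata (used by the
#'   Model Assembly: `contig_id`, `transcript_id`, `start`, `end`,
#'   `n_reads`).
#' @return A list of class `assembly`.
#' @export
assembly <- function(contigs, placements = NULL, source_label = "",
                     ma_info = NULL) {
  ids <- names(contigs)
  if (length(contigs) > 0L) {
    if (is.null(ids) || any(ids == "")) stop("contigs must be named")
    if (anyDuplicated(ids)) stop("duplicate contig id: ",
                                 ids[duplicated(ids)][1L])
    if (any(nchar(contigs) == 0L)) stop("empty contig sequence")
  }
  if (!is.null(placements)) {
    stopifnot(all(c("read_id", "contig_id") %in% names(placements)))
    unknown <- !(placements$contig_id %in% ids)
    if (any(unknown))
      stop("placement refers to unknown contig: ",
           placements$contig_id[unknown][1L])
  }
  structure(list(contigs = contigs, placements = placements,
                 source_label = source_label, ma_info = ma_info),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly%s: %d contigs, %d bp total\n",
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]")
              else "",
              length(x$contigs), sum(nchar(x$contigs))))
  if (!is.null(x$placements))
    cat(sprintf("  %d read placements (%d distinct reads)\n",
                nrow(x$placements), length(unique(x$placements$read_id))))
  invisible(x)
}

#' Load an assembly from FASTA (and optional placements TSV)
#' @param fasta_path Contig FASTA.
#' @param placements_path Optional TSV with columns `read_id`, `contig_id`.
#' @param source_label Provenance label (defaults to the file name).
#' @return An [assembly()].
#' @export
load_assembly <- function(fasta_path, placements_path = NULL,
                          source_label = basename(fasta_path)) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) == 0L) stop("empty assembly FASTA: ", fasta_path)
  contigs <- setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
  placements <- if (!is.null(placements_path))
    utils::read.table(placements_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  assembly(contigs, placements, source_label)
}

#' Write an assembly to FASTA (and optional placements TSV)
#' @param x An [assembly()].
#' @param fasta_path Output FASTA path.
#' @param placements_path Optional output TSV path for placements.
#' @return `fasta_path`, invisibly.
#' @export
write_assembly <- function(x, fasta_path, placements_path = NULL) {
  ss <- Biostrings::DNAStringSet(x$contigs)
  names(ss) <- names(x$contigs)
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  if (!is.null(placements_path) && !is.null(x$placements))
    utils::write.table(x$placements[, c("read_id", "contig_id")],
                       placements_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fasta_path)
}

#' Build the Model Assembly from origin-tagged reads
#'
#' The Model Assembly (MA) is the positionally optimal assembly: per
#' transcript, reads are merged into one contig whenever they share a common
#' origin transcript and their transcript-relative spans overlap by at least
#' one base pair. Merging uses origin coordinates only — never sequence — so
#' no sequence-based assembler can outperform it on the same reads. Each MA
#' contig spans the union of its member read intervals and its sequence is
#' the corresponding reference transcript substring.
#'
#' @param reads A `simulated_reads` data.frame (or any data.frame with
#'   `read_id`, `transcript_id`, `start`, `end`).
#' @param annotation A [transcriptome()] containing every origin transcript.
#' @return An [assembly()] with `placements` and `ma_info` populated;
#'   contig ids are `MA000001, ...` in (transcript, start) order.
#' @export
build_model_assembly <- function(reads, annotation) {
  miss <- !(reads$transcript_id %in% annotation$transcripts$transcript_id)
  if (any(miss))
    stop("read ", reads$read_id[miss][1L],
         " originates from unknown transcript ",
         reads$transcript_id[miss][1L])
  if (nrow(reads) == 0L)
    return(assembly(setNames(character(0L), character(0L)),
                    placements = data.frame(read_id = character(0L),
                                            contig_id = character(0L)),
                    source_label = "MA"))
  o <- order(reads$transcript_id, reads$start, reads$end)
  tx <- reads$transcript_id[o]
  start <- reads$start[o]
  end <- reads$end[o]
  rid <- reads$read_id[o]
  n <- length(tx)
  new_tx <- c(TRUE, tx[-1L] != tx[-n])
  contig_of <- integer(n)
  c_end <- integer(n)  # per-contig union end, grows as reads merge
  cid <- 0L
  cur_end <- -1L
  for (i in seq_len(n)) {
    if (new_tx[i] || start[i] >= cur_end) {  # overlap < 1 bp: open new contig
      cid <- cid + 1L
      cur_end <- end[i]
    } else {
      cur_end <- max(cur_end, end[i])
    }
    contig_of[i] <- cid
    c_end[cid] <- cur_end
  }
  c_end <- c_end[seq_len(cid)]
  first <- !duplicated(contig_of)
  c_start <- start[first]  # reads are start-sorted within transcript
  c_tx <- tx[first]
  ids <- sprintf("MA%06d", seq_len(cid))
  seqs <- substring(annotation$sequences[c_tx], c_start + 1L, c_end)
  names(seqs) <- ids
  info <- data.frame(contig_id = ids, transcript_id = c_tx,
                     start = as.integer(c_start), end = as.integer(c_end),
                     n_reads = tabulate(contig_of, cid),
                     stringsAsFactors = FALSE)
  placements <- data.frame(read_id = rid, contig_id = ids[contig_of],
                           stringsAsFactors = FALSE)
  assembly(seqs, placements, source_label = "MA", ma_info = info)
}

#' Filter an assembly by contig length and singleton status
#'
#' Standard pre-analysis filter: contigs shorter than `min_len` bases and
#' singletons (contigs with exactly one placed read) are discarded. The
#' filter applies identically to the Model Assembly and to external
#' assemblies, for comparability. When placements are unavailable (as for
#' assemblers that do not expose read tracing) the singleton filter is
#' skipped with a warning and only the length filter applies.
#'
#' @param x An [assembly()].
#' @param min_len Minimum retained contig length in bases (kept when
#'   `length >= min_len`; default 100).
#' @param drop_singletons Drop single-read contigs (default TRUE).
#' @return The filtered [assembly()] (placements and `ma_info` subset
#'   accordingly).
#' @export
filter_assembly <- function(x, min_len = 100L, drop_singletons = TRUE) {
  keep <- nchar(x$contigs) >= min_len
  if (drop_singletons) {
    if (is.null(x$placements)) {
      warning("placements unavailable; singleton filter skipped, ",
              "length filter only")
    } else {
      members <- table(x$placements$contig_id)
      nm <- as.integer(members[names(x$contigs)])
      nm[is.na(nm)] <- 0L
      keep <- keep & nm >= 2L
    }
  }
  contigs <- x$contigs[keep]
  placements <- if (!is.null(x$placements))
    x$placements[x$placements$contig_id %in% names(contigs), , drop = FALSE]
  ma_info <- if (!is.null(x$ma_info))
    x$ma_info[x$ma_info$contig_id %in% names(contigs), , drop = FALSE]
  assembly(contigs, placements, x$source_label, ma_info)
}
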