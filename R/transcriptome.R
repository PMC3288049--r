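#' Transcriptome annotation container
#'
#' A `transcriptome` bundles transcript sequences with their gene membership.
#' It is the source of truth for read origins and for classifying genes as
#' alternatively spliced (a gene is alternatively spliced iff it has at least
#' two transcript isoforms).
#'
#' @param sequences Named character vector of nucleotide sequences
#'   (names are transcript ids, unique).
#' @param gene_ids Character vector of gene ids, parallel to `sequences`.
#' @return An object of class `transcriptome`: a list with elements
#'   `sequences` (named character), `transcripts` (data.frame with columns
#'   `transcript_id`, `gene_id`, `length`) and `genes` (named list mapping
#'   gene id to its transcript ids).
#' @export
transcriptome <- function(sequences, gene_ids) {
  if (length(sequences) == 0L) stop("transcriptome must contain at least one transcript")
  tids <- names(sequences)
  if (is.null(tids) || anyNA(tids) || any(tids == ""))
    stop("all sequences must be named by transcript id")
  if (anyDuplicated(tids))
    stop("duplicate transcript id: ", tids[duplicated(tids)][1L])
  if (length(gene_ids) != length(sequences))
    stop("gene_ids must be parallel to sequences")
  sequences <- setNames(toupper(as.character(sequences)), tids)
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("sequence for ", tids[bad][1L], " contains non-ACGT characters")
  if (any(nchar(sequences) < 1L)) stop("zero-length transcript sequence")
  transcripts <- data.frame(
    transcript_id = tids,
    gene_id = as.character(gene_ids),
    length = nchar(sequences),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      sequences = sequences,
      transcripts = transcripts,
      genes = split(transcripts$transcript_id, transcripts$gene_id)
    ),
    class = "transcriptome"
  )
}

#' @export
print.transcriptome <- function(x, ...) {
  as_genes <- sum(is_alternatively_spliced(x))
  cat(sprintf(
    "transcriptome: %d transcripts, %d genes (%d alternatively spliced)\n",
    nrow(x$transcripts), length(x$genes), as_genes))
  cat(sprintf("  total length %d bp, transcript lengths %d-%d bp\n",
              sum(x$transcripts$length), min(x$transcripts$length),
              max(x$transcripts$length)))
  invisible(x)
}

#' Alternative-splicing status of genes
#'
#' A gene is alternatively spliced iff it has two or more transcript isoforms.
#'
#' @param annotation A [transcriptome()] object.
#' @return Named logical vector over gene ids.
#' @export
is_alternatively_spliced <- function(annotation) {
  vapply(annotation$genes, function(t) length(t) >= 2L, logical(1L))
}

#' Look up a transcript sequence
#' @param annotation A [transcriptome()] object.
#' @param transcript_id Transcript id.
#' @return The sequence as a character scalar.
#' @export
transcript_seq <- function(annotation, transcript_id) {
  s <- annotation$sequences[transcript_id]
  if (anyNA(s)) stop("unknown transcript id: ",
                     transcript_id[is.na(s)][1L])
  unname(s)
}

resolve_ambiguity <- function(seqs, mode = c("error", "resolve"), seed = NULL) {
  mode <- match.arg(mode)
  bad <- grepl("[^ACGT]", seqs)
  if (!any(bad)) return(seqs)
  if (mode == "error")
    stop("sequence contains ambiguity codes or non-ACGT characters (record ",
         names(seqs)[bad][1L], "); use ambiguity = \"resolve\" to randomize them")
  if (!is.null(seed)) set.seed(seed)
  for (i in which(bad)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    amb <- !(ch %in% c("A", "C", "G", "T"))
    iupac <- Biostrings::IUPAC_CODE_MAP
    repl <- vapply(ch[amb], function(code) {
      opts <- strsplit(iupac[[code]], "", fixed = TRUE)[[1L]]
      if (is.null(opts) || length(opts) == 0L) opts <- c("A", "C", "G", "T")
      sample(opts, 1L)
    }, character(1L))
    ch[amb] <- repl
    seqs[[i]] <- paste(ch, collapse = "")
  }
  seqs
}

#' Load transcript sequences from FASTA
#'
#' Gene membership is read from the header convention `"gene|transcript"`;
#' alternatively an explicit `gene_map` overrides the convention for headers
#' that carry a bare transcript id.
#'
#' @param fasta_path Path to a transcript FASTA file.
#' @param gene_map Optional data.frame with columns `transcript_id`,
#'   `gene_id` overriding the header convention.
#' @param ambiguity `"error"` (default) rejects non-ACGT bases; `"resolve"`
#'   replaces ambiguity codes by a random compatible base (seeded).
#' @param seed Seed for ambiguity resolution.
#' @return A [transcriptome()].
#' @export
load_transcripts <- function(fasta_path, gene_map = NULL,
                             ambiguity = c("error", "resolve"), seed = 1L) {
  if (!file.exists(fasta_path)) stop("file not found: ", fasta_path)
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) == 0L) stop("empty FASTA file: ", fasta_path)
  headers <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (!is.null(gene_map)) {
    stopifnot(all(c("transcript_id", "gene_id") %in% names(gene_map)))
    tids <- headers
    idx <- match(tids, gene_map$transcript_id)
    if (anyNA(idx)) stop("transcript ", tids[is.na(idx)][1L],
                         " missing from gene_map")
    gids <- gene_map$gene_id[idx]
  } else {
    parts <- strsplit(headers, "|", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 2L))
      stop("header '", headers[nf != 2L][1L],
           "' does not follow the gene|transcript convention; ",
           "supply gene_map instead")
    gids <- vapply(parts, `[[`, character(1L), 1L)
    tids <- vapply(parts, `[[`, character(1L), 2L)
  }
  if (anyDuplicated(tids))
    stop("duplicate transcript id: ", tids[duplicated(tids)][1L])
  names(seqs) <- tids
  seqs <- resolve_ambiguity(seqs, ambiguity, seed)
  transcriptome(seqs, gids)
}

#' Write a transcriptome to FASTA
#'
#' Headers follow the `"gene|transcript"` convention; record order is the
#' stored transcript order, so output is deterministic.
#'
#' @param annotation A [transcriptome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(annotation, path) {
  ss <- Biostrings::DNAStringSet(annotation$sequences)
  names(ss) <- paste(annotation$transcripts$gene_id,
                     annotation$transcripts$transcript_id, sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Splice transcript sequences from a genome and GTF/GFF annotation
#'
#' Exon records are grouped by `transcript_id`, sorted by genomic start, and
#' their sequences concatenated; minus-strand transcripts are
#' reverse-complemented. GTF 1-based inclusive coordinates are converted at
#' this boundary; all coordinates downstream are 0-based half-open and
#' transcript-relative.
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param gtf_path Path to a GTF/GFF file with exon features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @param biotype Optional character vector; when given, only transcripts
#'   whose `transcript_biotype` (or `gene_biotype`) attribute is in this set
#'   are kept. Default keeps all transcripts.
#' @return A [transcriptome()].
#' @export
load_annotation <- function(genome_fasta, gtf_path, biotype = NULL) {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- as.data.frame(rtracklayer::import(gtf_path))
  gr <- gr[tolower(as.character(gr$type)) == "exon", , drop = FALSE]
  if (nrow(gr) == 0L) stop("no exon features in ", gtf_path)
  if (!all(c("transcript_id", "gene_id") %in% names(gr)))
    stop("exon records must carry transcript_id and gene_id attributes")
  if (!is.null(biotype)) {
    bt <- if ("transcript_biotype" %in% names(gr)) gr$transcript_biotype
          else if ("gene_biotype" %in% names(gr)) gr$gene_biotype
          else stop("biotype filter requested but no biotype attribute present")
    gr <- gr[bt %in% biotype, , drop = FALSE]
    if (nrow(gr) == 0L) stop("no exons left after biotype filter")
  }
  df <- data.frame(
    contig = as.character(gr$seqnames),
    start = gr$start,   # 1-based inclusive (GTF)
    end = gr$end,
    strand = as.character(gr$strand),
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    stringsAsFactors = FALSE
  )
  widths <- setNames(Biostrings::width(genome), names(genome))
  miss <- !(df$contig %in% names(widths))
  if (any(miss)) stop("exon on unknown contig: ", df$contig[miss][1L])
  oob <- df$start < 1L | df$end > widths[df$contig]
  if (any(oob))
    stop("exon outside contig bounds: transcript ",
         df$transcript_id[oob][1L], " on ", df$contig[oob][1L])
  by_tx <- split(df, df$transcript_id)
  seqs <- character(length(by_tx))
  gids <- character(length(by_tx))
  for (i in seq_along(by_tx)) {
    ex <- by_tx[[i]]
    ex <- ex[order(ex$start), , drop = FALSE]
    pieces <- substring(as.character(genome[[ex$contig[1L]]]), ex$start, ex$end)
    s <- paste(pieces, collapse = "")
    if (ex$strand[1L] == "-") s <- revcomp(s)
    seqs[i] <- s
    gids[i] <- ex$gene_id[1L]
  }
  names(seqs) <- names(by_tx)
  transcriptome(seqs, gids)
}

#' Reverse-complement a nucleotide string
#' @param x Character vector of sequences over A/C/G/T.
#' @return Reverse complements, same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
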