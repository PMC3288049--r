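#' Sequencer configuration for the flow-cycle pyrosequencing model
#'
#' The simulator mimics 454 chemistry: nucleotides are flowed in the fixed
#' order T, A, C, G (one flow cycle = 4 flows); each flow reads one whole
#' homopolymer run of the flowed base, producing a light signal whose noise
#' grows with run length. Miscalled signals give homopolymer-length indels,
#' the platform's hallmark error mode; no substitutions are generated.
#'
#' @param flow_cycles Number of flow cycles (default 100, i.e. 400 flows).
#' @param sigma0 Baseline flow-signal noise s.d.
#' @param sigma1 Run-length-scaled noise: a run of length n draws its signal
#'   from `Normal(n, sigma0 + sigma1 * sqrt(n))`.
#' @param p_insert_zero Probability that a zero-mer flow (no template base)
#'   produces a spurious signal >= 0.5, inserting one base of the flowed
#'   nucleotide.
#' @return A list of class `sequencer_config`.
#' @export
sequencer_config <- function(flow_cycles = 100L, sigma0 = 0.03,
                             sigma1 = 0.09, p_insert_zero = 0.005) {
  if (flow_cycles < 1L) stop("flow_cycles must be >= 1")
  if (sigma0 < 0 || sigma1 < 0) stop("noise scales must be >= 0")
  if (p_insert_zero < 0 || p_insert_zero >= 1)
    stop("p_insert_zero must be in [0, 1)")
  structure(list(flow_cycles = as.integer(flow_cycles), sigma0 = sigma0,
                 sigma1 = sigma1, p_insert_zero = p_insert_zero),
            class = "sequencer_config")
}

FLOW_ORDER <- c("T", "A", "C", "G")

# Round a flow signal to a called run length: half away from zero, floored
# at 0. For the non-negative signals that matter this is floor(x + 0.5).
call_flow_signal <- function(signal) {
  pmax(0L, as.integer(floor(signal + 0.5)))
}

#' Sequence one fragment through the flow-cycle error model
#'
#' The template (the fragment or its reverse complement, per `orientation`)
#' is decomposed into homopolymer runs. Flows proceed in TACG order for
#' `4 * flow_cycles` flows; the flow matching each run draws a signal
#' `Normal(n, sigma0 + sigma1 * sqrt(n))` for true run length n, called as
#' the signal rounded half-away-from-zero and floored at 0. Zero-mer flows
#' between runs insert one flowed base with probability `p_insert_zero`.
#' Sequencing ends when flows are exhausted or the template is consumed.
#'
#' @param fragment_sequence Template nucleotide string (plus strand of the
#'   fragment).
#' @param orientation `"+"` sequences the fragment 5'->3'; `"-"` sequences
#'   its reverse complement.
#' @param config A [sequencer_config()].
#' @return A list: `sequence` (the read), `consumed` (error-free template
#'   bases consumed, which equals the origin span length).
#' @export
sequence_fragment <- function(fragment_sequence, orientation = "+",
                              config = sequencer_config()) {
  if (nchar(fragment_sequence) == 0L) stop("empty fragment sequence")
  template <- if (orientation == "-") revcomp(fragment_sequence)
              else fragment_sequence
  bases <- strsplit(template, "", fixed = TRUE)[[1L]]
  r <- rle(bases)
  run_base <- r$values
  run_len <- r$lengths
  pos <- match(run_base, FLOW_ORDER)      # 1..4 in flow order
  prev <- c(4L, pos[-length(pos)])        # flow 0 sits at G
  step <- (pos - prev) %% 4L
  step[step == 0L] <- 4L
  flow_at <- cumsum(step)
  n_flows <- 4L * config$flow_cycles

  keep <- flow_at <= n_flows
  run_base <- run_base[keep]; run_len <- run_len[keep]
  flow_at <- flow_at[keep]; step <- step[keep]
  consumed <- sum(run_len)
  if (length(run_len) == 0L)
    return(list(sequence = "", consumed = 0L))

  signal <- stats::rnorm(length(run_len), mean = run_len,
                         sd = config$sigma0 + config$sigma1 * sqrt(run_len))
  called <- call_flow_signal(signal)

  # zero-mer flows interleaved before each run (step - 1 of them)
  ins_base <- character(0L); ins_flow <- integer(0L)
  if (config$p_insert_zero > 0) {
    nz <- step - 1L
    zi <- rep.int(seq_along(step), nz)
    off <- sequence(nz)                       # 1..nz within each gap
    zflow <- flow_at[zi] - (nz[zi] - off + 1L)
    hit <- stats::runif(length(zflow)) < config$p_insert_zero
    if (any(hit)) {
      ins_flow <- zflow[hit]
      ins_base <- FLOW_ORDER[((ins_flow - 1L) %% 4L) + 1L]
    }
  }
  ev_flow <- c(flow_at, ins_flow)
  ev_base <- c(run_base, ins_base)
  ev_len <- c(called, rep.int(1L, length(ins_base)))
  o <- order(ev_flow)
  seq_out <- paste(rep.int(ev_base[o], ev_len[o]), collapse = "")
  list(sequence = seq_out, consumed = as.integer(consumed))
}

#' Sequence a fragment library into origin-tagged reads
#'
#' One read per fragment; orientation is Bernoulli(0.5). The read's origin
#' records the transcript-relative span of template actually consumed
#' (error-free span): forward reads consume from the fragment 5' end,
#' reverse reads from its 3' end. Read ids encode the origin losslessly
#' under the grammar `readNNN|transcript_id|gene_id|start|end|strand`.
#'
#' @param fragments Fragment data.frame (`transcript_id`, `start`, `end`),
#'   already size-selected/subsampled.
#' @param annotation A [transcriptome()] containing every origin transcript.
#' @param config A [sequencer_config()].
#' @param seed Integer seed.
#' @return A data.frame of class `simulated_reads` with columns `read_id`,
#'   `transcript_id`, `gene_id`, `start`, `end`, `strand`, `sequence`.
#' @export
sequence_library <- function(fragments, annotation,
                             config = sequencer_config(), seed = 1L) {
  n <- nrow(fragments)
  tx_idx <- match(fragments$transcript_id,
                  annotation$transcripts$transcript_id)
  if (anyNA(tx_idx))
    stop("fragment transcript not in annotation: ",
         fragments$transcript_id[is.na(tx_idx)][1L])
  set.seed(as.integer(seed))
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  gene_id <- annotation$transcripts$gene_id[tx_idx]
  seqs <- character(n); starts <- integer(n); ends <- integer(n)
  full <- annotation$sequences[tx_idx]
  for (i in seq_len(n)) {
    frag_seq <- substr(full[[i]], fragments$start[i] + 1L, fragments$end[i])
    r <- sequence_fragment(frag_seq, strand[i], config)
    seqs[i] <- r$sequence
    if (strand[i] == "+") {
      starts[i] <- fragments$start[i]
      ends[i] <- fragments$start[i] + r$consumed
    } else {
      starts[i] <- fragments$end[i] - r$consumed
      ends[i] <- fragments$end[i]
    }
  }
  keep <- nchar(seqs) > 0L
  ids <- sprintf("read%06d|%s|%s|%d|%d|%s", seq_len(n),
                 fragments$transcript_id, gene_id, starts, ends, strand)
  out <- data.frame(read_id = ids, transcript_id = fragments$transcript_id,
                    gene_id = gene_id, start = starts, end = ends,
                    strand = strand, sequence = seqs,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("simulated_reads", "data.frame")
  out
}

#' Parse an origin-encoding read header
#'
#' Header grammar: `readNNN|transcript_id|gene_id|start|end|strand` with
#' 0-based half-open transcript coordinates and strand `+`/`-`.
#'
#' @param header One or more header strings.
#' @return data.frame with columns `read_id`, `transcript_id`, `gene_id`,
#'   `start`, `end`, `strand`.
#' @export
parse_read_header <- function(header) {
  parts <- strsplit(sub("\\s.*$", "", header), "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop("malformed read header '", header[nf != 6L][1L],
         "': expected 6 |-separated fields ",
         "(read|transcript|gene|start|end|strand), got ", nf[nf != 6L][1L])
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end))
    stop("malformed read header: non-integer start/end field in '",
         header[is.na(start) | is.na(end)][1L], "'")
  bad <- !(m[, 6L] %in% c("+", "-"))
  if (any(bad))
    stop("malformed read header: strand field must be + or - in '",
         header[bad][1L], "'")
  if (any(end < start))
    stop("malformed read header: end < start in '", header[end < start][1L], "'")
  data.frame(read_id = header, transcript_id = m[, 2L], gene_id = m[, 3L],
             start = start, end = end, strand = m[, 6L],
             stringsAsFactors = FALSE)
}

#' Write reads to FASTA with origin-encoded headers
#' @param reads A `simulated_reads` data.frame.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read origin-tagged reads back from FASTA
#' @param path FASTA written by [write_reads_fasta()].
#' @return A `simulated_reads` data.frame.
#' @export
read_reads_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty reads FASTA: ", path)
  out <- parse_read_header(names(ss))
  out$sequence <- as.character(ss)
  class(out) <- c("simulated_reads", "data.frame")
  out
}

#' Zero-noise flow capacity of a template
#'
#' Number of template bases a noise-free flow run would consume — the upper
#' bound on error-free read length for the same template.
#'
#' @param template Nucleotide string.
#' @param flow_cycles Number of TACG flow cycles.
#' @return Integer base count.
#' @export
flow_capacity <- function(template, flow_cycles = 100L) {
  r <- sequence_fragment(template, "+",
                         sequencer_config(flow_cycles = flow_cycles,
                                          sigma0 = 0, sigma1 = 0,
                                          p_insert_zero = 0))
  nchar(r$sequence)
}
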