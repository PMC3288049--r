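#' Library-preparation configuration
#'
#' Collects every knob of the in-silico library prep: Zipf-law expression,
#' reverse transcription, mechanical fragmentation, size selection and
#' subsampling. Defaults correspond to a typical single 454 run simulated
#' from an annotated transcriptome: 20000 cells, transcription start site
#' jitter of 25 bp, poly-A tail modelling disabled, physical fragmentation
#' with mean fragment length 900 bp, and a 500-800 bp size-selection window.
#' `n_molecules` and `subsample_n` default to desk-scale values; at full
#' scale the corresponding run used 2e8 molecules and 800000 fragments.
#'
#' @param zipf_exponent Power-law exponent k (>= 0) of the rank-abundance
#'   law; relative abundance of the transcript at rank r is proportional to
#'   `r^-k`, optionally damped by `exp(-(r/zipf_tail_cutoff)^2)`.
#' @param zipf_tail_cutoff Optional Gaussian rank cutoff x0 (NULL disables).
#' @param n_cells Cell count; metadata only (counts are drawn in a single
#'   multinomial; no per-cell mechanics are modelled).
#' @param n_molecules Total transcript molecules expressed.
#' @param tss_sd Standard deviation (bases) of half-normal transcription
#'   start site jitter applied during reverse transcription.
#' @param polyA_shape,polyA_scale Poly-A tail model parameters; 0 disables
#'   tail modelling (the default, matching the simulated conditions).
#' @param fragmentation_lambda Mean fragment length (bases) of the
#'   Poisson-process mechanical breakage model.
#' @param cutoff_min,cutoff_max Inclusive size-selection bounds in bases.
#' @param subsample_n Number of fragments retained by random subsampling
#'   (NULL keeps all).
#' @param seed Integer seed used when the config drives a full run.
#' @return A list of class `library_config`.
#' @export
library_config <- function(zipf_exponent = 1.0, zipf_tail_cutoff = NULL,
                           n_cells = 20000L, n_molecules = 1e5,
                           tss_sd = 25, polyA_shape = 0, polyA_scale = 0,
                           fragmentation_lambda = 900,
                           cutoff_min = 500L, cutoff_max = 800L,
                           subsample_n = NULL, seed = 1L) {
  if (zipf_exponent < 0) stop("zipf_exponent must be >= 0")
  if (!is.null(zipf_tail_cutoff) && zipf_tail_cutoff <= 0)
    stop("zipf_tail_cutoff must be positive")
  if (fragmentation_lambda <= 0) stop("fragmentation_lambda must be positive")
  if (cutoff_min > cutoff_max) stop("cutoff_min > cutoff_max")
  if (any(c(n_cells, n_molecules, cutoff_min, cutoff_max, tss_sd) < 0))
    stop("lengths and counts must be non-negative")
  structure(list(
    zipf_exponent = zipf_exponent, zipf_tail_cutoff = zipf_tail_cutoff,
    n_cells = n_cells, n_molecules = n_molecules, tss_sd = tss_sd,
    polyA_shape = polyA_shape, polyA_scale = polyA_scale,
    fragmentation_lambda = fragmentation_lambda,
    cutoff_min = cutoff_min, cutoff_max = cutoff_max,
    subsample_n = subsample_n, seed = as.integer(seed)
  ), class = "library_config")
}

#' Simulate gene expression under a modified Zipf law
#'
#' Transcripts are assigned a random abundance rank; the relative abundance
#' at rank r is `r^-k`, optionally damped by a Gaussian tail cutoff
#' `exp(-(r/x0)^2)`. Integer molecule counts are drawn in a single
#' multinomial with `n_molecules` trials.
#'
#' @param annotation A [transcriptome()].
#' @param config A [library_config()].
#' @param seed Optional seed (defaults to `config$seed`).
#' @return A data.frame of class `expression_profile` with columns
#'   `transcript_id`, `rank`, `count`, and attribute `n_molecules`.
#' @export
simulate_expression <- function(annotation, config = library_config(),
                                seed = config$seed) {
  if (config$zipf_exponent < 0) stop("zipf_exponent must be >= 0")
  tids <- annotation$transcripts$transcript_id
  n <- length(tids)
  if (n == 0L) stop("annotation is empty")
  set.seed(as.integer(seed))
  ranks <- sample.int(n)
  p <- ranks^(-config$zipf_exponent)
  if (!is.null(config$zipf_tail_cutoff))
    p <- p * exp(-(ranks / config$zipf_tail_cutoff)^2)
  counts <- as.vector(stats::rmultinom(1L, size = config$n_molecules,
                                       prob = p / sum(p)))
  out <- data.frame(transcript_id = tids, rank = ranks, count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "n_molecules") <- config$n_molecules
  class(out) <- c("expression_profile", "data.frame")
  out
}

#' Reverse-transcribe molecules with 5' start-site jitter
#'
#' Models the 5'-to-3' representation bias of reverse transcription: each
#' cDNA molecule starts at `clamp(round(|Normal(0, tss_sd)|), 0, L - 1)` and
#' runs to the transcript 3' end (poly-A tail modelling disabled). With
#' `random_primers = TRUE` an additional uniform 3'-anchored truncation of
#' the start is applied (off by default).
#'
#' @param lengths Integer vector of transcript lengths, one per molecule.
#' @param tss_sd Start-site jitter standard deviation in bases.
#' @param random_primers Optional internal-priming truncation mode.
#' @return A data.frame with columns `start`, `end` (0-based half-open,
#'   transcript-relative), one row per molecule.
#' @export
reverse_transcribe <- function(lengths, tss_sd = 25, random_primers = FALSE) {
  n <- length(lengths)
  jitter <- round(abs(stats::rnorm(n, 0, tss_sd)))
  start <- pmin(pmax(jitter, 0), lengths - 1L)
  if (random_primers)
    start <- start + floor(stats::runif(n) * (lengths - start - 1L))
  data.frame(start = as.integer(start), end = as.integer(lengths))
}

#' Fragment cDNA molecules by a Poisson breakage process
#'
#' A mechanical (physical) breakage model: each molecule receives
#' `Poisson(length / lambda)` internal breakpoints placed uniformly at
#' random; the resulting fragments partition the molecule exactly.
#'
#' @param molecules data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open transcript coordinates).
#' @param lambda Mean fragment length in bases (> 0).
#' @return data.frame of fragments with columns `transcript_id`, `start`,
#'   `end`; within each molecule, fragments are contiguous and cover it.
#' @export
fragment_molecules <- function(molecules, lambda = 900) {
  if (lambda <= 0) stop("lambda must be positive")
  n <- nrow(molecules)
  if (n == 0L)
    return(data.frame(transcript_id = character(0L), start = integer(0L),
                      end = integer(0L), stringsAsFactors = FALSE))
  len <- molecules$end - molecules$start
  if (any(len <= 0L)) stop("empty molecule interval")
  nb <- stats::rpois(n, len / lambda)
  nb[len < 2L] <- 0L  # no internal cut point exists
  idx <- rep.int(seq_len(n), nb)
  # breakpoints: cut between bases, positions in [start+1, end-1]
  pos <- molecules$start[idx] + 1L +
    floor(stats::runif(length(idx)) * (len[idx] - 1L))
  o <- order(idx, pos)
  idx <- idx[o]; pos <- pos[o]
  dup <- c(FALSE, idx[-1L] == idx[-length(idx)] & pos[-1L] == pos[-length(pos)])
  idx <- idx[!dup]; pos <- as.integer(pos[!dup])

  ms <- c(seq_len(n), idx)
  starts <- c(molecules$start, pos)
  o1 <- order(ms, starts)
  me <- c(idx, seq_len(n))
  ends <- c(pos, molecules$end)
  o2 <- order(me, ends)
  data.frame(
    transcript_id = molecules$transcript_id[ms[o1]],
    start = as.integer(starts[o1]),
    end = as.integer(ends[o2]),
    stringsAsFactors = FALSE
  )
}

#' Size-select fragments
#'
#' Keeps exactly the fragments whose length lies in the inclusive window
#' `[cutoff_min, cutoff_max]`; input order is preserved.
#'
#' @param fragments Fragment data.frame (`transcript_id`, `start`, `end`).
#' @param cutoff_min,cutoff_max Inclusive bounds in bases.
#' @return The surviving fragments.
#' @export
size_select <- function(fragments, cutoff_min = 500L, cutoff_max = 800L) {
  len <- fragments$end - fragments$start
  fragments[len >= cutoff_min & len <= cutoff_max, , drop = FALSE]
}

#' Uniformly subsample fragments without replacement
#'
#' @param fragments Fragment data.frame.
#' @param n Number of fragments to keep (`n <= nrow(fragments)`).
#' @param seed Integer seed; the selection is deterministic per seed.
#' @return `n` fragments, in original relative order.
#' @export
subsample_fragments <- function(fragments, n, seed = 1L) {
  avail <- nrow(fragments)
  if (n > avail)
    stop("cannot subsample ", n, " fragments from ", avail,
         " available; lower subsample_n or raise n_molecules")
  set.seed(as.integer(seed))
  keep <- sort(sample.int(avail, n))
  fragments[keep, , drop = FALSE]
}

#' Run the full library-preparation chain
#'
#' Expression, reverse transcription, fragmentation, size selection and
#' (optionally) subsampling, in order, with per-stage seeds derived from
#' `config$seed`. Stage counts are reported via `message()`.
#'
#' @param annotation A [transcriptome()].
#' @param config A [library_config()].
#' @param verbose Emit per-stage counts (default TRUE).
#' @return A list with `profile` (expression profile), `fragments`
#'   (size-selected, subsampled fragment data.frame) and `counts` (named
#'   vector of per-stage totals).
#' @export
simulate_library <- function(annotation, config = library_config(),
                             verbose = TRUE) {
  seed <- config$seed
  profile <- simulate_expression(annotation, config, seed = seed)
  expressed <- profile[profile$count > 0L, , drop = FALSE]
  mol_tx <- rep.int(expressed$transcript_id, expressed$count)
  mol_len <- rep.int(
    annotation$transcripts$length[match(expressed$transcript_id,
                                        annotation$transcripts$transcript_id)],
    expressed$count)
  set.seed(seed + 1L)
  rt <- reverse_transcribe(mol_len, config$tss_sd)
  molecules <- data.frame(transcript_id = mol_tx, start = rt$start,
                          end = rt$end, stringsAsFactors = FALSE)
  set.seed(seed + 2L)
  fragments <- fragment_molecules(molecules, config$fragmentation_lambda)
  n_frag <- nrow(fragments)
  selected <- size_select(fragments, config$cutoff_min, config$cutoff_max)
  n_sel <- nrow(selected)
  if (!is.null(config$subsample_n))
    selected <- subsample_fragments(selected, config$subsample_n,
                                    seed = seed + 3L)
  counts <- c(molecules = nrow(molecules), fragments = n_frag,
              size_selected = n_sel, subsampled = nrow(selected))
  if (verbose)
    message(sprintf(
      "library: %d molecules -> %d fragments -> %d size-selected -> %d retained",
      counts[1L], counts[2L], counts[3L], counts[4L]))
  list(profile = profile, fragments = selected, counts = counts)
}

#' Write a fragment table to TSV
#' @param fragments Fragment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments[, c("transcript_id", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
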