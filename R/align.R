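#' Containment evaluation parameters
#'
#' Thresholds for deciding that one sequence is contained in a set: a local
#' alignment must pass the e-value cutoff and cover at least
#' `coverage_min` of the length of the sequence selected by
#' `coverage_denominator`. The default denominator is the contained
#' (query) sequence; `"reference_sequence"` instead demands coverage of the
#' containing-set (subject) sequence.
#'
#' @param evalue_max E-value cutoff (default 1e-9).
#' @param coverage_min Minimum aligned fraction (default 0.8).
#' @param coverage_denominator `"contained_sequence"` (default) or
#'   `"reference_sequence"`.
#' @param k Seed k-mer size of the builtin aligner (default 11).
#' @param match,mismatch,gap_open,gap_extend Builtin scoring (defaults
#'   +1/-2/-5/-2).
#' @param ka_K Karlin-Altschul K constant for the builtin e-value
#'   `E = K * m * n * exp(-lambda * S)`; lambda is solved from the scoring
#'   scheme. Both are backend-specific conventions: cross-backend agreement
#'   is on containment verdicts, not e-values.
#' @param max_gap Maximum gap (bases, on either sequence) bridged when
#'   chaining alignment segments across nearby diagonals.
#' @return A list of class `containment_params`.
#' @export
containment_params <- function(evalue_max = 1e-9, coverage_min = 0.8,
                               coverage_denominator = c("contained_sequence",
                                                        "reference_sequence"),
                               k = 11L, match = 1, mismatch = -2,
                               gap_open = 5, gap_extend = 2,
                               ka_K = 0.621, max_gap = 30L) {
  coverage_denominator <- match.arg(coverage_denominator)
  if (coverage_min <= 0 || coverage_min > 1)
    stop("coverage_min must be in (0, 1]")
  if (evalue_max <= 0) stop("evalue_max must be positive")
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 coverage_denominator = coverage_denominator,
                 k = as.integer(k), match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend, ka_K = ka_K,
                 lambda = ka_lambda(match, mismatch),
                 max_gap = as.integer(max_gap)),
            class = "containment_params")
}

# Ungapped Karlin-Altschul lambda for uniform base composition:
# solves sum_ij p_i p_j exp(lambda * s_ij) = 1 with p = 1/4.
ka_lambda <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-10)$root
}

seqs_of <- function(x) {
  if (inherits(x, "transcriptome")) x$sequences
  else if (inherits(x, "assembly")) x$contigs
  else if (is.character(x) && !is.null(names(x))) x
  else stop("expected a transcriptome, an assembly, or a named character vector")
}

empty_hits <- function() {
  data.frame(query_id = character(0L), subject_id = character(0L),
             strand = character(0L), q_start = integer(0L),
             q_end = integer(0L), s_start = integer(0L), s_end = integer(0L),
             matches = integer(0L), score = numeric(0L),
             evalue = numeric(0L), stringsAsFactors = FALSE)
}

# Best-scoring contiguous segment of a +match/-mismatch score vector
# (Kadane). Returns c(start, end, score, matches) in 1-based inclusive
# local coordinates, or NULL when all-negative.
best_segment <- function(is_match, match, mismatch) {
  sc <- ifelse(is_match, match, mismatch)
  best <- 0; cur <- 0
  bs <- be <- 0L; cs <- 1L
  for (i in seq_along(sc)) {
    cur <- cur + sc[i]
    if (cur <= 0) { cur <- 0; cs <- i + 1L }
    else if (cur > best) { best <- cur; bs <- cs; be <- i }
  }
  if (be == 0L) return(NULL)
  c(bs, be, best, sum(is_match[bs:be]))
}

# Global k-mer index over a set of subjects: environment mapping kmer ->
# row ids into parallel (subject_idx, position) vectors.
build_kmer_index <- function(subjects, k) {
  sidx <- list(); spos <- list(); kms <- list()
  for (i in seq_along(subjects)) {
    ns <- nchar(subjects[[i]])
    if (ns < k) next
    p <- 1:(ns - k + 1L)
    kms[[length(kms) + 1L]] <- substring(subjects[[i]], p, p + k - 1L)
    spos[[length(spos) + 1L]] <- p
    sidx[[length(sidx) + 1L]] <- rep.int(i, length(p))
  }
  kms <- unlist(kms); spos <- unlist(spos); sidx <- unlist(sidx)
  e <- new.env(hash = TRUE, parent = emptyenv())
  if (length(kms) > 0L)
    list2env(split(seq_along(kms), kms), envir = e)
  list(env = e, sidx = sidx, spos = spos)
}

# Seed one oriented query against the whole index, extend per (subject,
# diagonal), and chain. Returns hit rows (subject_idx, q_start, q_end,
# s_start, s_end, score, matches), 1-based inclusive.
align_query_segments <- function(qseq, qb, index, sub_bytes,
                                 k, match, mismatch,
                                 gap_open, gap_extend, max_gap) {
  nq <- length(qb)
  if (nq < k) return(NULL)
  p <- 1:(nq - k + 1L)
  qkm <- substring(qseq, p, p + k - 1L)
  qh <- list(); sh <- list()
  for (qi in p) {
    rows <- get0(qkm[qi], envir = index$env, ifnotfound = NULL)
    if (is.null(rows)) next
    qh[[length(qh) + 1L]] <- rep.int(qi, length(rows))
    sh[[length(sh) + 1L]] <- rows
  }
  if (length(qh) == 0L) return(NULL)
  qpos <- unlist(qh); rows <- unlist(sh)
  subj <- index$sidx[rows]; spos <- index$spos[rows]
  diag <- spos - qpos
  key <- paste(subj, diag)
  first <- !duplicated(key)
  subj <- subj[first]; diag <- diag[first]
  segs <- list()
  for (j in seq_along(subj)) {
    sb <- sub_bytes[[subj[j]]]
    d <- diag[j]; ns <- length(sb)
    qlo <- max(1L, 1L - d); qhi <- min(nq, ns - d)
    im <- qb[qlo:qhi] == sb[(qlo + d):(qhi + d)]
    seg <- best_segment(im, match, mismatch)
    if (is.null(seg) || seg[3L] < k * match) next
    qs <- qlo + seg[1L] - 1L
    qe <- qlo + seg[2L] - 1L
    segs[[length(segs) + 1L]] <-
      c(subj[j], qs, qe, qs + d, qe + d, seg[3L], seg[4L])
  }
  if (length(segs) == 0L) return(NULL)
  segs <- do.call(rbind, segs)
  out <- list()
  for (s_id in unique(segs[, 1L])) {
    ch <- chain_segments(segs[segs[, 1L] == s_id, -1L, drop = FALSE],
                         match, gap_open, gap_extend, max_gap)
    out[[length(out) + 1L]] <- cbind(s_id, ch)
  }
  do.call(rbind, out)
}

# Chain colinear segments across nearby diagonals (banded gapped
# extension); small overlaps between adjacent segments are trimmed.
# Returns hit rows (q_start q_end s_start s_end score matches), 1-based
# inclusive.
chain_segments <- function(segs, match, gap_open, gap_extend, max_gap,
                           overlap_slack = 10L) {
  segs <- segs[order(segs[, 1L], segs[, 2L]), , drop = FALSE]
  chains <- list()
  cur <- segs[1L, ]
  for (i in seq_len(nrow(segs))[-1L]) {
    s <- segs[i, ]
    gq <- s[1L] - cur[2L] - 1L
    gs <- s[3L] - cur[4L] - 1L
    if (gq >= -overlap_slack && gs >= -overlap_slack &&
        gq <= max_gap && gs <= max_gap && s[2L] > cur[2L] &&
        s[4L] > cur[4L]) {
      trim <- max(0L, -gq, -gs)
      g <- max(gq, gs) + trim
      pen <- if (g > 0) gap_open + gap_extend * (g - 1L) else 0
      seg_score <- s[5L] - trim * match
      if (seg_score > pen) {
        cur <- c(cur[1L], s[2L], cur[3L], s[4L],
                 cur[5L] + seg_score - pen, cur[6L] + s[6L] - trim)
        next
      }
    }
    chains[[length(chains) + 1L]] <- cur
    cur <- s
  }
  chains[[length(chains) + 1L]] <- cur
  do.call(rbind, chains)
}

#' Local alignment of every query against every subject
#'
#' The builtin backend is a seed-and-extend local aligner: exact k-mer
#' seeding, per-diagonal maximal-scoring ungapped extension
#' (+1 match / -2 mismatch by default), and banded chaining of colinear
#' segments across nearby diagonals with affine gap costs. E-values follow
#' the ungapped Karlin-Altschul formula `E = K * m * n * exp(-lambda * S)`
#' with `m` the query length, `n` the total subject length, and lambda
#' solved from the scoring scheme; constants are documented in
#' [containment_params()] and overridable. Both query strands are searched.
#'
#' The external backend parses standard 12-column tabular alignment output
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore, 1-based inclusive coordinates, converted here).
#'
#' @param queries,subjects Named character vectors of sequences (or
#'   [transcriptome()] / [assembly()] objects).
#' @param params A [containment_params()].
#' @param backend `"builtin"` (default) or a path/data.frame of 12-column
#'   tabular alignment output.
#' @return data.frame of hits: `query_id`, `subject_id`, `strand`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open; minus-strand
#'   query coordinates are on the reverse-complemented query), `matches`,
#'   `score`, `evalue`.
#' @export
align_all <- function(queries, subjects, params = containment_params(),
                      backend = "builtin") {
  if (!(is.character(backend) && length(backend) == 1L &&
        backend == "builtin"))
    return(parse_tabular_hits(backend))
  queries <- seqs_of(queries)
  subjects <- seqs_of(subjects)
  if (length(queries) == 0L || length(subjects) == 0L)
    stop("empty sequence set")
  k <- params$k
  short <- nchar(queries) < k
  if (any(short)) {
    warning(sum(short), " query/ies shorter than k = ", k, " skipped")
    queries <- queries[!short]
    if (length(queries) == 0L) return(empty_hits())
  }
  n_total <- sum(nchar(subjects))
  sub_bytes <- lapply(subjects, function(s) as.integer(charToRaw(s)))
  index <- build_kmer_index(subjects, k)
  rc <- revcomp(queries)
  out <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    for (strand in c("+", "-")) {
      qseq <- if (strand == "-") rc[[qi]] else queries[[qi]]
      qb <- as.integer(charToRaw(qseq))
      hits <- align_query_segments(qseq, qb, index, sub_bytes, k,
                                   params$match, params$mismatch,
                                   params$gap_open, params$gap_extend,
                                   params$max_gap)
      if (is.null(hits)) next
      ev <- params$ka_K * nchar(qseq) * n_total *
        exp(-params$lambda * hits[, 6L])
      out[[length(out) + 1L]] <- data.frame(
        query_id = qid, subject_id = names(subjects)[hits[, 1L]],
        strand = strand,
        q_start = as.integer(hits[, 2L] - 1L),
        q_end = as.integer(hits[, 3L]),
        s_start = as.integer(hits[, 4L] - 1L),
        s_end = as.integer(hits[, 5L]),
        matches = as.integer(hits[, 7L]), score = hits[, 6L],
        evalue = ev, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parse 12-column tabular alignment output
#'
#' Standard tabular format (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`); 1-based inclusive coordinates
#' are converted to 0-based half-open, and subject-descending coordinates
#' are normalized to `strand = "-"`.
#'
#' @param x Path to a tabular file, or an already-read 12-column data.frame.
#' @return Hits data.frame in the [align_all()] layout (`score` carries the
#'   bit score).
#' @export
parse_tabular_hits <- function(x) {
  df <- if (is.data.frame(x)) x
  else {
    if (!file.exists(x)) stop("cannot read tabular alignment file: ", x)
    if (file.size(x) == 0L) return(empty_hits())
    tryCatch(
      utils::read.table(x, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE),
      error = function(e) stop("unreadable tabular alignment file ", x,
                               ": ", conditionMessage(e)))
  }
  if (ncol(df) < 12L)
    stop("tabular alignment output must have 12 columns, got ", ncol(df))
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  minus <- df$sstart > df$send
  s1 <- ifelse(minus, df$send, df$sstart)
  s2 <- ifelse(minus, df$sstart, df$send)
  data.frame(
    query_id = as.character(df$qseqid), subject_id = as.character(df$sseqid),
    strand = ifelse(minus, "-", "+"),
    q_start = as.integer(df$qstart - 1L), q_end = as.integer(df$qend),
    s_start = as.integer(s1 - 1L), s_end = as.integer(s2),
    matches = as.integer(df$length - df$mismatch),
    score = df$bitscore, evalue = df$evalue, stringsAsFactors = FALSE)
}

#' Run NCBI blastn as an external alignment backend
#'
#' Convenience wrapper: writes the sequence sets to a temporary directory,
#' builds a nucleotide database, runs `blastn -task blastn -outfmt 6`, and
#' parses the tabular output. Requires `blastn`/`makeblastdb` on the PATH.
#'
#' @param queries,subjects Named character vectors (or package containers).
#' @param evalue_max Loose e-value cutoff passed to blastn (filter strictly
#'   downstream with [is_contained()]).
#' @param word_size Seed word size (default 11).
#' @return Hits data.frame in the [align_all()] layout.
#' @export
blastn_hits <- function(queries, subjects, evalue_max = 10, word_size = 11L) {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "")
    stop("blastn/makeblastdb not found on PATH")
  queries <- seqs_of(queries); subjects <- seqs_of(subjects)
  td <- tempfile("blastwork"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "q.fa"); sf <- file.path(td, "s.fa")
  of <- file.path(td, "hits.tsv")
  writeLines(paste0(">", names(queries), "\n", queries), qf)
  writeLines(paste0(">", names(subjects), "\n", subjects), sf)
  system2("makeblastdb", c("-in", sf, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  status <- system2("blastn",
                    c("-task", "blastn", "-query", qf, "-db", sf,
                      "-outfmt", "6", "-evalue", format(evalue_max),
                      "-word_size", word_size, "-dust", "no",
                      "-out", of),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("blastn exited with status ", status)
  parse_tabular_hits(of)
}

#' Containment decision for one sequence
#'
#' A sequence is contained in a set iff some single hit passes the e-value
#' cutoff and its aligned span covers at least `coverage_min` of the length
#' chosen by `coverage_denominator` (no multi-hit stitching).
#'
#' @param x_id Query sequence id.
#' @param hits Hits from [align_all()] with `x_id` among the queries.
#' @param x_len Query length (bases).
#' @param subject_lens Named vector of subject lengths (needed for the
#'   `"reference_sequence"` denominator).
#' @param params A [containment_params()].
#' @return Logical scalar.
#' @export
is_contained <- function(x_id, hits, x_len, subject_lens = NULL,
                         params = containment_params()) {
  h <- hits[hits$query_id == x_id & hits$evalue < params$evalue_max, ,
            drop = FALSE]
  if (nrow(h) == 0L) return(FALSE)
  if (params$coverage_denominator == "contained_sequence") {
    span <- h$q_end - h$q_start
    any(span >= params$coverage_min * x_len)
  } else {
    if (is.null(subject_lens))
      stop("subject_lens required for reference_sequence denominator")
    span <- h$s_end - h$s_start
    any(span >= params$coverage_min * subject_lens[h$subject_id])
  }
}

containment_fraction <- function(queries, subjects, params, backend) {
  hits <- align_all(queries, subjects, params, backend)
  qlen <- nchar(queries)
  slen <- nchar(subjects)
  ok <- vapply(names(queries), function(id)
    is_contained(id, hits, qlen[[id]], slen, params), logical(1L))
  list(contained = sum(ok), total = length(queries),
       fraction = sum(ok) / length(queries), per_query = ok, hits = hits)
}

#' Assembly specificity against a reference set
#'
#' The fraction of (post-filter) assembly contigs contained in the
#' reference set — the transcriptome annotation or the Model Assembly —
#' under the e-value and coverage thresholds in `params`.
#'
#' @param assembly An [assembly()] (or named sequence vector).
#' @param reference A [transcriptome()], [assembly()], or named vector.
#' @param params A [containment_params()].
#' @param backend Alignment backend, as in [align_all()].
#' @return List of class `containment_result`: `contained`, `total`,
#'   `fraction`, `percent`, plus per-query verdicts and the raw hits.
#' @export
specificity <- function(assembly, reference, params = containment_params(),
                        backend = "builtin") {
  q <- seqs_of(assembly)
  if (length(q) == 0L) stop("empty assembly")
  res <- containment_fraction(q, seqs_of(reference), params, backend)
  res$percent <- 100 * res$fraction
  res$measure <- "specificity"
  class(res) <- "containment_result"
  res
}

#' Reference sensitivity of an assembly
#'
#' The fraction of reference sequences (transcripts or Model Assembly
#' contigs) contained in the assembly; query/subject roles are swapped
#' relative to [specificity()].
#'
#' @inheritParams specificity
#' @return List of class `containment_result`, as for [specificity()].
#' @export
sensitivity <- function(reference, assembly, params = containment_params(),
                        backend = "builtin") {
  q <- seqs_of(reference)
  if (length(q) == 0L) stop("empty reference")
  res <- containment_fraction(q, seqs_of(assembly), params, backend)
  res$percent <- 100 * res$fraction
  res$measure <- "sensitivity"
  class(res) <- "containment_result"
  res
}

#' @export
print.containment_result <- function(x, ...) {
  cat(sprintf("%s: %d / %d contained (%.1f%%)\n",
              x$measure, x$contained, x$total, x$percent))
  invisible(x)
}
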