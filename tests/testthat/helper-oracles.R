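# Independent oracles and fixture builders shared across the suite.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Tiny annotation with arbitrary sequences; gene ids via "gene|transcript"
# naming convention kept out of the way.
tiny_tx <- function(seqs, genes = names(seqs)) transcriptome(seqs, genes)

# Brute-force N50: walk the descending lengths and return the one that
# closes half the total.
bf_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

# Brute-force model assembly: connected components of the pairwise
# >= 1 bp overlap graph, per transcript.
bf_model_assembly <- function(reads) {
  out <- list()
  for (t in sort(unique(reads$transcript_id))) {
    r <- reads[reads$transcript_id == t, , drop = FALSE]
    n <- nrow(r)
    adj <- outer(seq_len(n), seq_len(n),
                 function(i, j) r$start[i] < r$end[j] & r$start[j] < r$end[i])
    comp <- rep(NA_integer_, n)
    cc <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      cc <- cc + 1L
      queue <- i
      comp[i] <- cc
      while (length(queue) > 0L) {
        v <- queue[1L]; queue <- queue[-1L]
        nb <- which(adj[v, ] & is.na(comp))
        comp[nb] <- cc
        queue <- c(queue, nb)
      }
    }
    for (k in seq_len(cc))
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = t,
        start = min(r$start[comp == k]),
        end = max(r$end[comp == k]),
        n_reads = sum(comp == k),
        stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Brute-force zero-noise flow counter: walk the flows one at a time,
# consuming the template base by base (independent of the run-based
# implementation in the package).
bf_flow_consume <- function(template, flow_cycles = 100L) {
  bases <- strsplit(template, "", fixed = TRUE)[[1L]]
  i <- 1L
  for (f in rep(c("T", "A", "C", "G"), flow_cycles)) {
    while (i <= length(bases) && bases[i] == f) i <- i + 1L
  }
  i - 1L
}

zero_noise <- function(flow_cycles = 100L)
  sequencer_config(flow_cycles = flow_cycles, sigma0 = 0, sigma1 = 0,
                   p_insert_zero = 0)

# Random origin-tagged read table on a toy annotation (positions only; no
# sequences needed for positional tests).
random_read_table <- function(tx, n_reads, read_len = c(20L, 60L)) {
  tids <- tx$transcripts$transcript_id
  tid <- sample(tids, n_reads, replace = TRUE)
  len <- tx$transcripts$length[match(tid, tids)]
  rl <- pmin(sample(read_len[1L]:read_len[2L], n_reads, replace = TRUE), len)
  start <- floor(runif(n_reads) * (len - rl + 1L))
  data.frame(read_id = sprintf("r%04d", seq_len(n_reads)),
             transcript_id = tid, start = as.integer(start),
             end = as.integer(start + rl), stringsAsFactors = FALSE)
}

# Error count between a read and its error-free template span.
edit_errors <- function(read, template_span) {
  as.integer(utils::adist(read, template_span))
}
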