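#' Basic assembly statistics
#'
#' Computes the standard contig-length summary used to compare assemblies:
#' contig count, total bases, large-contig (>= 1 kbp, inclusive) count and
#' bases, maximum/mean/median contig length, and N50 — the contig length at
#' which the descending-sorted cumulative length first reaches half the
#' assembly's total bases ("half the assembly is represented by contigs of
#' this size or longer").
#'
#' @param x An [assembly()], or a numeric vector of contig lengths.
#' @return A list of class `assembly_metrics` with elements `n_contigs`,
#'   `total_bases`, `n_contigs_ge_1kbp`, `bases_in_contigs_ge_1kbp`,
#'   `max_len`, `mean_len`, `median_len`, `n50`.
#' @examples
#' compute_metrics(c(4, 3, 3, 2, 2, 2))$n50  # 3
#' @export
compute_metrics <- function(x) {
  lens <- if (inherits(x, "assembly")) unname(nchar(x$contigs))
          else unname(as.numeric(x))
  if (length(lens) == 0L) stop("empty assembly: no contigs to summarize")
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1L]]
  big <- lens >= 1000
  structure(list(
    n_contigs = length(lens),
    total_bases = total,
    n_contigs_ge_1kbp = sum(big),
    bases_in_contigs_ge_1kbp = sum(lens[big]),
    max_len = max(lens),
    mean_len = mean(lens),
    median_len = stats::median(lens),
    n50 = n50
  ), class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  rows <- c(
    "Number of contigs" = format(x$n_contigs),
    "Total bases" = format(x$total_bases),
    "Number of contigs (>= 1 kbp)" = format(x$n_contigs_ge_1kbp),
    "Total bases (in contigs >= 1 kbp)" = format(x$bases_in_contigs_ge_1kbp),
    "Maximal contig length" = format(x$max_len),
    "Average contig length" = format(round(x$mean_len, 1)),
    "Median contig length" = format(x$median_len),
    "N50" = format(x$n50)
  )
  cat(paste0(format(names(rows), width = 34), rows, collapse = "\n"), "\n")
  invisible(x)
}

#' Counts of contigs longer than length thresholds
#'
#' Cumulative contig counts at a set of length thresholds under a strict
#' "longer than" comparison (a 200 bp contig does not count at the 200
#' threshold).
#'
#' @param x An [assembly()] or numeric vector of contig lengths.
#' @param thresholds Length thresholds in bases (sorted internally).
#' @return Named integer vector, names = sorted thresholds; counts are
#'   non-increasing in the threshold.
#' @export
cumulative_length_counts <- function(x, thresholds = c(200, 400, 800, 1000)) {
  lens <- if (inherits(x, "assembly")) nchar(x$contigs) else as.numeric(x)
  thresholds <- sort(thresholds)
  setNames(vapply(thresholds, function(t) sum(lens > t), integer(1L)),
           thresholds)
}

#' Write an assembly metrics report to TSV
#' @param metrics An `assembly_metrics` object (or list of them, one column
#'   per assembly).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (inherits(metrics, "assembly_metrics")) metrics <- list(value = metrics)
  keys <- c("n_contigs", "total_bases", "n_contigs_ge_1kbp",
            "bases_in_contigs_ge_1kbp", "max_len", "mean_len", "median_len",
            "n50")
  df <- data.frame(metric = keys, stringsAsFactors = FALSE)
  for (nm in names(metrics))
    df[[nm]] <- unlist(metrics[[nm]][keys], use.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
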