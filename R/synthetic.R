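#' Generate a synthetic multi-isoform transcriptome
#'
#' Builds a small annotated transcriptome for simulation and testing: each
#' gene is a chain of exons with random sequence; alternatively spliced (AS)
#' genes carry extra isoforms produced by skipping internal exons, so that
#' isoforms of one gene share full exon sequences — the regime in which
#' sequence-only assemblers are prone to chimeric merges. Generation is
#' deterministic for a fixed seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param as_fraction Fraction of genes with >= 2 isoforms; the realized AS
#'   gene count is `round(n_genes * as_fraction)`.
#' @param max_isoforms Maximum isoforms per AS gene (>= 2).
#' @param exon_length Length-2 integer vector `c(min, max)` of exon lengths
#'   in bases.
#' @param n_exons Length-2 integer vector `c(min, max)` of exons per gene.
#'   AS genes need at least 3 exons so an internal exon can be skipped; the
#'   minimum is raised to 3 for them.
#' @param gc_content GC fraction in `[0, 1]` used to draw bases.
#' @param seed Integer seed.
#' @return A [transcriptome()]. Transcript ids are `"<gene>.<k>"`, e.g.
#'   `"g007.2"` for the second isoform of gene `g007`.
#' @examples
#' tx <- generate_synthetic_transcriptome(10, as_fraction = 0.5, seed = 7)
#' sum(is_alternatively_spliced(tx))
#' @export
generate_synthetic_transcriptome <- function(n_genes,
                                             as_fraction = 0.3,
                                             max_isoforms = 3L,
                                             exon_length = c(100L, 400L),
                                             n_exons = c(2L, 8L),
                                             gc_content = 0.5,
                                             seed = 1L) {
  stopifnot(n_genes >= 1L, max_isoforms >= 2L)
  if (as_fraction < 0 || as_fraction > 1) stop("as_fraction must be in [0, 1]")
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0, 1]")
  if (exon_length[1L] > exon_length[2L]) stop("exon_length: min > max")
  if (n_exons[1L] > n_exons[2L]) stop("n_exons: min > max")
  if (n_exons[1L] < 1L) stop("n_exons must be >= 1")
  set.seed(as.integer(seed))

  n_as <- round(n_genes * as_fraction)
  as_genes <- if (n_as > 0L) sample.int(n_genes, n_as) else integer(0L)
  base_probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
                  G = gc_content / 2, T = (1 - gc_content) / 2)

  rand_exon <- function(len) {
    paste(sample(names(base_probs), len, replace = TRUE, prob = base_probs),
          collapse = "")
  }

  seqs <- character(0L)
  gids <- character(0L)
  gw <- max(3L, nchar(as.character(n_genes)))
  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("g%0*d", gw, g)
    is_as <- g %in% as_genes
    ne_min <- if (is_as) max(3L, n_exons[1L]) else n_exons[1L]
    ne_max <- max(ne_min, n_exons[2L])
    ne <- sample(ne_min:ne_max, 1L)
    lens <- sample(exon_length[1L]:exon_length[2L], ne, replace = TRUE)
    exons <- vapply(lens, rand_exon, character(1L))
    isoforms <- list(paste(exons, collapse = ""))
    if (is_as) {
      k <- sample(2:max_isoforms, 1L)
      for (i in seq_len(k - 1L)) {
        skip <- sample(2:(ne - 1L), 1L)  # skip one internal exon
        isoforms[[i + 1L]] <- paste(exons[-skip], collapse = "")
      }
      isoforms <- unique(isoforms)
    }
    ids <- sprintf("%s.%d", gene_id, seq_along(isoforms))
    seqs <- c(seqs, setNames(unlist(isoforms), ids))
    gids <- c(gids, rep(gene_id, length(isoforms)))
  }
  transcriptome(seqs, gids)
}
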