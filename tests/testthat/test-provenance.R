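# Two-gene fixture: g1 is AS (t1, t1b share exon A), g2 single-isoform.
shared_exon_fixture <- function(seed = 1) {
  set.seed(seed)
  exA <- rand_seq(400)   # shared exon
  exB <- rand_seq(300)
  exC <- rand_seq(250)
  exD <- rand_seq(500)
  tiny_tx(c(t1 = paste0(exB, exA), t1b = paste0(exC, exA),
            t2 = exD),
          c("g1", "g1", "g2"))
}

test_that("unique-origin assemblies map every read exactly once", {
  set.seed(2)
  tx <- generate_synthetic_transcriptome(6, as_fraction = 0, seed = 2)
  frags <- random_read_table(tx, 120L, read_len = c(150L, 250L))
  frags$read_id <- NULL
  reads <- sequence_library(frags, tx, zero_noise(), seed = 3)
  ma <- build_model_assembly(reads, tx)
  rep <- map_reads_to_contigs(reads, ma)
  expect_equal(rep$reads_mapped, nrow(reads))
  expect_equal(rep$reads_multi, 0L)
  expect_equal(rep$contigs_hit, length(ma$contigs))

  # duplicating every contig forces every mapped read to be ambiguous
  dup <- assembly(c(ma$contigs,
                    setNames(ma$contigs, paste0(names(ma$contigs), "_copy"))))
  rep2 <- map_reads_to_contigs(reads, dup)
  expect_equal(rep2$reads_multi, rep2$reads_mapped)

  # best-hit-only counting removes the ambiguity
  rep3 <- map_reads_to_contigs(reads, dup, best_hit_only = TRUE)
  expect_equal(rep3$reads_multi, 0L)
})

test_that("reads from a shared exon map to the contigs of both isoforms", {
  tx <- shared_exon_fixture()
  # reads covering the shared exon on both isoforms; exon A starts at 300
  # in t1 and at 250 in t1b (0-based)
  reads <- data.frame(
    read_id = c("shared1", "shared2", "only1", "only2"),
    transcript_id = c("t1", "t1b", "t1", "t1b"),
    start = c(320L, 270L, 0L, 0L),
    end = c(520L, 470L, 200L, 200L),
    stringsAsFactors = FALSE)
  reads$gene_id <- c("g1", "g1", "g1", "g1")
  reads$strand <- "+"
  reads$sequence <- vapply(seq_len(nrow(reads)), function(i)
    substr(transcript_seq(tx, reads$transcript_id[i]), reads$start[i] + 1L,
           reads$end[i]), character(1L))
  ma <- build_model_assembly(reads, tx)
  expect_equal(length(ma$contigs), 4L)
  rep <- map_reads_to_contigs(reads, ma)
  # oracle: a read is ambiguous iff its sequence occurs in >= 2 contigs
  expected_multi <- vapply(seq_len(nrow(reads)), function(i)
    sum(vapply(ma$contigs, function(ct)
      grepl(reads$sequence[i], ct, fixed = TRUE), logical(1L))) >= 2L,
    logical(1L))
  multi_ids <- names(rep$mapping)[lengths(rep$mapping) >= 2L]
  expect_setequal(multi_ids, reads$read_id[expected_multi])
  expect_setequal(multi_ids, c("shared1", "shared2"))
})

test_that("ACE parsing yields one placement per RD record", {
  f <- withr::local_tempfile(fileext = ".ace")
  writeLines(c(
    "AS 2 3",
    "",
    "CO contig1 100 2 2 U",
    "ACGT",
    "",
    "RD read1.f 50 0 0",
    "ACGT",
    "RD read2 50 0 0",
    "ACGT",
    "CO contig2 80 1 1 U",
    "ACGT",
    "RD read2 50 0 0",
    "ACGT"
  ), f)
  pl <- parse_ace(f)
  expect_equal(nrow(pl), 3L)
  expect_identical(pl$read_id, c("read1", "read2", "read2"))  # suffix stripped
  expect_identical(pl$contig_id, c("contig1", "contig1", "contig2"))

  f2 <- withr::local_tempfile(fileext = ".ace")
  file.create(f2)
  expect_error(parse_ace(f2), "empty")

  f3 <- withr::local_tempfile(fileext = ".ace")
  writeLines(c("AS 1 1", "RD stray 10 0 0", "CO c 5 1 1 U"), f3)
  expect_error(parse_ace(f3), "RD record before any CO.*line 2")
})

test_that("chimera statistics match hand computation on the canonical fixture", {
  tx <- shared_exon_fixture()
  origins <- data.frame(
    read_id = sprintf("r%d", 1:8),
    transcript_id = c("t1", "t1", "t1", "t2", "t1", "t1", "t1", "t1"),
    stringsAsFactors = FALSE)
  placements <- data.frame(
    read_id = origins$read_id,
    contig_id = c(rep("A", 4L), rep("B", 4L)),
    stringsAsFactors = FALSE)
  rep <- chimera_stats(placements, origins, tx)
  expect_equal(rep$n_contigs, 2L)
  expect_equal(rep$non_chimeric_abs, 1L)
  expect_equal(rep$non_chimeric_rel, 0.5)
  per <- rep$per_contig[order(rep$per_contig$contig_id), ]
  expect_equal(per$misplaced_fraction, c(0.25, 0))
  expect_equal(per$is_chimeric, c(TRUE, FALSE))
  # both contigs' majority transcript t1 belongs to the AS gene g1
  expect_identical(per$as_status, c("AS", "AS"))
  expect_equal(rep$mean_misplaced_fraction_AS, 0.125)
  expect_true(is.na(rep$mean_misplaced_fraction_nonAS))

  # same placements under a single-isoform annotation: the split flips
  tx2 <- tiny_tx(c(t1 = rand_seq(300), t2 = rand_seq(300)), c("g1", "g2"))
  rep2 <- chimera_stats(placements, origins, tx2)
  expect_true(is.na(rep2$mean_misplaced_fraction_AS))
  expect_equal(rep2$mean_misplaced_fraction_nonAS, 0.125)

  # gene-level secondary fraction: t1/t1b are one gene, so a t1b read in a
  # t1-majority contig is transcript-misplaced but not gene-misplaced
  origins3 <- data.frame(read_id = c("x1", "x2"),
                         transcript_id = c("t1", "t1b"))
  pl3 <- data.frame(read_id = c("x1", "x2"), contig_id = c("C", "C"))
  rep3 <- chimera_stats(pl3, origins3, tx)
  expect_equal(rep3$per_contig$misplaced_fraction, 0.5)
  expect_equal(rep3$per_contig$misplaced_gene_fraction, 0)
})

test_that("majority ties break lexicographically and are reported", {
  tx <- shared_exon_fixture()
  origins <- data.frame(read_id = c("r1", "r2"),
                        transcript_id = c("t2", "t1"))
  pl <- data.frame(read_id = c("r1", "r2"), contig_id = c("Z", "Z"))
  expect_message(rep <- chimera_stats(pl, origins, tx), "tie")
  expect_identical(rep$per_contig$majority_transcript_id, "t1")
})

test_that("reports are invariant to read and contig order", {
  set.seed(5)
  tx <- shared_exon_fixture()
  origins <- data.frame(
    read_id = sprintf("r%d", 1:20),
    transcript_id = sample(c("t1", "t1b", "t2"), 20, TRUE))
  pl <- data.frame(read_id = origins$read_id,
                   contig_id = sample(c("A", "B", "C"), 20, TRUE))
  r1 <- chimera_stats(pl, origins, tx)
  perm <- sample(nrow(pl))
  r2 <- chimera_stats(pl[perm, ], origins[sample(nrow(origins)), ], tx)
  expect_equal(r1$non_chimeric_rel, r2$non_chimeric_rel)
  expect_equal(r1$mean_misplaced_fraction_AS, r2$mean_misplaced_fraction_AS)
  o1 <- r1$per_contig[order(r1$per_contig$contig_id), ]
  o2 <- r2$per_contig[order(r2$per_contig$contig_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("model-assembly placements are perfectly non-chimeric", {
  set.seed(6)
  tx <- generate_synthetic_transcriptome(8, as_fraction = 0.5, seed = 6)
  reads <- random_read_table(tx, 150L, read_len = c(30L, 80L))
  reads$gene_id <- tx$transcripts$gene_id[
    match(reads$transcript_id, tx$transcripts$transcript_id)]
  ma <- build_model_assembly(reads, tx)
  rep <- chimera_stats(ma$placements, reads, tx)
  expect_equal(rep$non_chimeric_rel, 1)
  expect_true(all(rep$per_contig$misplaced_fraction == 0))
})

test_that("misplacement on shared-exon fixtures is concentrated in AS genes", {
  # contigs constructed so only AS-gene contigs receive foreign reads
  tx <- shared_exon_fixture()
  origins <- data.frame(
    read_id = sprintf("r%d", 1:12),
    transcript_id = c(rep("t1", 4), "t1b", rep("t1b", 3), "t1",
                      rep("t2", 3)))
  pl <- data.frame(read_id = origins$read_id,
                   contig_id = c(rep("as1", 5), rep("as2", 4),
                                 rep("na1", 3)))
  rep <- chimera_stats(pl, origins, tx)
  expect_gt(rep$mean_misplaced_fraction_AS, rep$mean_misplaced_fraction_nonAS)
  expect_equal(rep$mean_misplaced_fraction_nonAS, 0)
})
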