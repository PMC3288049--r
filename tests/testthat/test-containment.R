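test_that("self-alignment yields a full-coverage, significant hit", {
  set.seed(1)
  s <- setNames(rand_seq(500), "x")
  hits <- align_all(s, s)
  self <- hits[which.max(hits$score), ]
  expect_identical(self$strand, "+")
  expect_equal(self$q_start, 0L)
  expect_equal(self$q_end, 500L)
  expect_equal(self$s_start, 0L)
  expect_equal(self$s_end, 500L)
  expect_lt(self$evalue, 1e-9)
  expect_true(is_contained("x", hits, 500L, c(x = 500L)))
})

test_that("unrelated random 500-mers are never contained", {
  set.seed(2)
  for (i in 1:100) {
    q <- setNames(rand_seq(500), "q")
    s <- setNames(rand_seq(500), "s")
    hits <- align_all(q, s)
    p <- containment_params()
    expect_false(is_contained("q", hits, 500L, c(s = 500L), p))
    p_ref <- containment_params(coverage_denominator = "reference_sequence")
    expect_false(is_contained("q", hits, 500L, c(s = 500L), p_ref))
  }
})

test_that("planted exact substrings of length >= 2k are recovered at the exact interval", {
  set.seed(3)
  p <- containment_params()
  for (i in 1:200) {
    n <- sample(200:400, 1L)
    subj <- rand_seq(n)
    plen <- sample((2L * p$k):min(100L, n - 2L), 1L)
    pos <- sample(0:(n - plen), 1L)             # 0-based plant position
    q <- setNames(substr(subj, pos + 1L, pos + plen), "plant")
    hits <- align_all(q, setNames(subj, "s"), p)
    fwd <- hits[hits$strand == "+" & hits$q_start == 0L &
                  hits$q_end == plen, , drop = FALSE]
    expect_gte(nrow(fwd), 1L)
    expect_true(any(fwd$s_start == pos & fwd$s_end == pos + plen))
  }
})

test_that("coverage denominator modes resolve containment differently", {
  set.seed(4)
  t1 <- rand_seq(1000)
  contig <- substr(t1, 301, 600)      # 300 bp exact substring
  subjects <- c(t1 = t1)
  hits <- align_all(c(c1 = contig), subjects)
  p_q <- containment_params()
  p_r <- containment_params(coverage_denominator = "reference_sequence")
  expect_true(is_contained("c1", hits, 300L, c(t1 = 1000L), p_q))
  expect_false(is_contained("c1", hits, 300L, c(t1 = 1000L), p_r))

  # 300 bp contig sharing only 100 bp: not contained either way
  shared <- paste0(substr(t1, 1, 100), rand_seq(200))
  h2 <- align_all(c(c2 = shared), subjects)
  expect_false(is_contained("c2", h2, 300L, c(t1 = 1000L), p_q))
  expect_false(is_contained("c2", h2, 300L, c(t1 = 1000L), p_r))
})

test_that("specificity and sensitivity count containments in the right direction", {
  set.seed(5)
  ref <- tiny_tx(setNames(replicate(10, rand_seq(600)), paste0("t", 1:10)),
                 paste0("g", 1:10))
  # assembly: exact copies of 4 transcripts + 2 random contigs
  contigs <- c(setNames(ref$sequences[1:4], paste0("c", 1:4)),
               setNames(replicate(2, rand_seq(600)), paste0("c", 5:6)))
  asm <- assembly(contigs)
  sp <- specificity(asm, ref)
  expect_equal(sp$contained, 4L)
  expect_equal(sp$total, 6L)
  expect_equal(round(sp$percent, 1), 66.7)
  sn <- sensitivity(ref, asm)
  expect_equal(sn$contained, 4L)
  expect_equal(sn$total, 10L)
  expect_equal(sn$percent, 40)

  # self-comparison: both measures 100%
  self_ref <- setNames(ref$sequences, paste0("r", 1:10))
  expect_equal(specificity(ref, self_ref)$percent, 100)
  expect_equal(sensitivity(self_ref, ref)$percent, 100)

  # a short contig covers no 600 bp transcript 80%
  one <- assembly(c(short1 = substr(ref$sequences[[1]], 1, 60)))
  expect_equal(sensitivity(ref, one)$percent, 0)

  # assembly of random sequence: specificity 0
  rnd <- assembly(setNames(replicate(3, rand_seq(500)), paste0("r", 1:3)))
  expect_equal(specificity(rnd, ref)$percent, 0)
})

test_that("adding perfect copies or random contigs moves the measures the right way", {
  set.seed(6)
  ref <- tiny_tx(setNames(replicate(5, rand_seq(500)), paste0("t", 1:5)),
                 paste0("g", 1:5))
  asm <- assembly(setNames(ref$sequences[1:2], c("a", "b")))
  sn0 <- sensitivity(ref, asm)
  plus <- assembly(c(asm$contigs, c(cnew = ref$sequences[[3]])))
  expect_gte(sensitivity(ref, plus)$contained, sn0$contained)
  sp0 <- specificity(asm, ref)
  noisy <- assembly(c(asm$contigs, c(junk = rand_seq(500))))
  expect_equal(specificity(noisy, ref)$contained, sp0$contained)
})

test_that("builtin and external blastn backends agree on containment verdicts", {
  set.seed(7)
  n_pairs <- 50L
  subjects <- setNames(replicate(n_pairs, rand_seq(800)),
                       sprintf("t%02d", 1:n_pairs))
  queries <- character(n_pairs)
  planted <- seq_len(n_pairs) <= 30L
  for (i in seq_len(n_pairs)) {
    queries[i] <- if (planted[i]) {
      len <- sample(150:600, 1L)
      pos <- sample(1:(800 - len + 1L), 1L)
      substr(subjects[[i]], pos, pos + len - 1L)
    } else rand_seq(sample(150:600, 1L))
  }
  names(queries) <- sprintf("c%02d", 1:n_pairs)
  p <- containment_params()
  hb <- align_all(queries, subjects, p)
  he <- blastn_hits(queries, subjects)
  qlen <- nchar(queries); slen <- nchar(subjects)
  vb <- vapply(names(queries), function(id)
    is_contained(id, hb, qlen[[id]], slen, p), logical(1L))
  ve <- vapply(names(queries), function(id)
    is_contained(id, he, qlen[[id]], slen, p), logical(1L))
  expect_identical(vb, ve)
  expect_true(all(vb[planted]))
  expect_false(any(vb[!planted]))
})

test_that("tabular parsing converts coordinates and flags minus-strand hits", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\ts1\t100.0\t200\t0\t0\t1\t200\t101\t300\t1e-50\t370",
    "q2\ts1\t95.0\t100\t5\t0\t11\t110\t400\t301\t1e-20\t150"
  ), f)
  h <- parse_tabular_hits(f)
  expect_equal(h$q_start, c(0L, 10L))
  expect_equal(h$q_end, c(200L, 110L))
  expect_equal(h$s_start, c(100L, 300L))
  expect_equal(h$s_end, c(300L, 400L))
  expect_identical(h$strand, c("+", "-"))
  expect_equal(h$matches, c(200L, 95L))
  expect_error(parse_tabular_hits(withr::local_tempfile()), "cannot read")
})

test_that("queries shorter than the seed size are skipped with a warning", {
  set.seed(8)
  s <- setNames(rand_seq(300), "s")
  expect_warning(h <- align_all(c(tiny = "ACGTAC", s2 = unname(s)), s),
                 "shorter than k")
  expect_true(all(h$query_id == "s2"))
})
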