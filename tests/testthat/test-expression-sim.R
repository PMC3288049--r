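short_tx <- function(n, len = 30L) {
  tiny_tx(setNames(replicate(n, rand_seq(len)), sprintf("t%04d", 1:n)),
          sprintf("g%04d", 1:n))
}

test_that("expression counts are multinomial over the Zipf-ranked transcripts", {
  set.seed(1)
  one <- short_tx(1)
  p <- simulate_expression(one, library_config(n_molecules = 1000), seed = 1)
  expect_equal(p$count, 1000L)

  # k = 0: symmetric; each of 4 transcripts near 250000
  four <- short_tx(4)
  p4 <- simulate_expression(four,
                            library_config(zipf_exponent = 0,
                                           n_molecules = 1e6), seed = 2)
  sd_mult <- sqrt(1e6 * 0.25 * 0.75)
  expect_true(all(abs(p4$count - 250000) < 5 * sd_mult))
  expect_equal(sum(p4$count), 1e6)
})

test_that("log-log rank-abundance slope recovers the Zipf exponent", {
  tx <- short_tx(1000)
  p <- simulate_expression(tx, library_config(zipf_exponent = 1,
                                              n_molecules = 1e6), seed = 3)
  top <- p[p$rank <= 100 & p$count > 0, ]
  fit <- stats::lm(log(count) ~ log(rank), data = top)
  expect_lt(abs(unname(stats::coef(fit)[2L]) + 1), 0.1)
})

test_that("negative Zipf exponent is rejected", {
  expect_error(library_config(zipf_exponent = -1), ">= 0")
})

test_that("the Gaussian tail cutoff suppresses high ranks", {
  tx <- short_tx(500)
  cfg <- library_config(zipf_exponent = 1, zipf_tail_cutoff = 50,
                        n_molecules = 1e6)
  p <- simulate_expression(tx, cfg, seed = 4)
  expect_equal(sum(p$count[p$rank > 200]), 0)   # exp(-(200/50)^2) ~ 1e-7
})

test_that("reverse transcription start jitter matches the half-normal mean", {
  # tss_sd = 0: whole transcript
  rt0 <- reverse_transcribe(rep(500L, 10L), tss_sd = 0)
  expect_true(all(rt0$start == 0L) && all(rt0$end == 500L))

  set.seed(5)
  rt <- reverse_transcribe(rep(10000L, 1e4), tss_sd = 25)
  mu <- 25 * sqrt(2 / pi)
  se <- 25 * sqrt(1 - 2 / pi) / sqrt(1e4)
  expect_lt(abs(mean(rt$start) - mu), 3 * se + 0.5)  # 0.5 for integer rounding
  expect_true(all(rt$end == 10000L))

  # clamping on short transcripts: start never reaches the 3' end
  set.seed(6)
  rt_short <- reverse_transcribe(rep(10L, 2000L), tss_sd = 50)
  expect_true(all(rt_short$start <= 9L))
  expect_true(all(rt_short$end - rt_short$start >= 1L))
})

test_that("fragmentation partitions each molecule exactly", {
  set.seed(7)
  mols <- data.frame(transcript_id = sprintf("t%d", 1:200),
                     start = sample(0:50, 200, TRUE), end = 0L)
  mols$end <- mols$start + sample(c(1L, 2L, 500L, 1500L), 200, TRUE)
  frags <- fragment_molecules(mols, lambda = 300)
  expect_equal(sum(frags$end - frags$start), sum(mols$end - mols$start))
  # fragments are contiguous within each molecule
  for (t in mols$transcript_id[1:50]) {
    fr <- frags[frags$transcript_id == t, ]
    m <- mols[mols$transcript_id == t, ]
    expect_equal(fr$start[1L], m$start)
    expect_equal(fr$end[nrow(fr)], m$end)
    if (nrow(fr) > 1L) expect_equal(fr$start[-1L], fr$end[-nrow(fr)])
  }
  expect_true(all(frags$end > frags$start))
})

test_that("mean fragment count matches 1 + length/lambda", {
  set.seed(8)
  mols <- data.frame(transcript_id = sprintf("m%05d", 1:1e4),
                     start = 0L, end = 1800L)
  frags <- fragment_molecules(mols, lambda = 900)
  counts <- table(frags$transcript_id)
  se <- sqrt(2 / 1e4)  # var(1 + Poisson(2)) = 2
  expect_lt(abs(mean(counts) - 3), 3 * se)
  expect_error(fragment_molecules(mols, lambda = 0), "positive")
})

test_that("size selection keeps the closed 500-800 window, preserving order", {
  fr <- data.frame(transcript_id = "t", start = 0L,
                   end = c(499L, 500L, 650L, 800L, 801L))
  kept <- size_select(fr, 500L, 800L)
  expect_equal(kept$end, c(500L, 650L, 800L))
  expect_equal(nrow(size_select(fr[0, ], 500L, 800L)), 0L)
  all_in <- data.frame(transcript_id = "t", start = 0L, end = c(500L, 700L))
  expect_identical(size_select(all_in, 500L, 800L), all_in)
})

test_that("subsampling is uniform, exact-size and seed-deterministic", {
  fr <- data.frame(transcript_id = sprintf("t%d", 1:10), start = 0L, end = 600L)
  expect_equal(nrow(subsample_fragments(fr, 10L, seed = 1)), 10L)
  s1 <- subsample_fragments(fr, 3L, seed = 42)
  s2 <- subsample_fragments(fr, 3L, seed = 42)
  expect_identical(s1, s2)
  expect_error(subsample_fragments(fr, 11L, seed = 1), "cannot subsample")

  # hypergeometric share of a 10%-abundance transcript
  big <- data.frame(
    transcript_id = c(rep("hot", 1e4), sprintf("c%05d", 1:9e4)),
    start = 0L, end = 600L)
  sub <- subsample_fragments(big, 1e4, seed = 9)
  share <- mean(sub$transcript_id == "hot")
  sd_h <- sqrt(1e4 * 0.1 * 0.9 * (1e5 - 1e4) / (1e5 - 1)) / 1e4
  expect_lt(abs(share - 0.1), 5 * sd_h)
})

test_that("expected counts are non-increasing in rank for k = 1", {
  tx <- short_tx(50)
  cfg <- library_config(zipf_exponent = 1, n_molecules = 1e6)
  acc <- numeric(50)
  for (s in 1:5) {
    p <- simulate_expression(tx, cfg, seed = s)
    acc <- acc + p$count[order(p$rank)]
  }
  # averaged over runs, counts decrease in rank over the leading ranks
  expect_true(all(diff(acc[1:10]) < 0))
  expect_gt(acc[1L], max(acc[-1L]))
})
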