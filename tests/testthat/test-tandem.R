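test_that("wraparound scoring matches closed forms and the substring
          enumeration oracle", {
  set.seed(21)
  w <- c(2, -7, -7)
  m <- randSeq(150)
  expect_equal(scoreArray(m, m, w)$score, 2 * 150)
  expect_equal(scoreArray(m, m, w)$copy_number, 1.0)

  reg <- strrep(m, 3)
  p <- 77
  old <- substr(reg, p, p)
  substr(reg, p, p) <- setdiff(BASES, old)[1]
  r <- scoreArray(reg, m, w)
  expect_equal(r$score, 2 * 449 - 7)
  expect_equal(r$copy_number, 3.0)
  expect_equal(paste(r$monomers, collapse = ""), reg)

  # tiny instances against the exhaustive substring oracle
  for (k in 1:6) {
    mono <- randSeq(sample(4:7, 1))
    region <- mutateRate(strrep(mono, sample(2:3, 1)), 0.1)
    got <- wraparoundAlign(region, mono, w, "global")$score
    expect_equal(got, oracleWraparound(region, mono, w))
  }
})

test_that("random regions score far below the acceptance floor", {
  set.seed(1)
  fails <- 0
  for (s in 1:25) {
    mono <- randSeq(100)
    region <- randSeq(200)
    if (wraparoundAlign(region, mono, c(2, -7, -7), "global")$score >= 50)
      fails <- fails + 1
  }
  expect_equal(fails, 0)
})

test_that("a 150 bp scaffold cannot hold an array and is skipped", {
  g <- stats::setNames(randSeq(150), "tiny")
  expect_message(
    tas <- detectTandemArrays(g, hineConfig(), verbose = TRUE),
    "skipped")
  expect_equal(length(tas), 0L)
})

test_that("a perfect planted array is recovered with exact period and
          near-exact boundaries", {
  set.seed(33)
  m <- randSeq(120)
  g <- plantedArrayGenome(m, 2)
  tas <- removeRedundant(detectTandemArrays(g, hineConfig()))
  expect_equal(length(tas), 1L)
  expect_equal(arrayPeriods(tas), 120L)
  expect_equal(copyNumbers(tas), 2.0)
  gr <- arrayRanges(tas)
  expect_equal(GenomicRanges::start(gr), 501L)
  expect_equal(GenomicRanges::end(gr), 740L)
  expect_equal(arrayScores(tas), 2L * 240L)
  # monomers concatenate to the genomic substring
  expect_equal(paste(monomerSeqs(tas)[[1]], collapse = ""),
               unname(substr(g, GenomicRanges::start(gr),
                             GenomicRanges::end(gr))))
})

test_that("a 99 bp monomer repeated five times is below the period window
          and absent", {
  set.seed(34)
  g <- plantedArrayGenome(randSeq(99), 5)
  tas <- removeRedundant(detectTandemArrays(g, hineConfig()))
  expect_equal(length(tas), 0L)
})

test_that("arrays containing N are rejected", {
  set.seed(35)
  m <- randSeq(120)
  g <- plantedArrayGenome(m, 3)
  v <- strsplit(g, "")[[1]]
  v[620] <- "N"
  g2 <- stats::setNames(paste(v, collapse = ""), "chr")
  tas <- detectTandemArrays(g2, hineConfig())
  expect_equal(length(tas), 0L)
})

test_that("detection is strand symmetric on perfect arrays", {
  set.seed(36)
  m <- randSeq(130)
  g <- plantedArrayGenome(m, 3, left = 600, right = 400)
  tas <- removeRedundant(detectTandemArrays(g, hineConfig()))
  grc <- stats::setNames(revComp(g), "chr")
  tasrc <- removeRedundant(detectTandemArrays(grc, hineConfig()))
  expect_equal(length(tas), 1L)
  expect_equal(length(tasrc), 1L)
  n <- unname(nchar(g))
  expect_equal(GenomicRanges::start(arrayRanges(tasrc)),
               n - GenomicRanges::end(arrayRanges(tas)) + 1L)
  expect_equal(GenomicRanges::end(arrayRanges(tasrc)),
               n - GenomicRanges::start(arrayRanges(tas)) + 1L)
})

test_that("redundancy removal follows the strictly-greater 50% rule with
          score/period/position tie-breaks", {
  mk <- function(starts, ends, scores, periods) {
    gr <- GenomicRanges::GRanges("c", IRanges::IRanges(starts, ends),
                                 strand = "+",
                                 array_id = sprintf("TR%06d",
                                                    seq_along(starts)),
                                 period = periods,
                                 copies = rep(2, length(starts)),
                                 score = scores,
                                 consensus = rep("ACGT", length(starts)))
    mono <- rep(list("ACGT"), length(starts))
    names(mono) <- sprintf("TR%06d", seq_along(starts))
    new("TandemArraySet", arrays = gr, monomers = mono,
        config = configAsList(hineConfig()))
  }
  # 90% overlap: higher score wins
  t1 <- removeRedundant(mk(c(1, 21), c(200, 220), c(600L, 300L),
                           c(100L, 100L)))
  expect_equal(length(t1), 1L)
  expect_equal(arrayScores(t1), 600L)

  # disjoint arrays are all retained
  t2 <- removeRedundant(mk(c(1, 500), c(200, 700), c(300L, 300L),
                           c(100L, 100L)))
  expect_equal(length(t2), 2L)

  # overlap of exactly half the shorter: both retained
  t3 <- removeRedundant(mk(c(1, 101), c(200, 300), c(300L, 300L),
                           c(100L, 100L)))
  expect_equal(length(t3), 2L)

  # interval-arithmetic property over random placements on a toy scaffold
  set.seed(40)
  for (k in 1:30) {
    s1 <- sample(1:500, 1); e1 <- s1 + sample(100:300, 1)
    s2 <- sample(1:500, 1); e2 <- s2 + sample(100:300, 1)
    tt <- removeRedundant(mk(c(s1, s2), c(e1, e2), c(400L, 350L),
                             c(100L, 100L)))
    ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
    shorter <- min(e1 - s1 + 1, e2 - s2 + 1)
    expect_equal(length(tt), if (ov > 0.5 * shorter) 1L else 2L)
  }
})

test_that("monomer histograms bin lengths and count copies", {
  set.seed(41)
  m <- randSeq(170)
  g <- plantedArrayGenome(m, 10)
  tas <- removeRedundant(detectTandemArrays(g, hineConfig()))
  h <- monomerLengthHistogram(tas)
  expect_equal(nrow(h$length_hist), 1L)
  expect_equal(h$length_hist$bin_start, 160L)
  expect_equal(h$length_hist$n_monomers, 10L)
  expect_equal(h$copies_hist$copies, 10L)

  empty <- detectTandemArrays(stats::setNames(randSeq(10000), "c"),
                              hineConfig())
  h0 <- monomerLengthHistogram(empty)
  expect_equal(nrow(h0$length_hist), 0L)

  # {2,2,3,5} copies -> 2-3-copy fraction 0.75
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 400, 800, 1300),
                                                     width = 100),
                               strand = "+",
                               array_id = sprintf("TR%06d", 1:4),
                               period = rep(100L, 4),
                               copies = c(2, 2, 3, 5), score = rep(100L, 4),
                               consensus = rep("A", 4))
  mono <- rep(list("A"), 4)
  names(mono) <- sprintf("TR%06d", 1:4)
  tt <- new("TandemArraySet", arrays = gr, monomers = mono,
            config = configAsList(hineConfig()))
  expect_equal(monomerLengthHistogram(tt)$frac_2_3, 0.75)
})

test_that("mutated planted arrays are still detected with accurate period", {
  set.seed(42)
  hits <- 0; per_ok <- 0
  n_trials <- 15
  for (k in seq_len(n_trials)) {
    m <- randSeq(sample(120:200, 1))
    copies <- sample(2:4, 1)
    region <- paste(vapply(seq_len(copies), function(z)
      mutateRate(m, 0.05), character(1)), collapse = "")
    g <- stats::setNames(paste0(randSeq(400), region, randSeq(400)), "chr")
    tas <- removeRedundant(detectTandemArrays(g, hineConfig()))
    if (length(tas) >= 1L) {
      hits <- hits + 1
      if (abs(arrayPeriods(tas)[1] - nchar(m)) <= 2) per_ok <- per_ok + 1
    }
  }
  expect_gte(hits, n_trials - 1)
  expect_gte(per_ok, n_trials - 1)
})
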