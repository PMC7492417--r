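.emptyTas <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    array_id = character(), period = integer(), copies = numeric(),
    score = integer(), consensus = character())
  new("TandemArraySet", arrays = gr, monomers = list(),
      config = configAsList(hineConfig()))
}

.emptyClusters <- function() {
  new("ArrayClusterSet",
      membership = S4Vectors::DataFrame(array_id = character(),
                                        cluster_id = character(),
                                        orientation = character(),
                                        rotation = integer()),
      consensus = character(0),
      stats = data.frame(cluster_id = character(), n_members = integer(),
                         total_bp = integer(), n_monomers = integer(),
                         consensus_length = integer(),
                         stringsAsFactors = FALSE),
      config = configAsList(hineConfig()))
}

# build a genome with planted LF-array-RF members of one cluster and
# return the pieces needed by the flank stages
plantFlankFixture <- function(n_members, lf, rf, monomer, copies = 3,
                              linker_len = 30, mutate = 0,
                              scaffold_len = 4000) {
  seqs <- character(n_members)
  arr_start <- arr_end <- integer(n_members)
  for (i in seq_len(n_members)) {
    lfm <- if (mutate > 0) mutateRate(lf, mutate) else lf
    rfm <- if (mutate > 0) mutateRate(rf, mutate) else rf
    array <- paste(vapply(seq_len(copies), function(z)
      if (mutate > 0) mutateRate(monomer, mutate) else monomer,
      character(1)), collapse = "")
    left <- randSeq(600)
    el <- paste0(lfm, randSeq(linker_len), array, rfm)
    seqs[i] <- paste0(left, el, randSeq(scaffold_len - 600 - nchar(el)))
    arr_start[i] <- 600 + nchar(lfm) + linker_len + 1
    arr_end[i] <- arr_start[i] + nchar(array) - 1
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs,
                                                     sprintf("s%02d",
                                                             seq_len(n_members))))
  members <- data.frame(unit_id = "U_1",
                        member_key = sprintf("m%02d", seq_len(n_members)),
                        scaffold = names(genome), start = arr_start,
                        end = arr_end, orientation = "+",
                        gap = NA_integer_, complete = TRUE,
                        array_ids = sprintf("m%02d", seq_len(n_members)),
                        stringsAsFactors = FALSE)
  list(genome = genome, members = members,
       units = list(units = data.frame(unit_id = "U_1", clusters = "CL1",
                                       stringsAsFactors = FALSE),
                    members = members))
}

test_that("flank extraction truncates at scaffold bounds and sets flags", {
  set.seed(70)
  m <- randSeq(120)
  seq <- paste0(randSeq(100), strrep(m, 2), randSeq(300))
  gr <- GenomicRanges::GRanges("s1", IRanges::IRanges(101, 340),
                               strand = "+", array_id = "TR000001",
                               period = 120L, copies = 2, score = 480L,
                               consensus = m)
  tas <- new("TandemArraySet", arrays = gr,
             monomers = list(TR000001 = c(m, m)),
             config = configAsList(hineConfig()))
  fl <- extractFlanks(tas, stats::setNames(seq, "s1"))
  expect_equal(nchar(fl$left_seq), 100L)   # truncated at scaffold start
  expect_equal(nchar(fl$right_seq), 300L)
  expect_false(fl$at_scaffold_edge)
  expect_false(fl$contains_N)

  # array ending exactly at the scaffold end is flagged
  seq2 <- paste0(randSeq(200), strrep(m, 2))
  gr2 <- gr
  GenomicRanges::ranges(gr2) <- IRanges::IRanges(201, 440)
  tas2 <- new("TandemArraySet", arrays = gr2,
              monomers = list(TR000001 = c(m, m)),
              config = configAsList(hineConfig()))
  fl2 <- extractFlanks(tas2, stats::setNames(seq2, "s1"))
  expect_true(fl2$at_scaffold_edge)

  # N in a flank is flagged
  seq3 <- paste0(randSeq(100), "NNN", randSeq(97), strrep(m, 2),
                 randSeq(300))
  gr3 <- gr
  GenomicRanges::ranges(gr3) <- IRanges::IRanges(201, 440)
  tas3 <- new("TandemArraySet", arrays = gr3,
              monomers = list(TR000001 = c(m, m)),
              config = configAsList(hineConfig()))
  fl3 <- extractFlanks(tas3, stats::setNames(seq3, "s1"))
  expect_true(fl3$contains_N)
})

test_that("a shared LF block flanked by random sequence is recovered
          exactly", {
  set.seed(71)
  lf <- randSeq(80)
  rf <- randSeq(60)
  left <- vapply(1:10, function(i) paste0(randSeq(300), lf), character(1))
  right <- vapply(1:10, function(i) paste0(rf, randSeq(300)), character(1))
  fc <- deriveFlankConsensus(left, right)
  expect_true(fc$valid)
  expect_true(grepl(fc$lf, lf, fixed = TRUE) ||
                grepl(lf, fc$lf, fixed = TRUE) ||
                alignSeqs(fc$lf, lf, "local")$identity > 0.99)
  expect_gte(alignSeqs(fc$rf, rf, "local")$matches / nchar(rf) , 0.95)
})

test_that("members with completely random flanks yield a no-consensus
          result", {
  set.seed(72)
  left <- vapply(1:8, function(i) randSeq(400), character(1))
  right <- vapply(1:8, function(i) randSeq(400), character(1))
  fc <- deriveFlankConsensus(left, right)
  expect_false(fc$valid)
  expect_match(fc$reason, "block|support")
})

test_that("fewer than five eligible members is a no-consensus reason", {
  fc <- deriveFlankConsensus(c("ACGTACGT", "ACGTACGT"),
                             c("ACGTACGT", "ACGTACGT"))
  expect_false(fc$valid)
  expect_match(fc$reason, "fewer than 5")
})

test_that("flank member identity follows the closed form", {
  set.seed(73)
  cons <- randSeq(60)
  expect_equal(flankMemberIdentity(cons, cons), 1.0)
  mm <- mutateFix(cons, 12)
  # 12 substitutions over 60 columns; the score-optimal alignment may
  # trade a mismatch pair for a gap pair, shifting identity by < 2%
  expect_lt(abs(flankMemberIdentity(mm, cons) - 0.80), 0.02)

  # distribution over planted members at 5% mutation
  ids <- vapply(1:40, function(i)
    flankMemberIdentity(mutateRate(cons, 0.05), cons), numeric(1))
  expect_lt(abs(mean(ids) - 0.95), 0.02)
})

test_that("profileFlanks recovers planted LF/RF despite the variable
          linker and respects eligibility flags", {
  set.seed(74)
  lf <- randSeq(70)
  rf <- randSeq(60)
  monomer <- randSeq(150)
  fx <- plantFlankFixture(10, lf, rf, monomer, mutate = 0.02)
  tas <- .emptyTas()
  fl <- profileFlanks(tas, .emptyClusters(), fx$genome,
                      units = fx$units)
  u <- flankUnits(fl)
  expect_true(u$valid)
  expect_gte(alignSeqs(u$lf, lf, "local")$matches / nchar(lf), 0.95)
  expect_gte(alignSeqs(u$rf, rf, "local")$matches / nchar(rf), 0.95)
  expect_false(u$flipped)
})

test_that("a unit whose members run in element-reverse orientation is
          flipped by the flank evidence", {
  set.seed(75)
  lf <- randSeq(70)
  rf <- randSeq(60)
  monomer <- randSeq(150)
  fx <- plantFlankFixture(10, lf, rf, monomer, mutate = 0.02)
  # pretend clustering anchored the representative on the other strand
  fx$units$members$orientation <- "-"
  tas <- .emptyTas()
  fl <- profileFlanks(tas, .emptyClusters(), fx$genome, units = fx$units)
  u <- flankUnits(fl)
  expect_true(u$valid)
  expect_true(u$flipped)
  expect_gte(alignSeqs(u$lf, lf, "local")$matches / nchar(lf), 0.95)
  units2 <- applyOrientationFlips(fx$units, fl)
  expect_true(all(units2$members$orientation == "+"))
})

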