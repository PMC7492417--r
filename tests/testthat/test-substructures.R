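test_that("chimera construction concatenates and records the junction", {
  ch <- buildChimera("AAA", "TTT")
  expect_equal(ch$sequence, "AAATTT")
  expect_equal(ch$junction, 3L)
  ch2 <- buildChimera(randSeq(80), randSeq(60))
  expect_equal(nchar(ch2$sequence), 140L)
  expect_error(buildChimera("", "TTT"), "non-empty")
})

test_that("inverted-repeat arms follow the closed-form score thresholds", {
  set.seed(60)
  # a perfect 7 bp arm scores exactly 14 and is reported
  arm7 <- "GATTCCA"
  lf <- paste0(arm7, randSeq(40))
  rf <- paste0(randSeq(40), rcOracle(arm7))
  ir <- findInvertedRepeats(buildChimera(lf, rf))
  planted <- ir[ir$left_start == 1L, , drop = FALSE]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$score, 14L)
  expect_equal(substr(lf, planted$left_start, planted$left_end), arm7)

  # a perfect 6 bp arm scores 12 and is rejected
  arm6 <- "GATTCC"
  lf6 <- paste0(arm6, randSeq(40))
  rf6 <- paste0(randSeq(40), rcOracle(arm6))
  ir6 <- findInvertedRepeats(buildChimera(lf6, rf6))
  expect_true(nrow(ir6) == 0L || ir6$score[1] != 12L)

  # 11 bp arms with one interior mismatch: score 15, identity 10/11
  arm11 <- "GATTCCAGTCA"
  arm11mm <- arm11
  substr(arm11mm, 6, 6) <- "A"  # C -> A interior mismatch
  lf11 <- paste0(arm11, randSeq(40))
  rf11 <- paste0(randSeq(40), rcOracle(arm11mm))
  ir11 <- findInvertedRepeats(buildChimera(lf11, rf11))
  expect_gte(nrow(ir11), 1L)
  expect_equal(ir11$score[1], 2L * 10L - 5L)
  expect_equal(ir11$identity[1], 10 / 11)
})

test_that("arm pairs inside one flank only are never reported", {
  set.seed(61)
  arm <- randSeq(12)
  lf <- paste0(arm, randSeq(10), rcOracle(arm))  # both arms inside LF
  rf <- randSeq(40)
  ir <- findInvertedRepeats(buildChimera(lf, rf))
  expect_equal(nrow(ir), 0L)
})

test_that("inverted-repeat detection agrees with an ungapped all-pairs
          oracle on short chimeras", {
  set.seed(62)
  cfg <- hineConfig()
  oracleIR <- function(lf, rf) {
    rcrf <- rcOracle(rf)
    nl <- nchar(lf); nr <- nchar(rcrf)
    best <- 0
    for (len in 7:min(nl, nr)) {
      for (i in seq_len(nl - len + 1)) for (j in seq_len(nr - len + 1)) {
        va <- strsplit(substr(lf, i, i + len - 1), "")[[1]]
        vb <- strsplit(substr(rcrf, j, j + len - 1), "")[[1]]
        mm <- sum(va != vb)
        sc <- 2 * (len - mm) - 5 * mm
        if ((len - mm) / len >= 0.90 && sc > best) best <- sc
      }
    }
    best
  }
  for (k in 1:8) {
    arm <- randSeq(sample(8:12, 1))
    lf <- paste0(randSeq(10), arm, randSeq(20))
    rf <- paste0(randSeq(20), rcOracle(mutateFix(arm, 1)), randSeq(10))
    ir <- findInvertedRepeats(buildChimera(lf, rf), cfg)
    got <- if (nrow(ir)) max(ir$score) else 0
    osc <- oracleIR(lf, rf)
    if (osc >= cfg$ir_min_score) expect_gte(got, osc) else
      expect_true(got == 0 || got >= cfg$ir_min_score)
  }
})

test_that("subTIR and internal IR are identified from a planted LF/RF
          layout", {
  set.seed(63)
  subtir <- "GGATCCATAGTC"
  spacer <- randSeq(5)
  ir9 <- substr(rcOracle(subtir), 1, 9)
  lf <- paste0(subtir, spacer, ir9, strrep("GTCC", 5))
  rf <- paste0(rcOracle(subtir), "GGCGC", "TTA", "GCGCC",
               randSeq(20))
  pairs <- findInvertedRepeats(buildChimera(lf, rf))
  ann <- identifySubtirIr(lf, rf, pairs)
  expect_equal(ann$subtir$seq, subtir)
  expect_equal(ann$subtir$lf_start, 1L)
  expect_equal(ann$ir$seq, ir9)
  expect_equal(ann$ir$spacer, 5L)
  expect_equal(ann$ir$mismatches, 0L)

  # no complementary segment at all -> subtir absent
  ann2 <- identifySubtirIr(randSeq(60), randSeq(60),
                           findInvertedRepeats(buildChimera(randSeq(60),
                                                            randSeq(60))))
  expect_null(ann2$subtir)
})

test_that("member-level subTIR annotation allows one mismatch", {
  set.seed(64)
  subtir <- "GGATCCATAGTC"
  lf_exact <- paste0(randSeq(5), subtir, randSeq(40))
  lf_1mm <- paste0(randSeq(5), mutateFix(subtir, 1), randSeq(40))
  lf_3mm <- paste0(randSeq(5), mutateFix(subtir, 3), randSeq(40))
  rf <- paste0(rcOracle(subtir), randSeq(40))
  fl <- new("FlankConsensusSet",
            units = S4Vectors::DataFrame(
              unit_id = "U_1", clusters = "CL1", lf = lf_exact, rf = rf,
              lf_support = 3L, rf_support = 3L, n_eligible = 3L,
              lf_mean_identity = 1, rf_mean_identity = 1, valid = TRUE,
              reason = "", flipped = FALSE),
            member_flanks = list(U_1 = data.frame(
              member_key = c("a", "b", "c"),
              lf = c(lf_exact, lf_1mm, lf_3mm),
              rf = rep(rf, 3), stringsAsFactors = FALSE)),
            config = configAsList(hineConfig()))
  ann <- annotateSubstructures(fl)
  mem <- ann$members
  expect_equal(mem$subtir_lf_found, c(TRUE, TRUE, FALSE))
  expect_equal(mem$subtir_lf_mismatches[1:2], c(0L, 1L))
})

test_that("palindrome detection matches construction and the exhaustive
          decomposition oracle", {
  p <- findPalindrome(paste0("GGCGC", "TTA", "GCGCC"), 0L)
  expect_equal(p$arm, 5L)
  expect_equal(p$loop, 3L)
  expect_equal(p$mismatches, 0L)

  expect_null(findPalindrome(strrep("A", 30), 0L))

  set.seed(65)
  for (k in 1:10) {
    win <- randSeq(sample(20:30, 1))
    got <- findPalindrome(win, 0L)
    oracle <- oraclePalindrome(win)
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_equal(got$arm, oracle$arm)
    }
  }
})

test_that("microsatellite detection finds the planted unit in the LF 3'
          half and respects IUPAC mode", {
  set.seed(66)
  lf <- paste0(randSeq(30), strrep("GTCC", 5))
  ms <- findMicrosatellite(lf)
  expect_equal(ms$unit, "GTCC")
  expect_equal(ms$copies, 5.0)

  # no unit repeated twice -> absent
  expect_null(findMicrosatellite("ACGTGATCGTAGCCATGCAATG"))

  # alternating GTCC/GTCT copies produce GTCY under IUPAC mode
  lf2 <- paste0(randSeq(30), strrep("GTCCGTCT", 3))
  ms2 <- findMicrosatellite(lf2, iupac = TRUE)
  expect_equal(ms2$unit, "GTCY")

  # a repeat in the 5' half does not qualify
  lf3 <- paste0(strrep("GTCC", 5), randSeq(60))
  ms3 <- findMicrosatellite(lf3)
  expect_true(is.null(ms3) || ms3$lf_start > nchar(lf3) / 2)
})

test_that("module order is asserted on annotated units", {
  set.seed(67)
  subtir <- "GGATCCATAGTC"
  lf <- paste0(subtir, "ACGTT", substr(rcOracle(subtir), 1, 9),
               strrep("GTCC", 5))
  rf <- paste0(rcOracle(subtir), "GGCGC", "TTA", "GCGCC", randSeq(15))
  fl <- new("FlankConsensusSet",
            units = S4Vectors::DataFrame(
              unit_id = "U_1", clusters = "CL1", lf = lf, rf = rf,
              lf_support = 5L, rf_support = 5L, n_eligible = 5L,
              lf_mean_identity = 1, rf_mean_identity = 1, valid = TRUE,
              reason = "", flipped = FALSE),
            member_flanks = list(),
            config = configAsList(hineConfig()))
  ann <- annotateSubstructures(fl)
  u <- ann$units
  expect_true(u$has_subtir)
  expect_true(u$has_ir)
  expect_true(u$has_microsat)
  expect_true(u$has_palindrome)
  expect_true(u$module_order_ok)
  expect_lt(u$subtir_lf_start, u$ir_lf_start)
  expect_lt(u$ir_lf_start, u$ms_lf_start)
  expect_gt(u$pal_rf_start, u$subtir_rf_start)
})
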