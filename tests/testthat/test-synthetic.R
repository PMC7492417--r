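test_that("genome generation is seed-deterministic with calibrated GC and
          validated inputs", {
  g1 <- generateGenome(2, 2e4, 0.33, seed = 7)
  g2 <- generateGenome(2, 2e4, 0.33, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- generateGenome(2, 2e4, 0.33, seed = 8)
  expect_false(identical(as.character(g1), as.character(g3)))

  big <- generateGenome(1, 1e6, 0.34, seed = 9)
  expect_lt(abs(gcContent(as.character(big[[1]])) - 0.34), 0.01)

  expect_error(generateGenome(1, 1e4, 1.0, seed = 1), "inside")
  expect_error(generateGenome(1, 1e4, 0, seed = 1), "inside")
  expect_error(generateGenome(1, 5e3, 0.4, seed = 1), "10 kb")
})

test_that("element models enforce the structural ranges by construction", {
  set.seed(100)
  m <- elementModel("FX", subtir = randSeq(12), ir_len = 9,
                    spacer = randSeq(5), ms_unit = "GTCC", ms_copies = 5,
                    monomers = c(CLX = randSeq(160)),
                    pal_arm = randSeq(7), pal_loop = randSeq(5))
  expect_equal(m$ir, substr(rcOracle(m$subtir), 1, 9))
  expect_equal(nchar(m$rf_core), 60L)
  expect_equal(m$pal, paste0(m$pal_arm, m$pal_loop, rcOracle(m$pal_arm)))
  # LF layout: subTIR + spacer + IR + microsatellite
  expect_equal(m$lf, paste0(m$subtir, m$spacer, m$ir, strrep("GTCC", 5)))
  expect_error(elementModel("FY", subtir = randSeq(8), ir_len = 7,
                            spacer = "A", ms_unit = "GTC", ms_copies = 4,
                            monomers = c(C = randSeq(150)),
                            pal_arm = randSeq(6), pal_loop = randSeq(4)))
})

test_that("the default roster is deterministic and mirrors the published
          design", {
  r1 <- defaultFamilyRoster()
  r2 <- defaultFamilyRoster()
  expect_identical(r1, r2)
  expect_equal(length(r1), 11L)
  clusters <- unlist(lapply(r1, function(m) names(m$monomers)))
  expect_equal(length(clusters), 13L)
  expect_setequal(clusters, paste0("CL", 1:13))
  groups <- vapply(r1, function(m) m$group, integer(1))
  expect_equal(sum(groups == 1L), 4L)
  expect_equal(sum(groups == 2L), 2L)
  expect_equal(sum(groups == 3L), 5L)
  # double-array families carry two clusters each
  expect_equal(names(r1$F10_13$monomers), c("CL10", "CL13"))
  expect_equal(names(r1$F11_12$monomers), c("CL11", "CL12"))
  # published per-cluster monomer lengths
  expect_equal(nchar(r1$F1$monomers[["CL1"]]), 167L)
  expect_equal(nchar(r1$F6$monomers[["CL6"]]), 147L)
  expect_equal(nchar(r1$F11_12$monomers[["CL12"]]), 138L)
})

test_that("planting is deterministic and truth intervals re-extract to the
          planted strings", {
  g <- generateGenome(1, 1e5, 0.33, seed = 10)
  models <- defaultFamilyRoster()["F5"]
  s1 <- plantElements(g, models, n_per_family = 6, seed = 11)
  s2 <- plantElements(g, models, n_per_family = 6, seed = 11)
  expect_identical(as.character(truthGenome(s1)),
                   as.character(truthGenome(s2)))

  tt <- truthRanges(s1)
  gen <- truthGenome(s1)
  for (i in which(!is.na(tt$seq))) {
    sub <- as.character(Biostrings::subseq(
      gen[[as.character(GenomicRanges::seqnames(tt))[i]]],
      GenomicRanges::start(tt)[i], GenomicRanges::end(tt)[i]))
    planted <- tt$seq[i]
    if (as.character(GenomicRanges::strand(tt))[i] == "-")
      planted <- rcOracle(planted)
    expect_identical(sub, planted)
  }

  # zero plants leave the genome untouched
  s0 <- plantElements(g, models, n_per_family = 0, seed = 1)
  expect_identical(as.character(truthGenome(s0)), as.character(g))
  expect_equal(length(truthRanges(s0)), 0L)
})

test_that("the copy-number law is dominated by 2-3 copies and sampled
          faithfully", {
  set.seed(12)
  model <- defaultFamilyRoster()$F5
  draws <- vapply(1:2000, function(z) hineminer:::.sampleCopies(model),
                  integer(1))
  expect_gte(min(draws), 2L)
  p <- c(0.35, 0.21, 0.14, 0.14 * (2 / 3)^(1:12))
  p <- p / sum(p)
  emp <- tabulate(draws - 1L, nbins = 14L)[1:3] / length(draws)
  expect_true(all(abs(emp - p[1:3]) < 3 * sqrt(p[1:3] * (1 - p[1:3]) / 2000)
                  + 0.01))
  expect_gt(mean(draws %in% 2:3), 0.5)
})

test_that("realized monomer mutations match the configured rate", {
  g <- generateGenome(1, 2e5, 0.33, seed = 13)
  synth <- plantElements(g, defaultFamilyRoster()["F5"],
                         n_per_family = 60, seed = 13)
  tt <- truthRanges(synth)
  arr <- tt[tt$type == "array"]
  truthm <- truthModels(synth)$F5$monomers[["CL5"]]
  p <- nchar(truthm)
  rates <- numeric(0)
  vb <- strsplit(truthm, "")[[1]]
  for (i in seq_along(arr)) {
    copies <- arr$copies[i]
    seqs <- substring(arr$seq[i], (seq_len(copies) - 1L) * p + 1L,
                      seq_len(copies) * p)
    for (s in seqs[nchar(seqs) == p]) {
      va <- strsplit(s, "")[[1]]
      rates <- c(rates, mean(va != vb))
    }
  }
  # a rare indel shifts the fixed-period chopping frame of every
  # downstream copy in that array (such copies read ~50-75% mismatched);
  # the substitution rate is measured on the in-frame copies
  clean <- rates[rates < 0.25]
  expect_gte(length(clean) / length(rates), 0.8)
  expect_lt(abs(mean(clean) - 0.05), 0.007)
})

test_that("decoys, truncations and empty paralogs are planted with
          coordinates that survive the reshuffle", {
  g <- generateGenome(2, 1e5, 0.33, seed = 14)
  synth <- plantElements(g, defaultFamilyRoster()[c("F1", "F5")],
                         n_per_family = 6, seed = 14)
  aug <- plantDecoysAndParalogs(synth, seed = 14, n_decoy_families = 1L,
                                n_decoy_copies = 4L, n_singletons = 3L,
                                n_truncated = 2L, paralog_fraction = 0.2)
  tt <- truthRanges(aug)
  expect_equal(sum(tt$type == "decoy_array"), 7L)
  expect_equal(sum(tt$type == "truncated_element"), 2L)
  expect_gte(sum(tt$type == "empty_paralog"), 1L)

  # every truth sequence still re-extracts exactly after shifting
  gen <- truthGenome(aug)
  for (i in which(!is.na(tt$seq))) {
    sub <- as.character(Biostrings::subseq(
      gen[[as.character(GenomicRanges::seqnames(tt))[i]]],
      GenomicRanges::start(tt)[i], GenomicRanges::end(tt)[i]))
    planted <- tt$seq[i]
    if (as.character(GenomicRanges::strand(tt))[i] == "-")
      planted <- rcOracle(planted)
    expect_identical(sub, planted)
  }

  # a planted paralog is recovered by the empty-site search at identity 1
  ep <- tt[tt$type == "empty_paralog"][1]
  partner <- tt[tt$type == "element" & tt$plant_id == ep$partner]
  hits <- emptySiteSearch(
    list(scaffold = as.character(GenomicRanges::seqnames(partner)),
         start = GenomicRanges::start(partner),
         end = GenomicRanges::end(partner)), gen)
  found <- any(hits$scaffold == as.character(GenomicRanges::seqnames(ep)) &
                 abs(hits$start - GenomicRanges::start(ep)) <= 2)
  expect_true(found)
  expect_true(all(hits$identity >= 0.8))
})

test_that("planting fails loudly when the genome cannot host the request", {
  g <- generateGenome(1, 1e4, 0.33, seed = 15)
  expect_error(plantElements(g, defaultFamilyRoster(), n_per_family = 40,
                             seed = 15), "insufficient")
})

test_that("the Rand index helper follows the pair-counting definition", {
  expect_equal(hineminer:::.randIndex(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               1)
  expect_equal(hineminer:::.randIndex(c(1, 1, 2, 2), c("a", "b", "a", "b")),
               1 / 3)
})
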