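# minimal TandemArraySet + ArrayClusterSet fixture with arrays at given
# positions/clusters for adjacency logic
adjacencyFixture <- function(starts, widths, clusters, orientations = "+",
                             scaffold = "s1") {
  n <- length(starts)
  orientations <- rep_len(orientations, n)
  ids <- sprintf("TR%06d", seq_len(n))
  gr <- GenomicRanges::GRanges(scaffold,
                               IRanges::IRanges(starts, width = widths),
                               strand = "+", array_id = ids,
                               period = 150L, copies = 2,
                               score = 500L, consensus = strrep("A", 10))
  mono <- rep(list("A"), n)
  names(mono) <- ids
  tas <- new("TandemArraySet", arrays = gr, monomers = mono,
             config = configAsList(hineConfig()))
  mm <- S4Vectors::DataFrame(array_id = ids, cluster_id = clusters,
                             orientation = orientations,
                             rotation = 0L)
  cons <- stats::setNames(
    vapply(unique(stats::na.omit(clusters)), function(z) randSeq(150),
           character(1)),
    unique(stats::na.omit(clusters)))
  cl <- new("ArrayClusterSet", membership = mm, consensus = cons,
            stats = data.frame(cluster_id = names(cons),
                               n_members = as.integer(
                                 table(clusters)[names(cons)]),
                               total_bp = 0L, n_monomers = 0L,
                               consensus_length = 150L,
                               stringsAsFactors = FALSE),
            config = configAsList(hineConfig()))
  list(tas = tas, clusters = cl)
}

test_that("double arrays merge under the gap ceiling and stay separate
          above it", {
  set.seed(80)
  # gap 0: merged into one unit with ordered clusters
  fx <- adjacencyFixture(starts = c(1000, 1300, 5000, 5300, 9000, 9300,
                                    13000, 13300),
                         widths = 300,
                         clusters = rep(c("CL1", "CL2"), 4))
  du <- detectDoubleArrays(fx$tas, fx$clusters)
  expect_equal(nrow(du$units), 1L)
  expect_equal(du$units$clusters, "CL1,CL2")
  expect_true(all(du$members$complete))

  # gap 1200: still merged
  fx2 <- adjacencyFixture(starts = c(1000, 2500, 5000, 6500, 9000, 10500),
                          widths = 300,
                          clusters = rep(c("CL1", "CL2"), 3))
  du2 <- detectDoubleArrays(fx2$tas, fx2$clusters)
  expect_equal(nrow(du2$units), 1L)

  # gap 2000: two separate single units
  fx3 <- adjacencyFixture(starts = c(1000, 3300, 6000, 8300, 11000, 13300),
                          widths = 300,
                          clusters = rep(c("CL1", "CL2"), 3))
  du3 <- detectDoubleArrays(fx3$tas, fx3$clusters)
  expect_equal(nrow(du3$units), 2L)
  expect_true(all(du3$units$clusters %in% c("CL1", "CL2")))
})

test_that("minus-orientation members reverse the element-space cluster
          order", {
  fx <- adjacencyFixture(starts = c(1000, 1300, 5000, 5300),
                         widths = 300,
                         clusters = c("CL2", "CL1", "CL2", "CL1"),
                         orientations = "-")
  du <- detectDoubleArrays(fx$tas, fx$clusters)
  expect_equal(nrow(du$units), 1L)
  expect_equal(du$units$clusters, "CL1,CL2")
})

test_that("element grouping separates flank-and-repeat, flank-only and
          unrelated designs", {
  set.seed(81)
  motif <- randSeq(60)
  monoA <- randSeq(160); substr(monoA, 21, 80) <- motif
  monoB <- randSeq(160); substr(monoB, 61, 120) <- mutateFix(motif, 8)
  monoC <- randSeq(160)
  monoD <- randSeq(160)
  flank1 <- randSeq(120)
  flank2 <- mutateRate(flank1, 0.08)
  flank3 <- randSeq(120)
  flank4 <- mutateRate(flank3, 0.08)
  el <- S4Vectors::DataFrame(
    element_id = c("E1", "E2", "E3", "E4"),
    unit_id = c("U_1", "U_2", "U_3", "U_4"),
    clusters = c("CL1", "CL2", "CL3", "CL4"),
    valid = TRUE, is_element = TRUE, flags = "",
    lf = c(substr(flank1, 1, 60), substr(flank2, 1, 60),
           substr(flank3, 1, 60), substr(flank4, 1, 60)),
    rf = c(substr(flank1, 61, 120), substr(flank2, 61, 120),
           substr(flank3, 61, 120), substr(flank4, 61, 120)))
  cl <- new("ArrayClusterSet",
            membership = S4Vectors::DataFrame(
              array_id = sprintf("TR%06d", 1:4),
              cluster_id = paste0("CL", 1:4),
              orientation = "+", rotation = 0L),
            consensus = c(CL1 = monoA, CL2 = monoB, CL3 = monoC,
                          CL4 = monoD),
            stats = data.frame(), config = configAsList(hineConfig()))
  es <- new("HineElementSet", elements = el,
            members = GenomicRanges::GRanges(), groups = data.frame(),
            report = data.frame(), config = configAsList(hineConfig()))
  g <- groupElements(es, cl)
  got <- stats::setNames(g$group, g$element_id)
  # E1/E2 share flanks and the monomer motif -> group 1;
  # E3/E4 share flanks with unrelated monomers -> group 2
  expect_equal(unname(got[c("E1", "E2")]), c(1L, 1L))
  expect_equal(unname(got[c("E3", "E4")]), c(2L, 2L))
})

test_that("a single element is trivially group 3", {
  el <- S4Vectors::DataFrame(element_id = "E1", unit_id = "U_1",
                             clusters = "CL1", valid = TRUE,
                             is_element = TRUE, flags = "",
                             lf = randSeq(60), rf = randSeq(60))
  cl <- new("ArrayClusterSet",
            membership = S4Vectors::DataFrame(array_id = "TR000001",
                                              cluster_id = "CL1",
                                              orientation = "+",
                                              rotation = 0L),
            consensus = c(CL1 = randSeq(150)), stats = data.frame(),
            config = configAsList(hineConfig()))
  es <- new("HineElementSet", elements = el,
            members = GenomicRanges::GRanges(), groups = data.frame(),
            report = data.frame(), config = configAsList(hineConfig()))
  g <- groupElements(es, cl)
  expect_equal(g$group, 3L)
})

test_that("the cluster report recomputes totals and percentages", {
  set.seed(82)
  m1 <- randSeq(150)
  m2 <- randSeq(160)
  g <- stats::setNames(paste0(
    randSeq(500), strrep(m1, 2), randSeq(700), strrep(m1, 4),
    randSeq(700), strrep(m2, 5), randSeq(500)), "s1")
  tas <- removeRedundant(detectTandemArrays(validateGenome(g)))
  cl <- clusterArrays(tas)
  rep <- clusterReport(tas, cl, g)
  tot <- rep[rep$cluster_id == "Total", ]
  per <- rep[rep$cluster_id != "Total", ]
  expect_equal(tot$n_arrays, sum(per$n_arrays))
  expect_equal(tot$total_bp, sum(per$total_bp))
  expect_equal(tot$n_monomers, sum(per$n_monomers))
  expect_equal(tot$pct_genome,
               round(100 * tot$total_bp /
                       hineConfig()$genome_size_for_proportion, 4))
  # arrays of 2 and 4 monomers: none >= 5, mean 3.00
  c1 <- per[per$n_arrays == 2, ]
  expect_equal(c1$n_ge5, 0L)
  expect_equal(c1$mean_monomers_per_array, 3.00)
})

test_that("published-table aggregation reproduces the printed totals", {
  tab <- read.delim(system.file("extdata",
                                "cg_hine_published_clusters.tsv",
                                package = "hineminer"))
  agg <- aggregateClusterTable(tab, genome_size = 559e6,
                               n_arrays_whole_set = 14591)
  expect_equal(agg$total_arrays, 7151)
  expect_equal(agg$total_ge5, 1729)
  expect_equal(agg$total_bp, 4758043)
  expect_equal(round(agg$pct_genome, 2), 0.85)
  expect_equal(round(agg$mean_monomers_per_array, 2), 3.62)
  expect_equal(round(agg$mean_gc_pct, 2), 35.78)
})

test_that("GC of an all-AT array region is zero in the report", {
  m <- strrep("ATTA", 40)  # low-complexity guard does not apply to GC math
  expect_equal(gcContent(m), 0)
})
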