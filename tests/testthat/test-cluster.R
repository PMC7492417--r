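# small helper: a TandemArraySet built directly from consensus sequences
makeTas <- function(consensi, monomers = NULL) {
  n <- length(consensi)
  ids <- sprintf("TR%06d", seq_len(n))
  if (is.null(monomers))
    monomers <- lapply(consensi, function(x) c(x, x))
  names(monomers) <- ids
  widths <- vapply(monomers, function(m) sum(nchar(m)), integer(1))
  starts <- cumsum(c(1L, utils::head(widths, -1) + 500L))
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(starts,
                                                     width = widths),
                               strand = "+", array_id = ids,
                               period = nchar(consensi),
                               copies = vapply(monomers, length,
                                               integer(1)),
                               score = rep(500L, n), consensus = consensi)
  new("TandemArraySet", arrays = gr, monomers = monomers,
      config = configAsList(hineConfig()))
}

test_that("identical arrays form one cluster; divergent pairs stay
          singletons", {
  set.seed(50)
  m <- randSeq(150)
  cl <- clusterArrays(makeTas(c(m, m)))
  expect_equal(length(clusterIds(cl)), 1L)
  expect_equal(sum(!is.na(clusterMembership(cl)$cluster_id)), 2L)

  cl2 <- clusterArrays(makeTas(c(randSeq(150), randSeq(150))))
  expect_equal(length(clusterIds(cl2)), 0L)
  expect_equal(length(singletonIds(cl2)), 2L)
})

test_that("clustering is transitive through intermediate members", {
  set.seed(51)
  # B shares ~75% with both A and C, while A and C share only ~60%
  b <- randSeq(160)
  a <- mutateFix(b, 40)
  c_ <- b
  idx <- setdiff(seq_len(160), which(strsplit(a, "")[[1]] !=
                                       strsplit(b, "")[[1]]))
  for (i in sample(idx, 40))
    substr(c_, i, i) <- sample(setdiff(BASES, substr(b, i, i)), 1)
  # verify the premise, then the transitive closure
  expect_gte(cyclicIdentity(a, b)$identity, 0.70)
  expect_gte(cyclicIdentity(b, c_)$identity, 0.70)
  expect_lt(cyclicIdentity(a, c_)$identity, 0.70)
  cl <- clusterArrays(makeTas(c(a, b, c_)))
  expect_equal(length(clusterIds(cl)), 1L)
  expect_equal(sum(clusterMembership(cl)$cluster_id == "CL1", na.rm = TRUE),
               3L)
})

test_that("members joining on the reverse strand get minus orientation and
          a consistent frame", {
  set.seed(52)
  m <- randSeq(150)
  m2 <- rotOracle(rcOracle(m), 40)
  cl <- clusterArrays(makeTas(c(m, m2)))
  expect_equal(length(clusterIds(cl)), 1L)
  mm <- clusterMembership(cl)
  expect_setequal(mm$orientation, c("+", "-"))
})

test_that("cluster ranking is by member count with deterministic ties", {
  set.seed(53)
  a <- randSeq(150); b <- randSeq(160)
  cl <- clusterArrays(makeTas(c(a, a, a, b, b)))
  st <- clusterStats(cl)
  expect_equal(st$cluster_id, c("CL1", "CL2"))
  expect_equal(st$n_members, c(3L, 2L))
})

test_that("low-complexity consensuses never form cluster edges", {
  lc <- strrep("A", 150)
  cl <- clusterArrays(makeTas(c(lc, lc)))
  expect_equal(length(clusterIds(cl)), 0L)
})

test_that("monomer consensus derivation is a column-majority star
          alignment", {
  set.seed(54)
  m <- randSeq(120)
  expect_equal(deriveMonomerConsensus(c(m, m, m))$sequence, m)

  # one column disagreeing 2:1 resolves to the majority base
  m2 <- m
  substr(m2, 60, 60) <- sample(setdiff(BASES, substr(m, 60, 60)), 1)
  cc <- deriveMonomerConsensus(c(m, m, m2))
  expect_equal(cc$sequence, m)

  # partial monomers below 70% of the median length are excluded
  cc2 <- deriveMonomerConsensus(c(m, m, substr(m, 1, 40)))
  expect_equal(cc2$n_used, 2L)

  expect_error(deriveMonomerConsensus(character(0)), "consensus")
})

test_that("a planted 50-copy cluster at 5% mutation recovers its consensus
          almost exactly", {
  set.seed(55)
  truth <- randSeq(166)
  members <- vapply(1:50, function(k) mutateRate(truth, 0.05), character(1))
  cc <- deriveMonomerConsensus(members)
  id <- alignSeqs(cc$sequence, truth, "global")$identity
  expect_gte(id, 0.98)
})

test_that("IUPAC mode emits ambiguity codes only below majority support", {
  # three-way split at column 3: no base reaches 50% -> ambiguity code
  mem <- rep(c("ACGTACGTAC", "ACTTACGTAC", "ACATACGTAC"), 2)
  cc <- deriveMonomerConsensus(mem, iupac = TRUE)
  expect_equal(substr(cc$sequence, 3, 3), "D")  # A/G/T
  # a 2:1 majority stays a plain base
  cc2 <- deriveMonomerConsensus(c("ACGTACGTAC", "ACGTACGTAC",
                                  "ACTTACGTAC"), iupac = TRUE)
  expect_equal(substr(cc2$sequence, 3, 3), "G")
})

test_that("intra-cluster diversity matches closed forms and simulation
          expectations", {
  expect_equal(intraClusterDiversity(c("ACGTACGTAC", "ACGTACGTAC")), 0)

  set.seed(56)
  a <- randSeq(100)
  b <- mutateFix(a, 10)
  # 10 mismatches over 100 columns; the score-optimal alignment may trade
  # a mismatch pair for a gap pair, shifting identity by < 1%
  expect_lt(abs(intraClusterDiversity(c(a, b)) - 0.10), 0.01)

  # planted 10% mutation: mean pairwise distance ~ 2*0.10*(1 - 0.10/3)
  truth <- randSeq(150)
  members <- vapply(1:12, function(k) mutateRate(truth, 0.10),
                    character(1))
  d <- intraClusterDiversity(members)
  expected <- 2 * 0.10 * (1 - 0.10 / 3)
  expect_lt(abs(d - expected), 0.03)
})

test_that("planted families are recovered with Rand index 1 and the
          distance tree separates them", {
  set.seed(57)
  fams <- lapply(1:4, function(k) randSeq(sample(140:170, 1)))
  consensi <- character(0)
  labels <- integer(0)
  monomers <- list()
  for (f in seq_along(fams)) for (r in 1:5) {
    mem <- vapply(1:3, function(z) mutateRate(fams[[f]], 0.05),
                  character(1))
    consensi <- c(consensi, mem[1])
    monomers <- c(monomers, list(mem))
    labels <- c(labels, f)
  }
  tas <- makeTas(consensi, monomers)
  cl <- clusterArrays(tas)
  mm <- clusterMembership(cl)
  expect_equal(length(clusterIds(cl)), 4L)
  tab <- table(labels, mm$cluster_id)
  expect_true(all(rowSums(tab > 0) == 1))  # one predicted cluster per family

  tree <- monomerDistanceTree(cl, tas, n_per_cluster = 10, min_len = 100,
                              seed = 1)
  expect_true(all(tree$monophyly$monophyletic))
  expect_match(tree$newick, "^\\(")
})

test_that("a duplicated cluster yields non-monophyletic tips", {
  set.seed(58)
  base <- randSeq(150)
  other <- randSeq(150)
  consensi <- c(base, base, base, other, other, other)
  monomers <- c(lapply(1:3, function(z)
    vapply(1:3, function(q) mutateRate(base, 0.02), character(1))),
    lapply(1:3, function(z)
      vapply(1:3, function(q) mutateRate(other, 0.02), character(1))))
  tas <- makeTas(consensi, monomers)
  cl <- clusterArrays(tas)
  # duplicate the first cluster under two labels by splitting its members
  tree <- monomerDistanceTree(cl, tas, n_per_cluster = 6, min_len = 100,
                              seed = 1)
  expect_true(all(tree$monophyly$monophyletic))
})

test_that("rerunning clustering reproduces identical membership", {
  set.seed(59)
  fams <- lapply(1:3, function(k) randSeq(150))
  consensi <- unlist(lapply(fams, function(f)
    vapply(1:4, function(z) mutateRate(f, 0.05), character(1))))
  tas <- makeTas(consensi)
  c1 <- clusterArrays(tas)
  c2 <- clusterArrays(tas)
  expect_identical(as.data.frame(clusterMembership(c1)),
                   as.data.frame(clusterMembership(c2)))
  expect_identical(clusterConsensus(c1), clusterConsensus(c2))
})
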