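#' Extract flanking sequence pairs for every array
#'
#' Up to \code{flank_len} bp (default 4,000) is taken from each side of each
#' array, truncated at scaffold bounds, in genomic orientation (the left
#' flank ends at the array start, the right flank starts at the array end).
#' Pairs at a scaffold edge or containing \code{N} are flagged; flagged pairs
#' are excluded from consensus building downstream.
#'
#' @param tas a \linkS4class{TandemArraySet}.
#' @param genome the genome \code{DNAStringSet}.
#' @param cfg a \linkS4class{HineConfig}.
#' @return a \code{DataFrame}: \code{array_id}, \code{left_seq},
#'   \code{right_seq}, \code{at_scaffold_edge}, \code{contains_N}.
#' @export
extractFlanks <- function(tas, genome, cfg = hineConfig()) {
  stopifnot(methods::is(tas, "TandemArraySet"))
  genome <- validateGenome(genome)
  gr <- tas@arrays
  n <- length(gr)
  left <- right <- character(n)
  edge <- hasN <- logical(n)
  for (i in seq_len(n)) {
    sc <- as.character(GenomicRanges::seqnames(gr))[i]
    fl <- .flankPair(genome, sc, GenomicRanges::start(gr)[i],
                     GenomicRanges::end(gr)[i], cfg$flank_len)
    left[i] <- fl$left; right[i] <- fl$right
    edge[i] <- fl$edge; hasN[i] <- fl$hasN
  }
  S4Vectors::DataFrame(array_id = arrayIds(tas), left_seq = left,
                       right_seq = right, at_scaffold_edge = edge,
                       contains_N = hasN)
}

# backoff > 0 keeps that many array-edge bases in each flank window, which
# absorbs the +/-1-2 bp ambiguity of detected array boundaries (a boundary
# base matching the consensus by chance is indistinguishable from a true
# array base) so that consensus building never loses flank head bases
.flankPair <- function(genome, scaffold, start, end, flank_len,
                       backoff = 0L) {
  seq <- genome[[scaffold]]
  n <- length(seq)
  ls <- max(1L, start - flank_len)
  le <- min(n, start - 1L + backoff)
  left <- if (le >= ls && start > 1L)
    as.character(Biostrings::subseq(seq, ls, le)) else ""
  re <- min(n, end + flank_len)
  rs <- max(1L, end + 1L - backoff)
  right <- if (end < n && re >= rs)
    as.character(Biostrings::subseq(seq, rs, re)) else ""
  list(left = left, right = right,
       edge = (start == 1L || end == n),
       hasN = grepl("N", left, fixed = TRUE) ||
         grepl("N", right, fixed = TRUE))
}

#' Global-alignment identity of a member flank window against a consensus
#'
#' @param member member flank window (character).
#' @param consensus flank consensus sequence.
#' @param cfg a \linkS4class{HineConfig} (alignment weights).
#' @return identity fraction (matches / alignment columns).
#' @export
flankMemberIdentity <- function(member, consensus, cfg = hineConfig()) {
  cpp_align(.checkSeq(member, "member"), .checkSeq(consensus, "consensus"),
            cfg$tr_match, cfg$tr_mismatch, cfg$tr_indel, FALSE)$identity
}

#' Derive LF and RF consensus sequences for one element unit
#'
#' Two-round procedure on orientation-normalized member flanks. The left
#' (LF) consensus must tolerate the variable 10-500 bp linker between the LF
#' module and the first repeat, so round 1 seeds column support by locally
#' aligning every member's array-proximal window (600 bp) onto a
#' deterministic reference member and trimming to the maximal block whose
#' column support exceeds \code{flank_support}; round 2 re-aligns all members
#' to the round-1 consensus and re-derives it. The right (RF) consensus is
#' 5'-anchored at the array end: round 1 is a positional column consensus
#' over the \code{rf_window} (60 bp), round 2 the same local refinement. LF
#' is bounded to 40-120 bp (3'-most block kept), RF to the supported block
#' within 60 bp. A unit with fewer than 5 eligible members, or whose
#' supported block is shorter than 20 bp, yields a no-consensus result with
#' a reason.
#'
#' @param left_flanks,right_flanks character vectors of orientation-normalized
#'   member flanks (left ends at the array start; right starts at the array
#'   end).
#' @param cfg a \linkS4class{HineConfig}.
#' @return list with \code{lf}, \code{rf} (character or \code{NA}),
#'   \code{lf_support}, \code{rf_support} (supporting member counts),
#'   \code{n_eligible}, \code{lf_mean_identity}, \code{rf_mean_identity},
#'   \code{valid}, \code{reason}.
#' @export
deriveFlankConsensus <- function(left_flanks, right_flanks,
                                 cfg = hineConfig()) {
  stopifnot(length(left_flanks) == length(right_flanks))
  n <- length(left_flanks)
  res <- list(lf = NA_character_, rf = NA_character_, lf_support = 0L,
              rf_support = 0L, n_eligible = n, lf_mean_identity = NA_real_,
              rf_mean_identity = NA_real_, valid = FALSE, reason = "")
  if (n < 5L) {
    res$reason <- "fewer than 5 eligible members"
    return(res)
  }
  lf <- .deriveLF(left_flanks, cfg)
  rf <- .deriveRF(right_flanks, cfg)
  res$lf <- lf$consensus; res$rf <- rf$consensus
  res$lf_support <- lf$n_support; res$rf_support <- rf$n_support
  res$lf_mean_identity <- lf$mean_identity
  res$rf_mean_identity <- rf$mean_identity
  if (is.na(lf$consensus) || is.na(rf$consensus)) {
    res$reason <- paste0(if (is.na(lf$consensus)) "no supported LF block; ",
                         if (is.na(rf$consensus)) "no supported RF block")
    return(res)
  }
  ok_support <- lf$n_support / n > cfg$flank_support &&
    rf$n_support / n > cfg$flank_support
  ok_ident <- lf$mean_identity > cfg$flank_identity &&
    rf$mean_identity > cfg$flank_identity
  if (!ok_support) res$reason <- "flank support below threshold"
  else if (!ok_ident) res$reason <- "member identity below threshold"
  res$valid <- ok_support && ok_ident
  res
}

.deriveLF <- function(left_flanks, cfg, window = 600L) {
  win <- vapply(left_flanks, function(x) {
    n <- nchar(x)
    substr(x, max(1L, n - window + 1L), n)
  }, character(1), USE.NAMES = FALSE)
  win <- win[nchar(win) >= 20L]
  if (length(win) < 2L)
    return(list(consensus = NA_character_, n_support = 0L,
                mean_identity = NA_real_))
  ref <- .pickReference(win)
  r1 <- .supportedBlockConsensus(ref, win, cfg, anchor = "right",
                                 max_len = 120L)
  if (is.na(r1$consensus))
    return(list(consensus = NA_character_, n_support = 0L,
                mean_identity = NA_real_))
  r2 <- .supportedBlockConsensus(r1$consensus, win, cfg, anchor = "right",
                                 max_len = 120L)
  if (is.na(r2$consensus)) r2 <- r1
  # the LF 5' edge is the element terminus (subTIR start); repair leading
  # bases lost to member-level edge trimming
  ext <- .extendConsensusLeft(r2$consensus, win, cfg)
  # the LF 3' end is the microsatellite tail, where periodic slippage in
  # member alignments smears column support; repair trailing units the
  # same way
  ext <- .extendConsensusRight(ext, win, cfg, max_ext = 12L)
  if (nchar(ext) > nchar(r2$consensus))
    r2 <- c(list(consensus = ext), .supportStats(ext, win, cfg))
  r2
}

.extendConsensusRight <- function(consensus, windows, cfg, max_ext = 6L) {
  n <- length(windows)
  for (it in seq_len(max_ext)) {
    votes <- character(0)
    L <- nchar(consensus)
    for (s in windows) {
      al <- cpp_align(s, consensus, cfg$tr_match, cfg$tr_mismatch,
                      cfg$tr_indel, TRUE)
      if (al$b_end == L && al$a_end < nchar(s))
        votes <- c(votes, substr(s, al$a_end + 1L, al$a_end + 1L))
    }
    if (length(votes) < 0.3 * n) break
    tab <- sort(table(votes), decreasing = TRUE)
    if (tab[1L] <= cfg$flank_support * length(votes)) break
    consensus <- paste0(consensus, names(tab)[1L])
  }
  consensus
}

# RF is 5'-anchored at the array end, but detected array ends jitter by a
# couple of bases, so round 1 seeds column support on a reference member
# window (as for LF) rather than on raw positions; the supported block is
# then trimmed left-anchored to the RF window length.
.deriveRF <- function(right_flanks, cfg) {
  win <- vapply(right_flanks, function(x)
    substr(x, 1L, min(nchar(x), cfg$rf_window + 20L)), character(1),
    USE.NAMES = FALSE)
  win <- win[nchar(win) >= 20L]
  if (length(win) < 2L)
    return(list(consensus = NA_character_, n_support = 0L,
                mean_identity = NA_real_))
  ref <- .pickReference(win)
  max_rf <- cfg$rf_window + 6L  # window plus the array-edge backoff
  r1 <- .supportedBlockConsensus(ref, win, cfg, anchor = "left",
                                 max_len = max_rf)
  if (is.na(r1$consensus))
    return(list(consensus = NA_character_, n_support = 0L,
                mean_identity = NA_real_))
  r2 <- .supportedBlockConsensus(r1$consensus, win, cfg, anchor = "left",
                                 max_len = max_rf)
  if (is.na(r2$consensus)) r2 <- r1
  # repair leading bases lost to reference-member boundary jitter: members
  # whose alignment dangles left of the consensus vote for prepended columns
  ext <- .extendConsensusLeft(r2$consensus, win, cfg)
  if (nchar(ext) > nchar(r2$consensus))
    r2 <- c(list(consensus = ext), .supportStats(ext, win, cfg))
  # RF must be 5'-anchored at the array end: a supported block that members
  # place deep inside their windows is not an RF (e.g. the LF microsatellite
  # seen through the variable linker in a wrongly oriented unit)
  if (!is.na(r2$consensus) && !is.na(r2$median_offset) &&
      r2$median_offset > 10)
    return(list(consensus = NA_character_, n_support = 0L,
                mean_identity = NA_real_))
  r2
}

# round-1 reference: the member window sharing the most 8-mers with the
# others (a member with mis-detected boundaries shares few and is never
# picked); ties resolve to the first member
.pickReference <- function(windows, k = 8L) {
  n <- length(windows)
  if (n <= 2L) return(windows[[1L]])
  tot <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      tot[i] <- tot[i] + cpp_kmer_share(windows[[j]], windows[[i]], k)
    }
  }
  windows[[which.max(tot)]]
}

.extendConsensusLeft <- function(consensus, windows, cfg, max_ext = 5L) {
  n <- length(windows)
  for (it in seq_len(max_ext)) {
    votes <- character(0)
    for (s in windows) {
      al <- cpp_align(s, consensus, cfg$tr_match, cfg$tr_mismatch,
                      cfg$tr_indel, TRUE)
      if (al$b_start == 1L && al$a_start > 1L)
        votes <- c(votes, substr(s, al$a_start - 1L, al$a_start - 1L))
    }
    if (length(votes) < 0.3 * n) break
    tab <- sort(table(votes), decreasing = TRUE)
    if (tab[1L] <= cfg$flank_support * length(votes)) break
    consensus <- paste0(names(tab)[1L], consensus)
  }
  consensus
}

# Local-alignment column support of member windows on a reference; the
# consensus is the plurality base over the maximal contiguous block of
# columns whose support exceeds flank_support.
.supportedBlockConsensus <- function(ref, windows, cfg, anchor = "right",
                                     max_len = 120L, min_block = 20L) {
  L <- nchar(ref)
  lv <- c("A", "C", "G", "T", "N")
  counts <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(lv, NULL))
  covered <- integer(L)
  idents <- numeric(0)
  n <- length(windows)
  for (s in windows) {
    al <- cpp_align(s, ref, cfg$tr_match, cfg$tr_mismatch, cfg$tr_indel, TRUE)
    if (al$b_end < al$b_start) next
    tr <- strsplit(al$transcript, "", fixed = TRUE)[[1L]]
    sv <- strsplit(s, "", fixed = TRUE)[[1L]]
    i <- al$a_start - 1L; j <- al$b_start - 1L
    for (op in tr) {
      if (op == "=" || op == "X") {
        i <- i + 1L; j <- j + 1L
        counts[sv[i], j] <- counts[sv[i], j] + 1L
        covered[j] <- covered[j] + 1L
      } else if (op == "I") i <- i + 1L
      else j <- j + 1L
    }
    idents <- c(idents, al$identity)
  }
  support <- covered / n
  ok <- support > cfg$flank_support
  blk <- .maximalRun(ok)
  if (is.null(blk) || diff(blk) + 1L < min_block)
    return(list(consensus = NA_character_, n_support = 0L,
                mean_identity = NA_real_))
  lo <- blk[1L]; hi <- blk[2L]
  if (hi - lo + 1L > max_len) {
    if (anchor == "right") lo <- hi - max_len + 1L else hi <- lo + max_len - 1L
  }
  basec <- counts[c("A", "C", "G", "T"), lo:hi, drop = FALSE]
  consensus <- paste(rownames(basec)[apply(basec, 2L, which.max)],
                     collapse = "")
  c(list(consensus = consensus), .supportStats(consensus, windows, cfg))
}

# supporting member: covers >= 80% of the consensus with identity above
# the configured floor
.supportStats <- function(consensus, windows, cfg) {
  n_support <- 0L
  idents <- numeric(0)
  offsets <- numeric(0)
  for (s in windows) {
    al <- cpp_align(s, consensus, cfg$tr_match, cfg$tr_mismatch,
                    cfg$tr_indel, TRUE)
    cov <- (al$b_end - al$b_start + 1L) / nchar(consensus)
    if (cov >= 0.8 && al$identity >= cfg$flank_identity) {
      n_support <- n_support + 1L
      idents <- c(idents, al$identity)
      offsets <- c(offsets, al$a_start - al$b_start)
    }
  }
  list(n_support = n_support,
       mean_identity = if (length(idents)) mean(idents) else NA_real_,
       median_offset = if (length(offsets)) stats::median(offsets) else
         NA_real_)
}

.maximalRun <- function(ok) {
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(starts[best], ends[best])
}

#' Propagate flank-determined orientation flips to the unit tables
#'
#' When \code{\link{profileFlanks}} flipped a unit (the flanks showed the
#' cluster representative was in element-reverse orientation), member
#' orientations and the cluster order of paired units must be flipped to
#' match before element assembly.
#'
#' @param units unit/member tables from \code{\link{detectDoubleArrays}}.
#' @param flanks the \linkS4class{FlankConsensusSet}.
#' @return the corrected unit tables.
#' @export
applyOrientationFlips <- function(units, flanks) {
  fu <- flankUnits(flanks)
  for (uid in fu$unit_id[fu$flipped %in% TRUE]) {
    sel <- units$members$unit_id == uid
    units$members$orientation[sel] <-
      ifelse(units$members$orientation[sel] == "-", "+", "-")
    usel <- units$units$unit_id == uid
    units$units$clusters[usel] <- paste(
      rev(strsplit(units$units$clusters[usel], ",")[[1L]]), collapse = ",")
  }
  units
}

# prefer the flipped orientation only on clear evidence: validity first,
# then RF support, then total support; ties keep the original
.preferFlip <- function(fc, fc_flip) {
  key <- function(x) c(as.integer(isTRUE(x$valid)),
                       as.integer(x$rf_support > 0), x$rf_support,
                       x$lf_support)
  a <- key(fc); b <- key(fc_flip)
  for (t in seq_along(a)) {
    if (b[t] > a[t]) return(TRUE)
    if (a[t] > b[t]) return(FALSE)
  }
  FALSE
}

#' Derive flank consensus sequences for every element unit
#'
#' Orchestrates flank profiling over element units (one per cluster, or one
#' per ordered cluster pair for double-array elements, see
#' \code{\link{detectDoubleArrays}}): member element loci are
#' orientation-normalized, eligible flank pairs (not at a scaffold edge, no
#' \code{N}) are collected, and \code{\link{deriveFlankConsensus}} is applied
#' per unit.
#'
#' @param tas a \linkS4class{TandemArraySet}.
#' @param clusters an \linkS4class{ArrayClusterSet}.
#' @param genome the genome \code{DNAStringSet}.
#' @param cfg a \linkS4class{HineConfig}.
#' @param units optional unit table from \code{\link{detectDoubleArrays}};
#'   by default every cluster is its own single-array unit.
#' @return a \linkS4class{FlankConsensusSet}.
#' @export
profileFlanks <- function(tas, clusters, genome, cfg = hineConfig(),
                          units = NULL) {
  stopifnot(methods::is(tas, "TandemArraySet"),
            methods::is(clusters, "ArrayClusterSet"))
  genome <- validateGenome(genome)
  if (is.null(units)) units <- detectDoubleArrays(tas, clusters, cfg)
  members <- units$members
  unit_tab <- units$units
  rows <- list()
  member_flanks <- list()
  for (u in seq_len(nrow(unit_tab))) {
    uid <- unit_tab$unit_id[u]
    mem <- members[members$unit_id == uid & members$complete, , drop = FALSE]
    lf_in <- rf_in <- character(0)
    keep_keys <- character(0)
    for (r in seq_len(nrow(mem))) {
      fl <- .flankPair(genome, mem$scaffold[r], mem$start[r], mem$end[r],
                       cfg$flank_len, backoff = 6L)
      if (fl$edge || fl$hasN) next
      if (identical(mem$orientation[r], "-")) {
        lf_m <- if (nzchar(fl$right)) revComp(fl$right) else ""
        rf_m <- if (nzchar(fl$left)) revComp(fl$left) else ""
      } else {
        lf_m <- fl$left; rf_m <- fl$right
      }
      if (!nzchar(lf_m) || !nzchar(rf_m)) next
      lf_in <- c(lf_in, lf_m); rf_in <- c(rf_in, rf_m)
      keep_keys <- c(keep_keys, mem$member_key[r])
    }
    # The cluster orientation is anchored to an arbitrary representative
    # array, but the element orientation is defined by the flanks (RF abuts
    # the array directly, LF sits behind the variable linker). Derive both
    # ways and keep the orientation whose RF consensus is supported.
    fc <- deriveFlankConsensus(lf_in, rf_in, cfg)
    fc_flip <- deriveFlankConsensus(revComp(rf_in), revComp(lf_in), cfg)
    flipped <- .preferFlip(fc, fc_flip)
    if (flipped) {
      fc <- fc_flip
      tmp <- lf_in
      lf_in <- revComp(rf_in)
      rf_in <- revComp(tmp)
    }
    rows[[u]] <- S4Vectors::DataFrame(
      unit_id = uid,
      clusters = if (flipped)
        paste(rev(strsplit(unit_tab$clusters[u], ",")[[1L]]),
              collapse = ",") else unit_tab$clusters[u],
      lf = fc$lf, rf = fc$rf, lf_support = fc$lf_support,
      rf_support = fc$rf_support, n_eligible = fc$n_eligible,
      lf_mean_identity = fc$lf_mean_identity,
      rf_mean_identity = fc$rf_mean_identity,
      valid = fc$valid, reason = fc$reason, flipped = flipped)
    member_flanks[[uid]] <- data.frame(member_key = keep_keys,
                                       lf = lf_in, rf = rf_in,
                                       stringsAsFactors = FALSE)
  }
  unit_df <- if (length(rows)) do.call(rbind, rows) else
    S4Vectors::DataFrame(unit_id = character(), clusters = character(),
                         lf = character(), rf = character(),
                         lf_support = integer(), rf_support = integer(),
                         n_eligible = integer(),
                         lf_mean_identity = numeric(),
                         rf_mean_identity = numeric(), valid = logical(),
                         reason = character(), flipped = logical())
  methods::new("FlankConsensusSet", units = unit_df,
               member_flanks = member_flanks, config = configAsList(cfg))
}
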