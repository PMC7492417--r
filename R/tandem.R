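#' Detect satellite-like tandem-repeat arrays
#'
#' Genome-wide detection of tandem arrays with 100-500 bp monomers and at
#' least two copies. Candidate periods are seeded by exact 12-mer matches at
#' distances inside the period window, seed evidence is merged into candidate
#' loci, the monomer is polished once by column majority over period-phased
#' chunks, and boundaries are refined by local wraparound dynamic programming
#' against the polished consensus. An array is reported when its wraparound
#' score against its own cyclic consensus reaches the configured minimum
#' (default 50 under weights +2/-7/-7), its fundamental period lies within
#' the period window, and its copy number reaches the minimum. Arrays
#' containing \code{N} are rejected. Detection is strand-symmetric: a tandem
#' array is its own feature on both strands and is reported on \code{+}.
#'
#' @param genome a \code{DNAStringSet} (or named character vector).
#' @param cfg a \linkS4class{HineConfig}.
#' @param verbose emit per-scaffold progress messages.
#' @return a \linkS4class{TandemArraySet}, sorted by (scaffold, start).
#'   Overlapping reports of the same locus may remain; apply
#'   \code{\link{removeRedundant}} to resolve them.
#' @export
detectTandemArrays <- function(genome, cfg = hineConfig(), verbose = FALSE) {
  genome <- validateGenome(genome)
  k <- 12L
  recs <- list()
  for (sc in names(genome)) {
    seq <- as.character(genome[[sc]])
    n <- nchar(seq)
    if (n < 2L * cfg$period_min) {
      if (verbose) message("scaffold '", sc, "' shorter than twice the ",
                           "minimum period; skipped")
      next
    }
    hits <- cpp_seed_hits(seq, k, cfg$period_min - 10L, cfg$period_max + 10L)
    if (nrow(hits) == 0L) next
    ord <- order(hits[, "pos"])
    pos <- hits[ord, "pos"]
    dst <- hits[ord, "dist"]
    groups <- .splitSeedGroups(pos, dst, gap = cfg$period_max + 10L)
    for (g in groups) {
      out <- .processSeedGroup(seq, g$pos, g$dist, k, cfg)
      if (length(out)) recs <- c(recs, lapply(out, function(r) {
        r$scaffold <- sc
        r
      }))
    }
  }
  .newTandemArraySet(recs, genome, cfg)
}

.splitSeedGroups <- function(pos, dst, gap) {
  if (!length(pos)) return(list())
  brk <- c(0L, which(diff(pos) > gap), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    list(pos = pos[idx], dist = dst[idx])
  })
}

# Iteratively refine one seed group, one distance mode at a time:
# consecutive distinct arrays chained into a single group (e.g. the two
# arrays of a double-array element, often with periods differing by one)
# are peeled off candidate by candidate. An accepted candidate consumes all
# seed evidence under its span; a rejected one consumes only the evidence
# of its own distance mode, so a neighbouring array with a slightly
# different period is still refined on its own terms.
.processSeedGroup <- function(seq, pos, dst, k, cfg, min_hits = 5L,
                              max_rounds = 60L) {
  out <- list()
  queue <- list(list(pos = pos, dist = dst))
  rounds <- 0L
  while (length(queue) && rounds < max_rounds) {
    rounds <- rounds + 1L
    g <- queue[[1L]]
    queue <- queue[-1L]
    if (length(g$pos) < min_hits) next
    tabd <- table(g$dist)
    m <- as.integer(names(tabd)[which.max(tabd)])
    selm <- g$dist == m
    if (sum(selm) < min_hits) selm <- rep(TRUE, length(g$pos))
    cand <- .refineCandidate(seq, g$pos[selm], g$dist[selm], k, cfg)
    if (!is.null(cand$record)) {
      out[[length(out) + 1L]] <- cand$record
      keep <- g$pos < cand$consumed[1L] - k | g$pos > cand$consumed[2L]
    } else {
      keep <- !(selm & g$pos >= cand$consumed[1L] - k &
                  g$pos <= cand$consumed[2L])
    }
    if (any(keep)) {
      sub <- .splitSeedGroups(g$pos[keep], g$dist[keep],
                              gap = cfg$period_max + 10L)
      queue <- c(queue, Filter(function(s) length(s$pos) >= min_hits, sub))
    }
  }
  out
}

.refineCandidate <- function(seq, pos, dst, k, cfg) {
  n <- nchar(seq)
  tab <- table(dst)
  p0 <- as.integer(names(tab)[which.max(tab)])
  lo <- min(pos)
  hi <- min(n, max(pos + dst) + k - 1L)
  reject <- list(record = NULL, consumed = c(lo, hi))

  cons <- .polishConsensus(seq, lo, hi, p0)
  if (is.null(cons)) return(reject)
  fp <- .fundamentalPeriod(cons)
  if (fp < nchar(cons)) {
    if (fp < cfg$period_min) return(reject)
    cons <- .polishConsensus(seq, lo, hi, fp)
    if (is.null(cons)) return(reject)
    p0 <- fp
  }
  p0 <- nchar(cons)
  if (p0 < cfg$period_min || p0 > cfg$period_max) return(reject)

  # round 1: boundaries from the seed-anchored consensus
  wlo <- max(1L, lo - p0 - 30L)
  whi <- min(n, hi + p0 + 30L)
  wa <- cpp_wraparound(substr(seq, wlo, whi), cons, cfg$tr_match,
                       cfg$tr_mismatch, cfg$tr_indel, TRUE)
  if (wa$end < wa$start) return(reject)
  g1s <- wlo + wa$start - 1L
  g1e <- wlo + wa$end - 1L

  # round 2: re-polish the monomer in the phase of the detected span,
  # letting the period move by +/-1 (seed distances can be off by one).
  # Each candidate period is carried through boundary refinement to its
  # final span; the true period is the one whose period-consistency refit
  # holds the longest span (an off-by-one period drifts out of register
  # and its refit collapses), with ties resolved towards the modal seed
  # distance, then by score. Neither the local nor the global DP score
  # discriminates +/-1-bp period errors directly, because gaps absorb the
  # drift and a single-chunk consensus fits itself exactly.
  best <- NULL
  for (p in unique(pmin(cfg$period_max,
                        pmax(cfg$period_min, p0 + (-1:1))))) {
    cand <- .evaluatePeriod(seq, g1s, g1e, p, cfg)
    if (is.null(cand)) next
    cand$span <- cand$end - cand$start + 1L
    if (is.null(best) || cand$span > best$span ||
        (cand$span == best$span &&
           abs(cand$period - p0) < abs(best$period - p0)) ||
        (cand$span == best$span &&
           abs(cand$period - p0) == abs(best$period - p0) &&
           cand$score > best$score))
      best <- cand
  }
  if (is.null(best)) return(reject)
  cons <- best$cons
  p0 <- best$period
  gstart <- best$start
  gend <- best$end
  region <- substr(seq, gstart, gend)
  consumed <- c(gstart, gend)
  if (grepl("N", region, fixed = TRUE))
    return(list(record = NULL, consumed = consumed))

  monomers <- .chopMonomers(region, p0)
  sc <- cpp_wraparound(region, cons, cfg$tr_match, cfg$tr_mismatch,
                       cfg$tr_indel, FALSE)$score
  # a chunk-majority re-polish helps when the chunks are in register but
  # can be badly out of frame when the reported period is off by one;
  # keep it only when it scores at least as well
  full <- monomers[nchar(monomers) == p0]
  if (length(full) >= 2L) {
    cons2 <- .majorityConsensus(full)
    if (nchar(cons2) == p0) {
      sc2 <- cpp_wraparound(region, cons2, cfg$tr_match, cfg$tr_mismatch,
                            cfg$tr_indel, FALSE)$score
      if (sc2 >= sc) {
        cons <- cons2
        sc <- sc2
      }
    }
  }
  copies <- round(nchar(region) / p0, 1)
  if (sc < cfg$tr_min_score || copies < cfg$min_copies)
    return(list(record = NULL, consumed = consumed))
  list(record = list(start = gstart, end = gend, period = p0,
                     copies = copies, score = sc, consensus = cons,
                     monomers = monomers),
       consumed = consumed)
}

# One candidate period carried end-to-end: polish the consensus in the
# detected phase, find boundaries by local wraparound DP, refine them by
# period consistency, and score the final span globally. The refit is
# trusted outright where it EXTENDS the DP span (mutated true edges are
# period-consistent yet locally score-negative under the heavy mismatch
# penalty); where it SHRINKS the span the boundary pair is arbitrated by
# global score -- a few chance-matching flank bases gain little (refit
# wins within a margin of 10) while a real indel-shifted copy the
# ungapped refit cannot see gains a lot (DP wins). Near-tied spans prefer
# one clearing the copy floor, then the shortest.
.evaluatePeriod <- function(seq, g1s, g1e, p, cfg) {
  n <- nchar(seq)
  cons <- .polishConsensus(seq, g1s, g1e, p)
  if (is.null(cons) || nchar(cons) != p) return(NULL)
  wlo <- max(1L, g1s - p - 30L)
  whi <- min(n, g1e + p + 30L)
  wa <- cpp_wraparound(substr(seq, wlo, whi), cons, cfg$tr_match,
                       cfg$tr_mismatch, cfg$tr_indel, TRUE)
  if (wa$end < wa$start) return(NULL)
  ws <- wlo + wa$start - 1L
  we <- wlo + wa$end - 1L
  ext <- .extendByPeriodicity(seq, ws, we, p)
  lefts <- if (ext[1L] <= ws) ext[1L] else unique(c(ext[1L], ws))
  rights <- if (ext[2L] >= we) ext[2L] else unique(c(ext[2L], we))
  spans <- NULL
  for (ls in lefts) for (rs in rights) {
    if (rs - ls + 1L < p) next
    sc0 <- cpp_wraparound(substr(seq, ls, rs), cons, cfg$tr_match,
                          cfg$tr_mismatch, cfg$tr_indel, FALSE)$score
    spans <- rbind(spans, data.frame(ls = ls, rs = rs, sc = sc0))
  }
  if (is.null(spans)) return(NULL)
  top <- max(spans$sc)
  okr <- spans[spans$sc >= top - 10L, , drop = FALSE]
  okr$meets <- round((okr$rs - okr$ls + 1L) / p, 1) >= cfg$min_copies
  okr <- okr[order(-okr$meets, okr$rs - okr$ls, -okr$sc), , drop = FALSE]
  list(score = okr$sc[1L], start = okr$ls[1L], end = okr$rs[1L],
       cons = cons, period = p)
}

# The local DP boundary can both under-shoot (mutated edge bases are
# locally unprofitable) and over-shoot (short chance matches against the
# rotated consensus, possibly via a gap, drag the boundary into the
# flank). Both are corrected by a period-consistency refit: scanning one
# period inward to one period outward of each DP boundary, each position
# scores +0.4 when it matches the base one period inside the array and
# -0.6 otherwise (a 60%-identity balance point: generous to mutated true
# edges, still strongly negative against ~25%-matching flank), and the
# boundary is placed at the maximal partial sum. Ties take the innermost
# position.
.extendByPeriodicity <- function(seq, gstart, gend, period) {
  n <- nchar(seq)
  # right boundary: walk from (gend - period) outward to (gend + period)
  anchor_r <- max(gstart + period - 1L, gend - period)
  best_q <- anchor_r; run <- 0; best_run <- 0
  q <- anchor_r
  while (q < min(n, gend + period)) {
    q <- q + 1L
    m <- substr(seq, q, q) == substr(seq, q - period, q - period) &&
      substr(seq, q, q) != "N"
    run <- run + (if (m) 0.4 else -0.6)
    if (run > best_run + 1e-9) { best_run <- run; best_q <- q }
  }
  gend2 <- best_q
  # left boundary: walk from (gstart + period) outward to (gstart - period)
  anchor_l <- min(gend2 - period + 1L, gstart + period)
  best_q <- anchor_l; run <- 0; best_run <- 0
  q <- anchor_l
  while (q > max(1L, gstart - period)) {
    q <- q - 1L
    m <- substr(seq, q, q) == substr(seq, q + period, q + period) &&
      substr(seq, q, q) != "N"
    run <- run + (if (m) 0.4 else -0.6)
    if (run > best_run + 1e-9) { best_run <- run; best_q <- q }
  }
  c(best_q, gend2)
}

# column-majority consensus over period-phased chunks anchored at `lo`;
# chunks too divergent from the first full chunk are excluded so that a
# junction between two different arrays does not corrupt the estimate
.polishConsensus <- function(seq, lo, hi, period, min_chunk_identity = 0.60) {
  len <- hi - lo + 1L
  m <- len %/% period
  if (m < 1L) return(NULL)
  region <- substr(seq, lo, lo + m * period - 1L)
  chunks <- .chopMonomers(region, period)
  chunks <- chunks[nchar(chunks) == period]
  if (!length(chunks)) return(NULL)
  if (length(chunks) > 1L) {
    ref <- chunks[[1L]]
    keep <- vapply(chunks, function(x) .ungappedIdentity(x, ref),
                   numeric(1)) >= min_chunk_identity
    if (sum(keep) >= 1L) chunks <- chunks[keep]
  }
  .majorityConsensus(chunks)
}

.ungappedIdentity <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(va == vb & va != "N")
}

# plurality base per column; deterministic A < C < G < T < N tie-break
.majorityConsensus <- function(chunks) {
  mat <- do.call(rbind, strsplit(chunks, "", fixed = TRUE))
  lv <- c("A", "C", "G", "T", "N")
  apply_fun <- function(col) {
    cnt <- tabulate(factor(col, levels = lv), nbins = 5L)
    lv[which.max(cnt)]
  }
  paste(apply(mat, 2L, apply_fun), collapse = "")
}

# smallest sub-period whose ungapped autocorrelation reaches `min_frac`;
# returns nchar(x) when the monomer is already fundamental
.fundamentalPeriod <- function(x, min_frac = 0.9) {
  n <- nchar(x)
  v <- strsplit(x, "", fixed = TRUE)[[1L]]
  for (d in seq_len(n %/% 2L)) {
    i <- seq_len(n - d)
    if (mean(v[i] == v[i + d] & v[i] != "N") >= min_frac) return(d)
  }
  n
}

.newTandemArraySet <- function(recs, genome, cfg) {
  if (!length(recs)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      array_id = character(), period = integer(), copies = numeric(),
      score = integer(), consensus = character())
    return(methods::new("TandemArraySet", arrays = gr, monomers = list(),
                        config = configAsList(cfg)))
  }
  df <- data.frame(
    scaffold = vapply(recs, `[[`, character(1), "scaffold"),
    start = vapply(recs, `[[`, integer(1), "start"),
    end = vapply(recs, `[[`, integer(1), "end"),
    period = vapply(recs, `[[`, integer(1), "period"),
    copies = vapply(recs, `[[`, numeric(1), "copies"),
    score = vapply(recs, function(r) as.integer(r$score), integer(1)),
    consensus = vapply(recs, `[[`, character(1), "consensus"),
    stringsAsFactors = FALSE)
  ord <- order(df$scaffold, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  mono <- lapply(recs, `[[`, "monomers")[ord]
  ids <- sprintf("TR%06d", seq_len(nrow(df)))
  names(mono) <- ids
  gr <- GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = "+",
    array_id = ids, period = df$period, copies = df$copies,
    score = df$score, consensus = df$consensus)
  if (!is.null(names(genome)))
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                         names(genome))
  methods::new("TandemArraySet", arrays = gr, monomers = mono,
               config = configAsList(cfg))
}

#' Resolve redundant overlapping array reports
#'
#' Among arrays whose overlap exceeds the configured fraction (default 50\%,
#' strictly greater) of the shorter array's length, the higher-scoring array
#' wins; ties are broken by smaller period, then leftmost start. The retained
#' set satisfies the pairwise rule exhaustively.
#'
#' @param tas a \linkS4class{TandemArraySet}.
#' @param cfg a \linkS4class{HineConfig} (\code{redundancy_overlap}).
#' @return a filtered \linkS4class{TandemArraySet} with ids reassigned in
#'   (scaffold, start) order.
#' @export
removeRedundant <- function(tas, cfg = hineConfig()) {
  stopifnot(methods::is(tas, "TandemArraySet"))
  gr <- tas@arrays
  if (length(gr) <= 1L) return(tas)
  m <- S4Vectors::mcols(gr)
  pri <- order(-m$score, m$period, GenomicRanges::start(gr),
               as.character(GenomicRanges::seqnames(gr)))
  keep <- logical(length(gr))
  for (i in pri) {
    acc <- which(keep)
    ok <- TRUE
    if (length(acc)) {
      hits <- GenomicRanges::findOverlaps(gr[i], gr[acc])
      for (j in S4Vectors::subjectHits(hits)) {
        a <- gr[i]; b <- gr[acc[j]]
        ov <- min(GenomicRanges::end(a), GenomicRanges::end(b)) -
          max(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
        shorter <- min(GenomicRanges::width(a), GenomicRanges::width(b))
        if (ov > cfg$redundancy_overlap * shorter) { ok <- FALSE; break }
      }
    }
    keep[i] <- ok
  }
  sel <- sort(which(keep))
  gr2 <- gr[sel]
  mono <- tas@monomers[S4Vectors::mcols(gr2)$array_id]
  ids <- sprintf("TR%06d", seq_along(gr2))
  names(mono) <- ids
  S4Vectors::mcols(gr2)$array_id <- ids
  methods::new("TandemArraySet", arrays = gr2, monomers = mono,
               config = tas@config)
}

#' Monomer-length and copies-per-array histograms
#'
#' @param tas a \linkS4class{TandemArraySet}.
#' @param bin_width monomer-length bin width in bp (bins aligned to
#'   multiples of \code{bin_width}).
#' @return list with \code{length_hist} (bin_start, bin_end, n_monomers),
#'   \code{copies_hist} (monomer copies rounded down, n_arrays) and
#'   \code{frac_2_3}, the fraction of arrays with 2-3 monomers.
#' @export
monomerLengthHistogram <- function(tas, bin_width = 20L) {
  stopifnot(methods::is(tas, "TandemArraySet"))
  if (length(tas) == 0L)
    return(list(length_hist = data.frame(bin_start = integer(),
                                         bin_end = integer(),
                                         n_monomers = integer()),
                copies_hist = data.frame(copies = integer(),
                                         n_arrays = integer()),
                frac_2_3 = NA_real_))
  lens <- nchar(unlist(tas@monomers, use.names = FALSE))
  bs <- (lens %/% bin_width) * bin_width
  tab <- table(bs)
  length_hist <- data.frame(bin_start = as.integer(names(tab)),
                            bin_end = as.integer(names(tab)) + bin_width,
                            n_monomers = as.integer(tab))
  cp <- floor(copyNumbers(tas) + 1e-9)
  ct <- table(cp)
  copies_hist <- data.frame(copies = as.integer(names(ct)),
                            n_arrays = as.integer(ct))
  list(length_hist = length_hist, copies_hist = copies_hist,
       frac_2_3 = mean(cp %in% c(2, 3)))
}
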