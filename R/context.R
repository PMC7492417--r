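#' Empty-site paralog search from junction chimeras
#'
#' For a member element locus, the 50 bp immediately upstream and the 50 bp
#' immediately downstream are merged into a 100 bp chimeric query -- the
#' reconstruction of the pre-insertion ("empty") allele. The query is
#' searched over both strands of all scaffolds with a seeded local aligner
#' (11-mer seeds, DP extension around each seed cluster) and hits are
#' reported when they reach \code{empty_min_identity} (80\%) identity over
#' \code{empty_min_coverage} (85\%) of the query length, excluding any hit
#' overlapping the source element's own locus.
#'
#' @param locus a one-row data.frame or list with \code{scaffold},
#'   \code{start}, \code{end} (1-based inclusive element span).
#' @param genome the genome \code{DNAStringSet}.
#' @param cfg a \linkS4class{HineConfig}.
#' @return data.frame of hits: scaffold, start, end, strand, identity,
#'   coverage, score, junction_pos (query junction position projected into
#'   the hit). Zero rows when none pass. Members with less than 50 bp
#'   clearance on either side are an error (skip upstream of this call).
#' @export
emptySiteSearch <- function(locus, genome, cfg = hineConfig()) {
  genome <- validateGenome(genome)
  fl <- cfg$empty_flank
  sc <- genome[[locus$scaffold]]
  if (is.null(sc)) stop("unknown scaffold: ", locus$scaffold)
  if (locus$start - fl < 1L || locus$end + fl > length(sc))
    stop("member locus has insufficient clearance (need ", fl,
         " bp on both sides)")
  left <- as.character(Biostrings::subseq(sc, locus$start - fl,
                                          locus$start - 1L))
  right <- as.character(Biostrings::subseq(sc, locus$end + 1L,
                                           locus$end + fl))
  query <- paste0(left, right)
  hits <- .seededLocalSearch(query, genome, cfg)
  if (nrow(hits)) {
    self <- hits$scaffold == locus$scaffold &
      hits$start <= locus$end + fl & hits$end >= locus$start - fl
    hits <- hits[!self, , drop = FALSE]
  }
  hits$junction_pos <- if (nrow(hits)) fl - hits$q_start + 1L else integer(0)
  hits
}

# seeded local search of a short query against all scaffolds, both strands
.seededLocalSearch <- function(query, genome, cfg, k = 11L, pad = 150L) {
  qlen <- nchar(query)
  out <- list()
  for (scn in names(genome)) {
    seq <- as.character(genome[[scn]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else revComp(query)
      sm <- cpp_shared_kmer_positions(seq, q, k)
      if (nrow(sm) == 0L) next
      # cluster seed diagonals into candidate windows
      diag <- sm[, "hay_pos"] - sm[, "needle_pos"]
      ord <- order(diag, sm[, "hay_pos"])
      diag <- diag[ord]
      hp <- sm[ord, "hay_pos"]
      grp <- cumsum(c(TRUE, diff(diag) > 30L | diff(hp) > qlen))
      for (g in unique(grp)) {
        sel <- grp == g
        lo <- max(1L, min(hp[sel]) - pad)
        hi <- min(nchar(seq), max(hp[sel]) + qlen + pad)
        win <- substr(seq, lo, hi)
        al <- cpp_align(win, q, cfg$tr_match, cfg$tr_mismatch,
                        cfg$tr_indel, TRUE)
        cov <- (al$b_end - al$b_start + 1L) / qlen
        if (cov >= cfg$empty_min_coverage &&
            al$identity >= cfg$empty_min_identity) {
          hs <- lo + al$a_start - 1L
          he <- lo + al$a_end - 1L
          qs <- if (strand == "+") al$b_start else qlen - al$b_end + 1L
          out[[length(out) + 1L]] <- data.frame(
            scaffold = scn, start = hs, end = he, strand = strand,
            identity = al$identity, coverage = cov, score = al$score,
            q_start = qs, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      score = integer(), q_start = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(-res$score, res$scaffold, res$start), , drop = FALSE]
  # deduplicate overlapping strand-mirror / windowing duplicates
  keep <- rep(TRUE, nrow(res))
  if (nrow(res) > 1L) {
    for (i in 2:nrow(res)) {
      for (j in which(keep[seq_len(i - 1L)])) {
        if (res$scaffold[i] == res$scaffold[j] &&
            res$start[i] <= res$end[j] && res$end[i] >= res$start[j]) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  res[keep, , drop = FALSE]
}

#' Insertion-site profile: junction dinucleotide, T-richness and TSD scan
#'
#' For each member locus the pre-insertion allele is reconstructed (1 bp
#' left + 1 bp right of the element gives the junction dinucleotide; +/-10
#' bp give the composition window). TT-dinucleotide frequency at the
#' junction is tested for enrichment against the genome-wide dinucleotide
#' background with an exact binomial test. The TSD scan compares the k bp
#' (k = 2..10) immediately left of the element start with the k bp
#' immediately right of the element end and reports the longest exact
#' duplication per member and the modal length across members (0 = no TSD).
#'
#' @param loci data.frame of member element loci: \code{scaffold},
#'   \code{start}, \code{end} (1-based inclusive).
#' @param genome the genome \code{DNAStringSet}.
#' @param cfg a \linkS4class{HineConfig}.
#' @return list with \code{junction} (per-member dinucleotide, T fraction in
#'   the +/-10 bp window, TSD length), \code{tt_frequency},
#'   \code{tt_background}, \code{p_value} (binomial enrichment),
#'   \code{tsd_modal_length}, \code{n_loci}, and \code{low_power}
#'   (TRUE when fewer than 20 loci were profiled).
#' @export
insertionSiteProfile <- function(loci, genome, cfg = hineConfig()) {
  genome <- validateGenome(genome)
  n <- nrow(loci)
  low_power <- n < 20L
  if (low_power)
    warning("fewer than 20 member loci; insertion profile has low power")
  dinuc <- character(n)
  tfrac <- numeric(n)
  tsd <- integer(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    sc <- genome[[loci$scaffold[i]]]
    s <- loci$start[i]; e <- loci$end[i]
    if (is.null(sc) || s < 2L || e > length(sc) - 1L) next
    lbase <- as.character(Biostrings::subseq(sc, s - 1L, s - 1L))
    rbase <- as.character(Biostrings::subseq(sc, e + 1L, e + 1L))
    dinuc[i] <- paste0(lbase, rbase)
    wl <- as.character(Biostrings::subseq(sc, max(1L, s - 10L), s - 1L))
    wr <- as.character(Biostrings::subseq(sc, e + 1L,
                                          min(length(sc), e + 10L)))
    wchars <- strsplit(paste0(wl, wr), "")[[1L]]
    tfrac[i] <- mean(wchars == "T")
    tsd[i] <- .longestTsd(sc, s, e, cfg$tsd_len_range)
    ok[i] <- TRUE
  }
  junction <- data.frame(scaffold = loci$scaffold, start = loci$start,
                         end = loci$end, dinucleotide = dinuc,
                         t_fraction_win = tfrac, tsd_len = tsd,
                         scored = ok, stringsAsFactors = FALSE)
  n_ok <- sum(ok)
  tt_freq <- if (n_ok) mean(dinuc[ok] == "TT") else NA_real_
  bg <- .dinucBackground(genome, "TT")
  pv <- if (n_ok)
    stats::binom.test(sum(dinuc[ok] == "TT"), n_ok, p = bg,
                      alternative = "greater")$p.value else NA_real_
  tsd_mode <- if (n_ok) .modalValue(tsd[ok]) else NA_integer_
  list(junction = junction, tt_frequency = tt_freq, tt_background = bg,
       p_value = pv, tsd_modal_length = tsd_mode, n_loci = n_ok,
       low_power = low_power)
}

.longestTsd <- function(sc, s, e, range) {
  best <- 0L
  for (k in seq(range[1], range[2])) {
    if (s - k < 1L || e + k > length(sc)) break
    left <- as.character(Biostrings::subseq(sc, s - k, s - 1L))
    right <- as.character(Biostrings::subseq(sc, e + 1L, e + k))
    if (identical(left, right)) best <- k
  }
  best
}

.modalValue <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

.dinucBackground <- function(genome, dinuc) {
  counts <- 0; total <- 0
  for (scn in names(genome)) {
    seq <- genome[[scn]]
    din <- Biostrings::dinucleotideFrequency(seq)
    counts <- counts + din[[dinuc]]
    total <- total + sum(din)
  }
  counts / total
}

#' Map array sequences exactly onto a reference assembly
#'
#' Exact (100\% identity) string matching of each array sequence over both
#' strands of a reference, the dispersal-mapping step used on
#' chromosome-scale assemblies. Matching uses
#' \code{Biostrings::vmatchPattern}.
#'
#' @param tas a \linkS4class{TandemArraySet} (or named character vector of
#'   array sequences).
#' @param reference the reference \code{DNAStringSet}.
#' @param genome genome the arrays were detected in (required when
#'   \code{tas} is a \code{TandemArraySet}, to extract array sequences).
#' @return a \code{GRanges} in BED-ready form (name = array id, score =
#'   match count for that array) with a per-sequence density summary in
#'   \code{metadata()$density} (hits per Mb per reference sequence).
#' @export
mapArraysExact <- function(tas, reference, genome = NULL) {
  reference <- validateGenome(reference)
  if (methods::is(tas, "TandemArraySet")) {
    if (is.null(genome)) stop("genome required to extract array sequences")
    genome <- validateGenome(genome)
    gr <- tas@arrays
    seqs <- vapply(seq_along(gr), function(i) {
      scn <- as.character(GenomicRanges::seqnames(gr))[i]
      as.character(Biostrings::subseq(genome[[scn]],
                                      GenomicRanges::start(gr)[i],
                                      GenomicRanges::end(gr)[i]))
    }, character(1))
    names(seqs) <- arrayIds(tas)
  } else {
    seqs <- tas
    if (is.null(names(seqs))) names(seqs) <- sprintf("TR%06d",
                                                     seq_along(seqs))
  }
  out <- list()
  for (nm in names(seqs)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seqs[[nm]] else revComp(seqs[[nm]])
      m <- Biostrings::vmatchPattern(pat, reference)
      for (scn in names(reference)) {
        ir <- m[[scn]]
        if (length(ir) == 0L) next
        out[[length(out) + 1L]] <- GenomicRanges::GRanges(
          seqnames = scn, ranges = ir, strand = strand, name = nm)
      }
    }
  }
  if (!length(out)) {
    res <- GenomicRanges::GRanges()
    res$name <- character(0)
    res$score <- integer(0)
  } else {
    res <- suppressWarnings(do.call(c, unname(out)))
    cnt <- table(res$name)
    res$score <- as.integer(cnt[res$name])
    res <- GenomicRanges::sort(res, ignore.strand = TRUE)
  }
  dens <- data.frame(
    seqname = names(reference),
    n_hits = vapply(names(reference), function(s)
      sum(as.character(GenomicRanges::seqnames(res)) == s), integer(1)),
    hits_per_mb = NA_real_, stringsAsFactors = FALSE)
  dens$hits_per_mb <- dens$n_hits / (Biostrings::width(reference) / 1e6)
  S4Vectors::metadata(res)$density <- dens
  res
}
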