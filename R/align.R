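#' Pairwise alignment under linear gap costs
#'
#' Optimal global (Needleman-Wunsch) or local (Smith-Waterman) alignment with
#' a fixed per-column indel cost, the scoring scheme used throughout the
#' tandem-repeat and substructure stages. Identity is defined as
#' matches / alignment columns, with gap columns counted in the denominator;
#' \code{N} never matches any base, including another \code{N}. Tie-breaking
#' is deterministic (diagonal, then gap in \code{b}, then gap in \code{a});
#' local alignments end at the first maximal cell in row-major order, so
#' repeated runs give byte-identical results.
#'
#' @param a,b character scalars over A/C/G/T/N (case-insensitive).
#' @param mode \code{"global"} or \code{"local"}.
#' @param weights numeric vector \code{c(match, mismatch, indel)} with
#'   \code{match > 0} and \code{mismatch, indel <= 0}, e.g. \code{c(2,-7,-7)}.
#' @return A list with elements \code{score}, \code{identity},
#'   \code{matches}, \code{columns}, aligned spans \code{a_start}, \code{a_end},
#'   \code{b_start}, \code{b_end} (1-based, inclusive; empty local alignments
#'   have \code{a_end < a_start}) and an edit \code{transcript} over
#'   \code{=} (match), \code{X} (mismatch), \code{I} (gap in \code{b}),
#'   \code{D} (gap in \code{a}).
#' @examples
#' alignSeqs("ACGT", "ACGT")$score            # 8
#' alignSeqs("AAAA", "AAAT")$identity          # 0.75
#' @export
alignSeqs <- function(a, b, mode = c("global", "local"),
                      weights = c(match = 2, mismatch = -7, indel = -7)) {
  mode <- match.arg(mode)
  a <- .checkSeq(a, "a")
  b <- .checkSeq(b, "b")
  w <- .checkWeights(weights)
  res <- cpp_align(a, b, w[1], w[2], w[3], mode == "local")
  res$mode <- mode
  res$weights <- w
  res
}

.checkSeq <- function(x, what = "sequence", allow_empty = FALSE) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet"))
    x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("'", what, "' must be a single character string")
  x <- toupper(x)
  if (!allow_empty && nchar(x) == 0L)
    stop("'", what, "' must be non-empty")
  if (grepl("[^ACGTN]", x))
    stop("'", what, "' contains symbols outside the A/C/G/T/N alphabet")
  x
}

.checkWeights <- function(weights) {
  if (length(weights) != 3L || !is.numeric(weights))
    stop("weights must be numeric c(match, mismatch, indel)")
  w <- as.integer(weights)
  if (w[1] <= 0L || w[2] > 0L || w[3] > 0L)
    stop("expected match > 0 and mismatch, indel <= 0")
  w
}

#' Reverse complement
#'
#' Length-preserving involution on A/C/G/T/N strings (\code{N} maps to
#' \code{N}). Thin wrapper over \code{Biostrings::reverseComplement} that
#' accepts and returns plain character vectors.
#'
#' @param seq character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @examples
#' revComp("ACGT")  # "ACGT"
#' revComp("AAN")   # "NTT"
#' @export
revComp <- function(seq) {
  if (methods::is(seq, "DNAStringSet") || methods::is(seq, "DNAString"))
    seq <- as.character(seq)
  if (!is.character(seq)) stop("seq must be character")
  up <- toupper(seq)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) stop("sequence contains symbols outside A/C/G/T/N")
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
  unname(out)
}

#' GC content with N excluded from the denominator
#'
#' @param seq character vector of A/C/G/T/N sequences.
#' @return numeric vector of (G+C)/(A+C+G+T) fractions; an all-N sequence
#'   yields \code{NaN} with a warning.
#' @examples
#' gcContent("ATGC")  # 0.5
#' gcContent("ATNN")  # 0.0 over denominator 2
#' @export
gcContent <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) seq <- as.character(seq)
  up <- toupper(seq)
  if (any(nchar(up) == 0L)) stop("sequences must be non-empty")
  if (any(grepl("[^ACGTN]", up)))
    stop("sequence contains symbols outside A/C/G/T/N")
  ss <- Biostrings::DNAStringSet(up)
  freq <- Biostrings::alphabetFrequency(ss, baseOnly = TRUE)
  gc <- freq[, "C"] + freq[, "G"]
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(acgt == 0L)) warning("all-N sequence: GC content undefined")
  unname(gc / acgt)
}

#' Exact cyclic identity between two monomers
#'
#' Tandem-repeat monomer phase is arbitrary, so monomers are compared by
#' maximising global-alignment identity over every rotation of \code{b} and
#' both orientations (exhaustive, not heuristic). Ties prefer higher score,
#' forward orientation, then the smallest rotation.
#'
#' @param a,b monomer sequences (character).
#' @param weights alignment weights, default the tandem scoring
#'   \code{c(2, -7, -7)}.
#' @return list with \code{identity}, \code{score}, \code{rotation} (0-based
#'   offset applied to \code{b}) and \code{orientation} (\code{+1}/\code{-1}).
#' @export
cyclicIdentity <- function(a, b, weights = c(2, -7, -7)) {
  a <- .checkSeq(a, "a")
  b <- .checkSeq(b, "b")
  w <- .checkWeights(weights)
  res <- cpp_cyclic_best(a, b, w[1], w[2], w[3])
  res$orientation <- if (res$orientation > 0) "+" else "-"
  res
}

#' Wraparound alignment of a region against a cyclic monomer
#'
#' TRF-style wraparound dynamic programming: the region is aligned against
#' unlimited cyclic repetitions of the monomer, with the monomer phase free at
#' both ends. \code{mode = "global"} aligns the full region (array scoring);
#' \code{mode = "local"} additionally leaves the region ends free, which is
#' how array boundaries are refined during detection.
#'
#' @param region,monomer character sequences.
#' @param weights alignment weights, default \code{c(2, -7, -7)}.
#' @param mode \code{"global"} or \code{"local"}.
#' @return list with \code{score}, aligned region span \code{start},
#'   \code{end} (1-based inclusive), \code{matches}, \code{columns},
#'   \code{copy_number} (aligned length / period, one decimal).
#' @examples
#' m <- strrep("ACGTT", 30)           # 150 bp monomer
#' wraparoundAlign(strrep(m, 2), m)$score  # 2 * 300
#' @export
wraparoundAlign <- function(region, monomer, weights = c(2, -7, -7),
                            mode = c("global", "local")) {
  mode <- match.arg(mode)
  region <- .checkSeq(region, "region")
  monomer <- .checkSeq(monomer, "monomer")
  w <- .checkWeights(weights)
  res <- cpp_wraparound(region, monomer, w[1], w[2], w[3], mode == "local")
  len <- max(0L, res$end - res$start + 1L)
  res$copy_number <- round(len / nchar(monomer), 1)
  res
}

#' Score a candidate array region against a monomer
#'
#' Wraparound global alignment of the full region against cyclic repetitions
#' of the monomer under the tandem weights, the score by which arrays are
#' accepted or rejected (minimum 50 by default configuration).
#'
#' @param region array region sequence.
#' @param monomer candidate monomer.
#' @param weights alignment weights, default \code{c(2, -7, -7)}.
#' @return list with \code{score}, \code{copy_number} (region length /
#'   period, one decimal) and \code{monomers}, the region chopped into
#'   period-length chunks in genomic order (last may be partial).
#' @export
scoreArray <- function(region, monomer, weights = c(2, -7, -7)) {
  region <- .checkSeq(region, "region")
  monomer <- .checkSeq(monomer, "monomer")
  if (nchar(region) < nchar(monomer))
    stop("region must be at least as long as the monomer")
  res <- wraparoundAlign(region, monomer, weights, mode = "global")
  p <- nchar(monomer)
  res$copy_number <- round(nchar(region) / p, 1)
  res$monomers <- .chopMonomers(region, p)
  res
}

.chopMonomers <- function(region, period) {
  n <- nchar(region)
  starts <- seq(1L, n, by = period)
  ends <- pmin(starts + period - 1L, n)
  substring(region, starts, ends)
}
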