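#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet;
#' duplicate scaffold identifiers and empty records are rejected. Headers are
#' truncated at the first whitespace, the convention used by assembly tools.
#'
#' @param path path to a FASTA file.
#' @return a named \code{Biostrings::DNAStringSet} (the genome container used
#'   throughout the package).
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("FASTA parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  validateGenome(ss)
}

#' Validate a genome assembly container
#'
#' @param genome a named \code{DNAStringSet} (or named character vector).
#' @return the validated, uppercased \code{DNAStringSet}.
#' @export
validateGenome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or named character vector")
  if (is.null(names(genome)) || any(names(genome) == ""))
    stop("every scaffold must be named")
  if (anyDuplicated(names(genome)))
    stop("duplicate scaffold id(s): ",
         paste(unique(names(genome)[duplicated(names(genome))]),
               collapse = ", "))
  if (any(Biostrings::width(genome) == 0L))
    stop("empty scaffold sequence(s) present")
  chr <- toupper(as.character(genome))
  if (any(grepl("[^ACGTN]", chr)))
    stop("genome contains symbols outside the A/C/G/T/N alphabet")
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(genome)
  out
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param seqs a \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Export genomic features as BED6 / GFF3
#'
#' Thin wrappers over \code{rtracklayer}: BED is emitted 0-based half-open,
#' GFF3 1-based inclusive (the standard dialects). Both round-trip through
#' \code{readBedFile} / \code{readGff3File}.
#'
#' @param gr a \code{GRanges}; for BED, \code{mcols(gr)$name} and
#'   \code{mcols(gr)$score} are used when present.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedFile <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname writeBedFile
#' @param source character scalar recorded in the GFF3 source column.
#' @export
writeGff3File <- function(gr, path, source = "hineminer") {
  stopifnot(methods::is(gr, "GRanges"))
  if (is.null(gr$type)) gr$type <- "region"
  gr$source <- source
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' @rdname writeBedFile
#' @export
readBedFile <- function(path) rtracklayer::import.bed(path)

#' @rdname writeBedFile
#' @export
readGff3File <- function(path) rtracklayer::import.gff3(path)

#' Write a TSV report with a configuration-echo header
#'
#' Every tabular report carries its configuration snapshot as commented
#' header lines so downstream readers can tell which thresholds produced it.
#'
#' @param df a data.frame.
#' @param path output path.
#' @param cfg optional \linkS4class{HineConfig} echoed as \code{#} comments.
#' @return \code{path}, invisibly.
#' @export
writeReportTsv <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    p <- configAsList(cfg)
    hdr <- vapply(names(p), function(k)
      paste0("# ", k, "=", paste(p[[k]], collapse = ",")), character(1))
    writeLines(hdr, con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReportTsv
#' @export
readReportTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# simple stage timer used by the pipeline orchestrator
.stageLog <- function(stage, expr, verbose = TRUE) {
  t0 <- Sys.time()
  if (verbose) message(sprintf("[%s] started", stage))
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}
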