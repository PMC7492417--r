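#' Run the full element-mining pipeline
#'
#' Executes detection, redundancy resolution, clustering, double-array unit
#' definition, flank profiling, substructure annotation, element assembly,
#' grouping and the summary report in order, failing fast with stage-named
#' errors. Every intermediate is a plain in-memory object; when
#' \code{outdir} is given, each stage also writes a plain-text artifact
#' (TSV/FASTA/BED/GFF3) plus a YAML configuration snapshot and a JSON run
#' manifest with MD5 hashes of all outputs, so a rerun with identical inputs
#' can be verified hash-for-hash.
#'
#' @param genome a \code{DNAStringSet} or FASTA path.
#' @param cfg a \linkS4class{HineConfig}.
#' @param outdir optional output directory.
#' @param seed seed echoed into the manifest (the core pipeline itself is
#'   deterministic).
#' @param verbose stage progress messages.
#' @return list with \code{arrays}, \code{clusters}, \code{units},
#'   \code{flanks}, \code{substructures}, \code{elements}, \code{groups},
#'   \code{report}, \code{manifest}.
#' @export
runHinePipeline <- function(genome, cfg = hineConfig(), outdir = NULL,
                            seed = 1L, verbose = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readGenome(genome)
  genome <- validateGenome(genome)

  tas0 <- .stageLog("detect", detectTandemArrays(genome, cfg), verbose)
  tas <- .stageLog("redundancy", removeRedundant(tas0, cfg), verbose)
  clusters <- .stageLog("cluster", clusterArrays(tas, cfg), verbose)
  units <- .stageLog("double-arrays", detectDoubleArrays(tas, clusters, cfg),
                     verbose)
  flanks <- .stageLog("flanks",
                      profileFlanks(tas, clusters, genome, cfg, units),
                      verbose)
  units <- applyOrientationFlips(units, flanks)
  subs <- .stageLog("substructures", annotateSubstructures(flanks, cfg),
                    verbose)
  elements <- .stageLog("elements",
                        assembleElements(tas, clusters, flanks, subs, units,
                                         genome, cfg), verbose)
  groups <- .stageLog("groups", groupElements(elements, clusters, cfg),
                      verbose)
  report <- .stageLog("report", clusterReport(tas, clusters, genome, cfg),
                      verbose)
  elements@groups <- groups
  elements@report <- report

  manifest <- list(seed = seed, config = configAsList(cfg),
                   n_scaffolds = length(genome),
                   genome_bp = sum(Biostrings::width(genome)),
                   n_arrays = length(tas),
                   n_clusters = length(clusterIds(clusters)),
                   n_elements = sum(elementModels(elements)$is_element))
  res <- list(arrays = tas, clusters = clusters, units = units,
              flanks = flanks, substructures = subs, elements = elements,
              groups = groups, report = report, manifest = manifest)
  if (!is.null(outdir)) {
    res$manifest <- .writePipelineOutputs(res, genome, cfg, outdir, manifest)
  }
  res
}

.writePipelineOutputs <- function(res, genome, cfg, outdir, manifest) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  tas <- res$arrays
  gr <- arrayRanges(tas)
  adf <- data.frame(
    array_id = arrayIds(tas),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    period = arrayPeriods(tas), copies = copyNumbers(tas),
    score = arrayScores(tas), consensus = arrayConsensus(tas))
  writeReportTsv(adf, p("arrays.tsv"), cfg)
  bed <- gr
  bed$name <- arrayIds(tas)
  bed$score <- pmin(1000L, arrayScores(tas))
  writeBedFile(bed, p("arrays.bed"))
  mm <- clusterMembership(res$clusters)
  writeReportTsv(as.data.frame(mm), p("clusters.tsv"), cfg)
  cons <- clusterConsensus(res$clusters)
  if (length(cons)) writeFasta(cons, p("consensus.fa"))
  fu <- as.data.frame(flankUnits(res$flanks))
  writeReportTsv(fu, p("flanks.tsv"), cfg)
  fseqs <- c(
    stats::setNames(fu$lf[!is.na(fu$lf)],
                    paste0(fu$unit_id[!is.na(fu$lf)], "_LF")),
    stats::setNames(fu$rf[!is.na(fu$rf)],
                    paste0(fu$unit_id[!is.na(fu$rf)], "_RF")))
  if (length(fseqs)) writeFasta(fseqs, p("flanks.fa"))
  writeReportTsv(as.data.frame(res$substructures$units),
                 p("substructures.tsv"), cfg)
  writeReportTsv(as.data.frame(elementModels(res$elements)),
                 p("elements.tsv"), cfg)
  mem <- elementMembers(res$elements)
  if (length(mem)) {
    mem$type <- "mobile_genetic_element"
    mem$ID <- mem$member_key
    writeGff3File(mem, p("members.gff3"))
  }
  writeReportTsv(res$report, p("report.tsv"), cfg)
  if (nrow(res$groups)) writeReportTsv(res$groups, p("groups.tsv"), cfg)
  writeConfigYaml(cfg, p("config.yaml"))
  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- stats::setNames(
    as.character(tools::md5sum(files)), basename(files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}
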