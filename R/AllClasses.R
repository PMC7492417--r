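#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
NULL

#' Set of detected tandem-repeat arrays
#'
#' One record per array surviving detection: location (as \code{GRanges}, 1-based
#' inclusive; BED output is converted to 0-based half-open on export), consensus
#' monomer period, copy number to one decimal, wraparound-DP score against the
#' array's own cyclic consensus, the consensus sequence, and the monomers in
#' genomic order (the last may be partial; their concatenation equals the
#' genomic substring of the interval).
#'
#' @slot arrays \code{GRanges} with metadata columns \code{array_id},
#'   \code{period}, \code{copies}, \code{score}, \code{consensus}.
#' @slot monomers named list of character vectors (per \code{array_id}).
#' @slot config parameter echo (named list).
#' @export
setClass("TandemArraySet",
         representation(arrays = "GRanges", monomers = "list",
                        config = "list"))

setValidity("TandemArraySet", function(object) {
  gr <- object@arrays
  m <- S4Vectors::mcols(gr)
  need <- c("array_id", "period", "copies", "score", "consensus")
  if (!all(need %in% colnames(m)))
    return(paste("arrays must carry mcols:", paste(need, collapse = ", ")))
  if (length(gr) && anyDuplicated(m$array_id))
    return("duplicate array ids")
  if (length(gr) && !setequal(names(object@monomers), m$array_id))
    return("monomer list names must match array ids")
  TRUE
})

#' @describeIn TandemArraySet number of arrays.
#' @param x a \code{TandemArraySet}.
#' @export
setMethod("length", "TandemArraySet", function(x) length(x@arrays))

#' Accessors for \linkS4class{TandemArraySet}
#'
#' @param x a \code{TandemArraySet}.
#' @return \code{arrayRanges}: the \code{GRanges}; \code{arrayIds},
#'   \code{arrayConsensus}: character vectors; \code{arrayPeriods},
#'   \code{copyNumbers}, \code{arrayScores}: numeric vectors;
#'   \code{monomerSeqs}: named list of monomer character vectors.
#' @export
arrayRanges <- function(x) x@arrays
#' @rdname arrayRanges
#' @export
arrayIds <- function(x) S4Vectors::mcols(x@arrays)$array_id
#' @rdname arrayRanges
#' @export
arrayPeriods <- function(x) S4Vectors::mcols(x@arrays)$period
#' @rdname arrayRanges
#' @export
copyNumbers <- function(x) S4Vectors::mcols(x@arrays)$copies
#' @rdname arrayRanges
#' @export
arrayScores <- function(x) S4Vectors::mcols(x@arrays)$score
#' @rdname arrayRanges
#' @export
arrayConsensus <- function(x) S4Vectors::mcols(x@arrays)$consensus
#' @rdname arrayRanges
#' @export
monomerSeqs <- function(x) x@monomers

setMethod("show", "TandemArraySet", function(object) {
  cat("TandemArraySet with", length(object), "arrays\n")
  if (length(object)) {
    p <- arrayPeriods(object)
    cat("  period range:", min(p), "-", max(p), "bp; copies:",
        sprintf("%.1f", min(copyNumbers(object))), "-",
        sprintf("%.1f", max(copyNumbers(object))), "\n")
    cat("  scaffolds:",
        length(unique(as.character(GenomicRanges::seqnames(object@arrays)))),
        "\n")
  }
  invisible(object)
})

#' Subset a TandemArraySet
#' @param x a \code{TandemArraySet}.
#' @param i logical or integer index over arrays.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TandemArraySet", function(x, i, j, ..., drop = FALSE) {
  gr <- x@arrays[i]
  methods::new("TandemArraySet", arrays = gr,
               monomers = x@monomers[S4Vectors::mcols(gr)$array_id],
               config = x@config)
})

#' Array similarity clusters and their monomer consensus sequences
#'
#' Arrays grouped by >= 70\% cyclic monomer-consensus identity (connected
#' components of the identity graph, >= 2 members); singletons are kept
#' separately as the divergent remainder. Clusters are ranked by member count
#' (\code{CL1} largest; ties by total bp, then smallest member id).
#'
#' @slot membership \code{DataFrame} with \code{array_id}, \code{cluster_id}
#'   (\code{NA} for singletons), \code{orientation} (relative to the cluster
#'   consensus), \code{rotation} (0-based monomer frame offset).
#' @slot consensus named character vector: cluster id -> monomer consensus.
#' @slot stats data.frame of per-cluster member/monomer/bp counts.
#' @slot config parameter echo.
#' @export
setClass("ArrayClusterSet",
         representation(membership = "DataFrame", consensus = "character",
                        stats = "data.frame", config = "list"))

setValidity("ArrayClusterSet", function(object) {
  mm <- object@membership
  if (!all(c("array_id", "cluster_id", "orientation", "rotation") %in%
           colnames(mm)))
    return("membership must have array_id, cluster_id, orientation, rotation")
  if (nrow(mm) && anyDuplicated(mm$array_id))
    return("an array may belong to at most one cluster")
  cl <- stats::na.omit(unique(mm$cluster_id))
  if (!all(cl %in% names(object@consensus)))
    return("every cluster needs a consensus sequence")
  TRUE
})

#' Accessors for \linkS4class{ArrayClusterSet}
#' @param x an \code{ArrayClusterSet}.
#' @return \code{clusterIds}: ranked cluster ids; \code{clusterConsensus}:
#'   named character vector of monomer consensuses; \code{clusterMembership}:
#'   the membership \code{DataFrame}; \code{clusterStats}: per-cluster
#'   statistics; \code{singletonIds}: unclustered array ids.
#' @export
clusterIds <- function(x) names(x@consensus)
#' @rdname clusterIds
#' @export
clusterConsensus <- function(x) x@consensus
#' @rdname clusterIds
#' @export
clusterMembership <- function(x) x@membership
#' @rdname clusterIds
#' @export
clusterStats <- function(x) x@stats
#' @rdname clusterIds
#' @export
singletonIds <- function(x) x@membership$array_id[is.na(x@membership$cluster_id)]

setMethod("show", "ArrayClusterSet", function(object) {
  n_cl <- length(object@consensus)
  n_single <- sum(is.na(object@membership$cluster_id))
  cat("ArrayClusterSet:", n_cl, "clusters,",
      nrow(object@membership) - n_single, "clustered arrays,",
      n_single, "singletons\n")
  if (n_cl) {
    top <- utils::head(object@stats, 3)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s: %d members, consensus %d bp\n", top$cluster_id[i],
                  top$n_members[i], nchar(object@consensus[top$cluster_id[i]])))
    if (n_cl > 3) cat("  ...\n")
  }
  invisible(object)
})

#' Flank consensus sequences per element unit
#'
#' Left (LF) and right (RF) flanking consensus sequences derived per element
#' unit (a cluster, or an ordered cluster pair for double-array elements).
#' LF is 3'-anchored upstream of the variable linker; RF is 5'-anchored at the
#' array end and trimmed to the supported block within the 60 bp window.
#'
#' @slot units \code{DataFrame}: \code{unit_id}, \code{clusters},
#'   \code{lf}, \code{rf}, support counts, eligibility counts, mean member
#'   identities, \code{valid}, \code{reason}.
#' @slot member_flanks named list (unit id -> per-member flank table).
#' @slot config parameter echo.
#' @export
setClass("FlankConsensusSet",
         representation(units = "DataFrame", member_flanks = "list",
                        config = "list"))

#' Accessors for \linkS4class{FlankConsensusSet}
#' @param x a \code{FlankConsensusSet}.
#' @return \code{flankUnits}: the per-unit \code{DataFrame};
#'   \code{memberFlanks}: per-member flank tables.
#' @export
flankUnits <- function(x) x@units
#' @rdname flankUnits
#' @export
memberFlanks <- function(x) x@member_flanks

setMethod("show", "FlankConsensusSet", function(object) {
  u <- object@units
  cat("FlankConsensusSet:", nrow(u), "element units,",
      sum(u$valid), "with valid LF/RF consensus\n")
  invisible(object)
})

#' Assembled HINE element models, groups and summary report
#'
#' @slot elements \code{DataFrame}: one row per element model (unit id,
#'   clusters, LF/RF, substructure annotation, completeness flags, linker
#'   statistics, orientation consistency).
#' @slot members \code{GRanges} of member loci with element assignment and
#'   per-member completeness flags.
#' @slot groups data.frame of element-group assignments (1/2/3) with the
#'   pairwise identity matrices kept in \code{metadata}.
#' @slot report data.frame, the per-cluster summary table.
#' @slot config parameter echo.
#' @export
setClass("HineElementSet",
         representation(elements = "DataFrame", members = "GRanges",
                        groups = "data.frame", report = "data.frame",
                        config = "list"))

#' Accessors for \linkS4class{HineElementSet}
#' @param x a \code{HineElementSet}.
#' @return \code{elementModels}: the element \code{DataFrame};
#'   \code{elementMembers}: member loci \code{GRanges};
#'   \code{elementGroups}: group assignment data.frame;
#'   \code{elementReport}: the per-cluster summary table.
#' @export
elementModels <- function(x) x@elements
#' @rdname elementModels
#' @export
elementMembers <- function(x) x@members
#' @rdname elementModels
#' @export
elementGroups <- function(x) x@groups
#' @rdname elementModels
#' @export
elementReport <- function(x) x@report

setMethod("show", "HineElementSet", function(object) {
  el <- object@elements
  cat("HineElementSet:", nrow(el), "element models (",
      sum(el$valid), "complete ),", length(object@members),
      "member loci\n")
  if (nrow(object@groups)) {
    tab <- table(object@groups$group)
    cat("  groups:", paste(sprintf("g%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(object)
})

#' Synthetic genome with planted ground truth
#'
#' @slot genome \code{DNAStringSet} with planted elements, decoys and
#'   paralogous empty sites.
#' @slot truth \code{GRanges} of planted features: element spans and
#'   per-module child features, decoys, empty paralogs; metadata columns
#'   carry family, type, planted sequences and insertion annotation.
#' @slot models list of family element models used for planting.
#' @slot params generation parameters (including the seed).
#' @export
setClass("SyntheticTruth",
         representation(genome = "DNAStringSet", truth = "GRanges",
                        models = "list", params = "list"))

#' Accessors for \linkS4class{SyntheticTruth}
#' @param x a \code{SyntheticTruth}.
#' @return \code{truthGenome}: the genome \code{DNAStringSet};
#'   \code{truthRanges}: planted-feature \code{GRanges};
#'   \code{truthModels}: family models used for planting.
#' @export
truthGenome <- function(x) x@genome
#' @rdname truthGenome
#' @export
truthRanges <- function(x) x@truth
#' @rdname truthGenome
#' @export
truthModels <- function(x) x@models

setMethod("show", "SyntheticTruth", function(object) {
  tt <- object@truth
  cat("SyntheticTruth:", length(object@genome), "scaffold(s),",
      sum(width(object@genome)), "bp;",
      sum(tt$type == "element"), "planted elements,",
      sum(tt$type == "decoy_array"), "decoy arrays,",
      sum(tt$type == "empty_paralog"), "empty paralogs\n")
  invisible(object)
})
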