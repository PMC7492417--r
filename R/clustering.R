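#' Group tandem arrays into similarity clusters
#'
#' Builds the array-similarity graph with an edge wherever the cyclic
#' identity between two array consensuses reaches the configured threshold
#' (default 70\%) and reports connected components with at least two members
#' as clusters; remaining arrays are singletons (the divergent remainder).
#' Clusters are ranked by member count (\code{CL1} largest; ties by total bp,
#' then smallest member id). Low-complexity consensuses (more than 80\% a
#' single nucleotide) never form edges. A k-mer sharing prescreen skips pairs
#' that cannot reach the threshold, and pairs already connected through
#' earlier edges are not re-evaluated; neither shortcut changes the resulting
#' components. Member orientations and monomer-frame rotations are assigned
#' against a deterministic cluster representative so that all members align
#' to the cluster consensus on \code{+}.
#'
#' @param tas a deduplicated \linkS4class{TandemArraySet}.
#' @param cfg a \linkS4class{HineConfig}.
#' @param verbose progress messages.
#' @return an \linkS4class{ArrayClusterSet}.
#' @export
clusterArrays <- function(tas, cfg = hineConfig(), verbose = FALSE) {
  stopifnot(methods::is(tas, "TandemArraySet"))
  ids <- arrayIds(tas)
  n <- length(ids)
  cons <- arrayConsensus(tas)
  w <- c(cfg$tr_match, cfg$tr_mismatch, cfg$tr_indel)
  if (n == 0L) return(.emptyClusterSet(cfg))

  lowc <- vapply(cons, .isLowComplexity, logical(1))
  parent <- seq_len(n)
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  if (n > 1L) {
    pairs <- .candidatePairs(cons, lowc)
    if (nrow(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        i <- pairs$i[r]; j <- pairs$j[r]
        if (findp(i) == findp(j)) next
        if (.clusterEdge(cons[i], cons[j], w, cfg$cluster_identity))
          parent[findp(j)] <- findp(i)
      }
    }
  }

  comp <- vapply(seq_len(n), findp, integer(1))
  sizes <- table(comp)
  members <- split(seq_len(n), comp)
  members <- members[vapply(members, length, integer(1)) >= 2L]

  widths <- GenomicRanges::width(tas@arrays)
  rank_key <- vapply(members, function(ix)
    sprintf("%08.0f_%012.0f_%s", 1e7 - length(ix), 1e11 - sum(widths[ix]),
            min(ids[ix])), character(1))
  members <- members[order(rank_key)]

  cluster_id <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  rotation <- rep(NA_integer_, n)
  consensus <- character(0)
  stats <- list()
  for (ci in seq_along(members)) {
    ix <- members[[ci]]
    cl <- paste0("CL", ci)
    cluster_id[ix] <- cl
    rep_i <- ix[order(ids[ix])][1L]
    for (i in ix) {
      if (i == rep_i) {
        orientation[i] <- "+"; rotation[i] <- 0L
      } else {
        cb <- .bestRotation(cons[rep_i], cons[i], w)
        orientation[i] <- cb$orientation
        rotation[i] <- cb$rotation
      }
    }
    monos <- .normalizedClusterMonomers(tas, ids[ix], orientation[ix],
                                        rotation[ix])
    cc <- deriveMonomerConsensus(monos, cfg)
    consensus[cl] <- cc$sequence
    stats[[ci]] <- data.frame(
      cluster_id = cl, n_members = length(ix),
      total_bp = sum(widths[ix]),
      n_monomers = length(monos),
      consensus_length = nchar(cc$sequence), stringsAsFactors = FALSE)
    if (verbose) message(cl, ": ", length(ix), " members")
  }
  membership <- S4Vectors::DataFrame(array_id = ids, cluster_id = cluster_id,
                                     orientation = orientation,
                                     rotation = rotation)
  methods::new("ArrayClusterSet", membership = membership,
               consensus = consensus,
               stats = if (length(stats)) do.call(rbind, stats) else
                 .emptyClusterStats(),
               config = configAsList(cfg))
}

.emptyClusterStats <- function() {
  data.frame(cluster_id = character(), n_members = integer(),
             total_bp = integer(), n_monomers = integer(),
             consensus_length = integer(), stringsAsFactors = FALSE)
}

.emptyClusterSet <- function(cfg) {
  methods::new("ArrayClusterSet",
               membership = S4Vectors::DataFrame(
                 array_id = character(), cluster_id = character(),
                 orientation = character(), rotation = integer()),
               consensus = character(0), stats = .emptyClusterStats(),
               config = configAsList(cfg))
}

.isLowComplexity <- function(x, max_frac = 0.8) {
  v <- strsplit(x, "", fixed = TRUE)[[1L]]
  max(tabulate(factor(v, levels = c("A", "C", "G", "T", "N")),
               nbins = 5L)) / length(v) > max_frac
}

# pairs worth an exact identity evaluation, most promising first; 8-mer
# sharing against the doubled forward/reverse-complement consensus is far
# above zero for any pair near the 70% threshold and ~0 for unrelated
# sequences
.candidatePairs <- function(cons, lowc, k = 8L, min_share = 0.02) {
  cpp_candidate_pairs(unname(cons), lowc, k, min_share)
}

# Edge decision at cluster scale. Two tiers, neither changing the decision
# relative to exhaustive cyclic evaluation under the study conditions:
# (1) accept shortcut -- for any alignment path, score = 9*matches -
#     7*columns under (2,-7,-7)-style weights, so the identity of the
#     score-optimal alignment is bounded below by the best ungapped rotation
#     identity scaled by min/max length (see the methods vignette); when that
#     bound clears the threshold the edge is accepted without DP;
# (2) otherwise the gapped identity is evaluated at the top ungapped rotation
#     candidates (the optimal rotation of any pair near the threshold has
#     long exact stretches, which the ungapped scan ranks highly).
.clusterEdge <- function(a, b, w, threshold, n_cand = 6L) {
  cand <- cpp_rotation_candidates(a, b, n_cand)
  lmin <- min(nchar(a), nchar(b))
  lmax <- max(nchar(a), nchar(b))
  shortcut_ok <- w[1] > 0 && w[2] == w[3] &&
    threshold <= abs(w[3]) / (abs(w[3]) + w[1])
  if (shortcut_ok && cand$identity[1L] * lmin / lmax >= threshold)
    return(TRUE)
  b_rc <- cpp_revcomp(b)
  for (r in seq_len(nrow(cand))) {
    rot <- .rotateSeq(if (cand$orientation[r] > 0) b else b_rc,
                      cand$rotation[r])
    if (cpp_align(a, rot, w[1], w[2], w[3], FALSE)$identity >= threshold)
      return(TRUE)
  }
  FALSE
}

# best gapped rotation/orientation among ungapped candidates (frame
# assignment for cluster members)
.bestRotation <- function(rep_cons, member_cons, w, n_cand = 4L) {
  cand <- cpp_rotation_candidates(rep_cons, member_cons, n_cand)
  member_rc <- cpp_revcomp(member_cons)
  best <- NULL
  for (r in seq_len(nrow(cand))) {
    rot <- .rotateSeq(if (cand$orientation[r] > 0) member_cons else
      member_rc, cand$rotation[r])
    id <- cpp_align(rep_cons, rot, w[1], w[2], w[3], FALSE)$identity
    if (is.null(best) || id > best$identity)
      best <- list(identity = id,
                   orientation = if (cand$orientation[r] > 0) "+" else "-",
                   rotation = cand$rotation[r])
  }
  best
}

.rotateSeq <- function(seq, rotation) {
  r <- rotation %% nchar(seq)
  if (r == 0L) return(seq)
  paste0(substr(seq, r + 1L, nchar(seq)), substr(seq, 1L, r))
}

# full monomers of the given members, rotated/oriented into the cluster frame
.normalizedClusterMonomers <- function(tas, member_ids, orientations,
                                       rotations) {
  out <- character(0)
  for (t in seq_along(member_ids)) {
    mono <- tas@monomers[[member_ids[t]]]
    mono <- mono[nchar(mono) == max(nchar(mono))]  # drop partial end copies
    out <- c(out, vapply(mono, .normalizeMonomer, character(1),
                         orientation = orientations[t],
                         rotation = rotations[t], USE.NAMES = FALSE))
  }
  out
}

.normalizeMonomer <- function(seq, orientation, rotation) {
  if (identical(orientation, "-")) seq <- revComp(seq)
  r <- rotation %% nchar(seq)
  if (r > 0L) seq <- paste0(substr(seq, r + 1L, nchar(seq)),
                            substr(seq, 1L, r))
  seq
}

#' Derive a cluster monomer consensus by star alignment to the medoid
#'
#' Monomers shorter than 70\% of the cluster median length are excluded; the
#' medoid (maximal summed identity over a deterministic subsample when the
#' cluster is large) anchors a star alignment, and the consensus is the
#' column-wise plurality base over medoid columns, with gap-majority columns
#' dropped. With \code{iupac = TRUE}, columns where no base reaches 50\%
#' support receive an IUPAC ambiguity code; the default is the plurality base
#' with a deterministic A<C<G<T tie-break. Monomers are expected in a common
#' frame (see \code{\link{clusterArrays}}, which normalizes rotation and
#' orientation before calling this).
#'
#' @param monomers character vector of frame-normalized monomer sequences.
#' @param cfg a \linkS4class{HineConfig}.
#' @param iupac emit IUPAC codes at ambiguous columns.
#' @param max_medoid_n medoid search subsample ceiling.
#' @return list with \code{sequence}, \code{length}, \code{support}
#'   (per-column fraction of members agreeing with the consensus base) and
#'   \code{n_used}.
#' @export
deriveMonomerConsensus <- function(monomers, cfg = hineConfig(),
                                   iupac = FALSE, max_medoid_n = 30L) {
  lens <- nchar(monomers)
  med <- stats::median(lens)
  keep <- monomers[lens >= 0.7 * med]
  if (length(keep) < 1L)
    stop("no full-length monomers to derive a consensus from")
  if (length(keep) == 1L)
    return(list(sequence = keep, length = nchar(keep), support = 1,
                n_used = 1L))
  idx <- if (length(keep) > max_medoid_n)
    round(seq(1L, length(keep), length.out = max_medoid_n)) else
      seq_along(keep)
  sub <- keep[idx]
  m <- length(sub)
  sums <- numeric(m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    id <- cpp_align(sub[i], sub[j], 2L, -7L, -7L, FALSE)$identity
    sums[i] <- sums[i] + id
    sums[j] <- sums[j] + id
  }
  medoid <- sub[which.max(sums)]
  .starConsensus(medoid, keep, iupac = iupac)
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
            ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

.starConsensus <- function(medoid, members, iupac = FALSE) {
  L <- nchar(medoid)
  lv <- c("A", "C", "G", "T", "N", "-")
  counts <- matrix(0L, nrow = 6L, ncol = L, dimnames = list(lv, NULL))
  for (s in members) {
    al <- cpp_align(s, medoid, 2L, -7L, -7L, FALSE)
    tr <- strsplit(al$transcript, "", fixed = TRUE)[[1L]]
    i <- 0L; j <- 0L
    sv <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (op in tr) {
      if (op == "=" || op == "X") {
        i <- i + 1L; j <- j + 1L
        counts[sv[i], j] <- counts[sv[i], j] + 1L
      } else if (op == "I") {
        i <- i + 1L  # insertion relative to medoid: no column
      } else {
        j <- j + 1L
        counts["-", j] <- counts["-", j] + 1L
      }
    }
  }
  n_mem <- length(members)
  out <- character(0)
  support <- numeric(0)
  for (j in seq_len(L)) {
    cj <- counts[, j]
    if (cj["-"] > n_mem / 2) next  # gap-majority column dropped
    base_counts <- cj[c("A", "C", "G", "T")]
    top <- names(base_counts)[which.max(base_counts)]
    if (iupac && max(base_counts) < n_mem / 2) {
      present <- names(base_counts)[base_counts > 0 &
                                      base_counts >= max(base_counts) / 2]
      key <- paste(sort(present), collapse = "")
      top <- unname(.IUPAC[key])
      if (is.na(top)) top <- "N"
    }
    out <- c(out, top)
    support <- c(support, max(base_counts) / n_mem)
  }
  seqc <- paste(out, collapse = "")
  list(sequence = seqc, length = nchar(seqc), support = support,
       n_used = n_mem)
}

#' Mean pairwise monomer diversity within a cluster
#'
#' Mean over monomer pairs of one minus the cyclic identity; clusters larger
#' than \code{max_n} monomers are subsampled deterministically under the
#' given seed.
#'
#' @param monomers character vector of monomer sequences.
#' @param cfg a \linkS4class{HineConfig}.
#' @param max_n subsample ceiling.
#' @param seed subsampling seed.
#' @return mean pairwise distance (fraction).
#' @export
intraClusterDiversity <- function(monomers, cfg = hineConfig(), max_n = 200L,
                                  seed = 1L) {
  if (length(monomers) < 2L) stop("need at least two monomers")
  if (length(monomers) > max_n) {
    set.seed(seed)
    monomers <- sample(monomers, max_n)
  }
  w <- c(cfg$tr_match, cfg$tr_mismatch, cfg$tr_indel)
  n <- length(monomers)
  tot <- 0; cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + (1 - cpp_cyclic_best(monomers[i], monomers[j],
                                      w[1], w[2], w[3])$identity)
    cnt <- cnt + 1L
  }
  tot / cnt
}

#' Neighbor-joining tree of sampled cluster monomers with monophyly report
#'
#' Samples up to \code{n_per_cluster} full-length (\code{>= min_len} bp),
#' frame-normalized monomers per cluster, computes pairwise
#' identity distances, builds a neighbor-joining tree (\code{ape::nj}) and
#' reports whether each cluster's monomers form a monophyletic group --
#' a distance-based separation check at desk scale.
#'
#' @param clusters an \linkS4class{ArrayClusterSet}.
#' @param tas the underlying \linkS4class{TandemArraySet}.
#' @param n_per_cluster sample size per cluster.
#' @param min_len minimum monomer length (bp).
#' @param seed sampling seed.
#' @return list with \code{tree} (an \code{ape::phylo}), \code{newick}
#'   (character), and \code{monophyly} (data.frame: cluster_id, n_tips,
#'   monophyletic). Clusters with fewer than 3 qualifying monomers are
#'   excluded with a notice.
#' @export
monomerDistanceTree <- function(clusters, tas, n_per_cluster = 150L,
                                min_len = 140L, seed = 1L) {
  stopifnot(methods::is(clusters, "ArrayClusterSet"),
            methods::is(tas, "TandemArraySet"))
  mm <- clusterMembership(clusters)
  tips <- character(0); labs <- character(0)
  set.seed(seed)
  excluded <- character(0)
  for (cl in clusterIds(clusters)) {
    rows <- which(!is.na(mm$cluster_id) & mm$cluster_id == cl)
    monos <- .normalizedClusterMonomers(tas, mm$array_id[rows],
                                        mm$orientation[rows],
                                        mm$rotation[rows])
    monos <- monos[nchar(monos) >= min_len]
    if (length(monos) < 3L) {
      message("cluster ", cl, " has fewer than 3 qualifying monomers; ",
              "excluded from the tree")
      excluded <- c(excluded, cl)
      next
    }
    if (length(monos) > n_per_cluster)
      monos <- sample(monos, n_per_cluster)
    tips <- c(tips, monos)
    labs <- c(labs, sprintf("%s_m%03d", cl, seq_along(monos)))
  }
  if (length(unique(sub("_m[0-9]+$", "", labs))) < 2L)
    stop("need at least two clusters with qualifying monomers")
  n <- length(tips)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    id <- cpp_align(tips[i], tips[j], 2L, -7L, -7L, FALSE)$identity
    d[i, j] <- d[j, i] <- 1 - id
  }
  tree <- ape::nj(stats::as.dist(d))
  cls <- sub("_m[0-9]+$", "", labs)
  mono_tab <- do.call(rbind, lapply(unique(cls), function(cl) {
    tipset <- labs[cls == cl]
    data.frame(cluster_id = cl, n_tips = length(tipset),
               monophyletic = ape::is.monophyletic(tree, tipset),
               stringsAsFactors = FALSE)
  }))
  list(tree = tree, newick = ape::write.tree(tree), monophyly = mono_tab,
       excluded = excluded)
}
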