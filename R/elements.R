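#' Define element units and merge double-array elements
#'
#' Some elements carry two consecutive tandem arrays from different clusters
#' (the paired-cluster organization). Two arrays are paired when they sit on
#' the same scaffold in consistent orientation with an inter-array gap of at
#' most \code{double_array_max_gap} bp (default 1,300) and no other array
#' between them; a cluster pair is declared a double-array unit when at
#' least half of both clusters' members pair this way, with the cluster
#' order recorded in element space (for minus-orientation members the
#' genomic order is reversed). All remaining clusters become single-array
#' units. Unpaired members of a paired unit are kept as incomplete members.
#'
#' @param tas a \linkS4class{TandemArraySet}.
#' @param clusters an \linkS4class{ArrayClusterSet}.
#' @param cfg a \linkS4class{HineConfig}.
#' @return list with \code{units} (data.frame: unit_id, clusters) and
#'   \code{members} (data.frame: unit_id, member_key, scaffold, start, end,
#'   orientation, gap, complete, array_ids).
#' @export
detectDoubleArrays <- function(tas, clusters, cfg = hineConfig()) {
  stopifnot(methods::is(tas, "TandemArraySet"),
            methods::is(clusters, "ArrayClusterSet"))
  mm <- clusterMembership(clusters)
  gr <- tas@arrays
  ids <- arrayIds(tas)
  cl_of <- stats::setNames(mm$cluster_id, mm$array_id)
  or_of <- stats::setNames(mm$orientation, mm$array_id)
  clustered <- ids[!is.na(cl_of[ids])]

  # adjacency events between clustered arrays
  events <- list()
  df <- data.frame(id = ids,
                   scaffold = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  df <- df[df$id %in% clustered, , drop = FALSE]
  df <- df[order(df$scaffold, df$start), , drop = FALSE]
  if (nrow(df) > 1L) {
    for (i in seq_len(nrow(df) - 1L)) {
      a <- df[i, ]; b <- df[i + 1L, ]
      if (a$scaffold != b$scaffold) next
      gap <- b$start - a$end - 1L
      if (gap > cfg$double_array_max_gap) next
      ca <- cl_of[[a$id]]; cb <- cl_of[[b$id]]
      if (ca == cb) next
      oa <- or_of[[a$id]]; ob <- or_of[[b$id]]
      if (oa != ob) next
      # element-space order: genomic order for "+", reversed for "-"
      pair <- if (oa == "+") c(ca, cb) else c(cb, ca)
      events[[length(events) + 1L]] <- data.frame(
        first = pair[1], second = pair[2],
        first_id = if (oa == "+") a$id else b$id,
        second_id = if (oa == "+") b$id else a$id,
        scaffold = a$scaffold, start = a$start, end = b$end,
        orientation = oa, gap = gap, stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(first = character(), second = character(),
               first_id = character(), second_id = character(),
               scaffold = character(), start = integer(), end = integer(),
               orientation = character(), gap = integer(),
               stringsAsFactors = FALSE)

  n_members <- table(mm$cluster_id[!is.na(mm$cluster_id)])
  paired <- character(0)
  pair_tab <- list()
  if (nrow(ev)) {
    key <- paste(ev$first, ev$second, sep = "|")
    for (k in unique(key)) {
      sub <- ev[key == k, , drop = FALSE]
      p <- sub$first[1]; q <- sub$second[1]
      if (p %in% paired || q %in% paired) next
      if (nrow(sub) >= 0.5 * n_members[[p]] &&
          nrow(sub) >= 0.5 * n_members[[q]]) {
        paired <- c(paired, p, q)
        pair_tab[[length(pair_tab) + 1L]] <- list(first = p, second = q,
                                                  events = sub)
      }
    }
  }

  units <- list(); members <- list()
  clnum <- function(x) sub("^CL", "", x)
  for (pt in pair_tab) {
    uid <- paste0("U_", clnum(pt$first), "_", clnum(pt$second))
    units[[length(units) + 1L]] <- data.frame(
      unit_id = uid, clusters = paste(pt$first, pt$second, sep = ","),
      stringsAsFactors = FALSE)
    sub <- pt$events
    members[[length(members) + 1L]] <- data.frame(
      unit_id = uid,
      member_key = paste(sub$first_id, sub$second_id, sep = "+"),
      scaffold = sub$scaffold, start = sub$start, end = sub$end,
      orientation = sub$orientation, gap = sub$gap, complete = TRUE,
      array_ids = paste(sub$first_id, sub$second_id, sep = ","),
      stringsAsFactors = FALSE)
    # unpaired members of either cluster: incomplete
    used <- c(sub$first_id, sub$second_id)
    for (cl in c(pt$first, pt$second)) {
      left_over <- mm$array_id[!is.na(mm$cluster_id) &
                                 mm$cluster_id == cl &
                                 !(mm$array_id %in% used)]
      if (length(left_over)) {
        ix <- match(left_over, ids)
        members[[length(members) + 1L]] <- data.frame(
          unit_id = uid, member_key = left_over,
          scaffold = as.character(GenomicRanges::seqnames(gr))[ix],
          start = GenomicRanges::start(gr)[ix],
          end = GenomicRanges::end(gr)[ix],
          orientation = or_of[left_over], gap = NA_integer_,
          complete = FALSE, array_ids = left_over,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (cl in setdiff(clusterIds(clusters), paired)) {
    uid <- paste0("U_", clnum(cl))
    units[[length(units) + 1L]] <- data.frame(
      unit_id = uid, clusters = cl, stringsAsFactors = FALSE)
    idsc <- mm$array_id[!is.na(mm$cluster_id) & mm$cluster_id == cl]
    ix <- match(idsc, ids)
    members[[length(members) + 1L]] <- data.frame(
      unit_id = uid, member_key = idsc,
      scaffold = as.character(GenomicRanges::seqnames(gr))[ix],
      start = GenomicRanges::start(gr)[ix],
      end = GenomicRanges::end(gr)[ix],
      orientation = or_of[idsc], gap = NA_integer_, complete = TRUE,
      array_ids = idsc, stringsAsFactors = FALSE)
  }
  list(units = if (length(units)) do.call(rbind, units) else
         data.frame(unit_id = character(), clusters = character()),
       members = if (length(members)) do.call(rbind, members) else
         data.frame(unit_id = character(), member_key = character(),
                    scaffold = character(), start = integer(),
                    end = integer(), orientation = character(),
                    gap = integer(), complete = logical(),
                    array_ids = character()))
}

#' Assemble HINE element models
#'
#' Combines clusters, flank consensus sequences and substructure annotation
#' into per-unit element models: an element is valid when its LF/RF
#' consensus exists, the subTIR pair is present and the module order holds;
#' otherwise it is emitted with completeness flags (a unit without a flank
#' consensus is reported as a bare tandem repeat, i.e. a non-element).
#' Member loci are extended from the array interval to the LF start / RF end
#' located by local alignment of the flank consensuses in the member flanks;
#' per-member linker lengths (LF 3' end to array start) are recorded, with
#' members flagged canonical when the linker falls within
#' \code{linker_range}. Orientation consistency per element is the fraction
#' of members whose array orientation matches the flank orientation.
#'
#' @param tas a \linkS4class{TandemArraySet}.
#' @param clusters an \linkS4class{ArrayClusterSet}.
#' @param flanks a \linkS4class{FlankConsensusSet}.
#' @param substructures result of \code{\link{annotateSubstructures}}.
#' @param units unit/member tables from \code{\link{detectDoubleArrays}}.
#' @param genome the genome \code{DNAStringSet}.
#' @param cfg a \linkS4class{HineConfig}.
#' @return a \linkS4class{HineElementSet} (groups and report slots are
#'   filled by \code{\link{groupElements}} / \code{\link{clusterReport}}
#'   via the pipeline, or can be attached manually).
#' @export
assembleElements <- function(tas, clusters, flanks, substructures, units,
                             genome, cfg = hineConfig()) {
  genome <- validateGenome(genome)
  fu <- flankUnits(flanks)
  su <- substructures$units
  rows <- list()
  member_grs <- list()
  for (i in seq_len(nrow(fu))) {
    uid <- fu$unit_id[i]
    srow <- su[su$unit_id == uid, , drop = FALSE]
    mem <- units$members[units$members$unit_id == uid, , drop = FALSE]
    has_flanks <- isTRUE(fu$valid[i])
    has_subtir <- nrow(srow) == 1L && isTRUE(srow$has_subtir)
    order_ok <- nrow(srow) == 1L && isTRUE(srow$module_order_ok)
    valid <- has_flanks && has_subtir && order_ok
    eid <- paste0("HINE_", paste(sub("^CL", "", strsplit(
      fu$clusters[i], ",")[[1]]), collapse = "_"))

    ann <- if (has_flanks)
      .annotateMembers(mem, fu$lf[i], fu$rf[i], genome, cfg) else NULL
    linkers <- if (!is.null(ann)) ann$linker[!is.na(ann$linker)] else
      numeric(0)
    canonical <- linkers >= 0 & linkers <= cfg$linker_range[2]
    ocons <- if (!is.null(ann)) .orientationFraction(ann) else NA_real_

    flags <- c(
      if (!has_flanks) "no-flank-consensus",
      if (has_flanks && !has_subtir) "missing-subtir",
      if (has_flanks && has_subtir && !order_ok) "module-order-violation",
      if (nrow(srow) == 1L && !isTRUE(srow$has_palindrome) && has_subtir)
        "incomplete-palindrome",
      if (nrow(srow) == 1L && !isTRUE(srow$has_microsat) && has_flanks)
        "missing-microsatellite")
    rows[[i]] <- S4Vectors::DataFrame(
      element_id = eid, unit_id = uid, clusters = fu$clusters[i],
      valid = valid, is_element = has_flanks && has_subtir,
      flags = paste(flags, collapse = ";"),
      lf = fu$lf[i], rf = fu$rf[i],
      n_members = nrow(mem),
      n_complete = sum(mem$complete),
      linker_mean = if (length(linkers)) round(mean(linkers), 1) else
        NA_real_,
      linker_min = if (length(linkers)) min(linkers) else NA_integer_,
      linker_max = if (length(linkers)) max(linkers) else NA_integer_,
      n_canonical = sum(canonical),
      orientation_consistency = ocons)
    if (!is.null(ann) && nrow(ann)) {
      member_grs[[uid]] <- GenomicRanges::GRanges(
        seqnames = ann$scaffold,
        ranges = IRanges::IRanges(start = ann$el_start, end = ann$el_end),
        strand = ifelse(ann$orientation == "-", "-", "+"),
        element_id = eid, unit_id = uid, member_key = ann$member_key,
        array_start = ann$start, array_end = ann$end,
        lf_found = ann$lf_found, rf_found = ann$rf_found,
        linker = ann$linker, complete = ann$complete,
        orientation_consistent = ann$consistent)
    }
  }
  el <- if (length(rows)) do.call(rbind, rows) else
    S4Vectors::DataFrame(element_id = character(), unit_id = character(),
                         clusters = character(), valid = logical(),
                         is_element = logical(), flags = character())
  members <- if (length(member_grs))
    suppressWarnings(do.call(c, unname(member_grs))) else
      GenomicRanges::GRanges()
  methods::new("HineElementSet", elements = el, members = members,
               groups = data.frame(), report = data.frame(),
               config = configAsList(cfg))
}

# locate LF/RF consensus occurrences around each member's array span and
# derive element boundaries, linker lengths and orientation consistency
.annotateMembers <- function(mem, lf, rf, genome, cfg, window = 700L) {
  n <- nrow(mem)
  out <- mem
  out$el_start <- mem$start; out$el_end <- mem$end
  out$lf_found <- out$rf_found <- logical(n)
  out$linker <- rep(NA_real_, n)
  out$consistent <- rep(NA, n)
  for (r in seq_len(n)) {
    sc <- genome[[mem$scaffold[r]]]
    L <- length(sc)
    lw_s <- max(1L, mem$start[r] - window)
    left_win <- if (mem$start[r] > 1L)
      as.character(Biostrings::subseq(sc, lw_s, mem$start[r] - 1L)) else ""
    rw_e <- min(L, mem$end[r] + window)
    right_win <- if (mem$end[r] < L)
      as.character(Biostrings::subseq(sc, mem$end[r] + 1L, rw_e)) else ""
    minus <- identical(mem$orientation[r], "-")
    lf_win <- if (minus) .rcOrEmpty(right_win) else left_win
    rf_win <- if (minus) .rcOrEmpty(left_win) else right_win

    lf_al <- .locateConsensus(lf_win, lf, cfg)
    rf_al <- .locateConsensus(rf_win, rf, cfg)
    out$lf_found[r] <- lf_al$found
    out$rf_found[r] <- rf_al$found

    if (lf_al$found) {
      # linker: distance from the LF match 3' end to the array start
      out$linker[r] <- nchar(lf_win) - lf_al$a_end
      lf_start_off <- nchar(lf_win) - (lf_al$a_start - (lf_al$b_start - 1L)) + 1L
      if (minus) out$el_end[r] <- mem$end[r] + lf_start_off
      else out$el_start[r] <- mem$start[r] - lf_start_off
    }
    if (rf_al$found) {
      rf_end_off <- rf_al$a_end + (nchar(rf) - rf_al$b_end)
      if (minus) out$el_start[r] <- mem$start[r] - rf_end_off
      else out$el_end[r] <- mem$end[r] + rf_end_off
    }
    out$el_start[r] <- max(1L, out$el_start[r])
    out$el_end[r] <- min(L, out$el_end[r])

    # orientation consistency: LF must sit on the LF side; if the array
    # were inverted relative to its flanks, LF would instead appear on the
    # RF side in reverse complement
    lf_inv <- .locateConsensus(.rcOrEmpty(rf_win), lf, cfg)
    if (lf_al$found || rf_al$found) {
      out$consistent[r] <- (lf_al$score >= lf_inv$score)
    } else if (lf_inv$found ||
               .locateConsensus(.rcOrEmpty(lf_win), rf, cfg)$found) {
      out$consistent[r] <- FALSE
    }
  }
  out
}

.rcOrEmpty <- function(x) if (nzchar(x)) revComp(x) else ""

.locateConsensus <- function(win, cons, cfg) {
  if (!nzchar(win) || is.na(cons))
    return(list(found = FALSE, score = -Inf, a_start = NA, a_end = NA,
                b_start = NA, b_end = NA))
  al <- cpp_align(win, cons, cfg$tr_match, cfg$tr_mismatch, cfg$tr_indel,
                  TRUE)
  cov <- (al$b_end - al$b_start + 1L) / nchar(cons)
  list(found = cov >= 0.8 && al$identity >= cfg$flank_identity,
       score = al$score, a_start = al$a_start, a_end = al$a_end,
       b_start = al$b_start, b_end = al$b_end)
}

.orientationFraction <- function(ann) {
  ok <- ann$consistent[!is.na(ann$consistent)]
  if (!length(ok)) return(NA_real_)
  mean(ok)
}

#' Orientation consistency report per element
#'
#' @param elements a \linkS4class{HineElementSet}.
#' @return data.frame with element_id, n_members_scored and the fraction of
#'   members whose array orientation matches the flank orientation (1.0 =
#'   the invariant organization).
#' @export
checkOrientationConsistency <- function(elements) {
  stopifnot(methods::is(elements, "HineElementSet"))
  el <- elementModels(elements)
  mem <- elementMembers(elements)
  out <- lapply(seq_len(nrow(el)), function(i) {
    mk <- mem[mem$element_id == el$element_id[i]]
    sc <- mk$orientation_consistent
    sc <- sc[!is.na(sc)]
    data.frame(element_id = el$element_id[i], n_members_scored = length(sc),
               fraction_consistent = if (length(sc)) mean(sc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group elements by flank and monomer relatedness
#'
#' Pairwise element similarity is measured two ways: flank relatedness is
#' the global-alignment identity of the concatenated LF+RF consensuses
#' (threshold \code{flank_threshold}); monomer relatedness is a significant
#' local similarity between the cluster monomer consensuses (best local
#' alignment against the doubled partner consensus on either strand with
#' identity >= \code{monomer_threshold} over at least \code{min_motif_len}
#' aligned columns and score >= \code{min_motif_score} under the tandem
#' weights) -- related monomers share conserved motifs even when globally
#' divergent. Group 1: connected components (size >= 2) of the graph whose
#' edges satisfy both criteria; group 2: among the remaining elements,
#' components (size >= 2) of the flank graph; group 3: the rest.
#'
#' @param elements a \linkS4class{HineElementSet} (or its element
#'   \code{DataFrame}).
#' @param clusters an \linkS4class{ArrayClusterSet} (monomer consensuses).
#' @param cfg a \linkS4class{HineConfig}.
#' @param flank_threshold,monomer_threshold identity thresholds.
#' @param min_motif_len,min_motif_score monomer local-similarity floor.
#' @return data.frame with element_id, group (1/2/3) and group_label;
#'   the pairwise identity matrices are attached as attributes
#'   \code{flank_identity} and \code{monomer_related}.
#' @export
groupElements <- function(elements, clusters, cfg = hineConfig(),
                          flank_threshold = 0.70, monomer_threshold = 0.70,
                          min_motif_len = 25L, min_motif_score = 40L) {
  el <- if (methods::is(elements, "HineElementSet"))
    elementModels(elements) else elements
  el <- el[el$is_element, , drop = FALSE]
  n <- nrow(el)
  if (n == 0L)
    return(data.frame(element_id = character(), group = integer(),
                      group_label = character()))
  ids <- el$element_id
  if (n == 1L) {
    res <- data.frame(element_id = ids, group = 3L,
                      group_label = "3: unrelated", stringsAsFactors = FALSE)
    return(res)
  }
  cons <- clusterConsensus(clusters)
  w <- c(cfg$tr_match, cfg$tr_mismatch, cfg$tr_indel)
  fm <- matrix(0, n, n, dimnames = list(ids, ids))
  mr <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  flank_seq <- paste0(el$lf, el$rf)
  cl_list <- strsplit(el$clusters, ",")
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- cpp_align(flank_seq[i], flank_seq[j], w[1], w[2], w[3], FALSE)
    fm[i, j] <- fm[j, i] <- al$identity
    rel <- FALSE
    for (ca in cl_list[[i]]) for (cb in cl_list[[j]]) {
      if (.monomerMotifRelated(cons[[ca]], cons[[cb]], w, monomer_threshold,
                               min_motif_len, min_motif_score)) rel <- TRUE
    }
    mr[i, j] <- mr[j, i] <- rel
  }
  fgraph <- fm >= flank_threshold
  bgraph <- fgraph & mr
  comp_b <- .components(bgraph)
  group <- rep(3L, n)
  for (cmp in comp_b) if (length(cmp) >= 2L) group[cmp] <- 1L
  rest <- which(group == 3L)
  if (length(rest) >= 2L) {
    comp_f <- .components(fgraph[rest, rest, drop = FALSE])
    for (cmp in comp_f) if (length(cmp) >= 2L) group[rest[cmp]] <- 2L
  }
  lab <- c("1: flanks and repeats related", "2: flanks related only",
           "3: unrelated")
  res <- data.frame(element_id = ids, group = group,
                    group_label = lab[group], stringsAsFactors = FALSE)
  attr(res, "flank_identity") <- fm
  attr(res, "monomer_related") <- mr
  res
}

.monomerMotifRelated <- function(a, b, w, min_identity, min_len,
                                 min_score) {
  if (is.null(a) || is.null(b)) return(FALSE)
  for (bb in c(paste0(b, b), paste0(revComp(b), revComp(b)))) {
    al <- cpp_align(a, bb, w[1], w[2], w[3], TRUE)
    if (al$score >= min_score && al$identity >= min_identity &&
        al$columns >= min_len) return(TRUE)
  }
  FALSE
}

.components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  out <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s; comp <- integer(0)
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      stack <- c(stack, nb)
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

#' Per-cluster summary report
#'
#' The per-cluster feature table: array count, count and percentage of
#' arrays with >= 5 monomers, total array length, proportion of the genome
#' assembly (computed against \code{genome_size_for_proportion}), monomer
#' count, mean monomers per array, GC percentage over the concatenated array
#' sequence, and consensus monomer length; plus a totals row (counts are
#' summed; mean monomers/array and GC are averaged over clusters, the
#' convention used for published per-cluster tables; the proportion is
#' recomputed from the summed length).
#'
#' @param tas a \linkS4class{TandemArraySet}.
#' @param clusters an \linkS4class{ArrayClusterSet}.
#' @param genome the genome \code{DNAStringSet} (for GC over array
#'   sequence).
#' @param cfg a \linkS4class{HineConfig}.
#' @return data.frame, one row per cluster plus a \code{Total} row.
#' @export
clusterReport <- function(tas, clusters, genome, cfg = hineConfig()) {
  stopifnot(methods::is(tas, "TandemArraySet"),
            methods::is(clusters, "ArrayClusterSet"))
  genome <- validateGenome(genome)
  mm <- clusterMembership(clusters)
  gr <- tas@arrays
  ids <- arrayIds(tas)
  rows <- list()
  for (cl in clusterIds(clusters)) {
    aids <- mm$array_id[!is.na(mm$cluster_id) & mm$cluster_id == cl]
    ix <- match(aids, ids)
    cp <- floor(copyNumbers(tas)[ix] + 1e-9)
    widths <- GenomicRanges::width(gr)[ix]
    seqs <- vapply(ix, function(t) {
      sc <- as.character(GenomicRanges::seqnames(gr))[t]
      as.character(Biostrings::subseq(genome[[sc]],
                                      GenomicRanges::start(gr)[t],
                                      GenomicRanges::end(gr)[t]))
    }, character(1))
    n_mono <- sum(vapply(tas@monomers[aids], length, integer(1)))
    rows[[cl]] <- data.frame(
      cluster_id = cl,
      n_arrays = length(aids),
      n_ge5 = sum(cp >= 5),
      pct_ge5 = round(100 * sum(cp >= 5) / length(aids), 2),
      total_bp = sum(widths),
      pct_genome = round(100 * sum(widths) /
                           cfg$genome_size_for_proportion, 4),
      n_monomers = n_mono,
      mean_monomers_per_array = round(mean(copyNumbers(tas)[ix]), 2),
      gc_pct = round(100 * gcContent(paste(seqs, collapse = "")), 2),
      consensus_length = nchar(clusterConsensus(clusters)[[cl]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cluster_id = character(), n_arrays = integer(),
                      n_ge5 = integer(), pct_ge5 = numeric(),
                      total_bp = integer(), pct_genome = numeric(),
                      n_monomers = integer(),
                      mean_monomers_per_array = numeric(),
                      gc_pct = numeric(), consensus_length = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (nrow(df)) {
    total <- data.frame(
      cluster_id = "Total",
      n_arrays = sum(df$n_arrays),
      n_ge5 = sum(df$n_ge5),
      pct_ge5 = round(100 * sum(df$n_ge5) / sum(df$n_arrays), 2),
      total_bp = sum(df$total_bp),
      pct_genome = round(100 * sum(df$total_bp) /
                           cfg$genome_size_for_proportion, 4),
      n_monomers = sum(df$n_monomers),
      mean_monomers_per_array = round(mean(df$mean_monomers_per_array), 2),
      gc_pct = round(mean(df$gc_pct), 2),
      consensus_length = as.integer(round(mean(df$consensus_length))),
      stringsAsFactors = FALSE)
    df <- rbind(df, total)
  }
  df
}

#' Aggregate a published-style per-cluster table
#'
#' Recomputes the totals row and derived percentages of a per-cluster table
#' (same columns as \code{\link{clusterReport}} input counts): summed
#' counts, the genome proportion from the summed length, the >= 5-monomer
#' percentage under both numerator conventions, and the mean-of-means
#' monomers/array and GC.
#'
#' @param tab data.frame with columns \code{n_arrays}, \code{n_ge5},
#'   \code{total_bp}, \code{n_monomers}, \code{mean_monomers_per_array},
#'   \code{gc_pct}.
#' @param genome_size assembly size in bp for the proportion.
#' @param n_arrays_whole_set optional whole-set array count for the second
#'   >= 5-monomer percentage convention.
#' @return named list of totals.
#' @export
aggregateClusterTable <- function(tab, genome_size = 559e6,
                                  n_arrays_whole_set = NA) {
  list(total_arrays = sum(tab$n_arrays),
       total_ge5 = sum(tab$n_ge5),
       pct_ge5_of_clustered = 100 * sum(tab$n_ge5) / sum(tab$n_arrays),
       pct_ge5_of_whole_set = if (is.na(n_arrays_whole_set)) NA_real_ else
         100 * sum(tab$n_ge5) / n_arrays_whole_set,
       total_bp = sum(tab$total_bp),
       pct_genome = 100 * sum(tab$total_bp) / genome_size,
       total_monomers = sum(tab$n_monomers),
       mean_monomers_per_array = mean(tab$mean_monomers_per_array),
       mean_gc_pct = mean(tab$gc_pct))
}
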