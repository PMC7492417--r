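#' Build an LF-RF chimeric construct
#'
#' Concatenates a left and right flanking sequence with the array removed,
#' recording the junction offset (the first RF position, equal to the LF
#' length).
#'
#' @param lf,rf flank sequences in their original orientations.
#' @return list with \code{sequence} and \code{junction} (0-based offset of
#'   the first RF base, i.e. \code{nchar(lf)}).
#' @examples
#' buildChimera("AAA", "TTT")  # "AAATTT", junction 3
#' @export
buildChimera <- function(lf, rf) {
  lf <- .checkSeq(lf, "lf")
  rf <- .checkSeq(rf, "rf")
  list(sequence = paste0(lf, rf), junction = nchar(lf))
}

#' Find inverted-repeat pairs between the LF and RF parts of a chimera
#'
#' Locally aligns the LF part against the reverse complement of the RF part
#' under the inverted-repeat weights (+2/-5/-7) and reports all
#' non-overlapping maximal pairs with score >= 14 and identity >= 90\%,
#' positionally filtered so the left arm lies entirely before the junction
#' and the right arm entirely after. Pairs are found by iterative best-hit
#' masking and returned sorted by score (descending).
#'
#' @param chimera list from \code{\link{buildChimera}} (or a character
#'   sequence together with \code{junction}).
#' @param cfg a \linkS4class{HineConfig}.
#' @param junction junction offset when \code{chimera} is a plain sequence.
#' @return data.frame with one row per pair: \code{left_start},
#'   \code{left_end}, \code{right_start}, \code{right_end} (1-based chimera
#'   coordinates), \code{arm_len} (left-arm length), \code{identity},
#'   \code{score}, \code{mismatches}.
#' @export
findInvertedRepeats <- function(chimera, cfg = hineConfig(),
                                junction = NULL) {
  if (is.list(chimera)) {
    junction <- chimera$junction
    chimera <- chimera$sequence
  }
  if (is.null(junction)) stop("junction offset required")
  lf <- substr(chimera, 1L, junction)
  rf <- substr(chimera, junction + 1L, nchar(chimera))
  if (!nzchar(lf) || !nzchar(rf)) return(.emptyIrTable())
  rcrf <- revComp(rf)
  rflen <- nchar(rf)
  out <- list()
  lf_work <- lf
  rc_work <- rcrf
  for (iter in 1:25) {
    al <- cpp_align(lf_work, rc_work, cfg$ir_match, cfg$ir_mismatch,
                    cfg$ir_indel, TRUE)
    if (al$score < cfg$ir_min_score) break
    if (al$identity >= cfg$ir_identity) {
      # right arm back onto RF coordinates, then chimera coordinates
      r_start <- rflen - al$b_end + 1L
      r_end <- rflen - al$b_start + 1L
      out[[length(out) + 1L]] <- data.frame(
        left_start = al$a_start, left_end = al$a_end,
        right_start = junction + r_start, right_end = junction + r_end,
        arm_len = al$a_end - al$a_start + 1L,
        identity = al$identity, score = al$score,
        mismatches = al$columns - al$matches, stringsAsFactors = FALSE)
    }
    # mask both arms so subsequent pairs are non-overlapping
    substr(lf_work, al$a_start, al$a_end) <-
      strrep("N", al$a_end - al$a_start + 1L)
    substr(rc_work, al$b_start, al$b_end) <-
      strrep("N", al$b_end - al$b_start + 1L)
  }
  if (!length(out)) return(.emptyIrTable())
  res <- do.call(rbind, out)
  res[order(-res$score, res$left_start), , drop = FALSE]
}

.emptyIrTable <- function() {
  data.frame(left_start = integer(), left_end = integer(),
             right_start = integer(), right_end = integer(),
             arm_len = integer(), identity = numeric(), score = integer(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

#' Identify the subTIR pair and the internal LF inverted repeat
#'
#' The subTIR is the highest-scoring inverted-repeat pair with an arm length
#' of 11-12 bp (ties: closest to the LF 5' end, then to the RF 3' end);
#' other pairs are kept as secondary. The internal IR is the best 7-12 bp
#' match to the reverse complement of the subTIR within LF, downstream of the
#' subTIR occurrence, separated by a 1-12 bp spacer, with at most
#' \code{motif_mismatch} mismatches (fewest mismatches, then longest arm,
#' then smallest spacer).
#'
#' @param lf,rf the flank consensus sequences.
#' @param ir_pairs data.frame from \code{\link{findInvertedRepeats}} run on
#'   \code{buildChimera(lf, rf)}.
#' @param cfg a \linkS4class{HineConfig}.
#' @return list with \code{subtir} (NULL when no 11-12 bp pair exists):
#'   sequence, LF and RF positions, mismatch count; \code{ir}: sequence,
#'   LF position, length, spacer, mismatches (NULL when absent);
#'   \code{secondary}: remaining pairs.
#' @export
identifySubtirIr <- function(lf, rf, ir_pairs, cfg = hineConfig()) {
  res <- list(subtir = NULL, ir = NULL, secondary = ir_pairs)
  if (!nrow(ir_pairs)) return(res)
  junction <- nchar(lf)
  # arms may carry 1-2 extra leading LF bases from the conserved insertion
  # context; accept up to +2 over the subTIR ceiling and trim below
  len_ok <- ir_pairs$arm_len >= cfg$subtir_len_range[1] &
    ir_pairs$arm_len <= cfg$subtir_len_range[2] + 2L
  cand <- ir_pairs[len_ok, , drop = FALSE]
  if (!nrow(cand)) return(res)
  ord <- order(-cand$score, cand$left_start, -cand$right_end)
  top <- cand[ord[1L], ]
  over <- top$arm_len - cfg$subtir_len_range[2]
  if (over > 0L) {
    # extras sit at the LF-leading / RF-trailing side of the pair: keep the
    # 3'-most subTIR-length window of the left arm and the matching
    # 5'-anchored window of the right arm
    top$left_start <- top$left_start + over
    top$right_end <- top$right_end - over
    top$arm_len <- cfg$subtir_len_range[2]
    lf_sub <- substr(lf, top$left_start, top$left_end)
    rf_sub <- substr(rf, top$right_start - junction,
                     top$right_end - junction)
    top$mismatches <- .hamming(lf_sub, revComp(rf_sub))
    top$identity <- 1 - top$mismatches / top$arm_len
  }
  res$secondary <- ir_pairs[!(ir_pairs$left_start == top$left_start &
                                ir_pairs$right_start == top$right_start), ,
                            drop = FALSE]
  subtir_seq <- substr(lf, top$left_start, top$left_end)
  res$subtir <- list(
    seq = subtir_seq,
    lf_start = top$left_start, lf_end = top$left_end,
    rf_start = top$right_start - junction,
    rf_end = top$right_end - junction,
    mismatches = top$mismatches, score = top$score,
    identity = top$identity)
  res$ir <- .findInternalIr(lf, res$subtir, cfg)
  res
}

# best 7-12 bp match to the reverse complement of the subTIR downstream of
# it: fewest mismatches first (an exact complement is the IR even when a
# longer arm with a mismatch exists), then longest, then smallest spacer
.findInternalIr <- function(lf, subtir, cfg) {
  target <- revComp(subtir$seq)
  best <- NULL
  better <- function(mm, L, s) {
    is.null(best) || mm < best$mismatches ||
      (mm == best$mismatches && L > best$len) ||
      (mm == best$mismatches && L == best$len && s < best$spacer)
  }
  for (L in seq(cfg$ir_len_range[2], cfg$ir_len_range[1])) {
    if (L > nchar(target)) next
    prefix <- substr(target, 1L, L)
    for (s in seq(cfg$ir_spacer_range[1], cfg$ir_spacer_range[2])) {
      st <- subtir$lf_end + s + 1L
      en <- st + L - 1L
      if (en > nchar(lf)) next
      cand <- substr(lf, st, en)
      mm <- .hamming(cand, prefix)
      if (mm <= cfg$motif_mismatch && better(mm, L, s))
        best <- list(seq = cand, lf_start = st, lf_end = en, len = L,
                     spacer = s, mismatches = mm)
    }
  }
  best
}

.hamming <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(va != vb | va == "N" | vb == "N")
}

#' Find the 3' palindrome downstream of the RF subTIR
#'
#' Exhaustively enumerates arm/loop decompositions in the RF window
#' downstream of the subTIR (arm >= 5 bp, loop 3-12 bp, at most one arm
#' mismatch) and reports the maximal-arm palindrome (ties: fewest
#' mismatches, smallest loop, leftmost). Stem-loop validity is arm
#' reverse-complementarity.
#'
#' @param rf the RF consensus sequence.
#' @param subtir_end 1-based end position of the subTIR within RF (0 to scan
#'   the whole RF).
#' @param cfg a \linkS4class{HineConfig}.
#' @param min_arm,max_loop,max_mismatch palindrome definition bounds.
#' @return list with \code{arm}, \code{loop}, \code{mismatches},
#'   \code{rf_start}, \code{rf_end} (positions within RF), \code{seq};
#'   or \code{NULL} when absent.
#' @export
findPalindrome <- function(rf, subtir_end = 0L, cfg = hineConfig(),
                           min_arm = 5L, max_loop = 12L, max_mismatch = 1L,
                           min_loop = 3L) {
  win <- substr(rf, subtir_end + 1L, nchar(rf))
  n <- nchar(win)
  if (n < 2L * min_arm + min_loop) return(NULL)
  v <- strsplit(win, "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  best <- NULL
  max_arm <- (n - min_loop) %/% 2L
  for (arm in seq(max_arm, min_arm)) {
    for (loop in seq(min_loop, max_loop)) {
      span <- 2L * arm + loop
      if (span > n) next
      for (st in seq_len(n - span + 1L)) {
        left <- v[st:(st + arm - 1L)]
        right <- v[(st + arm + loop):(st + span - 1L)]
        mm <- sum(left != comp[rev(right)])
        if (mm <= max_mismatch) {
          cand <- list(arm = arm, loop = loop, mismatches = mm,
                       rf_start = subtir_end + st,
                       rf_end = subtir_end + st + span - 1L,
                       seq = substr(win, st, st + span - 1L))
          if (is.null(best) || mm < best$mismatches ||
              (mm == best$mismatches && loop < best$loop))
            best <- cand
        }
      }
      if (!is.null(best) && best$mismatches == 0L) break
    }
    if (!is.null(best)) break  # maximal arm found
  }
  best
}

#' Detect the LF microsatellite
#'
#' Tandem detection with a 3-8 nt unit under the microsatellite weights
#' (+2/-3/-5), minimum score twice two clean copies (4 x unit length). The
#' reported repeat must lie in the 3' half of LF (nearest the array). Unit
#' consensus may carry IUPAC codes when copies disagree and
#' \code{iupac = TRUE}.
#'
#' @param lf the LF consensus sequence.
#' @param cfg a \linkS4class{HineConfig}.
#' @param iupac emit IUPAC ambiguity codes in the unit consensus.
#' @return list with \code{unit}, \code{copies} (one decimal),
#'   \code{lf_start}, \code{lf_end}, \code{score}; or \code{NULL}.
#' @export
findMicrosatellite <- function(lf, cfg = hineConfig(), iupac = FALSE) {
  n <- nchar(lf)
  best <- NULL
  seen <- character(0)
  for (u in seq(cfg$ms_unit_range[1], cfg$ms_unit_range[2])) {
    if (2L * u > n) next
    for (st in seq_len(n - u + 1L)) {
      unit <- substr(lf, st, st + u - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      # only fundamental units: a near-repetitive longer unit (e.g. an
      # 8-mer made of two similar 4-mers) is reported through its
      # fundamental period instead
      if (.fundamentalPeriod(unit, 0.75) < nchar(unit)) next
      if (.fundamentalPeriod(unit, 1.0) < cfg$ms_unit_range[1]) next
      if (unit %in% seen) next
      seen <- c(seen, unit)
      wa <- cpp_wraparound(lf, unit, cfg$ms_match, cfg$ms_mismatch,
                           cfg$ms_indel, TRUE)
      if (wa$score < 4L * u) next
      mid <- (wa$start + wa$end) / 2
      if (mid <= n / 2) next  # must sit in the 3' half of LF
      if (is.null(best) || wa$score > best$score ||
          (wa$score == best$score && u < nchar(best$unit))) {
        region <- substr(lf, wa$start, wa$end)
        copies_seqs <- .chopMonomers(region, u)
        full <- copies_seqs[nchar(copies_seqs) == u]
        unit_cons <- if (length(full) >= 2L)
          .msUnitConsensus(full, iupac) else unit
        best <- list(unit = unit_cons, copies = round(nchar(region) / u, 1),
                     lf_start = wa$start, lf_end = wa$end, score = wa$score)
      }
    }
  }
  best
}

.msUnitConsensus <- function(copies, iupac) {
  mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  out <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    cnt <- tabulate(factor(mat[, j], levels = c("A", "C", "G", "T")),
                    nbins = 4L)
    names(cnt) <- c("A", "C", "G", "T")
    if (iupac) {
      present <- names(cnt)[cnt > 0 & cnt >= max(cnt) / 2]
      key <- paste(sort(present), collapse = "")
      code <- unname(.IUPAC[key])
      out[j] <- if (is.na(code)) "N" else code
    } else {
      out[j] <- names(cnt)[which.max(cnt)]
    }
  }
  paste(out, collapse = "")
}

#' Annotate HINE substructures for every element unit
#'
#' Runs the chimera construction, inverted-repeat search, subTIR/IR
#' identification, palindrome and microsatellite detection on each unit with
#' a valid LF/RF consensus, and re-annotates the subTIR per member (motif
#' search allowing \code{motif_mismatch} mismatches via
#' \code{Biostrings::matchPattern}).
#'
#' @param flanks a \linkS4class{FlankConsensusSet}.
#' @param cfg a \linkS4class{HineConfig}.
#' @param iupac IUPAC mode for the microsatellite unit consensus.
#' @return list with \code{units}: a \code{DataFrame} (one row per unit with
#'   subTIR/IR/microsatellite/palindrome fields, presence flags and the
#'   module-order check), and \code{members}: per-member subTIR annotation
#'   table.
#' @export
annotateSubstructures <- function(flanks, cfg = hineConfig(),
                                  iupac = FALSE) {
  stopifnot(methods::is(flanks, "FlankConsensusSet"))
  u <- flankUnits(flanks)
  rows <- list()
  member_rows <- list()
  for (i in seq_len(nrow(u))) {
    uid <- u$unit_id[i]
    rec <- .emptySubstructureRow(uid)
    if (isTRUE(u$valid[i])) {
      lf <- u$lf[i]; rf <- u$rf[i]
      chim <- buildChimera(lf, rf)
      pairs <- findInvertedRepeats(chim, cfg)
      ann <- identifySubtirIr(lf, rf, pairs, cfg)
      ms <- findMicrosatellite(lf, cfg, iupac = iupac)
      if (!is.null(ann$subtir)) {
        st <- ann$subtir
        rec[c("subtir_seq", "subtir_lf_start", "subtir_lf_end",
              "subtir_rf_start", "subtir_rf_end", "subtir_mismatches")] <-
          list(st$seq, st$lf_start, st$lf_end, st$rf_start, st$rf_end,
               st$mismatches)
        rec$has_subtir <- TRUE
        pal <- findPalindrome(rf, st$rf_end, cfg)
        if (!is.null(pal)) {
          rec[c("pal_arm", "pal_loop", "pal_mismatches", "pal_rf_start",
                "pal_rf_end")] <-
            list(pal$arm, pal$loop, pal$mismatches, pal$rf_start,
                 pal$rf_end)
          rec$has_palindrome <- TRUE
        }
        if (!is.null(ann$ir)) {
          rec[c("ir_seq", "ir_lf_start", "ir_lf_end", "ir_spacer",
                "ir_mismatches")] <-
            list(ann$ir$seq, ann$ir$lf_start, ann$ir$lf_end, ann$ir$spacer,
                 ann$ir$mismatches)
          rec$has_ir <- TRUE
        }
        mem <- memberFlanks(flanks)[[uid]]
        if (!is.null(mem) && nrow(mem)) {
          member_rows[[uid]] <- .memberSubtirAnnotation(uid, mem, st$seq,
                                                       cfg)
        }
      }
      if (!is.null(ms)) {
        rec[c("ms_unit", "ms_copies", "ms_lf_start", "ms_lf_end")] <-
          list(ms$unit, ms$copies, ms$lf_start, ms$lf_end)
        rec$has_microsat <- TRUE
      }
      rec$module_order_ok <- .checkModuleOrder(rec)
    }
    rows[[i]] <- S4Vectors::DataFrame(rec)
  }
  units <- if (length(rows)) do.call(rbind, rows) else
    S4Vectors::DataFrame(.emptySubstructureRow("none"))[0, ]
  members <- if (length(member_rows)) do.call(rbind, member_rows) else
    data.frame(unit_id = character(), member_key = character(),
               subtir_lf_found = logical(), subtir_lf_mismatches = integer(),
               subtir_rf_found = logical(), subtir_rf_mismatches = integer(),
               stringsAsFactors = FALSE)
  list(units = units, members = members)
}

.emptySubstructureRow <- function(uid) {
  list(unit_id = uid,
       subtir_seq = NA_character_, subtir_lf_start = NA_integer_,
       subtir_lf_end = NA_integer_, subtir_rf_start = NA_integer_,
       subtir_rf_end = NA_integer_, subtir_mismatches = NA_integer_,
       ir_seq = NA_character_, ir_lf_start = NA_integer_,
       ir_lf_end = NA_integer_, ir_spacer = NA_integer_,
       ir_mismatches = NA_integer_,
       ms_unit = NA_character_, ms_copies = NA_real_,
       ms_lf_start = NA_integer_, ms_lf_end = NA_integer_,
       pal_arm = NA_integer_, pal_loop = NA_integer_,
       pal_mismatches = NA_integer_, pal_rf_start = NA_integer_,
       pal_rf_end = NA_integer_,
       has_subtir = FALSE, has_ir = FALSE, has_microsat = FALSE,
       has_palindrome = FALSE, module_order_ok = FALSE)
}

# LF module order 5'->3': subTIR < IR < microsatellite; RF: subTIR <
# palindrome. Compared on module starts (detected module ends can overlap
# by a few bases when a tandem microsatellite phase-extends into the IR).
# Missing modules do not break the order of those present.
.checkModuleOrder <- function(rec) {
  lf_pos <- c(rec$subtir_lf_start,
              if (isTRUE(rec$has_ir)) rec$ir_lf_start else NULL,
              if (isTRUE(rec$has_microsat)) rec$ms_lf_start else NULL)
  lf_ok <- !is.unsorted(unlist(lf_pos), strictly = TRUE)
  rf_ok <- !isTRUE(rec$has_palindrome) ||
    rec$pal_rf_start > rec$subtir_rf_start
  isTRUE(lf_ok) && isTRUE(rf_ok) && isTRUE(rec$has_subtir)
}

.memberSubtirAnnotation <- function(uid, mem, subtir_seq, cfg) {
  pat <- Biostrings::DNAString(subtir_seq)
  out <- lapply(seq_len(nrow(mem)), function(r) {
    # matchPattern with max.mismatch can report matches protruding past
    # the subject ends; keep only fully in-bounds hits
    inbounds <- function(hits, subject_len) {
      hits[Biostrings::start(hits) >= 1L &
             Biostrings::end(hits) <= subject_len]
    }
    empty_hit <- Biostrings::matchPattern(pat,
      Biostrings::DNAString(strrep("N", length(pat))))
    lf_hit <- if (nchar(mem$lf[r]) >= length(pat))
      inbounds(Biostrings::matchPattern(pat,
                                        Biostrings::DNAString(mem$lf[r]),
                                        max.mismatch = cfg$motif_mismatch),
               nchar(mem$lf[r]))
    else empty_hit
    rf_hit <- if (nchar(mem$rf[r]) >= length(pat))
      inbounds(Biostrings::matchPattern(
        Biostrings::reverseComplement(pat),
        Biostrings::DNAString(mem$rf[r]),
        max.mismatch = cfg$motif_mismatch), nchar(mem$rf[r]))
    else empty_hit
    lf_mm <- if (length(lf_hit)) {
      min(vapply(seq_along(lf_hit), function(h)
        .hamming(as.character(lf_hit[[h]]), subtir_seq), integer(1)))
    } else NA_integer_
    rf_mm <- if (length(rf_hit)) {
      min(vapply(seq_along(rf_hit), function(h)
        .hamming(as.character(rf_hit[[h]]), revComp(subtir_seq)),
        integer(1)))
    } else NA_integer_
    data.frame(unit_id = uid, member_key = mem$member_key[r],
               subtir_lf_found = length(lf_hit) > 0L,
               subtir_lf_mismatches = lf_mm,
               subtir_rf_found = length(rf_hit) > 0L,
               subtir_rf_mismatches = rf_mm, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
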