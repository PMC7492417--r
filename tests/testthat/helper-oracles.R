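# Independent brute-force oracles (pure R, no shared code with the
# implementation) and small fixture builders used across the suite.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n, bases = BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

mutateFix <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  idx <- sample(seq_along(v), k)
  for (i in idx) v[i] <- sample(setdiff(BASES, v[i]), 1)
  paste(v, collapse = "")
}

mutateRate <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1)
  paste(v, collapse = "")
}

rcOracle <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

rotOracle <- function(seq, r) {
  n <- nchar(seq)
  r <- r %% n
  if (r == 0) return(seq)
  paste0(substr(seq, r + 1, n), substr(seq, 1, r))
}

# global alignment score by plain DP (no traceback); N matches nothing
oracleGlobalScore <- function(a, b, w) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  D <- matrix(0, n + 1, m + 1)
  D[1, ] <- (0:m) * w[3]
  D[, 1] <- (0:n) * w[3]
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (va[i] == vb[j] && va[i] != "N") w[1] else w[2]
    D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + w[3],
                           D[i + 1, j] + w[3])
  }
  D[n + 1, m + 1]
}

# global alignment with the same deterministic tie-break convention
# (diagonal, then gap in b, then gap in a); returns score, matches, columns
oracleGlobalFull <- function(a, b, w) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  D <- matrix(0, n + 1, m + 1)
  D[1, ] <- (0:m) * w[3]
  D[, 1] <- (0:n) * w[3]
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (va[i] == vb[j] && va[i] != "N") w[1] else w[2]
    D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + w[3],
                           D[i + 1, j] + w[3])
  }
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    s <- if (i > 0 && j > 0 && va[i] == vb[j] && va[i] != "N") w[1] else w[2]
    if (i > 0 && j > 0 && D[i + 1, j + 1] == D[i, j] + s) {
      matches <- matches + (va[i] == vb[j] && va[i] != "N")
      i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + w[3]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  list(score = D[n + 1, m + 1], matches = matches, columns = cols,
       identity = matches / cols)
}

# local alignment as exhaustive best-window enumeration: max global score
# over all substring pairs (lengths <= ~12 only)
oracleLocalEnum <- function(a, b, w) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      sc <- oracleGlobalScore(sa, substr(b, j1, j2), w)
      if (sc > best) best <- sc
    }
  }
  best
}

# Smith-Waterman score by plain R DP (independent implementation used at
# lengths where full enumeration is infeasible)
oracleLocalDP <- function(a, b, w) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  prev <- numeric(m + 1)
  best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    for (j in seq_len(m)) {
      s <- if (va[i] == vb[j] && va[i] != "N") w[1] else w[2]
      cur[j + 1] <- max(0, prev[j] + s, prev[j + 1] + w[3], cur[j] + w[3])
      if (cur[j + 1] > best) best <- cur[j + 1]
    }
    prev <- cur
  }
  best
}

# wraparound score oracle: max global score of the region against every
# substring of the monomer repeated enough times (small instances only)
oracleWraparound <- function(region, monomer, w) {
  reps <- strrep(monomer, ceiling(nchar(region) / nchar(monomer)) + 2)
  n <- nchar(reps)
  best <- -Inf
  for (i in seq_len(n)) for (j in i:n) {
    sc <- oracleGlobalScore(region, substr(reps, i, j), w)
    if (sc > best) best <- sc
  }
  best
}

# exhaustive palindrome decomposition oracle
oraclePalindrome <- function(window, min_arm = 5, min_loop = 3,
                             max_loop = 12, max_mm = 1) {
  v <- strsplit(window, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  n <- length(v)
  best <- NULL
  for (arm in seq(min_arm, (n - min_loop) %/% 2)) {
    for (loop in min_loop:max_loop) {
      span <- 2 * arm + loop
      if (span > n) next
      for (st in seq_len(n - span + 1)) {
        left <- v[st:(st + arm - 1)]
        right <- v[(st + arm + loop):(st + span - 1)]
        mm <- sum(left != comp[rev(right)])
        if (mm <= max_mm && (is.null(best) || arm > best$arm))
          best <- list(arm = arm, loop = loop, mm = mm, start = st)
      }
    }
  }
  best
}

# a perfect planted tandem fixture: unique left + copies x monomer + right;
# the three context bases on each side are forced to mismatch the cyclic
# continuation of the monomer so array boundaries are unambiguous
plantedArrayGenome <- function(monomer, copies, left = 500, right = 500,
                               name = "chr") {
  p <- nchar(monomer)
  lf <- strsplit(randSeq(left), "")[[1]]
  rf <- strsplit(randSeq(right), "")[[1]]
  mono <- strsplit(monomer, "")[[1]]
  for (t in 1:3) {
    # left context base at distance t from the array start continues the
    # cycle at monomer position p - t + 1; force a mismatch
    lf[left - t + 1] <- sample(setdiff(BASES, mono[(p - t) %% p + 1]), 1)
    rf[t] <- sample(setdiff(BASES, mono[(t - 1) %% p + 1]), 1)
  }
  seqs <- paste0(paste(lf, collapse = ""), strrep(monomer, copies),
                 paste(rf, collapse = ""))
  stats::setNames(seqs, name)
}
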