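## Word-seeded, ungapped-extension local matching engine.
##
## This one engine backs three analyses: short-repeat discovery within one
## genome (word size 7, BLASTN-like +2/-3 scoring with Karlin-Altschul
## E-values), inverted-repeat detection (word size 21, near-exact), and
## cross-genome homology interval mapping. Seeds are exact shared words;
## extension is ungapped along the diagonal with an X-drop stop, which keeps
## the hit set exactly reproducible and makes the exhaustive small-sequence
## oracle in the tests meaningful.

## Maximal-scoring segments over the run-length encoding of a diagonal
## match vector. Deterministic greedy X-drop: each emitted segment starts
## and ends on a match run; scanning resumes after the emitted best end.
## Returns a matrix with columns run_start, run_end, score.
segments_from_runs <- function(rl, rv, match, mismatch, xdrop) {
  R <- length(rl)
  rs <- ifelse(rv, match * rl, mismatch * rl)
  out <- vector("list", 0L)
  r <- 1L
  while (r <= R) {
    if (!rv[r]) { r <- r + 1L; next }
    cur <- 0; best <- 0; best_end <- r
    rr <- r
    while (rr <= R) {
      cur <- cur + rs[rr]
      if (cur > best && rv[rr]) { best <- cur; best_end <- rr }
      if (cur <= 0 || cur < best - xdrop) break
      rr <- rr + 1L
    }
    out[[length(out) + 1L]] <- c(r, best_end, best)
    r <- best_end + 1L
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

## Scan two integer-encoded sequences for ungapped local matches.
## x2 may be the same vector as x1 (self comparison) or a reverse complement;
## coordinate mapping back to the original strand is the caller's job.
## min_diag = 1 restricts a self comparison to the upper triangle.
scan_diagonal_hits <- function(x1, x2, word_size, match = 1, mismatch = -2,
                               min_score = 12, xdrop = 10, min_diag = NULL,
                               group_gap = 200L, pad = 60L) {
  n1 <- length(x1); n2 <- length(x2)
  k1 <- kmer_codes(x1, word_size)
  k2 <- kmer_codes(x2, word_size)
  if (length(k1) == 0L || length(k2) == 0L) return(empty_hits())
  d1 <- data.table::data.table(code = k1, i = seq_along(k1))[!is.na(code)]
  d2 <- data.table::data.table(code = k2, j = seq_along(k2))[!is.na(code)]
  pairs <- merge(d1, d2, by = "code", allow.cartesian = TRUE)
  if (nrow(pairs) == 0L) return(empty_hits())
  pairs[, diag := j - i]
  if (!is.null(min_diag)) pairs <- pairs[diag >= min_diag]
  if (nrow(pairs) == 0L) return(empty_hits())
  data.table::setorder(pairs, diag, i)
  # preallocated result columns, doubled on demand
  cap <- 1024L; nres <- 0L
  qs <- qe <- ln <- mt <- integer(cap); sc <- numeric(cap); dg <- integer(cap)
  push <- function(a, b, d, m, s) {
    if (nres == cap) {
      cap <<- cap * 2L
      length(qs) <<- cap; length(qe) <<- cap; length(ln) <<- cap
      length(mt) <<- cap; length(sc) <<- cap; length(dg) <<- cap
    }
    nres <<- nres + 1L
    qs[nres] <<- a; qe[nres] <<- b; dg[nres] <<- d
    ln[nres] <<- b - a + 1L; mt[nres] <<- m; sc[nres] <<- s
  }
  diag_groups <- split(pairs$i, pairs$diag)
  diags <- as.integer(names(diag_groups))
  for (idx in seq_along(diag_groups)) {
    d <- diags[idx]
    si <- diag_groups[[idx]]
    grp <- cumsum(c(1L, diff(si) > group_gap))
    for (g in split(si, grp)) {
      lo <- max(1L, 1L - d, min(g) - pad)
      hi <- min(n1, n2 - d, max(g) + word_size - 1L + pad)
      if (hi < lo) next
      mv <- x1[lo:hi] == x2[(lo:hi) + d]
      mv[is.na(mv)] <- FALSE
      r <- rle(mv)
      segs <- segments_from_runs(r$lengths, r$values, match, mismatch, xdrop)
      if (is.null(segs)) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (s in seq_len(nrow(segs))) {
        if (segs[s, 3] < min_score) next
        a <- starts[segs[s, 1]]; b <- ends[segs[s, 2]]
        push(lo + a - 1L, lo + b - 1L, d, sum(mv[a:b]), segs[s, 3])
      }
    }
  }
  if (nres == 0L) return(empty_hits())
  keep <- seq_len(nres)
  out <- data.frame(q_start = qs[keep], q_end = qe[keep],
                    s_start = qs[keep] + dg[keep], s_end = qe[keep] + dg[keep],
                    length = ln[keep], matches = mt[keep],
                    score = sc[keep], identity = mt[keep] / ln[keep])
  out[order(out$q_start, out$s_start), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             length = integer(0), matches = integer(0),
             score = numeric(0), identity = numeric(0))
}

## Map subject intervals found against a reverse complement back onto the
## forward strand of the original (length n) sequence.
map_rc_intervals <- function(hits, n) {
  if (nrow(hits) == 0L) return(hits)
  s1 <- n - hits$s_end + 1L
  s2 <- n - hits$s_start + 1L
  hits$s_start <- s1
  hits$s_end <- s2
  hits
}

## Both-orientation local hits between two sequences (or one against itself).
## Returns hits with an `orientation` column; subject coordinates are always
## on the forward strand of sequence 2.
pairwise_hits <- function(seq1, seq2 = NULL, word_size = 7, match = 1,
                          mismatch = -2, min_score = 12, xdrop = 10) {
  x1 <- seq_to_int(seq1)
  self <- is.null(seq2)
  if (self) seq2 <- seq1
  x2 <- seq_to_int(seq2)
  n2 <- length(x2)
  fwd <- scan_diagonal_hits(x1, x2, word_size, match, mismatch, min_score,
                            xdrop, min_diag = if (self) 1L else NULL)
  rc <- scan_diagonal_hits(x1, rev(5L - x2), word_size, match, mismatch,
                           min_score, xdrop)
  rc <- map_rc_intervals(rc, n2)
  if (self && nrow(rc) > 0L) {
    # a palindromic match reports itself; inverted pairs appear mirrored
    rc <- rc[!(rc$q_start == rc$s_start & rc$q_end == rc$s_end), , drop = FALSE]
    if (nrow(rc) > 0L) {
      swap <- rc$q_start > rc$s_start
      tmp_s <- rc$q_start[swap]; tmp_e <- rc$q_end[swap]
      rc$q_start[swap] <- rc$s_start[swap]; rc$q_end[swap] <- rc$s_end[swap]
      rc$s_start[swap] <- tmp_s; rc$s_end[swap] <- tmp_e
      rc <- unique(rc)
    }
  }
  fwd$orientation <- rep("direct", nrow(fwd))
  rc$orientation <- rep("inverted", nrow(rc))
  out <- rbind(fwd, rc)
  out[order(out$q_start, out$s_start), , drop = FALSE]
}
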