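#' Detect the quadripartite structure of a plastome
#'
#' Finds the longest pair of disjoint reverse-complement segments (the
#' inverted repeat, IR) of at least `min_len` bases at identity at least
#' `min_identity`, using exact 21-mer seeding of the sequence against its
#' reverse complement with ungapped chaining. The shorter single-copy
#' stretch between the two IR copies is labelled SSC, the longer LSC; with
#' the conventional linearisation (record starting in the LSC) the earlier
#' IR copy is IRb and the later IRa. Ties on IR length are broken by higher
#' identity, then by leftmost start.
#'
#' @param record A [plastome_record()] (or a plain DNA string).
#' @param min_len Minimum IR length in bases (>= 100).
#' @param min_identity Minimum reverse-complement identity, in (0.9, 1].
#' @return A `quadripartite_map`: list with `has_ir`, `ira`, `irb` (2-column
#'   start/end vectors), `lsc`, `ssc` (data frames of intervals; the LSC may
#'   wrap the origin and then has two rows), `ir_length`, `identity`,
#'   `nonredundant_length`, `genome_length`.
#' @export
detect_inverted_repeat <- function(record, min_len = 1000,
                                   min_identity = 0.99) {
  stopifnot(min_len >= 100, min_identity > 0.9, min_identity <= 1)
  seqc <- if (inherits(record, "plastome_record")) record$sequence else record
  n <- nchar(seqc)
  no_ir <- structure(list(has_ir = FALSE, ira = NULL, irb = NULL,
                          lsc = data.frame(start = 1L, end = n),
                          ssc = NULL, ir_length = 0L, identity = NA_real_,
                          nonredundant_length = n, genome_length = n),
                     class = "quadripartite_map")
  if (n < 2 * min_len) {
    warning("sequence shorter than twice min_len; reporting has_ir = FALSE")
    return(no_ir)
  }
  x <- seq_to_int(seqc)
  hits <- scan_diagonal_hits(x, rev(5L - x), word_size = 21L,
                             match = 1, mismatch = -3,
                             min_score = max(21, floor(min_len / 2)),
                             xdrop = 100, group_gap = 1000L, pad = 500L)
  hits <- map_rc_intervals(hits, n)
  if (nrow(hits) > 0L) {
    swap <- hits$q_start > hits$s_start
    if (any(swap)) {
      tmp_s <- hits$q_start[swap]; tmp_e <- hits$q_end[swap]
      hits$q_start[swap] <- hits$s_start[swap]
      hits$q_end[swap] <- hits$s_end[swap]
      hits$s_start[swap] <- tmp_s; hits$s_end[swap] <- tmp_e
    }
    hits <- unique(hits)
    ok <- hits$length >= min_len & hits$identity >= min_identity &
      hits$q_end < hits$s_start  # disjoint copies
    hits <- hits[ok, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(no_ir)
  hits <- hits[order(-hits$length, -hits$identity, hits$q_start), , drop = FALSE]
  h <- hits[1, ]
  irb <- c(start = h$q_start, end = h$q_end)
  ira <- c(start = h$s_start, end = h$s_end)
  between_len <- ira["start"] - irb["end"] - 1L
  wrap_len <- n - ira["end"] + irb["start"] - 1L
  between <- data.frame(start = irb["end"] + 1L, end = ira["start"] - 1L)
  wrap <- if (ira["end"] < n && irb["start"] > 1) {
    data.frame(start = c(ira["end"] + 1L, 1L), end = c(n, irb["start"] - 1L))
  } else if (ira["end"] < n) {
    data.frame(start = ira["end"] + 1L, end = n)
  } else if (irb["start"] > 1) {
    data.frame(start = 1L, end = irb["start"] - 1L)
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  if (between_len <= wrap_len) {
    ssc <- between; lsc <- wrap
  } else {
    ssc <- wrap; lsc <- between
  }
  structure(list(has_ir = TRUE, ira = ira, irb = irb, lsc = lsc, ssc = ssc,
                 ir_length = as.integer(h$length), identity = h$identity,
                 nonredundant_length = n - as.integer(h$length),
                 genome_length = n),
            class = "quadripartite_map")
}

#' @export
print.quadripartite_map <- function(x, ...) {
  if (!x$has_ir) {
    cat(sprintf("quadripartite_map: no IR detected (%d bp genome)\n",
                x$genome_length))
  } else {
    cat(sprintf(
      "quadripartite_map: IR %d bp at %.4f identity; non-redundant %d bp\n",
      x$ir_length, x$identity, x$nonredundant_length))
  }
  invisible(x)
}

#' Non-redundant plastome length (one IR copy retained)
#'
#' @param map A `quadripartite_map`.
#' @return Total genome length minus one IR copy when an IR is present,
#'   otherwise the total length.
#' @export
nonredundant_length <- function(map) {
  stopifnot(inherits(map, "quadripartite_map"))
  map$nonredundant_length
}

#' Extract the IR-reduced sequence (one IR copy removed)
#'
#' Removes the IRa copy, leaving LSC + IRb + SSC in genome order, the input
#' expected by the short-repeat and homology analyses.
#'
#' @param record A [plastome_record()].
#' @param map Optional precomputed `quadripartite_map`.
#' @param ... Passed to [detect_inverted_repeat()].
#' @return A DNA string.
#' @export
ir_reduced_sequence <- function(record, map = NULL, ...) {
  seqc <- if (inherits(record, "plastome_record")) record$sequence else record
  if (is.null(map)) map <- detect_inverted_repeat(record, ...)
  if (!map$has_ir) return(seqc)
  paste0(substring(seqc, 1L, map$ira["start"] - 1L),
         if (map$ira["end"] < nchar(seqc))
           substring(seqc, map$ira["end"] + 1L, nchar(seqc)) else "")
}

#' GC content by plastome region with bootstrap confidence intervals
#'
#' GC fraction per region (N bases excluded from numerator and denominator)
#' with a percentile 95% CI from a nonparametric bootstrap over
#' non-overlapping 1 kb windows (1000 resamples). Regions shorter than two
#' windows get an `NA` CI.
#'
#' @param record A [plastome_record()] or DNA string.
#' @param regions Named list of `c(start, end)` pairs, or a
#'   `quadripartite_map` (then LSC/SSC/IR regions are used).
#' @param window Bootstrap window size in bases.
#' @param n_boot Bootstrap resamples.
#' @return Data frame: region, gc, ci_lo, ci_hi, length; attribute
#'   `genome_gc` carries the genome-wide GC.
#' @export
gc_by_region <- function(record, regions = NULL, window = 1000L,
                         n_boot = 1000L) {
  seqc <- if (inherits(record, "plastome_record")) record$sequence else record
  n <- nchar(seqc)
  if (inherits(regions, "quadripartite_map")) {
    map <- regions
    regions <- list()
    reg_df <- function(df) lapply(seq_len(nrow(df)),
                                  function(i) c(df$start[i], df$end[i]))
    if (map$has_ir) {
      regions$LSC <- reg_df(map$lsc)
      regions$SSC <- reg_df(map$ssc)
      regions$IR <- list(unname(map$irb), unname(map$ira))
    } else {
      regions$LSC <- list(c(1L, n))
    }
  } else if (is.null(regions)) {
    regions <- list(genome = list(c(1L, n)))
  } else {
    regions <- lapply(regions, function(r) if (is.list(r)) r else list(r))
  }
  out <- lapply(names(regions), function(nm) {
    ivs <- regions[[nm]]
    for (iv in ivs) {
      if (iv[1] < 1 || iv[2] > n || iv[1] > iv[2])
        stop("region '", nm, "' outside the genome")
    }
    pieces <- vapply(ivs, function(iv) substring(seqc, iv[1], iv[2]), "")
    rseq <- paste(pieces, collapse = "")
    gcv <- gc_fraction(rseq)
    wins <- if (nchar(rseq) >= 2 * window) {
      substring(rseq, seq(1, nchar(rseq) - window + 1, by = window),
                seq(window, nchar(rseq), by = window))
    } else character(0)
    ci <- c(NA_real_, NA_real_)
    if (length(wins) >= 2) {
      wgc <- vapply(wins, gc_fraction, numeric(1))
      bs <- vapply(seq_len(n_boot), function(b)
        mean(sample(wgc, length(wgc), replace = TRUE)), numeric(1))
      ci <- unname(stats::quantile(bs, c(0.025, 0.975)))
    }
    data.frame(region = nm, gc = gcv, ci_lo = ci[1], ci_hi = ci[2],
               length = nchar(rseq))
  })
  res <- do.call(rbind, out)
  attr(res, "genome_gc") <- gc_fraction(seqc)
  res
}

#' Report the genes flanking the four IR junctions
#'
#' For the junctions JLB (LSC/IRb), JSB (IRb/SSC), JSA (SSC/IRa) and JLA
#' (IRa/LSC), reports the nearest annotated feature on each side with its
#' distance in bases; a feature spanning a junction is reported on both
#' sides with `overlap = TRUE`.
#'
#' @param record A [plastome_record()] with annotated features.
#' @param map A `quadripartite_map` with `has_ir = TRUE`.
#' @return Data frame: junction, position (last base before the boundary),
#'   upstream, upstream_dist, downstream, downstream_dist, overlap.
#' @export
junction_report <- function(record, map) {
  stopifnot(inherits(map, "quadripartite_map"))
  if (!map$has_ir) stop("no IR: junctions undefined")
  f <- record$features
  if (nrow(f) == 0) {
    warning("no features annotated; junction report is empty")
    return(data.frame(junction = character(0), position = integer(0),
                      upstream = character(0), upstream_dist = integer(0),
                      downstream = character(0), downstream_dist = integer(0),
                      overlap = logical(0)))
  }
  # Junction positions: boundary after the last base of the upstream region.
  ssc_between <- map$ssc$start[1] > map$irb["end"]
  jpos <- if (ssc_between) {
    c(JLB = unname(map$irb["start"] - 1L), JSB = unname(map$irb["end"]),
      JSA = unname(map$ira["start"] - 1L), JLA = unname(map$ira["end"]))
  } else {
    c(JSB = unname(map$irb["start"] - 1L), JLB = unname(map$irb["end"]),
      JLA = unname(map$ira["start"] - 1L), JSA = unname(map$ira["end"]))
  }
  n <- genome_length(record)
  out <- lapply(names(jpos), function(j) {
    p <- jpos[[j]]
    spans <- f$start <= p & f$end > p
    # circular distances from the junction boundary (after base p)
    up_dist <- (p - f$end) %% n
    dn_dist <- (f$start - p - 1L) %% n
    up <- if (any(spans)) which(spans)[1] else which.min(up_dist)
    dn <- if (any(spans)) which(spans)[1] else which.min(dn_dist)
    data.frame(junction = j, position = p,
               upstream = f$name[up],
               upstream_dist = if (spans[up]) 0L else up_dist[up],
               downstream = f$name[dn],
               downstream_dist = if (spans[dn]) 0L else dn_dist[dn],
               overlap = any(spans))
  })
  do.call(rbind, out)
}
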