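#' Scan a sequence for open reading frames
#'
#' Finds ORFs in all six frames (or one strand): each ORF starts at the
#' first ATG after the previous in-frame stop and runs to the next in-frame
#' stop (included) or to the end of the sequence. Coordinates are reported
#' on the forward strand of the input, 1-based inclusive.
#'
#' @param sequence DNA string.
#' @param strand `"both"`, `"+"` or `"-"`.
#' @param min_codons Minimum ORF length in codons, stop included (>= 10 by
#'   spec of the classifier; smaller values allowed for toy sequences).
#' @return Data frame: start, end, strand, frame, n_codons, has_stop.
#' @export
orf_scan <- function(sequence, strand = c("both", "+", "-"), min_codons = 10L) {
  strand <- match.arg(strand)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  scan_one <- function(s, str) {
    res <- NULL
    for (fr in 0:2) {
      ncod <- (nchar(s) - fr) %/% 3L
      if (ncod < 1) next
      cods <- substring(s, fr + seq(1, by = 3, length.out = ncod),
                        fr + seq(3, by = 3, length.out = ncod))
      is_stop <- cods %in% stops
      is_atg <- cods == "ATG"
      seg <- cumsum(c(TRUE, head(is_stop, -1)))  # segment id after each stop
      for (g in split(seq_len(ncod), seg)) {
        a <- g[is_atg[g]]
        if (length(a) == 0) next
        a <- a[1]
        stop_in <- g[is_stop[g]]
        b <- if (length(stop_in) > 0) stop_in[1] else g[length(g)]
        if (b < a) next
        len <- b - a + 1L
        if (len < min_codons) next
        p1 <- fr + (a - 1L) * 3L + 1L
        p2 <- fr + b * 3L
        if (str == "+") {
          res <- rbind(res, data.frame(start = p1, end = p2, strand = "+",
                                       frame = fr + 1L, n_codons = len,
                                       has_stop = length(stop_in) > 0))
        } else {
          res <- rbind(res, data.frame(start = n - p2 + 1L, end = n - p1 + 1L,
                                       strand = "-", frame = fr + 1L,
                                       n_codons = len,
                                       has_stop = length(stop_in) > 0))
        }
      }
    }
    res
  }
  out <- NULL
  if (strand %in% c("both", "+")) out <- rbind(out, scan_one(sequence, "+"))
  if (strand %in% c("both", "-"))
    out <- rbind(out, scan_one(revcomp(sequence), "-"))
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      n_codons = integer(0), has_stop = logical(0)))
  out[order(out$start, out$end), , drop = FALSE]
}

#' Default alignment scoring for coverage computation
#'
#' Global (Needleman-Wunsch) scoring: match +1, mismatch -1, gap open -5,
#' gap extend -1 (first gap base costs -5, each additional base -1).
#'
#' @return A named list of scoring parameters.
#' @export
alignment_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = -5, gap_extend = -1)
}

#' Global alignment and reference coverage
#'
#' Optimal global alignment of a reference CDS against a query ORF under
#' affine gap costs. Coverage is the fraction of reference bases aligned to
#' query bases (not gaps), the annotation-coverage definition used for the
#' intact/pseudogene decision.
#'
#' @param ref_cds Reference CDS string.
#' @param query_orf Query ORF string.
#' @param scoring Scoring list as from [alignment_scoring()].
#' @return List: score, coverage, aligned_ref_bases, ref_length,
#'   alignment (two aligned strings).
#' @export
global_align <- function(ref_cds, query_orf, scoring = alignment_scoring()) {
  if (nchar(ref_cds) == 0 || nchar(query_orf) == 0)
    stop("global_align requires non-empty sequences")
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  # Biostrings charges gapOpening + L * gapExtension for an L-base gap;
  # the stated open/extend convention charges open + (L-1) * extend.
  go <- -(scoring$gap_open - scoring$gap_extend)
  ge <- -scoring$gap_extend
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(ref_cds)),
    subject = Biostrings::DNAString(toupper(query_orf)),
    substitutionMatrix = sm, gapOpening = go, gapExtension = ge,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  aligned <- sum(pa != "-" & sa != "-")
  list(score = Biostrings::score(al),
       coverage = aligned / nchar(ref_cds),
       aligned_ref_bases = aligned,
       ref_length = nchar(ref_cds),
       alignment = c(ref = paste(pa, collapse = ""),
                     query = paste(sa, collapse = "")))
}

#' Classify one gene from its reference coverage
#'
#' Coverage at or above the threshold (default 70%, inclusive) is intact;
#' below is pseudogene. A gene with no detectable homologous region in the
#' genome is lost (`present = FALSE`). Genes on the override list (default
#' `psbI`, whose shortened CDS is a normal autotroph variant) are annotated
#' intact whenever present with coverage at least `override_floor`.
#'
#' @param coverage Coverage in `[0, 1]` (ignored when `present = FALSE`).
#' @param threshold Intactness threshold (inclusive).
#' @param present Is any homologous region detectable in the genome?
#' @param gene Optional gene symbol, checked against `overrides`.
#' @param overrides Character vector of exception genes.
#' @param override_floor Minimum coverage for an override to apply.
#' @return `"intact"`, `"pseudogene"` or `"lost"`.
#' @export
classify_gene <- function(coverage, threshold = 0.70, present = TRUE,
                          gene = NULL, overrides = "psbI",
                          override_floor = 0.5) {
  if (!present) return("lost")
  stopifnot(coverage >= 0, coverage <= 1)
  if (coverage >= threshold) return("intact")
  if (!is.null(gene) && gene %in% overrides && coverage >= override_floor)
    return("intact")
  "pseudogene"
}

#' Apply the coordinated ndh-gene rule
#'
#' If any ndh gene is a pseudogene or lost, every ndh gene is downgraded:
#' intact calls become pseudogene (the sequence is still present), lost
#' calls stay lost. Coverage values are preserved as evidence and
#' `cascade_applied` marks the calls changed by the rule. The rule reflects
#' the all-or-none assembly of the NDH complex. Idempotent.
#'
#' @param calls Data frame of gene-status calls with columns `gene`,
#'   `status`, `coverage`, `cascade_applied`.
#' @return The updated calls.
#' @export
apply_ndh_cascade <- function(calls) {
  ndh <- grepl("^ndh", calls$gene)
  if (!any(ndh)) return(calls)
  if (any(calls$status[ndh] != "intact")) {
    change <- ndh & calls$status == "intact"
    calls$status[change] <- "pseudogene"
    calls$cascade_applied[change] <- TRUE
  }
  calls
}

#' Classify every reference gene in a plastome
#'
#' For each reference CDS: locate the homologous region in the genome (seed
#' and extend, anchors of at least `min_anchor` bases); if none, the gene is
#' lost. Otherwise align the maximal-coverage candidate ORF overlapping the
#' locus to the reference CDS and classify by coverage. The coordinated
#' ndh rule is applied afterwards unless `cascade = FALSE`.
#'
#' @param record A [plastome_record()].
#' @param ref_cds Named character vector (or `DNAStringSet`) of reference
#'   CDS sequences.
#' @param threshold Coverage threshold for intactness.
#' @param min_anchor Minimum homology anchor (bases) for gene presence.
#' @param cascade Apply [apply_ndh_cascade()]?
#' @param overrides Exception genes passed to [classify_gene()].
#' @param min_codons Minimum candidate ORF length in codons.
#' @return Data frame: gene, coverage, status, cascade_applied, reason.
#' @export
classify_genome <- function(record, ref_cds, threshold = 0.70,
                            min_anchor = 50L, cascade = TRUE,
                            overrides = "psbI", min_codons = 10L) {
  if (methods::is(ref_cds, "DNAStringSet"))
    ref_cds <- setNames(as.character(ref_cds), names(ref_cds))
  genome <- record$sequence
  orfs <- orf_scan(genome, min_codons = min_codons)
  calls <- lapply(names(ref_cds), function(g) {
    hits <- pairwise_hits(ref_cds[[g]], genome, word_size = 11L,
                          min_score = min_anchor - 10L)
    hits <- hits[hits$length >= min_anchor, , drop = FALSE]
    if (nrow(hits) == 0L) {
      return(data.frame(gene = g, coverage = NA_real_, status = "lost",
                        cascade_applied = FALSE,
                        reason = "no homologous region"))
    }
    # the gene locus: hits clustering around the strongest anchor (a gene
    # inside the IR also hits its mirrored copy; only one locus is scored)
    bh <- hits[which.max(hits$length), ]
    near <- hits[hits$orientation == bh$orientation &
                   hits$s_start <= bh$s_end + 5000L &
                   hits$s_end >= bh$s_start - 5000L, , drop = FALSE]
    lo <- min(near$s_start); hi <- max(near$s_end)
    cand <- orfs[orfs$end >= lo & orfs$start <= hi, , drop = FALSE]
    # keep candidates in the reading frame implied by the strongest
    # anchor: an ORF in another frame over the same DNA aligns at the
    # nucleotide level with spuriously high coverage
    if (nrow(cand) > 0L) {
      inframe <- if (bh$orientation == "direct") {
        off <- bh$s_start - bh$q_start
        cand$strand == "+" & ((cand$start - off - 1L) %% 3L == 0L)
      } else {
        cand$strand == "-" &
          ((bh$q_start + bh$s_end - cand$end - 1L) %% 3L == 0L)
      }
      if (any(inframe)) cand <- cand[inframe, , drop = FALSE]
    }
    if (nrow(cand) == 0L) {
      return(data.frame(gene = g, coverage = 0, status = "pseudogene",
                        cascade_applied = FALSE,
                        reason = "homologous region without candidate ORF"))
    }
    # coverage cannot exceed len(candidate)/len(reference): scan in
    # decreasing length and stop once no shorter ORF can beat the best
    cand <- cand[order(-(cand$end - cand$start)), , drop = FALSE]
    rlen <- nchar(ref_cds[[g]])
    best <- 0
    for (i in seq_len(nrow(cand))) {
      if ((cand$end[i] - cand$start[i] + 1) / rlen <= best) break
      q <- substring(genome, cand$start[i], cand$end[i])
      if (cand$strand[i] == "-") q <- revcomp(q)
      best <- max(best, global_align(ref_cds[[g]], q)$coverage)
    }
    data.frame(gene = g, coverage = best,
               status = classify_gene(best, threshold, TRUE, g, overrides),
               cascade_applied = FALSE,
               reason = sprintf("best ORF coverage %.3f over %d candidates",
                                best, nrow(cand)))
  })
  calls <- do.call(rbind, calls)
  if (cascade) calls <- apply_ndh_cascade(calls)
  calls
}

#' Genes intact in every genome of a set
#'
#' @param status_list Named list of gene-status data frames (one per
#'   genome, as from [classify_genome()]).
#' @param gene_universe Genes every genome must report on.
#' @return Character vector of genes intact everywhere.
#' @export
shared_gene_set <- function(status_list, gene_universe) {
  for (nm in names(status_list)) {
    missing <- setdiff(gene_universe, status_list[[nm]]$gene)
    if (length(missing) > 0)
      stop("genome '", nm, "' lacks status calls for: ",
           paste(missing, collapse = ", "))
  }
  keep <- gene_universe
  for (st in status_list) {
    ok <- st$gene[st$status == "intact"]
    keep <- intersect(keep, ok)
  }
  keep
}
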