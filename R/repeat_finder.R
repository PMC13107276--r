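## Karlin-Altschul parameters for ungapped +1/-2 nucleotide scoring
## (the classic blastn default pair for these scores).
KA_LAMBDA <- 1.33
KA_K <- 0.62

#' Find short dispersed repeats by genome self-comparison
#'
#' Self-alignment of an IR-reduced plastome (one IR copy retained) with
#' exact word seeds (default word size 7) and ungapped X-drop extension
#' scored +1/-2. Hit significance is the Karlin-Altschul expectation
#' E = K m n exp(-lambda S). The self-diagonal is excluded, inverted hits
#' are deduplicated keeping the pair with the smaller first coordinate, and
#' hits of 500 bp or more are discarded (they belong to the large-repeat
#' class, not the short-repeat class analysed here).
#'
#' @param sequence IR-reduced DNA string (or a [plastome_record()]; the raw
#'   record sequence is then used as-is, reduce it first with
#'   [ir_reduced_sequence()]).
#' @param word_size Exact seed length (>= 4).
#' @param max_evalue Report hits with E-value at most this (default 6, the
#'   relaxed threshold used for repeat-content comparisons).
#' @param max_len Hits at or above this length are discarded.
#' @return Data frame of hits: q_start, q_end, s_start, s_end, orientation,
#'   length, matches, identity, score, evalue.
#' @export
find_short_repeats <- function(sequence, word_size = 7L, max_evalue = 6,
                               max_len = 500L) {
  if (word_size < 4L) stop("word_size < 4 would explode the seed set")
  seqc <- if (inherits(sequence, "plastome_record")) sequence$sequence else sequence
  n <- nchar(seqc)
  min_score <- max(word_size + 1L,
                   ceiling(log(KA_K * as.numeric(n) * n / max_evalue) / KA_LAMBDA))
  hits <- pairwise_hits(seqc, NULL, word_size = word_size,
                        match = 1, mismatch = -2,
                        min_score = min_score, xdrop = 10)
  if (nrow(hits) == 0L) {
    hits$evalue <- numeric(0)
    return(hits)
  }
  hits$evalue <- KA_K * as.numeric(n) * n * exp(-KA_LAMBDA * hits$score)
  hits <- hits[hits$length < max_len & hits$evalue <= max_evalue, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Merge repeat hits into a non-redundant genomic footprint
#'
#' Unions the query and subject intervals of a hit set; overlapping or
#' bookended intervals are merged.
#'
#' @param hits Hit data frame (from [find_short_repeats()]).
#' @return List: `intervals` (data frame start/end) and `total_length`.
#' @export
merge_hits <- function(hits) {
  if (nrow(hits) == 0L)
    return(list(intervals = data.frame(start = integer(0), end = integer(0)),
                total_length = 0L))
  ir <- IRanges::reduce(IRanges::IRanges(
    start = c(hits$q_start, hits$s_start),
    end = c(hits$q_end, hits$s_end)))
  list(intervals = data.frame(start = BiocGenerics::start(ir),
                              end = BiocGenerics::end(ir)),
       total_length = sum(IRanges::width(ir)))
}

#' Short-repeat content across E-value thresholds
#'
#' Computes the merged short-repeat footprint at each E-value threshold;
#' content is the merged length divided by the (IR-reduced) sequence
#' length. One hit search at the loosest threshold is filtered per
#' threshold, so content is monotone non-decreasing in E by construction.
#'
#' @param sequence IR-reduced DNA string.
#' @param thresholds E-value thresholds (default spans 1e-10 to the relaxed
#'   value 6).
#' @param word_size Seed word size.
#' @return Data frame: threshold, length, content.
#' @export
repeat_content_curve <- function(sequence,
                                 thresholds = c(1e-10, 1e-5, 1e-2, 1, 6),
                                 word_size = 7L) {
  seqc <- if (inherits(sequence, "plastome_record")) sequence$sequence else sequence
  n <- nchar(seqc)
  thresholds <- sort(thresholds)
  hits <- find_short_repeats(seqc, word_size = word_size,
                             max_evalue = max(thresholds))
  out <- lapply(thresholds, function(t) {
    m <- merge_hits(hits[hits$evalue <= t, , drop = FALSE])
    data.frame(threshold = t, length = m$total_length,
               content = m$total_length / n)
  })
  do.call(rbind, out)
}

#' Slope of repeat content against log10 E-value
#'
#' Ordinary least squares of content on log10(E) with a t-based 95%
#' confidence interval; the slope measures how much low-similarity repeat
#' sequence a genome accumulates as the threshold relaxes.
#'
#' @param profile Data frame from [repeat_content_curve()].
#' @return List: slope, ci95, r2, n.
#' @export
content_slope <- function(profile) {
  if (nrow(profile) < 3) stop("need at least 3 thresholds for a slope")
  fit <- lm(content ~ log10(threshold), data = profile)
  sl <- unname(coef(fit)[2])
  ci <- tryCatch(suppressWarnings(confint(fit)[2, ]),
                 error = function(e) c(NA_real_, NA_real_))
  if (!any(is.na(ci)) && (sl < ci[1] || sl > ci[2])) ci <- sort(ci)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = sl, ci95 = unname(ci), r2 = r2, n = nrow(profile))
}
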