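#' Homology intervals between two (IR-reduced) plastomes
#'
#' Cross-genome local matching with the same seed-and-extend engine as the
#' repeat search (word size 7, +2/-3, ungapped). Anchors shorter than
#' `min_anchor` are dropped as seed-level noise, then anchor footprints are
#' merged (per orientation kept in the hit table, merged regardless of
#' orientation in the interval lists).
#'
#' @param query,reference DNA strings (IR-reduced) or [plastome_record()]s.
#' @param word_size Seed word size.
#' @param min_anchor Minimum anchor length in bases.
#' @param max_gap Merge anchors separated by at most this many bases.
#' @return A `homology_map`: list with `query_id`, `reference_id`,
#'   `query_length`, `reference_length`, `hits`, `intervals_on_query`,
#'   `intervals_on_reference` (data frames start/end).
#' @export
homology_intervals <- function(query, reference, word_size = 7L,
                               min_anchor = 30L, max_gap = 25L) {
  qid <- if (inherits(query, "plastome_record")) query$id else "query"
  rid <- if (inherits(reference, "plastome_record")) reference$id else "reference"
  qs <- if (inherits(query, "plastome_record")) query$sequence else query
  rs <- if (inherits(reference, "plastome_record")) reference$sequence else reference
  hits <- pairwise_hits(qs, rs, word_size = word_size, match = 1,
                        mismatch = -2,
                        min_score = max(word_size + 1L, min_anchor - 10L),
                        xdrop = 10)
  hits <- hits[hits$length >= min_anchor, , drop = FALSE]
  merge_iv <- function(st, en, gap) {
    if (length(st) == 0L)
      return(data.frame(start = integer(0), end = integer(0)))
    ir <- IRanges::reduce(IRanges::IRanges(start = st, end = en),
                          min.gapwidth = gap + 1L)
    data.frame(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
  }
  structure(list(query_id = qid, reference_id = rid,
                 query_length = nchar(qs), reference_length = nchar(rs),
                 hits = hits,
                 intervals_on_query = merge_iv(hits$q_start, hits$q_end, max_gap),
                 intervals_on_reference = merge_iv(hits$s_start, hits$s_end, max_gap)),
            class = "homology_map")
}

interval_complement <- function(iv, len, min_fragment = 1L) {
  ir <- IRanges::IRanges(start = iv$start, end = iv$end)
  comp <- IRanges::setdiff(IRanges::IRanges(1L, len), ir)
  comp <- comp[IRanges::width(comp) >= min_fragment]
  data.frame(start = BiocGenerics::start(comp), end = BiocGenerics::end(comp))
}

#' Classify insertions and deletions from a homology map
#'
#' Query sequence without reference homology is insertion; reference
#' sequence without query homology is deletion. Contents follow the
#' comparative-plastomics convention: insertion content is insertion length
#' over the query genome length, deletion content is deletion length over
#' the reference genome length.
#'
#' @param map A `homology_map` from [homology_intervals()].
#' @param min_fragment Fragments below this length are dropped.
#' @return List: insertions, deletions (data frames), insertion_length,
#'   deletion_length, insertion_content, deletion_content.
#' @export
classify_indels <- function(map, min_fragment = 30L) {
  stopifnot(inherits(map, "homology_map"))
  ins <- interval_complement(map$intervals_on_query, map$query_length,
                             min_fragment)
  del <- interval_complement(map$intervals_on_reference, map$reference_length,
                             min_fragment)
  ilen <- if (nrow(ins)) sum(ins$end - ins$start + 1L) else 0L
  dlen <- if (nrow(del)) sum(del$end - del$start + 1L) else 0L
  list(insertions = ins, deletions = del,
       insertion_length = ilen, deletion_length = dlen,
       insertion_content = ilen / map$query_length,
       deletion_content = dlen / map$reference_length)
}

#' Fragments of a genome with no homology in any comparator
#'
#' Complement, on the target, of the union of homology intervals against
#' every comparator genome. Fragments are annotated with any overlapping
#' gene feature and with IR membership when a quadripartite map is given.
#'
#' @param target A [plastome_record()] or DNA string (IR-reduced).
#' @param comparators Named list of DNA strings / records.
#' @param min_fragment Minimum reported fragment length.
#' @param map Optional `quadripartite_map` of the target for the IR flag.
#' @param ... Passed to [homology_intervals()].
#' @return Data frame: start, end, length, gene, in_ir.
#' @export
species_specific_fragments <- function(target, comparators,
                                       min_fragment = 30L, map = NULL, ...) {
  stopifnot(length(comparators) >= 1)
  ts <- if (inherits(target, "plastome_record")) target$sequence else target
  all_iv <- data.frame(start = integer(0), end = integer(0))
  for (comp in comparators) {
    hm <- homology_intervals(ts, comp, ...)
    all_iv <- rbind(all_iv, hm$intervals_on_query)
  }
  union_iv <- if (nrow(all_iv)) {
    ir <- IRanges::reduce(IRanges::IRanges(all_iv$start, all_iv$end))
    data.frame(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
  } else all_iv
  frag <- interval_complement(union_iv, nchar(ts), min_fragment)
  if (nrow(frag) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gene = character(0),
                      in_ir = logical(0)))
  frag$length <- frag$end - frag$start + 1L
  feats <- if (inherits(target, "plastome_record")) target$features else
    empty_features()
  frag$gene <- vapply(seq_len(nrow(frag)), function(i) {
    ov <- feats$start <= frag$end[i] & feats$end >= frag$start[i]
    if (any(ov)) paste(unique(feats$name[ov]), collapse = ",") else NA_character_
  }, character(1))
  frag$in_ir <- if (!is.null(map) && isTRUE(map$has_ir)) {
    frag$start <= map$irb["end"] & frag$end >= map$irb["start"] |
      frag$start <= map$ira["end"] & frag$end >= map$ira["start"]
  } else NA
  frag
}
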