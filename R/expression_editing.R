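#' Fragment counts container
#'
#' @param counts Feature-by-sample matrix of fragment counts (a properly
#'   paired read pair is one fragment).
#' @param lengths Feature lengths in bases (named or in row order).
#' @param totals Total fragments mapped per sample, both strands (defaults
#'   to the column sums, i.e. the features partition all mapped fragments).
#' @param strand Optional per-feature strand.
#' @return A `fragment_counts` list.
#' @export
fragment_counts <- function(counts, lengths, totals = colSums(counts),
                            strand = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), all(lengths > 0),
            length(lengths) == nrow(counts),
            length(totals) == ncol(counts))
  if (any(totals < apply(counts, 2, max)))
    stop("per-sample totals below a per-feature count")
  structure(list(counts = counts, lengths = lengths, totals = totals,
                 strand = strand), class = "fragment_counts")
}

#' FPKM from fragment counts
#'
#' FPKM = (fragments for the feature x 1e6) / (total fragments in the
#' sample x feature length in kilobases).
#'
#' @param fc A [fragment_counts()] object.
#' @return Feature-by-sample FPKM matrix.
#' @export
fpkm <- function(fc) {
  stopifnot(inherits(fc, "fragment_counts"))
  if (any(fc$totals <= 0)) stop("zero total fragments in a sample")
  len_kb <- fc$lengths / 1000
  sweep(fc$counts / len_kb, 2, fc$totals / 1e6, "/")
}

#' Hierarchical clustering of an expression matrix
#'
#' Average-linkage (UPGMA) agglomeration on Euclidean distances, over both
#' features (rows) and samples (columns), with Newick exports of the two
#' dendrograms.
#'
#' @param mat Numeric matrix (e.g. FPKM), features x samples.
#' @return List: `features`, `samples` (hclust objects), `feature_newick`,
#'   `sample_newick`.
#' @export
cluster_expression <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("expression matrix contains non-finite values")
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need at least 2 features and 2 samples")
  hf <- hclust(dist(mat, method = "euclidean"), method = "average")
  hs <- hclust(dist(t(mat), method = "euclidean"), method = "average")
  list(features = hf, samples = hs,
       feature_newick = ape::write.tree(ape::as.phylo(hf)),
       sample_newick = ape::write.tree(ape::as.phylo(hs)))
}

#' RNA-editing caller thresholds
#'
#' Defaults follow common organellar variant-calling practice: minimum
#' coverage 60, minimum variant frequency 10%, maximum binomial variant
#' p-value 1e-6 (against the sequencing error rate), and a strand-bias
#' filter that applies only when one strand carries more than 65% of the
#' variant reads, rejecting the site when the two-sided Fisher test of
#' variant versus total reads by strand has p below 1e-5.
#'
#' @param min_coverage,min_freq,max_variant_p,strand_bias_p,bias_threshold,error_rate
#'   Caller thresholds; see description.
#' @return Named list of parameters.
#' @export
editing_params <- function(min_coverage = 60L, min_freq = 0.10,
                           max_variant_p = 1e-6, strand_bias_p = 1e-5,
                           bias_threshold = 0.65, error_rate = 0.001) {
  stopifnot(min_coverage > 0, min_freq > 0, min_freq < 1,
            max_variant_p > 0, strand_bias_p > 0, error_rate > 0)
  list(min_coverage = min_coverage, min_freq = min_freq,
       max_variant_p = max_variant_p, strand_bias_p = strand_bias_p,
       bias_threshold = bias_threshold, error_rate = error_rate)
}

#' Call C-to-U RNA-editing sites from a strand-resolved pileup
#'
#' A site is called when (i) total coverage meets `min_coverage`, (ii) the
#' variant fraction meets `min_freq`, (iii) the one-sided binomial tail
#' P(X >= x | n, error_rate) is at most `max_variant_p`, and (iv) when one
#' strand carries more than `bias_threshold` of the variant reads, the
#' two-sided Fisher strand test does not reject (p >= `strand_bias_p`).
#' Only reference-C positions with T variants (sense-strand C-to-U) and
#' reference-G positions with A variants (editing of a minus-strand gene)
#' are considered candidates. Efficiency is the variant fraction.
#'
#' @param pileup Data frame with columns `pos`, `strand` (`"+"`/`"-"`, the
#'   read strand), `ref`, `A`, `C`, `G`, `T` (one row per position and
#'   strand).
#' @param cds_map Optional CDS table (columns `gene`, `start`, `end`,
#'   `strand`) used to assign gene, codon position and silent status.
#' @param params Thresholds from [editing_params()].
#' @param genome Genome string; required for silent/non-silent annotation.
#' @return Data frame: pos, ref, alt, coverage, variant_reads, efficiency,
#'   edit_type, gene, codon_pos, cds_codon, silent.
#' @export
call_editing_sites <- function(pileup, cds_map = NULL,
                               params = editing_params(), genome = NULL) {
  stopifnot(all(c("pos", "strand", "ref", "A", "C", "G", "T") %in%
                  names(pileup)))
  dt <- data.table::as.data.table(pileup)
  tot <- dt[, .(ref = ref[1],
                A = sum(A), C = sum(C), G = sum(G), T = sum(T),
                A_plus = sum(A[strand == "+"]), T_plus = sum(T[strand == "+"]),
                cov_plus = sum(A[strand == "+"] + C[strand == "+"] +
                                 G[strand == "+"] + T[strand == "+"])),
            by = pos]
  tot[, coverage := A + C + G + T]
  tot[, alt := ifelse(ref == "C", "T", ifelse(ref == "G", "A", NA_character_))]
  tot <- tot[!is.na(alt)]
  tot[, x := ifelse(alt == "T", T, A)]
  tot[, x_plus := ifelse(alt == "T", T_plus, A_plus)]
  tot <- tot[coverage >= params$min_coverage & x / coverage >= params$min_freq]
  if (nrow(tot) == 0L) return(empty_editing_sites())
  tot[, p_var := pbinom(x - 1L, coverage, params$error_rate,
                        lower.tail = FALSE)]
  tot <- tot[p_var <= params$max_variant_p]
  if (nrow(tot) == 0L) return(empty_editing_sites())
  keep <- vapply(seq_len(nrow(tot)), function(i) {
    xp <- tot$x_plus[i]; xm <- tot$x[i] - tot$x_plus[i]
    if (tot$x[i] == 0) return(TRUE)
    bias <- max(xp, xm) / tot$x[i]
    if (bias <= params$bias_threshold) return(TRUE)
    np <- tot$cov_plus[i]; nm <- tot$coverage[i] - tot$cov_plus[i]
    tab <- matrix(c(xp, np - xp, xm, nm - xm), nrow = 2)
    fisher.test(tab)$p.value >= params$strand_bias_p
  }, logical(1))
  tot <- tot[keep]
  if (nrow(tot) == 0L) return(empty_editing_sites())
  out <- data.frame(pos = tot$pos, ref = tot$ref, alt = tot$alt,
                    coverage = tot$coverage, variant_reads = tot$x,
                    efficiency = tot$x / tot$coverage,
                    edit_type = "C-to-U",
                    gene = NA_character_, codon_pos = NA_integer_,
                    cds_codon = NA_integer_, silent = NA)
  if (!is.null(cds_map) && nrow(cds_map) > 0) {
    for (i in seq_len(nrow(out))) {
      hit <- which(cds_map$start <= out$pos[i] & cds_map$end >= out$pos[i])
      if (length(hit) == 0) next
      hit <- hit[1]
      ann <- annotate_cds_position(out$pos[i], out$alt[i], cds_map[hit, ],
                                   genome)
      out$gene[i] <- cds_map$gene[hit]
      out$codon_pos[i] <- ann$codon_pos
      out$cds_codon[i] <- ann$codon_number
      out$silent[i] <- ann$silent
    }
  }
  out
}

empty_editing_sites <- function() {
  data.frame(pos = integer(0), ref = character(0), alt = character(0),
             coverage = integer(0), variant_reads = integer(0),
             efficiency = numeric(0), edit_type = character(0),
             gene = character(0), codon_pos = integer(0),
             cds_codon = integer(0), silent = logical(0))
}

## Codon position / silent annotation of a substitution inside one CDS row.
annotate_cds_position <- function(pos, alt, cds_row, genome) {
  if (cds_row$strand == "+") {
    off <- pos - cds_row$start  # 0-based offset in CDS
  } else {
    off <- cds_row$end - pos
  }
  codon_number <- off %/% 3L + 1L
  codon_pos <- off %% 3L + 1L
  silent <- NA
  if (!is.null(genome)) {
    if (cds_row$strand == "+") {
      c0 <- cds_row$start + (codon_number - 1L) * 3L
      codon <- substring(genome, c0, c0 + 2L)
      mut <- codon
      substr(mut, codon_pos, codon_pos) <- alt
    } else {
      c0 <- cds_row$end - (codon_number - 1L) * 3L
      codon <- revcomp(substring(genome, c0 - 2L, c0))
      mut <- codon
      altc <- chartr("ACGT", "TGCA", alt)
      substr(mut, codon_pos, codon_pos) <- altc
    }
    silent <- identical(translate_codons(codon), translate_codons(mut))
  }
  list(codon_number = codon_number, codon_pos = codon_pos, silent = silent)
}

#' Editing sites shared by every species and their efficiency matrix
#'
#' Sites are matched by gene and CDS codon coordinate (falling back to
#' genomic position for intergenic sites). Only sites present in every
#' species are kept.
#'
#' @param site_lists Named list of editing-site data frames (from
#'   [call_editing_sites()]).
#' @return List: `sites` (character keys), `efficiency` (species x sites
#'   matrix).
#' @export
shared_editing_sites <- function(site_lists) {
  stopifnot(length(site_lists) >= 2)
  key_of <- function(df) {
    ifelse(is.na(df$gene), paste0("pos:", df$pos),
           paste0(df$gene, ":", df$cds_codon, ":", df$codon_pos))
  }
  keys <- lapply(site_lists, key_of)
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) {
    warning("no editing sites shared by all species")
    return(list(sites = character(0),
                efficiency = matrix(numeric(0), nrow = length(site_lists),
                                    ncol = 0,
                                    dimnames = list(names(site_lists), NULL))))
  }
  eff <- matrix(NA_real_, nrow = length(site_lists), ncol = length(common),
                dimnames = list(names(site_lists), common))
  for (i in seq_along(site_lists)) {
    eff[i, ] <- site_lists[[i]]$efficiency[match(common, keys[[i]])]
  }
  list(sites = common, efficiency = eff)
}
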