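#' @importFrom stats optim optimize setNames lm coef pbinom rbinom rnbinom
#'   runif rnorm sample.int aov fisher.test shapiro.test cor.test p.adjust
#'   pchisq qt pt var sd median dist hclust as.dendrogram qwilcox confint
#' @importFrom utils head tail combn
#' @importFrom data.table data.table as.data.table setorder := .N
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-string wrapper around [Biostrings::reverseComplement()].
#'
#' @param x A single DNA string over `A,C,G,T,N`.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Integer encoding A=1 C=2 G=3 T=4, N/other = NA.
seq_to_int <- function(x) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  match(v, DNA_BASES)
}

int_to_seq <- function(v) paste(DNA_BASES[v], collapse = "")

## k-mer integer codes (base-4); windows containing N -> NA.
## Returns vector of length n-k+1.
kmer_codes <- function(iv, k) {
  n <- length(iv)
  if (n < k) return(integer(0))
  v <- iv - 1L
  v[is.na(v)] <- -1e6  # poison N so any window containing it goes negative
  code <- numeric(n - k + 1L)
  for (j in seq_len(k)) {
    code <- code + v[j:(n - k + j)] * 4^(k - j)
  }
  code[code < 0] <- NA_real_
  code
}

## Validate a DNA string, reporting offending symbols.
check_dna <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(toupper(x), "", fixed = TRUE)[[1]]),
                 c(DNA_BASES, "N"))
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-ACGTN characters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

random_dna <- function(n, gc = 0.38) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## GC fraction of a string, N excluded from numerator and denominator.
gc_fraction <- function(x) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  v <- v[v != "N"]
  if (length(v) == 0) return(NA_real_)
  mean(v %in% c("G", "C"))
}
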