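## Genetic-code machinery shared by the codon models, NG86 counting and the
## RNA-editing caller. Codons are ordered by TCAG nesting (the convention of
## most codon-model software); the sense alphabet drops the three stops of
## the standard code, which plastid protein genes follow.

.codon_cache <- new.env(parent = emptyenv())

#' Sense-codon tables for the standard genetic code
#'
#' Returns (and caches) the 61-state sense-codon alphabet together with the
#' single-nucleotide neighbour structure used to build MG94 rate matrices and
#' Nei-Gojobori counts.
#'
#' @return A list with elements `codons` (61 codon strings), `aa` (their
#'   amino acids), `codon_nt` (61 x 3 matrix of nucleotide indices into
#'   `c("T","C","A","G")`), and `nb`, a data.frame of directed codon pairs
#'   differing at exactly one position with columns `i`, `j`, `pos`,
#'   `from_nt`, `to_nt`, `syn`.
#' @export
codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  b <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  cod64 <- paste0(g$p1, g$p2, g$p3)
  aa64 <- unname(Biostrings::GENETIC_CODE[cod64])
  keep <- aa64 != "*"
  codons <- cod64[keep]
  aa <- aa64[keep]
  codon_nt <- t(vapply(strsplit(codons, "", fixed = TRUE),
                       function(x) match(x, b), integer(3)))
  n <- length(codons)
  ii <- jj <- pos <- from_nt <- to_nt <- integer(0)
  syn <- logical(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(codon_nt[i, ] != codon_nt[j, ])
      if (length(d) == 1L) {
        ii <- c(ii, i); jj <- c(jj, j); pos <- c(pos, d)
        from_nt <- c(from_nt, codon_nt[i, d]); to_nt <- c(to_nt, codon_nt[j, d])
        syn <- c(syn, aa[i] == aa[j])
      }
    }
  }
  tab <- list(codons = codons, aa = aa, codon_nt = codon_nt,
              nb = data.frame(i = ii, j = jj, pos = pos,
                              from_nt = from_nt, to_nt = to_nt, syn = syn))
  .codon_cache$tab <- tab
  tab
}

## Map codon strings to indices in the 61-state alphabet (NA for stops/other).
codon_index <- function(x) {
  tab <- codon_tables()
  match(toupper(x), tab$codons)
}

## Split an in-frame nucleotide string into codon strings.
split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
  substring(x, seq(1, n, by = 3), seq(3, n, by = 3))
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[toupper(codons)])
}
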