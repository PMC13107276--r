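## Independent oracles used across the suite. Each is written as a direct,
## brute-force restatement of the quantity being checked, sharing no code
## path with the package implementation.

## Exhaustive global-alignment score under affine gaps (open charged on the
## first gap base, extend on each additional). Plain recursion over all
## alignment paths; feasible only for short sequences.
oracle_align_score <- function(ref, query, match = 1, mismatch = -1,
                               open = -5, extend = -1) {
  x <- strsplit(ref, "")[[1]]
  y <- strsplit(query, "")[[1]]
  m <- length(x); n <- length(y)
  rec <- function(i, j, prev) {
    if (i == m && j == n) return(0)
    best <- -Inf
    if (i < m && j < n) {
      s <- if (x[i + 1] == y[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i < m) {
      g <- if (prev == "X") extend else open
      best <- max(best, g + rec(i + 1, j, "X"))
    }
    if (j < n) {
      g <- if (prev == "Y") extend else open
      best <- max(best, g + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(0, 0, "M")
}

## Nei-Gojobori pathway oracle: depth-first enumeration of substitution
## orders between two codons, dropping paths through stop codons (all-path
## fallback when every order is blocked). Returns averaged (syn, nonsyn)
## difference counts.
oracle_ng_path <- function(cod1, cod2) {
  aa <- function(cod) unname(Biostrings::GENETIC_CODE[cod])
  c1 <- strsplit(cod1, "")[[1]]; c2 <- strsplit(cod2, "")[[1]]
  dpos <- which(c1 != c2)
  paths <- list()
  dfs <- function(cur, remaining, steps) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- steps
      return(invisible(NULL))
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- c2[p]
      a1 <- aa(paste(cur, collapse = "")); a2 <- aa(paste(nxt, collapse = ""))
      step <- list(syn = (a1 == a2 && a1 != "*"),
                   through_stop = (a2 == "*" || a1 == "*"))
      dfs(nxt, setdiff(remaining, p), c(steps, list(step)))
    }
  }
  dfs(c1, dpos, list())
  valid <- vapply(paths, function(pp)
    !any(vapply(pp, `[[`, logical(1), "through_stop")), logical(1))
  use <- if (any(valid)) paths[valid] else paths
  sd <- mean(vapply(use, function(pp)
    sum(vapply(pp, `[[`, logical(1), "syn")), numeric(1)))
  nd <- mean(vapply(use, function(pp)
    sum(!vapply(pp, `[[`, logical(1), "syn")), numeric(1)))
  c(sd = sd, nd = nd)
}

## Per-codon synonymous site count computed directly (changes to stops are
## nonsynonymous).
oracle_ng_sites <- function(cod) {
  aa <- function(x) unname(Biostrings::GENETIC_CODE[x])
  v <- strsplit(cod, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(c("T", "C", "A", "G"), v[p])) {
      alt <- v; alt[p] <- b
      alt <- paste(alt, collapse = "")
      if (aa(alt) != "*" && aa(alt) == aa(cod)) s <- s + 1 / 3
    }
  }
  s
}

## All maximal exact repeats of length >= minlen by O(n^2) per-diagonal
## comparison, both orientations. Returns a data frame of interval pairs
## (first interval lexicographically smaller).
oracle_exact_repeats <- function(seqc, minlen = 12L) {
  x <- strsplit(seqc, "")[[1]]
  n <- length(x)
  out <- NULL
  scan <- function(y, inverted) {
    # direct self-comparison needs only the upper triangle (d >= 1);
    # against the reverse complement every diagonal is distinct
    drange <- if (inverted) (-(n - minlen)):(n - minlen)
    else seq_len(n - minlen)
    for (d in drange) {
      lo <- max(1L, 1L - d); hi <- min(n, n - d)
      if (hi - lo + 1L < minlen) next
      mv <- x[lo:hi] == y[(lo:hi) + d]
      r <- rle(mv)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= minlen)) {
        a <- lo + starts[k] - 1L; b <- lo + ends[k] - 1L
        if (!inverted) {
          q <- c(a, b); s <- c(a + d, b + d)
        } else {
          q <- c(a, b); s <- c(n - (b + d) + 1L, n - (a + d) + 1L)
        }
        if (inverted && q[1] == s[1] && q[2] == s[2]) next
        if (q[1] > s[1]) { tmp <- q; q <- s; s <- tmp }
        out <<- rbind(out, data.frame(q1 = q[1], q2 = q[2],
                                      s1 = s[1], s2 = s[2],
                                      orientation = if (inverted)
                                        "inverted" else "direct"))
      }
    }
  }
  scan(x, inverted = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  scan(rev(unname(comp[x])), inverted = TRUE)
  if (is.null(out)) {
    return(data.frame(q1 = integer(0), q2 = integer(0), s1 = integer(0),
                      s2 = integer(0), orientation = character(0)))
  }
  unique(out)
}

## Direct recomputation of UPGMA (average linkage) merge heights from the
## pairwise distance matrix: average of all cross-cluster distances at
## each merge of the hclust result.
oracle_avg_linkage_heights <- function(mat, hc) {
  D <- as.matrix(dist(mat))
  n <- nrow(D)
  members <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    pick <- function(v) if (v < 0) members[[-v]] else members[[n + v]]
    a <- pick(hc$merge[k, 1]); b <- pick(hc$merge[k, 2])
    heights[k] <- mean(D[a, b])
    members[[n + k]] <- c(a, b)
  }
  heights
}

## Random short DNA for alignment oracles (lengths capped so that full
## path enumeration stays feasible).
random_pair_short <- function() {
  repeat {
    m <- sample(2:12, 1); n <- sample(2:12, 1)
    # Delannoy-type path count grows with the product; cap it
    if (m * n <= 40) break
  }
  c(paste(sample(c("A", "C", "G", "T"), m, replace = TRUE), collapse = ""),
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

## A small shared roster/config for fast genome-scale tests.
small_roster <- function() {
  ros <- default_gene_roster()
  keep <- c("psbA", "psbI", "rbcL", "rps19", "rpoA", "clpP", "rpl2", "trnH",
            "rrn16", "ndhB", "ndhF", "ndhH", "ndhA", "ndhI", "ndhG", "ndhE",
            "psaC", "ndhD", "ndhJ", "ndhK", "ndhC")
  ros[ros$gene %in% keep, ]
}

small_config <- function(...) {
  default_generator_config(lsc_len = 12000, ir_len = 6000, ssc_len = 11000,
                           roster = small_roster(), ...)
}

protein_genes <- function(roster) {
  roster$gene[!roster$category %in% c("tRNA", "rRNA")]
}
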