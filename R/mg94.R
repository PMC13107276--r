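#' Codon alignments
#'
#' A `codon_alignment` stores equal-length, in-frame, gap-free coding
#' sequences over the 61 sense codons of the standard genetic code (the
#' product of upstream codon-aware alignment and cleaning, which this
#' package does not perform).
#'
#' @param seqs Named character vector of nucleotide strings (equal length,
#'   multiple of 3, no stop codons).
#' @return A `codon_alignment`: list with `taxa`, `idx` (taxa x codon-site
#'   matrix of indices into the 61-codon alphabet; NA for gap/ambiguous
#'   codons).
#' @export
codon_alignment <- function(seqs) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  n <- unique(nchar(seqs))
  if (length(n) != 1) stop("sequences differ in length")
  if (n %% 3 != 0) stop("alignment length is not a multiple of 3")
  idx <- t(vapply(seqs, function(s) {
    cods <- split_codons(s)
    ci <- codon_index(cods)
    stops <- !is.na(match(toupper(cods), c("TAA", "TAG", "TGA")))
    if (any(stops))
      stop("internal stop codon at codon position ", which(stops)[1])
    ci
  }, integer(n / 3)))
  if (n / 3 == 1) idx <- matrix(idx, nrow = length(seqs))
  rownames(idx) <- names(seqs)
  structure(list(taxa = names(seqs), idx = idx, n_codons = ncol(idx)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa x %d codons\n",
              length(x$taxa), x$n_codons))
  invisible(x)
}

#' Read a codon alignment from aligned FASTA
#' @param path Aligned FASTA file.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  codon_alignment(setNames(as.character(ss), names(ss)))
}

#' Write a codon alignment to FASTA
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_codon_alignment <- function(aln, path) {
  tab <- codon_tables()
  seqs <- apply(aln$idx, 1, function(r) paste(tab$codons[r], collapse = ""))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- aln$taxa
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Empirical F3x4 codon frequencies of an alignment
#'
#' Position-specific nucleotide frequencies across the three codon
#' positions, multiplied and renormalised over the 61 sense codons.
#'
#' @param aln A [codon_alignment()].
#' @return Numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  tab <- codon_tables()
  counts <- tabulate(aln$idx[!is.na(aln$idx)], nbins = 61)
  posfreq <- matrix(0, nrow = 3, ncol = 4)
  for (p in 1:3) {
    for (b in 1:4) {
      posfreq[p, b] <- sum(counts[tab$codon_nt[, p] == b])
    }
  }
  posfreq <- posfreq / rowSums(posfreq)
  # guard absent bases: tiny floor keeps the chain irreducible
  posfreq <- pmax(posfreq, 1e-6)
  posfreq <- posfreq / rowSums(posfreq)
  pi <- posfreq[1, tab$codon_nt[, 1]] * posfreq[2, tab$codon_nt[, 2]] *
    posfreq[3, tab$codon_nt[, 3]]
  pi / sum(pi)
}

#' HKY exchangeability matrix
#'
#' @param kappa Transition/transversion rate ratio.
#' @return 4x4 symmetric matrix in `T,C,A,G` base order.
#' @export
hky_exchangeabilities <- function(kappa) {
  ex <- matrix(1, 4, 4)
  ex[1, 2] <- ex[2, 1] <- kappa  # T<->C
  ex[3, 4] <- ex[4, 3] <- kappa  # A<->G
  diag(ex) <- 0
  ex
}

#' MG94-type codon rate matrix
#'
#' Rates are nonzero only between codons differing at one nucleotide:
#' q_ij = s(a,b) * pi_j * (omega if nonsynonymous), with s the nucleotide
#' exchangeabilities and pi the codon equilibrium frequencies (F3x4 in the
#' standard workflow). The matrix is scaled to one expected substitution
#' per codon per unit branch length.
#'
#' @param pi Codon equilibrium frequencies (length 61).
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param exch 4x4 nucleotide exchangeability matrix in `T,C,A,G` order
#'   (e.g. [hky_exchangeabilities()]).
#' @return 61x61 rate matrix with zero row sums.
#' @export
mg94_rate_matrix <- function(pi, omega, exch) {
  tab <- codon_tables()
  nb <- tab$nb
  Q <- matrix(0, 61, 61)
  Q[cbind(nb$i, nb$j)] <- exch[cbind(nb$from_nt, nb$to_nt)] * pi[nb$j] *
    ifelse(nb$syn, 1, omega)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

## Synonymous and nonsynonymous components of the raw (unscaled) expected
## flux; the average rate of the unscaled MG94 matrix is syn + omega*nonsyn.
mg94_flux_components <- function(pi, exch) {
  nb <- codon_tables()$nb
  base <- pi[nb$i] * exch[cbind(nb$from_nt, nb$to_nt)] * pi[nb$j]
  c(syn = sum(base[nb$syn]), nonsyn = sum(base[!nb$syn]))
}

## Symmetrised eigendecomposition of a reversible rate matrix; P(t) is then
## U1 %*% (exp(values * t) * U2t).
rate_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U1 = e$vectors / d, U2t = t(e$vectors * d), values = e$values)
}

prob_matrix <- function(es, t) {
  P <- es$U1 %*% (exp(es$values * t) * es$U2t)
  P[P < 0] <- 0
  P
}

## Preprocess alignment + tree for repeated likelihood evaluation:
## postorder edge list, site-pattern compression, F3x4 frequencies.
prep_lik <- function(aln, tree) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  miss <- setdiff(tree$tip.label, aln$taxa)
  if (length(miss) > 0)
    stop("taxa in tree but not alignment: ", paste(miss, collapse = ", "))
  tr <- ape::reorder.phylo(tree, "postorder")
  idx <- aln$idx[match(tr$tip.label, aln$taxa), , drop = FALSE]
  key <- apply(idx, 2, paste, collapse = ".")
  first <- !duplicated(key)
  pat <- idx[, first, drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[first])))
  list(tree = tr, patterns = pat, weights = w, site_of_pattern = match(key, key[first]),
       pi = f3x4_frequencies(aln), n_tip = length(tr$tip.label),
       n_codons = aln$n_codons)
}

## Core pruning likelihood. omega_edge gives the dN/dS ratio applying to
## each edge (rows of tree$edge); eigen systems are cached per distinct
## omega in `cache` (an environment) when supplied.
##
## Branch lengths are expected substitutions per codon for a site evolving
## at `ref_omega` (the background process). Other omegas share the same
## normalisation constant, so omega raises or lowers the substitution rate
## as well as its synonymous/nonsynonymous composition (the convention of
## the standard branch and branch-site machinery). ref_omega = NULL makes
## every matrix self-normalised (only meaningful for single-omega models).
## Returns the per-pattern log-likelihood vector.
mg94_site_loglik_core <- function(prep, omega_edge, exch, pi = prep$pi,
                                  cache = NULL, ref_omega = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  tr <- prep$tree
  pat <- prep$patterns
  npat <- ncol(pat)
  n_tip <- prep$n_tip
  n_node <- tr$Nnode
  edges <- tr$edge
  elen <- tr$edge.length
  fl <- mg94_flux_components(pi, exch)
  raw_rate <- function(om) unname(fl[1] + om * fl[2])
  ref_rate <- if (is.null(ref_omega)) NULL else raw_rate(ref_omega)
  get_eigen <- function(om) {
    key <- sprintf("w%.12g", om)
    es <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(es)) return(es)
    es <- rate_eigen(mg94_rate_matrix(pi, om, exch), pi)
    es$rel_rate <- if (is.null(ref_rate)) 1 else raw_rate(om) / ref_rate
    assign(key, es, envir = cache)
    es
  }
  cond <- vector("list", n_tip + n_node)
  logscale <- numeric(npat)
  ones <- matrix(1, 61, npat)
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    es <- get_eigen(omega_edge[e])
    P <- prob_matrix(es, elen[e] * es$rel_rate)
    contrib <- if (child <= n_tip) {
      st <- pat[child, ]
      m <- matrix(1, 61, npat)
      ok <- !is.na(st)
      m[, ok] <- P[, st[ok], drop = FALSE]
      m
    } else if (is.null(cond[[child]])) {
      # degenerate internal node without children (e.g. a dangling old
      # root left by re-rooting utilities): contributes no information
      matrix(1, 61, npat)
    } else {
      P %*% cond[[child]]
    }
    if (is.null(cond[[parent]])) {
      cond[[parent]] <- contrib
    } else {
      cond[[parent]] <- cond[[parent]] * contrib
      M <- cond[[parent]]
      cm <- M[cbind(max.col(t(M)), seq_len(npat))]
      cm[cm <= 0] <- 1
      cond[[parent]] <- sweep(cond[[parent]], 2, cm, "/")
      logscale <- logscale + log(cm)
    }
  }
  root <- n_tip + 1L
  lik <- as.vector(pi %*% cond[[root]])
  log(pmax(lik, 1e-300)) + logscale
}

#' MG94 log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over the 61-state MG94 chain, with separate
#' foreground and background omega values applied per branch.
#'
#' @param aln A [codon_alignment()].
#' @param tree An `ape::phylo` tree with branch lengths in expected
#'   substitutions per codon.
#' @param omega_bg Background omega.
#' @param omega_fg Foreground omega (defaults to the background value).
#' @param foreground Logical vector over `tree$edge` rows marking
#'   foreground branches (default none).
#' @param kappa HKY transition/transversion ratio.
#' @param exch Optional full exchangeability matrix (overrides `kappa`).
#' @param pi Codon frequencies (default F3x4 from the alignment).
#' @return The log-likelihood.
#' @export
mg94_loglik <- function(aln, tree, omega_bg, omega_fg = omega_bg,
                        foreground = NULL, kappa = 2, exch = NULL,
                        pi = NULL) {
  prep <- prep_lik(aln, tree)
  if (!is.null(pi)) prep$pi <- pi
  if (is.null(exch)) exch <- hky_exchangeabilities(kappa)
  ne <- nrow(prep$tree$edge)
  fg <- rep(FALSE, ne)
  if (!is.null(foreground)) fg <- reorder_foreground(tree, prep$tree, foreground)
  om <- ifelse(fg, omega_fg, omega_bg)
  sum(prep$weights *
        mg94_site_loglik_core(prep, om, exch, pi = prep$pi,
                              ref_omega = omega_bg))
}

## Foreground flags are supplied against the original tree's edge order;
## map them onto the postorder copy by child-node identity.
reorder_foreground <- function(orig, post, fg) {
  stopifnot(length(fg) == nrow(orig$edge))
  fg[match(post$edge[, 2], orig$edge[, 2])]
}

#' Mark the foreground branches of a tree
#'
#' Branch labelling follows the `#1` suffix convention: tip or internal
#' node labels ending in `#1` mark their parent edge as foreground.
#' Alternatively pass `taxon` to mark the terminal branch of one tip.
#'
#' @param tree An `ape::phylo`.
#' @param taxon Optional tip label whose terminal edge is foreground.
#' @return List: `tree` (labels stripped of `#1`), `foreground` (logical
#'   per edge row).
#' @export
foreground_edges <- function(tree, taxon = NULL) {
  fg_nodes <- integer(0)
  tl <- tree$tip.label
  marked_tips <- grepl("#1$", tl)
  if (any(marked_tips)) {
    fg_nodes <- c(fg_nodes, which(marked_tips))
    tree$tip.label <- sub("\\s*#1$", "", tl)
  }
  if (!is.null(tree$node.label)) {
    marked_nodes <- grepl("#1$", tree$node.label)
    if (any(marked_nodes)) {
      fg_nodes <- c(fg_nodes, length(tree$tip.label) + which(marked_nodes))
      tree$node.label <- sub("\\s*#1$", "", tree$node.label)
    }
  }
  if (!is.null(taxon)) {
    hit <- match(taxon, tree$tip.label)
    if (is.na(hit)) stop("taxon not in tree: ", taxon)
    fg_nodes <- c(fg_nodes, hit)
  }
  fg <- tree$edge[, 2] %in% fg_nodes
  list(tree = tree, foreground = fg)
}

#' Read a newick tree with `#1` foreground labels
#'
#' @param text_or_path Newick string or file path.
#' @return As [foreground_edges()]: the cleaned tree and the per-edge
#'   foreground flags.
#' @export
read_labeled_tree <- function(text_or_path) {
  tr <- if (file.exists(text_or_path)) ape::read.tree(text_or_path)
  else ape::read.tree(text = text_or_path)
  foreground_edges(tr)
}
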