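#' Default plastid gene roster for the synthetic generator
#'
#' A compact but realistic plastid gene set: photosynthesis genes (PS), the
#' eleven ndh genes with their two cluster arrangements (ndhJ-ndhK-ndhC and
#' ndhH-ndhA-ndhI-ndhG-ndhE-psaC-ndhD), housekeeping genes (HK), and the
#' rRNA/tRNA features placed in the inverted repeat. CDS lengths are the
#' real tobacco-like lengths (multiples of 3, stop included).
#'
#' @return Data frame: gene, category, length, region.
#' @export
default_gene_roster <- function() {
  df <- rbind(
    data.frame(gene = c("psbA", "psbB", "psbD", "psbE", "psbI", "rbcL",
                        "psaA", "psaB", "petA", "petB", "atpA", "atpB",
                        "atpE", "atpH", "atpI", "ycf3", "ycf4"),
               category = "PS",
               length = c(1062, 1527, 1062, 252, 111, 1428, 2253, 2205,
                          963, 648, 1524, 1497, 402, 246, 744, 507, 555),
               region = "LSC"),
    data.frame(gene = c("ndhJ", "ndhK", "ndhC"), category = "ndh",
               length = c(477, 675, 363), region = "LSC"),
    data.frame(gene = c("rpoA", "rpoB", "rps2", "rps4", "rps15",
                        "rpl16", "rpl32", "clpP", "matK", "accD", "ccsA",
                        "rps19"),  # rps19 last: it flanks the LSC/IRb junction
               category = "HK",
               length = c(1014, 3213, 711, 606, 273, 408, 174, 591,
                          1530, 1491, 966, 279),
               region = "LSC"),
    data.frame(gene = c("rpl2", "ndhB"), category = c("HK", "ndh"),
               length = c(825, 1533), region = "IR"),
    data.frame(gene = c("rrn16", "rrn23"), category = "rRNA",
               length = c(1491, 2811), region = "IR"),
    data.frame(gene = "trnH", category = "tRNA", length = 75, region = "IR"),
    data.frame(gene = c("ndhF", "ndhH", "ndhA", "ndhI", "ndhG", "ndhE",
                        "psaC", "ndhD"),
               category = c("ndh", "ndh", "ndh", "ndh", "ndh", "ndh",
                            "PS", "ndh"),
               length = c(2241, 1182, 1092, 501, 531, 306, 246, 1503),
               region = "SSC"))
  df$region <- factor(df$region, levels = c("LSC", "IR", "SSC"))
  df
}

#' Default synthetic-plastome configuration
#'
#' Layout defaults (LSC 84 kb, IR 25 kb, SSC 18 kb; genome-wide GC 0.38)
#' match a typical autotroph plastome. The degradation plan, insertions,
#' inversions and repeat plan are empty by default (an intact autotroph).
#'
#' @param lsc_len,ir_len,ssc_len Region lengths in bases.
#' @param gc Background (intergenic) GC fraction.
#' @param roster Gene roster as [default_gene_roster()]; a subset shrinks
#'   the genome for fast tests.
#' @param plan Degradation plan: data frame with columns `gene`, `action`
#'   (`truncate`, `delete_internal`, `remove`), `param` (target coverage
#'   fraction for truncate; deleted bases for delete_internal).
#' @param insertions Data frame `length`, `gc`, `region` of foreign blocks.
#' @param inversions List of `c(from_gene, to_gene)` spans (within one
#'   region) to invert.
#' @param repeats Data frame `length`, `gc`, `orientation`
#'   (`direct`/`inverted`), `region`: planted dispersed repeat pairs.
#' @param ref_seed Seed from which the shared reference CDS set is derived
#'   (keep identical across genomes of one comparative scenario).
#' @return Config list.
#' @export
default_generator_config <- function(lsc_len = 84000L, ir_len = 25000L,
                                     ssc_len = 18000L, gc = 0.38,
                                     roster = default_gene_roster(),
                                     plan = NULL, insertions = NULL,
                                     inversions = NULL, repeats = NULL,
                                     ref_seed = 42L) {
  stopifnot(lsc_len > 0, ir_len >= 0, ssc_len > 0, gc > 0, gc < 1)
  list(lsc_len = as.integer(lsc_len), ir_len = as.integer(ir_len),
       ssc_len = as.integer(ssc_len), gc = gc, roster = roster,
       plan = plan, insertions = insertions, inversions = inversions,
       repeats = repeats, ref_seed = as.integer(ref_seed))
}

#' Reference CDS set for a roster
#'
#' Deterministic (seeded) CDS sequences: ATG start, random non-stop
#' codons, terminal stop. These play the role of the well-characterised
#' reference CDS set that annotation coverage is computed against.
#'
#' @param roster Gene roster data frame.
#' @param seed RNG seed.
#' @param gc Approximate GC of the coding sequence.
#' @return Named character vector of CDS strings (protein genes and ndh
#'   only; rRNA/tRNA features get plain random sequences).
#' @export
make_reference_cds <- function(roster, seed = 42L, gc = 0.38) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  out <- setNames(vector("character", nrow(roster)), roster$gene)
  for (i in seq_len(nrow(roster))) {
    len <- roster$length[i]
    if (roster$category[i] %in% c("tRNA", "rRNA")) {
      out[i] <- random_dna(len, gc)
      next
    }
    ncod <- len %/% 3L
    nb <- ncod - 2L
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    draw <- function(k) {
      m <- matrix(sample(DNA_BASES, 3L * k, replace = TRUE, prob = p),
                  ncol = 3)
      paste0(m[, 1], m[, 2], m[, 3])
    }
    body <- draw(nb)
    repeat {
      bad <- which(body %in% stops)
      if (length(bad) == 0L) break
      body[bad] <- draw(length(bad))
    }
    out[i] <- paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic plastome with planted ground truth
#'
#' Assembles LSC + IRb + SSC + IRa (IRa the exact reverse complement of
#' IRb), places the roster genes region by region with random intergenic
#' spacers, applies the degradation plan (premature-stop truncations to a
#' target coverage fraction, internal deletions, whole-gene removals),
#' plants insertions / SSC inversions / dispersed repeats, and records the
#' complete truth, including the expected post-cascade gene statuses.
#' Identical seed and config give byte-identical output.
#'
#' @param config From [default_generator_config()].
#' @param seed RNG seed.
#' @param id Record id.
#' @param trophic_class Trophic class to attach.
#' @return List: `record` (a [plastome_record()]), `truth` (gene statuses,
#'   IR/indel/repeat intervals, reference CDS, seed).
#' @export
make_plastome <- function(config = default_generator_config(), seed = 1L,
                          id = sprintf("SYN%06d", seed),
                          trophic_class = "AP") {
  set.seed(seed)
  roster <- config$roster
  ref_cds <- if (!is.null(config$ref_cds)) config$ref_cds else
    make_reference_cds(roster, config$ref_seed, config$gc)
  plan <- config$plan
  act_of <- function(g) {
    if (is.null(plan)) return(NULL)
    k <- match(g, plan$gene)
    if (is.na(k)) NULL else plan[k, ]
  }
  stops <- c("TAA", "TAG", "TGA")
  truth_status <- setNames(rep("intact", nrow(roster)), roster$gene)

  gene_piece <- function(g) {
    s <- ref_cds[[g]]
    a <- act_of(g)
    status <- "intact"
    if (!is.null(a)) {
      if (a$action == "remove") return(NULL)
      if (a$action == "truncate") {
        ncod <- nchar(s) %/% 3L
        at <- max(2L, min(ncod - 1L, floor(a$param * ncod)))
        substr(s, (at - 1L) * 3L + 1L, at * 3L) <- "TAA"
        status <- "pseudogene"
      } else if (a$action == "delete_internal") {
        n <- nchar(s)
        dl <- min(a$param, n - 60L)
        if (dl %% 3L == 0L) dl <- dl + 1L  # force a frameshift
        from <- floor(n / 3)
        s <- paste0(substring(s, 1, from), substring(s, from + dl + 1L, n))
        status <- "pseudogene"
      }
    }
    list(seq = s, status = status)
  }

  build_region <- function(genes) {
    pieces <- list()
    for (g in genes) {
      sp <- random_dna(sample(100:400, 1), config$gc)
      pieces[[length(pieces) + 1L]] <- list(name = NA, seq = sp,
                                            strand = "+", category = NA,
                                            status = NA)
      gp <- gene_piece(g)
      if (is.null(gp)) { truth_status[g] <<- "lost"; next }
      truth_status[g] <<- gp$status
      k <- match(g, roster$gene)
      pieces[[length(pieces) + 1L]] <- list(name = g, seq = gp$seq,
                                            strand = "+",
                                            category = roster$category[k],
                                            status = gp$status)
    }
    pieces
  }

  lsc <- build_region(roster$gene[roster$region == "LSC"])
  irb <- build_region(roster$gene[roster$region == "IR"])
  ssc <- build_region(roster$gene[roster$region == "SSC"])

  # inversions: reverse-complement a span of pieces covering the genes
  if (!is.null(config$inversions)) {
    for (iv in config$inversions) {
      for (regname in c("lsc", "irb", "ssc")) {
        reg <- get(regname)
        nm <- vapply(reg, function(p) as.character(p$name), "")
        a <- match(iv[1], nm); b <- match(iv[2], nm)
        if (is.na(a) || is.na(b)) next
        if (a > b) { tmp <- a; a <- b; b <- tmp }
        span <- rev(reg[a:b])
        span <- lapply(span, function(p) {
          p$seq <- revcomp(p$seq)
          p$strand <- if (p$strand == "+") "-" else "+"
          p
        })
        assign(regname, c(reg[seq_len(a - 1L)], span,
                          if (b < length(reg)) reg[(b + 1L):length(reg)]))
        break
      }
    }
  }

  pad_region <- function(pieces, target, what) {
    used <- sum(vapply(pieces, function(p) nchar(p$seq), numeric(1)))
    if (used > target)
      stop("plan overflow: ", what, " needs ", used, " > ", target, " bases")
    if (used < target)
      pieces[[length(pieces) + 1L]] <- list(name = NA,
                                            seq = random_dna(target - used,
                                                             config$gc),
                                            strand = "+", category = NA,
                                            status = NA)
    pieces
  }
  lsc <- pad_region(lsc, config$lsc_len, "LSC")
  irb <- pad_region(irb, config$ir_len, "IR")
  ssc <- pad_region(ssc, config$ssc_len, "SSC")

  cat_seq <- function(pieces) paste(vapply(pieces, `[[`, "", "seq"),
                                    collapse = "")
  lsc_seq <- cat_seq(lsc); irb_seq <- cat_seq(irb); ssc_seq <- cat_seq(ssc)

  # planted foreign insertions: reject candidates sharing a >= 20 bp anchor
  ins_truth <- NULL
  host_for_check <- paste0(lsc_seq, irb_seq, ssc_seq)
  if (!is.null(config$insertions)) {
    for (k in seq_len(nrow(config$insertions))) {
      row <- config$insertions[k, ]
      repeat {
        block <- random_dna(row$length, row$gc)
        h <- pairwise_hits(block, host_for_check, word_size = 11L,
                           min_score = 15)
        if (nrow(h[h$length >= 20, ]) == 0L) break
      }
      tgt <- if (is.null(row$region)) "lsc" else tolower(row$region)
      reg <- get(tgt <- match.arg(tgt, c("lsc", "irb", "ssc")))
      # insert between two pieces (never inside a gene)
      at <- sample(seq_len(length(reg) + 1L) - 1L, 1)
      piece <- list(name = NA, seq = block, strand = "+", category = NA,
                    status = NA)
      reg <- append(reg, list(piece), after = at)
      assign(tgt, reg)
      ins_truth <- rbind(ins_truth,
                         data.frame(region = tgt, length = row$length,
                                    gc = row$gc))
    }
    lsc_seq <- cat_seq(lsc); irb_seq <- cat_seq(irb); ssc_seq <- cat_seq(ssc)
  }

  # planted dispersed repeats: a fresh unit copied to two spacer positions
  rep_truth <- NULL
  if (!is.null(config$repeats)) {
    for (k in seq_len(nrow(config$repeats))) {
      row <- config$repeats[k, ]
      unit <- random_dna(row$length, if (is.null(row$gc)) config$gc else row$gc)
      second <- if (identical(row$orientation, "inverted")) revcomp(unit) else unit
      # append both copies into the LSC tail spacer region
      lsc_seq <- paste0(lsc_seq, unit,
                        random_dna(sample(200:500, 1), config$gc), second)
      rep_truth <- rbind(rep_truth,
                         data.frame(length = row$length,
                                    orientation = row$orientation))
    }
  }

  # anchor the SSC termini so the exact IR cannot extend by a chance
  # complementary base across the junctions (keeps truth == detection)
  substr(ssc_seq, 1L, 1L) <- "A"
  substr(ssc_seq, nchar(ssc_seq), nchar(ssc_seq)) <- "A"
  genome <- paste0(lsc_seq, irb_seq, ssc_seq, revcomp(irb_seq))

  # feature coordinates
  feats <- empty_features()
  offset <- 0L
  add_pieces <- function(pieces, offset, mirror = FALSE) {
    rows <- NULL
    pos <- offset
    for (p in pieces) {
      w <- nchar(p$seq)
      if (!is.na(p$name)) {
        rows <- rbind(rows, data.frame(
          name = p$name, category = p$category, strand = p$strand,
          start = pos + 1L, end = pos + w, exon = 1L,
          status = "unknown", wrap = FALSE))
      }
      pos <- pos + w
    }
    rows
  }
  feats <- rbind(feats, add_pieces(lsc, 0L))
  lsc_n <- nchar(lsc_seq); irb_n <- nchar(irb_seq); ssc_n <- nchar(ssc_seq)
  feats <- rbind(feats, add_pieces(irb, lsc_n))
  feats <- rbind(feats, add_pieces(ssc, lsc_n + irb_n))
  # mirrored IRa copies
  ira_off <- lsc_n + irb_n + ssc_n
  irb_feats <- add_pieces(irb, lsc_n)
  if (!is.null(irb_feats)) {
    mir <- irb_feats
    s <- irb_feats$start - lsc_n; e <- irb_feats$end - lsc_n
    mir$start <- ira_off + (irb_n - e + 1L)
    mir$end <- ira_off + (irb_n - s + 1L)
    mir$strand <- ifelse(irb_feats$strand == "+", "-", "+")
    feats <- rbind(feats, mir)
  }
  feats <- feats[order(feats$start), ]
  rownames(feats) <- NULL

  # truth: post-cascade expected statuses
  expected <- truth_status
  ndh <- grepl("^ndh", names(expected))
  if (any(expected[ndh] != "intact")) {
    expected[ndh & expected == "intact"] <- "pseudogene"
  }

  record <- plastome_record(id, genome, taxon = id,
                            trophic_class = trophic_class, features = feats)
  truth <- list(
    gene_status = truth_status, gene_status_cascaded = expected,
    ir = list(irb = c(start = lsc_n + 1L, end = lsc_n + irb_n),
              ira = c(start = ira_off + 1L, end = ira_off + irb_n),
              ir_length = irb_n),
    insertions = ins_truth, repeats = rep_truth,
    ref_cds = ref_cds, seed = seed)
  list(record = record, truth = truth)
}

#' Default tree for selection simulations
#'
#' A balanced ultrametric 8-taxon tree of depth 0.5 substitutions per
#' codon (every edge 0.125), the standard scenario for branch-model
#' recovery experiments in this package.
#'
#' @param foreground_taxon Tip whose terminal branch is foreground.
#' @return List as [foreground_edges()]: `tree`, `foreground`.
#' @export
default_selection_tree <- function(foreground_taxon = "t1") {
  nwk <- paste0("((((t1:0.125,t2:0.125):0.125,(t3:0.125,t4:0.125):0.125)",
                ":0.125,((t5:0.125,t6:0.125):0.125,(t7:0.125,t8:0.125)",
                ":0.125):0.125):0.125);")
  foreground_edges(ape::read.tree(text = nwk), taxon = foreground_taxon)
}

#' Simulate a codon alignment under branch-specific MG94
#'
#' Root codons are drawn from the F3x4-style stationary distribution; each
#' branch evolves its states with the transition probabilities of the MG94
#' chain at that branch's omega (foreground vs background), optionally with
#' branch-site site classes. Stop codons cannot arise by construction (the
#' state space is the 61 sense codons).
#'
#' @param tree `ape::phylo` with branch lengths (substitutions/codon).
#' @param n_codons Number of codon sites.
#' @param seed RNG seed.
#' @param omega_bg,omega_fg Background and foreground omega.
#' @param foreground Logical per edge row of `tree$edge` (default none).
#' @param kappa HKY kappa.
#' @param nt_freqs 3x4 matrix of position-specific nucleotide frequencies
#'   in `T,C,A,G` order (default mildly AT-rich, plastome-like).
#' @param site_classes Optional list with `props` and matrices/vectors
#'   `omega_bg`, `omega_fg` per class, for branch-site simulations.
#' @return List: `aln` (a [codon_alignment()]), `truth` (per-edge omegas,
#'   per-site classes, pi, seed).
#' @export
simulate_codon_alignment <- function(tree, n_codons, seed = 1L,
                                     omega_bg = 0.2, omega_fg = omega_bg,
                                     foreground = NULL, kappa = 2,
                                     nt_freqs = NULL, site_classes = NULL) {
  set.seed(seed)
  tab <- codon_tables()
  if (is.null(nt_freqs)) {
    nt_freqs <- matrix(rep(c(0.32, 0.18, 0.32, 0.18), each = 3), nrow = 3)
  }
  pi <- nt_freqs[1, tab$codon_nt[, 1]] * nt_freqs[2, tab$codon_nt[, 2]] *
    nt_freqs[3, tab$codon_nt[, 3]]
  pi <- pi / sum(pi)
  ex <- hky_exchangeabilities(kappa)
  ne <- nrow(tree$edge)
  fg <- if (is.null(foreground)) rep(FALSE, ne) else foreground
  if (is.null(site_classes)) {
    cls <- rep(1L, n_codons)
    om_bg_cls <- omega_bg; om_fg_cls <- omega_fg
  } else {
    cls <- sample.int(length(site_classes$props), n_codons, replace = TRUE,
                      prob = site_classes$props)
    om_bg_cls <- site_classes$omega_bg
    om_fg_cls <- site_classes$omega_fg
  }
  n_tip <- length(tree$tip.label)
  states <- matrix(NA_integer_, nrow = n_tip + tree$Nnode, ncol = n_codons)
  root <- n_tip + 1L
  states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
  # shared normalisation: branch lengths are substitutions/codon for the
  # class-1 background process; other omegas scale the rate accordingly
  fl <- mg94_flux_components(pi, ex)
  ref_rate <- unname(fl[1] + om_bg_cls[1] * fl[2])
  omset <- sort(unique(c(om_bg_cls, om_fg_cls)))
  eig <- lapply(omset, function(om) {
    es <- rate_eigen(mg94_rate_matrix(pi, om, ex), pi)
    es$rel_rate <- unname(fl[1] + om * fl[2]) / ref_rate
    es
  })
  names(eig) <- sprintf("%.12g", omset)
  # preorder traversal: reverse postorder
  tr <- ape::reorder.phylo(tree, "postorder")
  fg_post <- if (is.null(foreground)) rep(FALSE, ne) else
    reorder_foreground(tree, tr, fg)
  for (e in rev(seq_len(ne))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    om_cls <- if (fg_post[e]) om_fg_cls else om_bg_cls
    for (c_id in unique(cls)) {
      om <- om_cls[c_id]
      es <- eig[[sprintf("%.12g", om)]]
      P <- prob_matrix(es, tr$edge.length[e] * es$rel_rate)
      P <- pmax(P, 0)
      sites <- which(cls == c_id)
      par_states <- states[parent, sites]
      for (s in unique(par_states)) {
        here <- sites[par_states == s]
        states[child, here] <- sample.int(61, length(here), replace = TRUE,
                                          prob = P[s, ])
      }
    }
  }
  seqs <- setNames(vapply(seq_len(n_tip), function(i)
    paste(tab$codons[states[i, ]], collapse = ""), ""), tr$tip.label)
  list(aln = codon_alignment(seqs),
       truth = list(omega_bg = om_bg_cls, omega_fg = om_fg_cls,
                    classes = cls, pi = pi, kappa = kappa, seed = seed))
}

#' Simulate negative-binomial fragment counts from true FPKM
#'
#' Expected counts invert the FPKM formula; observed counts are negative
#' binomial with the given dispersion (Poisson in the dispersion = 0
#' limit).
#'
#' @param fpkm_truth Feature-by-sample matrix (or vector) of true FPKM.
#' @param lengths Feature lengths in bases.
#' @param total_fragments Per-sample totals (recycled).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed RNG seed.
#' @return List: `counts` (a [fragment_counts()]), `truth` (expected
#'   counts and the input FPKM).
#' @export
simulate_counts <- function(fpkm_truth, lengths, total_fragments,
                            dispersion = 0.05, seed = 1L) {
  set.seed(seed)
  fpkm_truth <- as.matrix(fpkm_truth)
  stopifnot(all(fpkm_truth >= 0), all(lengths > 0))
  if (any(total_fragments <= 0)) stop("zero total fragments")
  totals <- rep(total_fragments, length.out = ncol(fpkm_truth))
  mu <- sweep(fpkm_truth * (lengths / 1000), 2, totals / 1e6, "*")
  counts <- if (dispersion <= 0) {
    matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = nrow(mu))
  }
  dimnames(counts) <- dimnames(fpkm_truth)
  list(counts = fragment_counts(counts, lengths, totals),
       truth = list(expected = mu, fpkm = fpkm_truth, seed = seed))
}

#' Simulate a strand-resolved pileup with planted editing sites
#'
#' Coverage per position is uniform on `coverage`, split binomially
#' between strands; sequencing errors occur at `error_rate` per base,
#' uniformly over the three alternatives. Planted sites carry the variant
#' (T for a C reference, A for a G reference) at the planted efficiency,
#' with an optional strand bias in the variant reads.
#'
#' @param genome DNA string.
#' @param site_plan Data frame `pos`, `efficiency`, optional `bias`
#'   (fraction of variant reads pushed to the plus strand, default 0.5).
#'   Positions must be C or G in the genome.
#' @param coverage Length-2 range for per-position coverage.
#' @param error_rate Per-base sequencing error rate.
#' @param seed RNG seed.
#' @param region Optional `c(start, end)` restriction.
#' @param strand_split Expected fraction of fragments on the plus strand.
#' @return List: `pileup` (data frame pos/strand/ref/A/C/G/T), `truth`.
#' @export
simulate_pileup <- function(genome, site_plan = NULL,
                            coverage = c(150, 400), error_rate = 0.001,
                            seed = 1L, region = NULL, strand_split = 0.5) {
  set.seed(seed)
  n_all <- nchar(genome)
  if (is.null(region)) region <- c(1L, n_all)
  pos <- region[1]:region[2]
  n <- length(pos)
  refv <- strsplit(toupper(substring(genome, region[1], region[2])),
                   "")[[1]]
  ref_i <- match(refv, DNA_BASES)
  if (!is.null(site_plan)) {
    rp <- refv[match(site_plan$pos, pos)]
    if (any(!rp %in% c("C", "G")))
      stop("site plan positions must be C or G in the genome")
    if (is.null(site_plan$bias)) site_plan$bias <- 0.5
  }
  cov <- if (coverage[1] == coverage[2]) rep(coverage[1], n) else
    sample(coverage[1]:coverage[2], n, replace = TRUE)
  cov_p <- rbinom(n, cov, strand_split)
  cov_m <- cov - cov_p
  make_strand <- function(covs) {
    err <- rbinom(n, covs, error_rate)
    e1 <- rbinom(n, err, 1 / 3)
    e2 <- rbinom(n, err - e1, 1 / 2)
    e3 <- err - e1 - e2
    counts <- matrix(0L, nrow = n, ncol = 4)
    counts[cbind(seq_len(n), ref_i)] <- covs - err
    alt_cols <- matrix(0L, nrow = n, ncol = 3)
    for (b in 1:4) {
      rows <- which(ref_i == b)
      others <- setdiff(1:4, b)
      counts[cbind(rows, others[1])] <- counts[cbind(rows, others[1])] + e1[rows]
      counts[cbind(rows, others[2])] <- counts[cbind(rows, others[2])] + e2[rows]
      counts[cbind(rows, others[3])] <- counts[cbind(rows, others[3])] + e3[rows]
    }
    counts
  }
  cp <- make_strand(cov_p)
  cm <- make_strand(cov_m)
  realized <- NULL
  if (!is.null(site_plan)) {
    for (k in seq_len(nrow(site_plan))) {
      i <- match(site_plan$pos[k], pos)
      f <- site_plan$efficiency[k]; b <- site_plan$bias[k]
      fp <- min(1, 2 * b * f * (0.5 / strand_split))
      fm <- min(1, 2 * (1 - b) * f * (0.5 / (1 - strand_split)))
      ref_col <- ref_i[i]
      alt_col <- if (refv[i] == "C") 4L else 1L  # T for C, A for G
      vp <- rbinom(1, cp[i, ref_col], fp)
      vm <- rbinom(1, cm[i, ref_col], fm)
      cp[i, ref_col] <- cp[i, ref_col] - vp; cp[i, alt_col] <- cp[i, alt_col] + vp
      cm[i, ref_col] <- cm[i, ref_col] - vm; cm[i, alt_col] <- cm[i, alt_col] + vm
      realized <- rbind(realized, data.frame(
        pos = site_plan$pos[k], efficiency = site_plan$efficiency[k],
        coverage = cov[i], variant_reads = vp + vm,
        realized_efficiency = (vp + vm) / cov[i]))
    }
  }
  pileup <- rbind(
    data.frame(pos = pos, strand = "+", ref = refv,
               A = cp[, 1], C = cp[, 2], G = cp[, 3], T = cp[, 4]),
    data.frame(pos = pos, strand = "-", ref = refv,
               A = cm[, 1], C = cm[, 2], G = cm[, 3], T = cm[, 4]))
  pileup <- pileup[order(pileup$pos, pileup$strand), ]
  rownames(pileup) <- NULL
  list(pileup = pileup,
       truth = list(sites = realized, error_rate = error_rate, seed = seed))
}
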