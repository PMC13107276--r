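test_that("fpkm implements the formula exactly", {
  fc <- fragment_counts(matrix(c(10, 0), ncol = 1,
                               dimnames = list(c("a", "b"), "s1")),
                        lengths = c(1000, 500), totals = 1e6)
  out <- fpkm(fc)
  expect_equal(out["a", "s1"], 10)   # 10 * 1e6 / (1e6 * 1) = 10
  expect_equal(out["b", "s1"], 0)    # zero count -> zero FPKM
  expect_error(fpkm(fragment_counts(matrix(0, 1, 1), 100, totals = 0)))
})

test_that("FPKM conservation identity holds when features partition reads", {
  set.seed(61)
  counts <- matrix(rpois(40, 800), nrow = 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  lens <- sample(200:3000, 10)
  fc <- fragment_counts(counts, lens)  # totals default to column sums
  f <- fpkm(fc)
  conserved <- colSums(f * (lens / 1000))
  expect_equal(unname(conserved), rep(1e6, 4), tolerance = 1e-9)
})

test_that("average-linkage clustering matches direct recomputation", {
  # three points on a line: the nearby pair merges first
  m <- matrix(c(0, 1, 10), ncol = 1)
  rownames(m) <- c("p0", "p1", "p10")
  cl <- cluster_expression(cbind(m, m))
  first <- sort(cl$features$merge[1, ])
  expect_equal(sort(rownames(m)[-first[1:2]]), c("p0", "p1"))
  # identical profiles merge at height 0
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  cl2 <- cluster_expression(m2)
  expect_equal(min(cl2$features$height), 0)
  # random matrices: merge heights equal the cross-cluster average oracle
  set.seed(62)
  for (k in 1:5) {
    mm <- matrix(rnorm(24), nrow = 6)
    hc <- cluster_expression(mm)$features
    expect_equal(hc$height, oracle_avg_linkage_heights(mm, hc),
                 tolerance = 1e-10)
  }
  expect_error(cluster_expression(matrix(c(1, NA, 2, 3), 2)), "finite")
  # newick export carries all labels
  expect_true(all(vapply(rownames(m2), grepl, logical(1),
                         x = cluster_expression(m2)$feature_newick,
                         fixed = TRUE)))
})

test_that("editing caller applies coverage, frequency, binomial and bias rules", {
  base <- data.frame(pos = 1L, strand = c("+", "-"), ref = "C",
                     A = 0L, C = 0L, G = 0L, T = 0L)
  # coverage 59 at 50% variant: below min coverage -> not called
  p1 <- base; p1$C <- c(15L, 15L); p1$T <- c(15L, 14L)
  expect_equal(nrow(call_editing_sites(p1)), 0L)
  # coverage 100 with 30 balanced variant reads: called at efficiency 0.30
  p2 <- base; p2$C <- c(35L, 35L); p2$T <- c(15L, 15L)
  got <- call_editing_sites(p2)
  expect_equal(nrow(got), 1L)
  expect_equal(got$efficiency, 0.30)
  expect_equal(got$alt, "T")
  # direct binomial check of the variant p-value rule at epsilon = 0.001
  expect_lt(pbinom(29, 100, 0.001, lower.tail = FALSE), 1e-6)
  # same counts but all variants on one strand: strand bias rejects
  p3 <- base; p3$C <- c(20L, 50L); p3$T <- c(30L, 0L)
  expect_equal(nrow(call_editing_sites(p3)), 0L)
  # frequency below 10% not called even with huge coverage
  p4 <- base; p4$C <- c(500L, 500L); p4$T <- c(40L, 40L)
  expect_equal(nrow(call_editing_sites(p4)), 0L)
  # G -> A on the reverse-strand gene is a C-to-U candidate
  p5 <- data.frame(pos = 9L, strand = c("+", "-"), ref = "G",
                   A = c(20L, 20L), C = 0L, G = c(30L, 30L), T = 0L)
  got5 <- call_editing_sites(p5)
  expect_equal(got5$edit_type, "C-to-U")
  expect_equal(got5$efficiency, 0.4)
})

test_that("silent and codon-position annotation follows the genetic code", {
  # gene on + strand: CCC CAT -> codon 2 position 2 C->T gives CAT->CTT? no:
  # genome ATGCCA, CDS 1..6; edit at pos 5 (codon 2 pos 2) C->T: CCA->CTA
  genome <- "ATGCCA"
  cds <- data.frame(gene = "g1", start = 1L, end = 6L, strand = "+")
  pu <- data.frame(pos = 5L, strand = c("+", "-"), ref = "C",
                   A = 0L, C = c(30L, 30L), G = 0L, T = c(20L, 20L))
  got <- call_editing_sites(pu, cds_map = cds, genome = genome)
  expect_equal(got$gene, "g1")
  expect_equal(got$codon_pos, 2L)
  expect_equal(got$cds_codon, 2L)
  expect_false(got$silent)  # CCA (Pro) -> CTA (Leu)
  # third-position synonymous edit: CCC -> CCT is silent
  genome2 <- "ATGCCC"
  pu2 <- data.frame(pos = 6L, strand = c("+", "-"), ref = "C",
                    A = 0L, C = c(30L, 30L), G = 0L, T = c(20L, 20L))
  got2 <- call_editing_sites(pu2, cds_map = cds, genome = genome2)
  expect_true(got2$silent)
  expect_equal(got2$codon_pos, 3L)
  # minus-strand gene: genome revcomp of ATGCCA; same codon logic mirrored
  genome3 <- revcomp("ATGCCA")  # TGGCAT; gene on minus strand 1..6
  cds3 <- data.frame(gene = "g3", start = 1L, end = 6L, strand = "-")
  # sense codon 2 position 2 sits at genome position 2 (G), edit G->A
  pu3 <- data.frame(pos = 2L, strand = c("+", "-"), ref = "G",
                    A = c(20L, 20L), C = 0L, G = c(30L, 30L), T = 0L)
  got3 <- call_editing_sites(pu3, cds_map = cds3, genome = genome3)
  expect_equal(got3$codon_pos, 2L)
  expect_false(got3$silent)
})

test_that("shared editing sites intersect by gene/codon key", {
  a <- data.frame(pos = c(10, 20), gene = c("g1", "g2"),
                  cds_codon = c(4, 7), codon_pos = c(2, 2),
                  efficiency = c(0.5, 0.8))
  b <- data.frame(pos = c(11, 21), gene = c("g1", "g2"),
                  cds_codon = c(4, 7), codon_pos = c(2, 2),
                  efficiency = c(0.4, 0.9))
  sh <- shared_editing_sites(list(A = a, B = b))
  expect_equal(length(sh$sites), 2L)
  expect_equal(dim(sh$efficiency), c(2L, 2L))
  expect_equal(sh$efficiency["B", "g2:7:2"], 0.9)
  # one species missing a site -> excluded
  sh2 <- shared_editing_sites(list(A = a, B = b[1, ]))
  expect_equal(sh2$sites, "g1:4:2")
  expect_warning(shared_editing_sites(list(A = a[0, ], B = b)), "shared")
})

test_that("planted editing sites are recovered with binomial-scale error", {
  set.seed(63)
  genome <- random_dna(20000)
  cpos <- which(strsplit(genome, "")[[1]] == "C")
  plan <- data.frame(pos = sample(cpos, 25),
                     efficiency = runif(25, 0.3, 0.9))
  sim <- simulate_pileup(genome, plan, coverage = c(150, 400), seed = 64)
  sites <- call_editing_sites(sim$pileup)
  found <- plan$pos %in% sites$pos
  expect_true(all(found))
  eff <- sites$efficiency[match(plan$pos, sites$pos)]
  # binomial sampling bound: |eff_hat - eff| within ~4 sd
  sdmax <- sqrt(plan$efficiency * (1 - plan$efficiency) / 150)
  expect_true(all(abs(eff - plan$efficiency) < 4.5 * sdmax))
  # strand-biased planted site is rejected by the bias filter
  plan_b <- data.frame(pos = sample(setdiff(cpos, plan$pos), 3),
                       efficiency = 0.4, bias = 0.97)
  sim_b <- simulate_pileup(genome, plan_b, coverage = c(200, 400), seed = 65)
  sites_b <- call_editing_sites(sim_b$pileup)
  expect_false(any(plan_b$pos %in% sites_b$pos))
})

test_that("planted efficiency differences are recovered by ANOVA + LSD", {
  set.seed(66)
  n_sites <- 18
  species_eff <- list(A = 0.35, B = 0.6, C = 0.62, D = 0.65)
  lists <- lapply(species_eff, function(mu) {
    data.frame(pos = seq_len(n_sites), gene = "g",
               cds_codon = seq_len(n_sites), codon_pos = 2,
               efficiency = pmin(0.99, pmax(0.01,
                                            rnorm(n_sites, mu, 0.08))))
  })
  sh <- shared_editing_sites(lists)
  vals <- as.vector(t(sh$efficiency))
  grp <- rep(rownames(sh$efficiency), each = n_sites)
  res <- anova_lsd(vals, grp)
  expect_lt(res$p_value, 0.05)
  # the low-efficiency species carries a letter shared with no other group
  la <- res$letters[["A"]]
  others <- unlist(strsplit(paste(res$letters[names(res$letters) != "A"],
                                  collapse = ""), ""))
  expect_false(any(strsplit(la, "")[[1]] %in% others))
})
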