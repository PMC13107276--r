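test_that("the MG94 rate matrix is a valid reversible generator", {
  set.seed(71)
  fgm <- default_selection_tree()
  sim <- simulate_codon_alignment(fgm$tree, 80, seed = 72, omega_bg = 0.4)
  pi <- f3x4_frequencies(sim$aln)
  for (om in c(0.1, 1, 3)) {
    Q <- mg94_rate_matrix(pi, om, hky_exchangeabilities(2.5))
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    D <- pi * Q
    expect_lt(max(abs(D - t(D))), 1e-10)      # detailed balance
    expect_equal(-sum(pi * diag(Q)), 1)       # unit mean rate
    offdiag <- Q[row(Q) != col(Q)]
    expect_true(all(offdiag >= 0))
  }
})

test_that("two-taxon pruning equals the direct sum over states", {
  set.seed(73)
  tr <- ape::read.tree(text = "(a:0.21,b:0.34);")
  for (k in 1:10) {
    sim <- simulate_codon_alignment(tr, 40, seed = 100 + k,
                                    omega_bg = runif(1, 0.1, 2),
                                    kappa = runif(1, 1, 5))
    pi <- f3x4_frequencies(sim$aln)
    om <- runif(1, 0.05, 3)
    # random GTR exchangeabilities
    ex <- matrix(0, 4, 4)
    ex[upper.tri(ex)] <- runif(6, 0.3, 3)
    ex <- ex + t(ex)
    Q <- mg94_rate_matrix(pi, om, ex)
    tt <- sum(tr$edge.length)
    P <- plastevol:::prob_matrix(plastevol:::rate_eigen(Q, pi), tt)
    i1 <- sim$aln$idx[1, ]; i2 <- sim$aln$idx[2, ]
    direct <- sum(log(pi[i1] * P[cbind(i1, i2)]))
    prun <- mg94_loglik(sim$aln, tr, omega_bg = om, exch = ex, pi = pi)
    expect_lt(abs(direct - prun), 1e-8)
  }
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  set.seed(74)
  fgm <- default_selection_tree()
  sim <- simulate_codon_alignment(fgm$tree, 60, seed = 75, omega_bg = 0.3)
  l1 <- mg94_loglik(sim$aln, fgm$tree, omega_bg = 0.3, kappa = 2)
  rerooted <- ape::root(fgm$tree, outgroup = "t5")
  l2 <- mg94_loglik(sim$aln, rerooted, omega_bg = 0.3, kappa = 2)
  expect_lt(abs(l1 - l2), 1e-6)
})

test_that("nested fits respect the likelihood ordering", {
  set.seed(76)
  fgm <- default_selection_tree()
  sim <- simulate_codon_alignment(fgm$tree, 120, seed = 77,
                                  omega_bg = 0.3, omega_fg = 0.7,
                                  foreground = fgm$foreground)
  fits <- fit_selection_models(sim$aln, fgm$tree, fgm$foreground)
  expect_gte(fits$b_free$lnl, fits$M0$lnl - 1e-6)
  expect_gte(fits$b_free$lnl, fits$b_neut$lnl - 1e-6)
  tst <- lrt(fits$b_free, fits$M0)
  expect_gte(tst$statistic, 0)
  expect_equal(tst$df, 1)
})

test_that("b_free recovers branch-specific omega on one long gene", {
  fgm <- default_selection_tree()
  sim <- simulate_codon_alignment(fgm$tree, 500, seed = 78,
                                  omega_bg = 0.2, omega_fg = 0.8,
                                  foreground = fgm$foreground)
  fits <- fit_selection_models(sim$aln, fgm$tree, fgm$foreground)
  expect_lt(abs(fits$b_free$omega_bg - 0.2), 0.15)
  expect_lt(abs(fits$b_free$omega_fg - 0.8), 0.4)
  expect_gt(fits$b_free$omega_fg, fits$b_free$omega_bg)
})

test_that("classify_selection implements the decision tree", {
  mk <- function(lnl, wbg, wfg = wbg, np = 1) {
    list(lnl = lnl, omega_bg = wbg, omega_fg = wfg, kappa = 2,
         n_free_params = np, convergence = TRUE)
  }
  # significant b_free vs M0, fg > bg, no deviation from neutrality
  fits <- list(M0 = mk(-1000, 0.3), b_neut = mk(-997.2, 0.2, 1),
               b_free = mk(-996.7, 0.2, 0.8, 2))
  out <- classify_selection(fits)
  expect_equal(out$constraint_status, "Relaxed")
  expect_true(out$relaxed_selection)
  expect_equal(out$delta_omega, (0.8 - 0.2) / 0.2)
  # strengthened: significant and fg < bg, fg far from neutral
  fits2 <- list(M0 = mk(-1000, 0.3), b_neut = mk(-999.5, 0.35, 1),
                b_free = mk(-995, 0.35, 0.05, 2))
  out2 <- classify_selection(fits2)
  expect_equal(out2$constraint_status, "Strengthened")
  expect_false(out2$relaxed_selection)
  # non-significant: NS
  fits3 <- list(M0 = mk(-1000, 0.3), b_neut = mk(-999.9, 0.3, 1),
                b_free = mk(-999.9, 0.3, 0.31, 2))
  expect_equal(classify_selection(fits3)$constraint_status, "NS")
  # omega at the exclusion bound
  fits4 <- list(M0 = mk(-1000, 0.3), b_neut = mk(-990, 0.3, 1),
                b_free = mk(-990, 0.3, 12, 2))
  expect_true(classify_selection(fits4)$excluded)
  expect_error(classify_selection(fits[c("M0", "b_free")]), "b_neut")
  # table-driven randomized check of the p/omega logic
  set.seed(79)
  for (k in 1:40) {
    l0 <- -1000
    d1 <- runif(1, 0, 6); d2 <- runif(1, 0, 6)
    wbg <- runif(1, 0.05, 1); wfg <- runif(1, 0.05, 3)
    ff <- list(M0 = mk(l0, runif(1, 0.1, 1)),
               b_neut = mk(l0 + d1 / 2 - d2 / 2, wbg, 1),
               b_free = mk(l0 + d1 / 2, wbg, wfg, 2))
    got <- classify_selection(ff)
    p1 <- pchisq(d1, 1, lower.tail = FALSE)
    p2 <- pchisq(d2, 1, lower.tail = FALSE)
    want <- if (p1 >= 0.05) "NS" else if (wfg > wbg) "Relaxed"
    else "Strengthened"
    expect_equal(got$constraint_status, want)
    expect_equal(got$relaxed_selection, p1 < 0.05 && p2 >= 0.05)
  }
})

test_that("beb ratios bin as published", {
  expect_equal(beb_bin(1 / 500), "<0.25%")
  expect_equal(beb_bin(2 / 500), "0.25-0.50%")
  expect_equal(beb_bin(5 / 500), ">0.50%")
  expect_equal(beb_bin(2 / 500, significant = FALSE), "none")
})

test_that("ng86 counts match canonical small cases", {
  r0 <- ng86_rates("ATGGCT", "ATGGCT")
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0)
  # single synonymous difference TTT -> TTC (Phe/Phe)
  r1 <- ng86_rates("TTT", "TTC")
  expect_equal(r1$Sd, 1); expect_equal(r1$Nd, 0)
  # site counts from the direct oracle
  expect_equal(r1$S, (oracle_ng_sites("TTT") + oracle_ng_sites("TTC")) / 2)
  expect_equal(r1$pS, r1$Sd / r1$S)
  # a nonsynonymous difference
  r2 <- ng86_rates("AAA", "AGA")  # Lys -> Arg
  expect_equal(r2$Nd, 1); expect_equal(r2$Sd, 0)
  # two-position pair averaged over pathways, against the oracle
  o <- oracle_ng_path("TTT", "GTC")
  r3 <- ng86_rates("TTT", "GTC")
  expect_equal(r3$Sd, unname(o["sd"]))
  expect_equal(r3$Nd, unname(o["nd"]))
  # saturation flag
  expect_error(ng86_rates("TTT", "TT"), "length")
})

test_that("ng86 recovers omega from simulated divergence", {
  tr <- ape::read.tree(text = "(a:0.35,b:0.35);")
  hits <- 0; reps <- 20
  for (k in seq_len(reps)) {
    sim <- simulate_codon_alignment(tr, 500, seed = 300 + k, omega_bg = 0.3)
    tab <- codon_tables()
    s1 <- paste(tab$codons[sim$aln$idx[1, ]], collapse = "")
    s2 <- paste(tab$codons[sim$aln$idx[2, ]], collapse = "")
    om <- ng86_rates(s1, s2)$omega
    if (!is.na(om) && om > 0.2 && om < 0.45) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("hky85 distance is symmetric and matches K80 in the kappa->1 limit", {
  set.seed(80)
  s1 <- random_dna(2000, gc = 0.5)
  # apply random substitutions with equal rates (JC-like)
  v <- strsplit(s1, "")[[1]]
  idx <- sample(2000, 160)
  v[idx] <- vapply(v[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  s2 <- paste(v, collapse = "")
  d12 <- hky85_distance(s1, s2)
  d21 <- hky85_distance(s2, s1)
  expect_lt(abs(d12$distance - d21$distance), 1e-4)
  expect_equal(hky85_distance(s1, s1)$distance, 0, tolerance = 1e-6)
  # K80 closed form on the same pair
  p <- mean(v != strsplit(s1, "")[[1]] &
              (paste0(strsplit(s1, "")[[1]], v) %in%
                 c("AG", "GA", "CT", "TC")))
  q <- mean(v != strsplit(s1, "")[[1]]) - p
  k80 <- -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q)
  expect_lt(abs(d12$distance - k80), 0.01)
})

test_that("branch rate regression recovers a constructed slope", {
  rates <- data.frame(branch = paste0("b", 1:8),
                      dN = seq(0.01, 0.08, by = 0.01))
  rates$dS <- 4 * rates$dN
  fit <- branch_rate_regression(rates)
  expect_equal(fit$slope_dS_on_dN, 4)
  expect_equal(fit$slope_dN_on_dS, 0.25)
  # an excluded branch is reported by its own ratio regardless
  rates2 <- rbind(rates, data.frame(branch = "odd", dN = 0.2, dS = 0.28))
  fit2 <- branch_rate_regression(rates2, exclude = "odd")
  expect_equal(fit2$slope_dS_on_dN, 4)
  expect_equal(fit2$excluded$ratio, 1.4)
  expect_error(branch_rate_regression(rates[1:2, ]), "at least 3")
  bad <- data.frame(branch = c("a", "b", "c"), dN = 0.1, dS = c(1, 2, 3))
  expect_error(branch_rate_regression(bad), "variance")
})

test_that("branch-site test detects planted positive selection and sites", {
  fgm <- default_selection_tree()
  # a clearly detectable episode: 20% of sites at foreground omega 6
  sim <- simulate_codon_alignment(
    fgm$tree, 500, seed = 81, omega_bg = 0.2, omega_fg = 6,
    foreground = fgm$foreground,
    site_classes = list(props = c(0.65, 0.15, 0.2),
                        omega_bg = c(0.2, 1, 0.2),
                        omega_fg = c(0.2, 1, 6)))
  bs <- branch_site_test(sim$aln, fgm$tree, fgm$foreground, kappa = 2)
  expect_lt(bs$lrt$p_value, 0.05)
  expect_gt(bs$bsA$w2, 1)
  if (length(bs$selected_sites) > 0) {
    truth <- which(sim$truth$classes == 3)
    expect_gte(mean(bs$selected_sites %in% truth), 0.5)
  }
  expect_equal(bs$beb_ratio, length(bs$selected_sites) / 500)
  expect_error(branch_site_test(sim$aln, fgm$tree,
                                rep(FALSE, nrow(fgm$tree$edge))),
               "foreground")
})

test_that("branch-site null data does not trigger spurious rejection", {
  fgm <- default_selection_tree()
  rej <- 0; reps <- 6
  for (k in seq_len(reps)) {
    sim <- simulate_codon_alignment(fgm$tree, 150, seed = 400 + k,
                                    omega_bg = 0.3, omega_fg = 1,
                                    foreground = fgm$foreground)
    bs <- branch_site_test(sim$aln, fgm$tree, fgm$foreground, kappa = 2)
    if (bs$lrt$p_value < 0.05) rej <- rej + 1
  }
  expect_lte(rej, 2)  # small-sample guard at nominal 5%
})

test_that("pairwise ML omega tracks the simulation truth", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  sim <- simulate_codon_alignment(tr, 500, seed = 82, omega_bg = 0.3)
  tab <- codon_tables()
  s1 <- paste(tab$codons[sim$aln$idx[1, ]], collapse = "")
  s2 <- paste(tab$codons[sim$aln$idx[2, ]], collapse = "")
  pw <- pairwise_mg94(s1, s2, kappa = 2)
  expect_lt(abs(pw$omega - 0.3), 0.15)
  expect_lt(abs(pw$t - 0.6), 0.25)
  expect_gt(pw$dS, pw$dN)  # purifying regime
})
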