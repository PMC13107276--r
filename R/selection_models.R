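OMEGA_BOUNDS <- c(1e-4, 20)

## Shared optimizer wrapper: box-constrained L-BFGS-B on log-scale
## parameters, returning the best of the supplied starts.
optim_best <- function(starts, fn, lower, upper) {
  best <- NULL
  for (s in starts) {
    r <- tryCatch(
      optim(s, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(fnscale = -1, maxit = 200, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(r)) next
    if (is.null(best) || r$value > best$value) best <- r
  }
  if (is.null(best)) stop("optimization failed from every start")
  best
}

#' Fit MG94 branch models to a gene
#'
#' Fits the one-ratio model (M0), the foreground-fixed-neutral model
#' (b_neut: foreground omega = 1, background free) and the two-ratio model
#' (b_free: both free). kappa (HKY) is estimated jointly with omega under
#' M0 and reused for the other models; branch lengths are taken from the
#' tree (optionally rescaled under M0 with `optimize_blen = TRUE`) and held
#' fixed across models so the models stay nested in the omega parameters.
#' Extra starts on an omega grid are tried whenever a nested fit falls
#' below its null.
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo` with branch lengths (substitutions per codon).
#' @param foreground Logical per edge row of `tree$edge`; see
#'   [foreground_edges()].
#' @param models Which of `"M0"`, `"b_neut"`, `"b_free"` to fit.
#' @param kappa Fixed kappa; `NULL` estimates it under M0.
#' @param optimize_blen Rescale tree length under M0 before fitting.
#' @return Named list of fits; each has `model`, `lnl`, `omega_bg`,
#'   `omega_fg`, `kappa`, `n_free_params`, `convergence`.
#' @export
fit_selection_models <- function(aln, tree, foreground,
                                 models = c("M0", "b_neut", "b_free"),
                                 kappa = NULL, optimize_blen = FALSE) {
  prep <- prep_lik(aln, tree)
  fg <- reorder_foreground(tree, prep$tree, foreground)
  lb <- log(OMEGA_BOUNDS[1]); ub <- log(OMEGA_BOUNDS[2])
  cache <- new.env(parent = emptyenv())
  ll <- function(om_bg, om_fg, kap, scale = 1) {
    prep2 <- prep
    if (scale != 1) prep2$tree$edge.length <- prep$tree$edge.length * scale
    ex <- hky_exchangeabilities(kap)
    om <- ifelse(fg, om_fg, om_bg)
    sum(prep$weights * mg94_site_loglik_core(prep2, om, ex,
                                             ref_omega = om_bg))
  }
  fits <- list()

  # --- M0 ---------------------------------------------------------------
  est_kappa <- is.null(kappa)
  if (est_kappa) {
    f <- function(p) ll(exp(p[1]), exp(p[1]), exp(p[2]))
    r <- optim_best(list(c(log(0.3), log(2))),
                    f, c(lb, log(0.1)), c(ub, log(50)))
    kap <- exp(r$par[2]); om0 <- exp(r$par[1])
  } else {
    f <- function(p) ll(exp(p[1]), exp(p[1]), kappa)
    r <- optim_best(list(log(0.3)), f, lb, ub)
    kap <- kappa; om0 <- exp(r$par[1])
  }
  scale <- 1
  if (optimize_blen) {
    g <- function(ls) ll(om0, om0, kap, scale = exp(ls))
    rs <- optim_best(list(0), g, log(0.05), log(20))
    scale <- exp(rs$par[1])
    prep$tree$edge.length <- prep$tree$edge.length * scale
    r$value <- rs$value
  }
  fits$M0 <- list(model = "M0", lnl = r$value, omega_bg = om0,
                  omega_fg = om0, kappa = kap,
                  n_free_params = 1L, convergence = r$convergence == 0)
  if (!("b_neut" %in% models) && !("b_free" %in% models))
    return(fits[intersect(names(fits), models)])

  # --- b_neut: omega_fg == 1 -------------------------------------------
  if ("b_neut" %in% models) {
    f <- function(p) ll(exp(p[1]), 1, kap)
    r <- optim_best(list(log(om0)), f, lb, ub)
    fits$b_neut <- list(model = "b_neut", lnl = r$value,
                        omega_bg = exp(r$par[1]), omega_fg = 1, kappa = kap,
                        n_free_params = 1L, convergence = r$convergence == 0)
  }

  # --- b_free -----------------------------------------------------------
  if ("b_free" %in% models) {
    f <- function(p) ll(exp(p[1]), exp(p[2]), kap)
    starts <- list(c(log(om0), log(om0)))
    r <- optim_best(starts, f, c(lb, lb), c(ub, ub))
    # nesting guard: b_free must not fall below M0 (or b_neut)
    floor_lnl <- max(fits$M0$lnl,
                     if (!is.null(fits$b_neut)) fits$b_neut$lnl else -Inf)
    if (r$value < floor_lnl - 1e-6) {
      grid <- c(0.1, 0.3, 0.5, 1, 2)
      extra <- c(lapply(grid, function(w) c(log(om0), log(w))),
                 list(c(log(om0), log(1))))
      r2 <- optim_best(c(starts, extra), f, c(lb, lb), c(ub, ub))
      if (r2$value > r$value) r <- r2
    }
    fits$b_free <- list(model = "b_free", lnl = r$value,
                        omega_bg = exp(r$par[1]), omega_fg = exp(r$par[2]),
                        kappa = kap, n_free_params = 2L,
                        convergence = r$convergence == 0)
  }
  fits[intersect(c("M0", "b_neut", "b_free"), models)]
}

#' Likelihood-ratio test between nested model fits
#'
#' 2 * (lnL_alt - lnL_null) against chi-squared with df equal to the
#' difference in free parameters. Small negative statistics (numerical
#' convergence slack) are clamped to zero.
#'
#' @param alt,null Fits from [fit_selection_models()] or
#'   [branch_site_test()].
#' @param df Degrees of freedom (default from the fits' parameter counts).
#' @return List: statistic, df, p_value.
#' @export
lrt <- function(alt, null, df = NULL) {
  stat <- 2 * (alt$lnl - null$lnl)
  if (stat < -1e-4)
    warning(sprintf("alternative lnL below null by %.3g; check convergence",
                    -stat / 2))
  stat <- max(stat, 0)
  if (is.null(df)) df <- alt$n_free_params - null$n_free_params
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Branch-site test for episodic positive selection
#'
#' Fits branch-site model A (four site classes; omega2 >= 1 free on the
#' foreground branch) against its null (omega2 fixed at 1) and reports the
#' df = 1 LRT together with empirical-Bayes posterior probabilities of
#' membership in the positively selected classes at the MLEs (NEB);
#' selected sites are those with posterior >= `posterior_cut`.
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo` with branch lengths.
#' @param foreground Logical per edge row; exactly one foreground branch
#'   set is required.
#' @param kappa Fixed kappa (`NULL`: estimated under M0 first).
#' @param posterior_cut Posterior threshold for calling a selected site.
#' @return List: `bsA1`, `bsA` (fits with class proportions), `lrt`,
#'   `posterior` (per codon site), `selected_sites`, `beb_ratio`.
#' @export
branch_site_test <- function(aln, tree, foreground, kappa = NULL,
                             posterior_cut = 0.95) {
  if (!any(foreground)) stop("no foreground branch set")
  prep <- prep_lik(aln, tree)
  fg <- reorder_foreground(tree, prep$tree, foreground)
  if (is.null(kappa)) {
    kappa <- fit_selection_models(aln, tree, foreground, models = "M0")$M0$kappa
  }
  ex <- hky_exchangeabilities(kappa)
  site_ll <- function(om_bg, om_fg, cache, ref) {
    mg94_site_loglik_core(prep, ifelse(fg, om_fg, om_bg), ex, cache = cache,
                          ref_omega = ref)
  }
  npat <- ncol(prep$patterns)
  mix_lnl <- function(p0, p1, w0, w2, return_post = FALSE) {
    cache <- new.env(parent = emptyenv())
    p2 <- max(1 - p0 - p1, 0)
    p2a <- p2 * p0 / (p0 + p1)
    p2b <- p2 * p1 / (p0 + p1)
    L <- rbind(site_ll(w0, w0, cache, w0), site_ll(1, 1, cache, w0),
               site_ll(w0, w2, cache, w0), site_ll(1, w2, cache, w0))
    pr <- c(p0, p1, p2a, p2b)
    keep <- pr > 0
    lmax <- apply(L[keep, , drop = FALSE], 2, max)
    lik <- colSums(pr[keep] * exp(sweep(L[keep, , drop = FALSE], 2, lmax)))
    ll <- sum(prep$weights * (log(lik) + lmax))
    if (!return_post) return(ll)
    post_pat <- colSums(pr[3:4] * exp(sweep(L[3:4, , drop = FALSE], 2, lmax))) /
      lik
    if (!keep[3]) post_pat <- rep(0, npat)
    list(lnl = ll, posterior = post_pat[prep$site_of_pattern])
  }
  unpack <- function(par, null) {
    z <- exp(c(par[1], par[2], 0))
    pr <- z / sum(z)
    w0 <- exp(par[3])
    w2 <- if (null) 1 else exp(par[4])
    list(p0 = pr[1], p1 = pr[2], w0 = w0, w2 = w2)
  }
  fit_bs <- function(null) {
    f <- function(par) {
      q <- unpack(par, null)
      mix_lnl(q$p0, q$p1, q$w0, q$w2)
    }
    lower <- c(-8, -8, log(1e-4)); upper <- c(8, 8, log(0.999))
    starts <- list(c(log(3), log(1), log(0.2)),
                   c(log(1), log(1), log(0.5)))
    if (!null) {
      lower <- c(lower, log(1)); upper <- c(upper, log(OMEGA_BOUNDS[2]))
      starts <- lapply(starts, function(s) c(s, log(2)))
      starts <- c(starts, list(c(log(3), log(1), log(0.2), log(1.0001))))
    }
    r <- optim_best(starts, f, lower, upper)
    q <- unpack(r$par, null)
    c(q, list(lnl = r$value, convergence = r$convergence == 0,
              n_free_params = if (null) 3L else 4L))
  }
  f0 <- fit_bs(TRUE)
  f1 <- fit_bs(FALSE)
  if (f1$lnl < f0$lnl - 1e-6) {
    # refit the alternative from the null solution
    f <- function(par) { q <- unpack(par, FALSE); mix_lnl(q$p0, q$p1, q$w0, q$w2) }
    r <- optim_best(list(c(log(f0$p0 / (1 - f0$p0 - f0$p1 + 1e-9)),
                           log(f0$p1 / (1 - f0$p0 - f0$p1 + 1e-9)),
                           log(f0$w0), log(1.0001))),
                    f, c(-8, -8, log(1e-4), log(1)),
                    c(8, 8, log(0.999), log(OMEGA_BOUNDS[2])))
    q <- unpack(r$par, FALSE)
    if (r$value > f1$lnl)
      f1 <- c(q, list(lnl = r$value, convergence = r$convergence == 0,
                      n_free_params = 4L))
  }
  test <- lrt(f1, f0, df = 1)
  post <- mix_lnl(f1$p0, f1$p1, f1$w0, f1$w2, return_post = TRUE)$posterior
  sel <- which(post >= posterior_cut)
  list(bsA1 = f0, bsA = f1, lrt = test, posterior = post,
       selected_sites = sel,
       beb_ratio = length(sel) / prep$n_codons)
}

#' Bin a branch-site selected-site ratio
#'
#' @param beb_ratio Selected sites over protein length.
#' @param significant Was the branch-site LRT significant?
#' @return `"none"`, `"<0.25%"`, `"0.25-0.50%"` or `">0.50%"`.
#' @export
beb_bin <- function(beb_ratio, significant = TRUE) {
  if (!significant || is.na(beb_ratio)) return("none")
  if (beb_ratio < 0.0025) "<0.25%" else if (beb_ratio <= 0.005)
    "0.25-0.50%" else ">0.50%"
}

#' Classify the selective regime of a gene
#'
#' Decision tree over the branch-model fits: genes with a significant
#' b_free vs M0 LRT (p < alpha) get a constraint status, Relaxed when the
#' foreground omega exceeds the background, Strengthened when it is lower;
#' relaxed selection additionally requires that the foreground does not
#' deviate from neutrality (b_free vs b_neut p >= alpha). Genes with any
#' extreme omega estimate (>= 10 or <= 0.001 in any model) are excluded.
#'
#' @param fits List from [fit_selection_models()] with `M0`, `b_neut`,
#'   `b_free`.
#' @param bs Optional result of [branch_site_test()].
#' @param alpha Significance level for the LRTs.
#' @param exclude_bounds Exclusion omega bounds `c(low, high)`.
#' @return One-row data frame: constraint_status, relaxed_selection,
#'   delta_omega, omega_fg, omega_bg, p_bfree_m0, p_bfree_bneut,
#'   bs_p, beb_ratio, beb_bin, excluded.
#' @export
classify_selection <- function(fits, bs = NULL, alpha = 0.05,
                               exclude_bounds = c(0.001, 10)) {
  for (m in c("M0", "b_neut", "b_free")) {
    if (is.null(fits[[m]])) stop("missing fit for model ", m)
  }
  # estimated omegas only (b_neut's foreground is fixed at 1, not estimated)
  omegas <- c(fits$M0$omega_bg, fits$b_neut$omega_bg,
              fits$b_free$omega_bg, fits$b_free$omega_fg)
  excluded <- any(omegas >= exclude_bounds[2] | omegas <= exclude_bounds[1]) ||
    !all(vapply(fits, function(f) isTRUE(f$convergence), logical(1)))
  p1 <- lrt(fits$b_free, fits$M0, df = 1)$p_value
  p2 <- lrt(fits$b_free, fits$b_neut, df = 1)$p_value
  wfg <- fits$b_free$omega_fg; wbg <- fits$b_free$omega_bg
  status <- if (p1 >= alpha || wfg == wbg) "NS" else
    if (wfg > wbg) "Relaxed" else "Strengthened"
  relaxed <- p1 < alpha && p2 >= alpha
  bs_p <- if (!is.null(bs)) bs$lrt$p_value else NA_real_
  ratio <- if (!is.null(bs)) bs$beb_ratio else NA_real_
  data.frame(constraint_status = status, relaxed_selection = relaxed,
             delta_omega = (wfg - wbg) / wbg, omega_fg = wfg, omega_bg = wbg,
             p_bfree_m0 = p1, p_bfree_bneut = p2,
             bs_p = bs_p, beb_ratio = ratio,
             beb_bin = beb_bin(ratio, !is.na(bs_p) && bs_p < alpha),
             excluded = excluded)
}

## ---- Nei-Gojobori (1986) pairwise counting --------------------------------

.ng_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  tb <- get0("tab", envir = .ng_cache, inherits = FALSE)
  if (!is.null(tb)) return(tb)
  tab <- codon_tables()
  bases <- c("T", "C", "A", "G")
  stops <- c("TAA", "TAG", "TGA")
  # synonymous site fraction per codon: changes to stops count nonsynonymous
  syn_sites <- vapply(seq_len(61), function(i) {
    cod <- strsplit(tab$codons[i], "")[[1]]
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, cod[p])) {
        alt <- cod; alt[p] <- b
        alt <- paste(alt, collapse = "")
        if (!(alt %in% stops) && tab$aa[match(alt, tab$codons)] == tab$aa[i])
          s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  # pathway-averaged synonymous / nonsynonymous differences per codon pair
  sd <- nd <- matrix(0, 61, 61)
  perms <- list(`1` = list(1L), `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  aa_of <- function(cod) unname(Biostrings::GENETIC_CODE[cod])
  for (i in seq_len(61)) {
    ci <- strsplit(tab$codons[i], "")[[1]]
    for (j in seq_len(61)) {
      if (i == j) next
      cj <- strsplit(tab$codons[j], "")[[1]]
      dpos <- which(ci != cj)
      k <- length(dpos)
      tot_s <- tot_n <- 0; nvalid <- 0
      alt_s <- alt_n <- 0  # fallback including stop-crossing paths
      for (ord in perms[[as.character(k)]]) {
        cur <- ci; ps <- pn <- 0; valid <- TRUE
        for (step in ord) {
          nxt <- cur; nxt[dpos[step]] <- cj[dpos[step]]
          a1 <- aa_of(paste(cur, collapse = ""))
          a2 <- aa_of(paste(nxt, collapse = ""))
          if (a2 == "*" || a1 == "*") valid <- FALSE
          if (a1 == a2 && a1 != "*") ps <- ps + 1 else pn <- pn + 1
          cur <- nxt
        }
        alt_s <- alt_s + ps; alt_n <- alt_n + pn
        if (valid) { tot_s <- tot_s + ps; tot_n <- tot_n + pn; nvalid <- nvalid + 1 }
      }
      nperm <- length(perms[[as.character(k)]])
      if (nvalid > 0) {
        sd[i, j] <- tot_s / nvalid; nd[i, j] <- tot_n / nvalid
      } else {
        sd[i, j] <- alt_s / nperm; nd[i, j] <- alt_n / nperm
      }
    }
  }
  tb <- list(syn_sites = syn_sites, sd = sd, nd = nd)
  assign("tab", tb, envir = .ng_cache)
  tb
}

#' Nei-Gojobori (1986) pairwise dN and dS
#'
#' Synonymous/nonsynonymous site counts averaged over the two sequences
#' (changes to stop codons counted as nonsynonymous), differences averaged
#' with equal weight over all minimal substitution pathways that avoid stop
#' codons (falling back to all pathways when every one is blocked), and the
#' Jukes-Cantor correction d = -3/4 log(1 - 4p/3).
#'
#' @param seq1,seq2 Equal-length, in-frame, gap-free coding sequences.
#' @return List: S, N, Sd, Nd, pS, pN, dS, dN, omega, saturated.
#' @export
ng86_rates <- function(seq1, seq2) {
  c1 <- codon_index(split_codons(seq1))
  c2 <- codon_index(split_codons(seq2))
  if (length(c1) != length(c2)) stop("sequences differ in codon length")
  if (any(is.na(c1)) || any(is.na(c2)))
    stop("sequences contain stop or ambiguous codons")
  tb <- ng86_tables()
  S <- (sum(tb$syn_sites[c1]) + sum(tb$syn_sites[c2])) / 2
  N <- 3 * length(c1) - S
  Sd <- sum(tb$sd[cbind(c1, c2)])
  Nd <- sum(tb$nd[cbind(c1, c2)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
       omega = if (is.finite(dS) && dS > 0) dN / dS else NA_real_,
       saturated = !is.finite(dS) || !is.finite(dN))
}

## ---- pairwise ML under MG94 (runmode=pairwise analogue) -------------------

#' Two-sequence ML estimates of dN and dS under MG94
#'
#' Joint maximum likelihood of the divergence time and omega for one
#' sequence pair under MG94 x HKY with F3x4 frequencies; dN and dS are
#' derived from the fitted rate matrix by partitioning the expected flux
#' into nonsynonymous and synonymous substitutions per respective site
#' (sites counted by the mutational opportunity under omega = 1).
#'
#' @param seq1,seq2 In-frame coding sequences of equal length.
#' @param kappa HKY kappa (fixed).
#' @return List: t, omega, dN, dS, lnl.
#' @export
pairwise_mg94 <- function(seq1, seq2, kappa = 2) {
  aln <- codon_alignment(c(a = seq1, b = seq2))
  tree <- ape::read.tree(text = "(a:0.5,b:0.5);")
  prep <- prep_lik(aln, tree)
  ex <- hky_exchangeabilities(kappa)
  f <- function(p) {
    prep$tree$edge.length <- rep(exp(p[1]) / 2, 2)
    sum(prep$weights *
          mg94_site_loglik_core(prep, rep(exp(p[2]), 2), ex,
                                ref_omega = exp(p[2])))
  }
  r <- optim_best(list(c(log(0.2), log(0.3)), c(log(0.5), log(1))),
                  f, c(log(1e-6), log(OMEGA_BOUNDS[1])),
                  c(log(15), log(OMEGA_BOUNDS[2])))
  t <- exp(r$par[1]); om <- exp(r$par[2])
  flux <- mg94_flux(prep$pi, om, ex)
  list(t = t, omega = om,
       dN = t * flux$nonsyn_frac / flux$n_frac_sites,
       dS = t * flux$syn_frac / flux$s_frac_sites, lnl = r$value)
}

## Expected substitution flux split and site opportunity under MG94.
mg94_flux <- function(pi, omega, ex) {
  tab <- codon_tables()
  nb <- tab$nb
  rate <- ex[cbind(nb$from_nt, nb$to_nt)] * pi[nb$j] *
    ifelse(nb$syn, 1, omega)
  tot <- sum(pi[nb$i] * rate)
  syn <- sum((pi[nb$i] * rate)[nb$syn]) / tot
  # site opportunity at omega = 1 (proportion of mutational flux)
  rate1 <- ex[cbind(nb$from_nt, nb$to_nt)] * pi[nb$j]
  tot1 <- sum(pi[nb$i] * rate1)
  s_sites <- sum((pi[nb$i] * rate1)[nb$syn]) / tot1
  list(syn_frac = syn, nonsyn_frac = 1 - syn,
       s_frac_sites = s_sites, n_frac_sites = 1 - s_sites)
}

## ---- HKY85 pairwise distance (non-coding regions) -------------------------

#' ML pairwise distance under HKY85
#'
#' Joint maximum likelihood of the distance and kappa for one aligned
#' nucleotide pair under HKY85 with empirical base frequencies. Sites with
#' gaps or N are dropped.
#'
#' @param seq1,seq2 Aligned nucleotide strings of equal length.
#' @return List: distance, kappa, lnl, saturated.
#' @export
hky85_distance <- function(seq1, seq2) {
  v1 <- strsplit(toupper(seq1), "")[[1]]
  v2 <- strsplit(toupper(seq2), "")[[1]]
  if (length(v1) != length(v2)) stop("sequences differ in length")
  b <- c("T", "C", "A", "G")
  i1 <- match(v1, b); i2 <- match(v2, b)
  ok <- !is.na(i1) & !is.na(i2)
  i1 <- i1[ok]; i2 <- i2[ok]
  if (length(i1) == 0) stop("no comparable sites")
  counts <- matrix(0, 4, 4)
  for (k in seq_along(i1)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1
  pi <- (tabulate(i1, 4) + tabulate(i2, 4)) / (2 * length(i1))
  pi <- pmax(pi, 1e-9); pi <- pi / sum(pi)
  hky_q <- function(kap) {
    ex <- hky_exchangeabilities(kap)
    Q <- ex * rep(pi, each = 4)
    diag(Q) <- -rowSums(Q)
    Q / (-sum(pi * diag(Q)))
  }
  f <- function(p) {
    t <- exp(p[1]); kap <- exp(p[2])
    es <- rate_eigen(hky_q(kap), pi)
    P <- prob_matrix(es, t)
    P <- pmax(P, 1e-300)
    sum(counts * log(pi * P))
  }
  r <- optim_best(list(c(log(0.1), log(2)), c(log(1), log(2))),
                  f, c(log(1e-8), log(0.05)), c(log(12), log(100)))
  t <- exp(r$par[1])
  list(distance = if (t > 11) Inf else t, kappa = exp(r$par[2]),
       lnl = r$value, saturated = t > 11)
}

## ---- branch-level dN/dS regression ----------------------------------------

#' Regression between per-branch dN and dS rates
#'
#' Ordinary least squares of dS on dN (and the reverse) over tree branches,
#' with nominated branches excluded from the regression and reported
#' separately by their own dS/dN ratio. A tight dS-on-dN slope across
#' branches reflects a shared mutation-rate axis; an excluded branch whose
#' ratio falls far from the slope is decoupled from it.
#'
#' @param rates Data frame with columns `branch`, `dN`, `dS`.
#' @param exclude Branch labels excluded from the regression.
#' @return List: slope_dS_on_dN, slope_dN_on_dS, ci95, r2, n, excluded
#'   (data frame with per-branch dS/dN ratios).
#' @export
branch_rate_regression <- function(rates, exclude = NULL) {
  stopifnot(all(c("branch", "dN", "dS") %in% names(rates)))
  keep <- !(rates$branch %in% exclude)
  d <- rates[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 branches after exclusion")
  if (var(d$dN) == 0 || var(d$dS) == 0)
    stop("degenerate variance in dN or dS")
  fit1 <- lm(dS ~ dN, data = d)
  fit2 <- lm(dN ~ dS, data = d)
  exc <- rates[!keep, , drop = FALSE]
  exc$ratio <- exc$dS / exc$dN
  list(slope_dS_on_dN = unname(coef(fit1)[2]),
       slope_dN_on_dS = unname(coef(fit2)[2]),
       ci95 = unname(suppressWarnings(confint(fit1)[2, ])),
       r2 = suppressWarnings(summary(fit1)$r.squared),
       n = nrow(d), excluded = exc)
}
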