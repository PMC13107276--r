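test_that("orf_scan handles canonical toy cases", {
  got <- orf_scan("ATGAAATAA", min_codons = 2)
  expect_equal(nrow(got[got$strand == "+", ]), 1L)
  expect_equal(got$start[1], 1L)
  expect_equal(got$end[1], 9L)
  expect_equal(got$n_codons[1], 3L)
  expect_true(got$has_stop[1])
  # no ATG anywhere -> nothing
  expect_equal(nrow(orf_scan("CCCCCCCCCCCC", min_codons = 2)), 0L)
  # ORF running off the end without a stop
  open <- orf_scan("ATGAAAAAA", min_codons = 2)
  expect_false(open$has_stop[open$strand == "+"][1])
})

test_that("orf_scan agrees with a brute-force six-frame enumeration", {
  set.seed(21)
  seqc <- random_dna(5000)
  got <- orf_scan(seqc, min_codons = 10)
  # oracle: walk each frame of each strand directly
  stops <- c("TAA", "TAG", "TGA")
  oracle <- NULL
  for (str in c("+", "-")) {
    s <- if (str == "+") seqc else revcomp(seqc)
    n <- nchar(s)
    for (fr in 0:2) {
      ncod <- (n - fr) %/% 3
      if (ncod < 1) next
      cods <- substring(s, fr + 3 * (seq_len(ncod) - 1) + 1,
                        fr + 3 * seq_len(ncod))
      open_at <- NA
      for (k in seq_len(ncod)) {
        if (is.na(open_at) && cods[k] == "ATG") open_at <- k
        if (!is.na(open_at) && (cods[k] %in% stops || k == ncod)) {
          len <- k - open_at + 1
          if (len >= 10) {
            p1 <- fr + (open_at - 1) * 3 + 1; p2 <- fr + k * 3
            if (str == "-") { t1 <- n - p2 + 1; p2 <- n - p1 + 1; p1 <- t1 }
            oracle <- rbind(oracle, data.frame(start = p1, end = p2,
                                               strand = str))
          }
          open_at <- NA
        }
      }
    }
  }
  oracle <- oracle[order(oracle$start, oracle$end), ]
  expect_equal(got$start, oracle$start)
  expect_equal(got$end, oracle$end)
  expect_equal(got$strand, oracle$strand)
})

test_that("global_align reproduces trivial scores and coverage", {
  set.seed(22)
  s <- random_dna(300)
  al <- global_align(s, s)
  expect_equal(al$score, 300)
  expect_equal(al$coverage, 1.0)
  # internal 3-nt deletion: all remaining query bases align
  q <- paste0(substring(s, 1, 150), substring(s, 154, 300))
  al2 <- global_align(s, q)
  expect_equal(al2$aligned_ref_bases, 297)
  expect_equal(al2$coverage, 297 / 300)
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("global_align score equals exhaustive enumeration on short pairs", {
  set.seed(23)
  for (k in 1:25) {
    p <- random_pair_short()
    got <- global_align(p[1], p[2])$score
    expect_equal(got, oracle_align_score(p[1], p[2]),
                 info = paste(p, collapse = " vs "))
  }
})

test_that("deleting aligned query bases never increases coverage", {
  set.seed(24)
  ref <- random_dna(120)
  q <- ref
  prev <- global_align(ref, q)$coverage
  for (k in 1:6) {
    # delete a 6-base chunk from the query each round
    cut <- sample(nchar(q) - 10, 1)
    q <- paste0(substring(q, 1, cut), substring(q, cut + 7, nchar(q)))
    cov <- global_align(ref, q)$coverage
    expect_lte(cov, prev + 1e-12)
    prev <- cov
  }
})

test_that("classify_gene applies the inclusive 70% rule and overrides", {
  expect_equal(classify_gene(0.79), "intact")
  expect_equal(classify_gene(0.71), "intact")
  expect_equal(classify_gene(0.70), "intact")   # inclusive threshold
  expect_equal(classify_gene(0.699), "pseudogene")
  expect_equal(classify_gene(0.49), "pseudogene")
  expect_equal(classify_gene(0.9, present = FALSE), "lost")
  # psbI-style exception: intact below threshold when present
  expect_equal(classify_gene(0.65, gene = "psbI"), "intact")
  expect_equal(classify_gene(0.65, gene = "psbA"), "pseudogene")
  expect_equal(classify_gene(0.3, gene = "psbI"), "pseudogene")
})

test_that("the ndh cascade downgrades all ndh genes and is idempotent", {
  calls <- data.frame(
    gene = c(paste0("ndh", LETTERS[1:11]), "psbA", "rbcL"),
    status = "intact", coverage = 0.99, cascade_applied = FALSE)
  expect_identical(apply_ndh_cascade(calls), calls)  # all intact: unchanged
  calls$status[calls$gene == "ndhA"] <- "pseudogene"
  out <- apply_ndh_cascade(calls)
  ndh <- grepl("^ndh", out$gene)
  expect_true(all(out$status[ndh] != "intact"))
  expect_equal(sum(out$cascade_applied), 10L)  # the ten others
  expect_false(out$cascade_applied[out$gene == "ndhA"])
  expect_equal(out$status[out$gene == "psbA"], "intact")
  # coverage preserved as evidence
  expect_equal(out$coverage[out$gene == "ndhB"], 0.99)
  # lost genes stay lost; intact become pseudogene
  calls2 <- calls
  calls2$status[calls2$gene == "ndhF"] <- "lost"
  out2 <- apply_ndh_cascade(calls2)
  expect_equal(out2$status[out2$gene == "ndhF"], "lost")
  expect_equal(out2$status[out2$gene == "ndhB"], "pseudogene")
  # idempotence
  expect_identical(apply_ndh_cascade(out), out)
})

test_that("classifier recovers planted statuses on a synthetic genome", {
  cfg <- small_config(plan = data.frame(
    gene = c("ndhD", "clpP", "rpoA"),
    action = c("truncate", "remove", "truncate"),
    param = c(0.45, NA, 0.55)))
  g <- make_plastome(cfg, seed = 31, trophic_class = "CP")
  ref <- g$truth$ref_cds[protein_genes(small_roster())]
  calls <- classify_genome(g$record, ref)
  expect_equal(setNames(calls$status, calls$gene),
               g$truth$gene_status_cascaded[calls$gene])
  expect_lt(abs(calls$coverage[calls$gene == "ndhD"] - 0.45), 0.05)
  expect_true(all(calls$cascade_applied[calls$gene %in%
                                          c("ndhB", "ndhJ", "ndhK")]))
})

test_that("shared_gene_set intersects intact calls and validates input", {
  univ <- c("psbA", "rbcL", "rpl22", "ndhA")
  mk <- function(status) data.frame(gene = univ, status = status)
  two <- list(g1 = mk(rep("intact", 4)), g2 = mk(rep("intact", 4)))
  expect_equal(shared_gene_set(two, univ), univ)
  two$g2$status[two$g2$gene == "rpl22"] <- "pseudogene"
  expect_equal(shared_gene_set(two, univ), setdiff(univ, "rpl22"))
  bad <- list(g1 = mk(rep("intact", 4)), g2 = mk(rep("intact", 4))[1:3, ])
  expect_error(shared_gene_set(bad, univ), "ndhA")
})
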