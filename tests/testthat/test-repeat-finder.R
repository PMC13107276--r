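test_that("a planted exact duplication is reported once, with its E-value", {
  set.seed(41)
  s <- random_dna(5000)
  unit <- random_dna(60)
  # mismatching flanks (C..A vs G..T) pin the maximal hit to the unit
  g <- paste0(substring(s, 1, 1000), "C", unit, "A",
              substring(s, 1001, 3000), "G", unit, "T",
              substring(s, 3001, 5000))
  hits <- find_short_repeats(g)
  big <- hits[hits$length >= 50, ]
  expect_equal(nrow(big), 1L)
  expect_equal(big$orientation, "direct")
  expect_equal(c(big$q_start, big$q_end), c(1002, 1061))
  expect_equal(c(big$s_start, big$s_end), c(3064, 3123))
  expect_equal(big$identity, 1.0)
  expect_lt(big$evalue, 1e-20)
  # inverted copy found, on forward-strand coordinates (A/C flanks block
  # complementary chance extension)
  gi <- paste0(substring(s, 1, 1000), "C", unit, "A",
               substring(s, 1001, 3000), "A", revcomp(unit), "C",
               substring(s, 3001, 5000))
  hi <- find_short_repeats(gi)
  bigi <- hi[hi$length >= 50, ]
  expect_equal(nrow(bigi), 1L)
  expect_equal(bigi$orientation, "inverted")
  expect_equal(c(bigi$q_start, bigi$q_end), c(1002, 1061))
  expect_equal(c(bigi$s_start, bigi$s_end), c(3064, 3123))
})

test_that("word size below 4 is rejected; short sequences yield no hits", {
  expect_error(find_short_repeats("ACGTACGTACGT", word_size = 3), "word_size")
  # a sequence with no repeated 7-mer off-diagonal
  expect_equal(nrow(find_short_repeats("ACGTACGAACCGGTTGACTGCAT")), 0L)
})

test_that("every maximal exact repeat >= 12 bp is contained in some hit", {
  set.seed(42)
  for (k in 1:4) {
    g <- random_dna(2000, gc = 0.4)
    # plant a couple of shortish repeats to enrich the comparison
    u1 <- random_dna(15); u2 <- random_dna(25)
    g <- paste0(g, u1, random_dna(80), u1, random_dna(50), u2,
                random_dna(60), revcomp(u2))
    hits <- find_short_repeats(g, max_evalue = 6)
    oracle <- oracle_exact_repeats(g, 12L)
    for (r in seq_len(nrow(oracle))) {
      o <- oracle[r, ]
      contained <- any(
        hits$orientation == o$orientation &
          hits$q_start <= o$q1 & hits$q_end >= o$q2 &
          hits$s_start <= o$s1 & hits$s_end >= o$s2)
      mirrored <- any(
        hits$orientation == o$orientation &
          hits$q_start <= o$s1 & hits$q_end >= o$s2 &
          hits$s_start <= o$q1 & hits$s_end >= o$q2)
      expect_true(contained || mirrored,
                  info = sprintf("repeat %d-%d / %d-%d (%s) missed",
                                 o$q1, o$q2, o$s1, o$s2, o$orientation))
    }
  }
})

test_that("every reported hit contains at least one exact shared word", {
  set.seed(43)
  g <- paste0(random_dna(3000), substring(random_dna(3000), 1, 40))
  hits <- find_short_repeats(g)
  x <- strsplit(g, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in seq_len(nrow(hits))) {
    q <- x[hits$q_start[r]:hits$q_end[r]]
    s <- x[hits$s_start[r]:hits$s_end[r]]
    if (hits$orientation[r] == "inverted") s <- rev(unname(comp[s]))
    shared <- FALSE
    for (i in seq_len(length(q) - 6)) {
      if (all(q[i:(i + 6)] == s[i:(i + 6)])) { shared <- TRUE; break }
    }
    expect_true(shared)
  }
})

test_that("merge_hits unions intervals like a sweep-line oracle", {
  h <- data.frame(q_start = c(10L, 15L), q_end = c(19L, 29L),
                  s_start = c(100L, 200L), s_end = c(109L, 209L))
  m <- merge_hits(h)
  expect_equal(m$intervals$start, c(10L, 100L, 200L))
  expect_equal(m$intervals$end, c(29L, 109L, 209L))
  expect_equal(m$total_length, 20L + 10L + 10L)
  # random interval sets vs direct membership counting
  set.seed(44)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    st <- sample(500, n); en <- st + sample(5:50, n, replace = TRUE)
    h <- data.frame(q_start = st, q_end = en,
                    s_start = st + 600L, s_end = en + 600L)
    m <- merge_hits(h)
    covered <- rep(FALSE, 1500)
    for (i in seq_len(n)) {
      covered[st[i]:en[i]] <- TRUE
      covered[(st[i] + 600L):(en[i] + 600L)] <- TRUE
    }
    expect_equal(m$total_length, sum(covered))
  }
  none <- data.frame(q_start = integer(0), q_end = integer(0),
                     s_start = integer(0), s_end = integer(0))
  expect_equal(merge_hits(none)$total_length, 0L)
})

test_that("repeat content is monotone in the E-value threshold", {
  set.seed(45)
  thresholds <- c(1e-10, 1e-5, 1e-2, 1, 6)
  for (k in 1:3) {
    g <- paste0(random_dna(3000), random_dna(40), random_dna(500))
    u <- random_dna(35)
    g <- paste0(g, u, random_dna(300), u)
    prof <- repeat_content_curve(g, thresholds)
    expect_true(all(diff(prof$content) >= 0))
    expect_true(all(prof$content >= 0 & prof$content <= 1))
  }
  # no repeats at all: flat zero curve
  set.seed(46)
  prof0 <- repeat_content_curve("ACGTTGCAACGGATCCTAGGAT", thresholds)
  expect_true(all(prof0$content == 0))
})

test_that("content_slope matches closed-form least squares", {
  # constructed exact linearity: content = 0.01 * log10(E) + c
  thr <- c(1e-8, 1e-6, 1e-4, 1e-2, 1)
  prof <- data.frame(threshold = thr, length = 0,
                     content = 0.01 * log10(thr) + 0.1)
  sl <- content_slope(prof)
  expect_equal(sl$slope, 0.01, tolerance = 1e-10)
  expect_equal(sl$r2, 1)
  # flat curve: slope 0, CI containing 0
  pf <- data.frame(threshold = thr, length = 5, content = 0.02)
  s0 <- content_slope(pf)
  expect_equal(s0$slope, 0)
  expect_true(is.na(s0$ci95[1]) ||
                (s0$ci95[1] <= 0 && s0$ci95[2] >= 0))
  # random curves vs normal equations
  set.seed(47)
  for (k in 1:5) {
    y <- runif(5)
    pr <- data.frame(threshold = thr, length = 0, content = y)
    x <- log10(thr)
    beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(content_slope(pr)$slope, beta)
  }
  expect_error(content_slope(prof[1:2, ]), "at least 3")
})
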