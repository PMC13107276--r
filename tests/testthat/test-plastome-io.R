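test_that("FASTA round trip preserves sequence and id", {
  set.seed(11)
  rec <- plastome_record("TEST1", random_dna(3000), trophic_class = "AP")
  fa <- tempfile(fileext = ".fasta")
  write_plastome(rec, fa)
  back <- read_plastome(fa, "fasta")
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$id, "TEST1")
  expect_equal(nrow(back$features), 0L)
})

test_that("GFF3 round trip preserves feature coordinates", {
  set.seed(12)
  feats <- data.frame(name = c("psbA", "rbcL"), category = c("PS", "PS"),
                      strand = c("+", "-"), start = c(101L, 1001L),
                      end = c(400L, 1600L), exon = 1L,
                      status = "unknown", wrap = FALSE)
  rec <- plastome_record("TEST2", random_dna(2000), features = feats)
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  write_plastome(rec, fa, gff)
  f2 <- read_features_gff(gff)
  expect_equal(f2$start, feats$start)
  expect_equal(f2$end, feats$end)
  expect_equal(f2$name, feats$name)
  expect_equal(f2$strand, feats$strand)
})

test_that("invalid plastome inputs are rejected with informative errors", {
  expect_error(plastome_record("X", ""), "empty")
  expect_error(plastome_record("X", "ACGTQ"), "non-ACGTN")
  feats <- data.frame(name = "g", category = "HK", strand = "+",
                      start = 5L, end = 50L, exon = 1L,
                      status = "unknown", wrap = FALSE)
  expect_error(plastome_record("X", "ACGTACGT", features = feats),
               "outside")
  fa <- tempfile(fileext = ".fasta")
  writeLines(">empty_header_only", fa)
  expect_error(read_plastome(fa, "fasta"))
})

test_that("a GenBank flat file is parsed into sequence and features", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       SYNTH001                 120 bp    DNA     circular PLN",
    "DEFINITION  Synthetic test plastome fragment.",
    "  ORGANISM  Testus syntheticus",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..36",
    "                     /gene=\"psbA\"",
    "     CDS             complement(40..60)",
    "                     /gene=\"ndhB\"",
    "     tRNA            join(70..80,90..100)",
    "                     /gene=\"trnH\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), gb)
  rec <- read_plastome(gb, "genbank")
  expect_equal(nchar(rec$sequence), 120L)
  expect_equal(rec$taxon, "Testus syntheticus")
  expect_equal(sort(unique(rec$features$name)), c("ndhB", "psbA", "trnH"))
  psbA <- rec$features[rec$features$name == "psbA", ]
  expect_equal(c(psbA$start, psbA$end), c(10L, 36L))
  expect_equal(rec$features$strand[rec$features$name == "ndhB"], "-")
  trn <- rec$features[rec$features$name == "trnH", ]
  expect_equal(nrow(trn), 2L)  # two exons from the join location
  expect_equal(trn$start, c(70L, 90L))
})

test_that("planted IR is detected exactly and lengths follow", {
  set.seed(13)
  lsc <- random_dna(30000); ir <- random_dna(10000)
  # A...A termini block chance complementary extension across the junctions
  ssc <- paste0("A", random_dna(4998), "A")
  genome <- paste0(lsc, ir, ssc, revcomp(ir))
  map <- detect_inverted_repeat(genome, min_len = 1000)
  expect_true(map$has_ir)
  expect_equal(map$ir_length, 10000L)
  expect_equal(nonredundant_length(map), 45000L)
  expect_equal(unname(map$irb), c(30001, 40000))
  expect_equal(unname(map$ira), c(45001, 55000))
  # SSC is the shorter single-copy stretch between the copies
  expect_equal(map$ssc$start, 40001)
  expect_equal(map$ssc$end, 45000)
  # partition property
  reg_len <- function(df) sum(df$end - df$start + 1)
  expect_equal(reg_len(map$lsc) + reg_len(map$ssc) + 2 * map$ir_length,
               nchar(genome))
  # IR symmetry at the reported coordinates
  ira_seq <- substring(genome, map$ira["start"], map$ira["end"])
  irb_seq <- substring(genome, map$irb["start"], map$irb["end"])
  expect_identical(revcomp(ira_seq), irb_seq)
})

test_that("genomes without an IR report has_ir = FALSE", {
  set.seed(14)
  expect_false(detect_inverted_repeat(random_dna(8000), min_len = 500)$has_ir)
  expect_warning(m <- detect_inverted_repeat(random_dna(150), min_len = 100),
                 "shorter")
  expect_false(m$has_ir)
  expect_equal(nonredundant_length(m), 150L)
})

test_that("gc_by_region matches a one-pass base tally and handles N", {
  expect_equal(gc_by_region("GGCC")$gc, 1.0)
  expect_equal(gc_by_region("AATT")$gc, 0.0)
  expect_equal(gc_by_region(strrep("ACGT", 100))$gc, 0.5)
  set.seed(15)
  s <- random_dna(5000, gc = 0.4)
  got <- gc_by_region(s, regions = list(a = c(1, 2500), b = c(2501, 5000)))
  tally <- function(x) {
    v <- strsplit(x, "")[[1]]
    sum(v %in% c("G", "C")) / sum(v != "N")
  }
  expect_equal(got$gc[1], tally(substring(s, 1, 2500)))
  expect_equal(got$gc[2], tally(substring(s, 2501, 5000)))
  expect_equal(attr(got, "genome_gc"), tally(s))
  # genome GC is the base-weighted mean of the region GCs
  expect_equal(sum(got$gc * got$length) / sum(got$length),
               attr(got, "genome_gc"))
  # N excluded from numerator and denominator
  expect_equal(gc_by_region("GGNNAA")$gc, 0.5)
  expect_error(gc_by_region("ACGT", regions = list(a = c(1, 10))), "outside")
})

test_that("junction report names the flanking genes with distances", {
  set.seed(16)
  lsc <- random_dna(6000); ir <- random_dna(2500)
  ssc <- paste0("A", random_dna(1498), "A")
  # layout: LSC [1,6000], IRb [6001,8500], SSC [8501,10000], IRa [10001,12500]
  genome <- paste0(lsc, ir, ssc, revcomp(ir))
  feats <- data.frame(
    name = c("rps19", "rpl2", "ndhF", "spanner"),
    category = c("HK", "HK", "ndh", "HK"), strand = "+",
    start = c(5691L, 6101L, 8600L, 9950L),
    end = c(5990L, 6400L, 9000L, 10200L), exon = 1L,
    status = "unknown", wrap = FALSE)
  rec <- plastome_record("J1", genome, features = feats)
  map <- detect_inverted_repeat(rec, min_len = 1000)
  jr <- junction_report(rec, map)
  jlb <- jr[jr$junction == "JLB", ]
  expect_equal(jlb$upstream, "rps19")
  expect_equal(jlb$upstream_dist, 10L)
  expect_equal(jlb$downstream, "rpl2")
  jsb <- jr[jr$junction == "JSB", ]
  expect_equal(jsb$upstream, "rpl2")
  expect_equal(jsb$downstream, "ndhF")
  jsa <- jr[jr$junction == "JSA", ]
  expect_true(jsa$overlap)  # 'spanner' crosses the SSC/IRa boundary
  expect_equal(jsa$upstream, "spanner")
  rec0 <- plastome_record("J2", genome)
  expect_warning(jr0 <- junction_report(rec0, map), "no features")
  expect_equal(nrow(jr0), 0L)
})
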