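## Shared study scenario for the analysis scripts: a small panel of seven
## synthetic plastomes with planted degradation, mirroring a comparative
## design with three obligate autotrophs (AP1-AP3), three pitfall-trap
## carnivore analogues (CP1-CP3, coordinated ndh loss, mild deletions)
## and one flypaper-trap analogue ("CPx", the structurally dynamic
## lineage: ndh pseudogenes, partial clpP loss, foreign insertions,
## extra dispersed repeats). All genomes share one reference CDS set
## (ref_seed) so coverage-based annotation is meaningful.
##
## Sizes are reduced relative to real plastomes (~32 kb vs ~150 kb) so the
## whole workflow runs in minutes; every structural element (quadripartite
## layout, gene clusters, junction genes) is preserved.

library(plastevol)

SCENARIO_SEED <- 20260926L

scenario_roster <- function() {
  ros <- default_gene_roster()
  keep <- c("psbA", "psbI", "rbcL", "rps19", "rpoA", "rps2", "rps15",
            "rpl32", "clpP", "rpl2", "trnH", "rrn16",
            "ndhB", "ndhF", "ndhH", "ndhA", "ndhI", "ndhG", "ndhE",
            "psaC", "ndhD", "ndhJ", "ndhK", "ndhC")
  ros[ros$gene %in% keep, ]
}

scenario_config <- function(plan = NULL, insertions = NULL, repeats = NULL,
                            inversions = NULL) {
  default_generator_config(lsc_len = 14000L, ir_len = 7000L,
                           ssc_len = 11000L, gc = 0.38,
                           roster = scenario_roster(), plan = plan,
                           insertions = insertions, repeats = repeats,
                           inversions = inversions, ref_seed = 42L)
}

scenario_panel <- function() {
  ndh_trunc <- function(genes, covs) {
    data.frame(gene = genes, action = "truncate", param = covs)
  }
  list(
    AP1 = list(class = "AP", cfg = scenario_config(), seed = 1011L),
    AP2 = list(class = "AP", cfg = scenario_config(), seed = 1012L),
    AP3 = list(class = "AP", cfg = scenario_config(), seed = 1013L),
    CP1 = list(class = "CP", seed = 1021L, cfg = scenario_config(
      plan = rbind(ndh_trunc(c("ndhB", "ndhJ"), c(0.5, 0.45)),
                   data.frame(gene = c("ndhA", "ndhI"), action = "remove",
                              param = NA)))),
    CP2 = list(class = "CP", seed = 1022L, cfg = scenario_config(
      plan = rbind(ndh_trunc(c("ndhB", "ndhK"), c(0.55, 0.4)),
                   data.frame(gene = "ndhF", action = "remove",
                              param = NA)))),
    CP3 = list(class = "CP", seed = 1023L, cfg = scenario_config(
      plan = rbind(ndh_trunc(c("ndhB", "ndhC"), c(0.5, 0.5)),
                   data.frame(gene = "ndhA", action = "delete_internal",
                              param = 250)))),
    CPx = list(class = "CP", seed = 1031L, cfg = scenario_config(
      plan = rbind(ndh_trunc(c("ndhD", "ndhF"), c(0.45, 0.4)),
                   data.frame(gene = "clpP", action = "delete_internal",
                              param = 200)),
      insertions = data.frame(length = c(900, 600), gc = c(0.6, 0.65),
                              region = c("IR", "LSC")),
      repeats = data.frame(length = c(80, 60), gc = c(0.2, 0.25),
                           orientation = c("direct", "inverted")),
      inversions = list(c("ndhA", "ndhE"))))
  )
}

build_panel <- function() {
  panel <- scenario_panel()
  Map(function(nm, p) {
    g <- make_plastome(p$cfg, seed = p$seed, id = nm,
                       trophic_class = p$class)
    g$class <- p$class
    g
  }, names(panel), panel)
}

results_dir <- function() {
  d <- file.path("results")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
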