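#!/usr/bin/env Rscript
## Generates the synthetic study panel (3 autotroph analogues, 3 pitfall
## carnivore analogues with coordinated ndh degradation, 1 structurally
## dynamic flypaper analogue) and writes the genomes, features and planted
## truth under results/synthetic/. Everything downstream re-derives its
## inputs from these files or regenerates them deterministically.

source(file.path("analysis", "scenario.R"))

out <- file.path(results_dir(), "synthetic")
dir.create(out, showWarnings = FALSE)

panel <- build_panel()
truth_rows <- NULL
for (nm in names(panel)) {
  g <- panel[[nm]]
  write_plastome(g$record, file.path(out, paste0(nm, ".fasta")),
                 gff = file.path(out, paste0(nm, ".gff3")))
  truth_rows <- rbind(truth_rows, data.frame(
    genome = nm, trophic_class = g$class,
    gene = names(g$truth$gene_status_cascaded),
    planted_status = unname(g$truth$gene_status_cascaded)))
  message(sprintf("%s (%s): %d bp, %d features, planted IR %d bp",
                  nm, g$class, genome_length(g$record),
                  nrow(g$record$features), g$truth$ir$ir_length))
}
write.table(truth_rows, file.path(out, "planted_gene_status.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# the shared reference CDS set used for annotation coverage
ref <- panel[[1]]$truth$ref_cds
ros <- scenario_roster()
prot <- ros$gene[!ros$category %in% c("tRNA", "rRNA")]
ss <- Biostrings::DNAStringSet(ref[prot])
Biostrings::writeXStringSet(ss, file.path(out, "reference_cds.fasta"))
message("reference CDS set: ", length(prot), " protein genes")
message("done: ", out)
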