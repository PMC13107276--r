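#!/usr/bin/env Rscript
## Coverage-based gene classification of every panel genome against the
## shared reference CDS set, the coordinated ndh rule, agreement with the
## planted truth, the presence/absence matrix and shared gene sets.

source(file.path("analysis", "scenario.R"))

panel <- build_panel()
ros <- scenario_roster()
prot <- ros$gene[!ros$category %in% c("tRNA", "rRNA")]

all_calls <- NULL
status_by_genome <- list()
for (nm in names(panel)) {
  g <- panel[[nm]]
  calls <- classify_genome(g$record, g$truth$ref_cds[prot])
  calls$genome <- nm
  calls$planted <- unname(g$truth$gene_status_cascaded[calls$gene])
  all_calls <- rbind(all_calls, calls)
  status_by_genome[[nm]] <- calls
  message(sprintf("%s: %d intact / %d pseudogene / %d lost; agreement %.0f%%",
                  nm, sum(calls$status == "intact"),
                  sum(calls$status == "pseudogene"),
                  sum(calls$status == "lost"),
                  100 * mean(calls$status == calls$planted)))
}
d <- results_dir()
write.table(all_calls, file.path(d, "gene_status.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## presence/absence (intact) matrix, genomes x genes
pam <- sapply(status_by_genome, function(cl)
  as.integer(cl$status == "intact")[match(prot, cl$gene)])
rownames(pam) <- prot
write.table(t(pam), file.path(d, "presence_absence.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)

## shared gene sets: carnivores + autotrophs, then the whole panel
shared_all <- shared_gene_set(status_by_genome, prot)
message(sprintf("genes intact in every genome: %d of %d (%s)",
                length(shared_all), length(prot),
                paste(head(shared_all, 8), collapse = ", ")))
writeLines(shared_all, file.path(d, "shared_genes.txt"))
message(sprintf("overall planted-truth agreement: %.1f%%",
                100 * mean(all_calls$status == all_calls$planted)))
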