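#!/usr/bin/env Rscript
## Plastome structure and repeat landscapes across the panel: quadripartite
## maps, non-redundant lengths, per-region GC, junction genes, short-repeat
## content across E-value thresholds with the content-vs-log10(E) slope,
## and the correlation between repeat content and GC.

source(file.path("analysis", "scenario.R"))

panel <- build_panel()
struct <- NULL; profiles <- NULL; slopes <- NULL
for (nm in names(panel)) {
  g <- panel[[nm]]
  map <- detect_inverted_repeat(g$record, min_len = 1000)
  gc <- gc_by_region(g$record, map, n_boot = 200)
  nr <- ir_reduced_sequence(g$record, map)
  prof <- repeat_content_curve(nr, c(1e-10, 1e-5, 1e-2, 1, 6))
  sl <- content_slope(prof)
  struct <- rbind(struct, data.frame(
    genome = nm, trophic_class = g$class,
    length = genome_length(g$record),
    ir_length = map$ir_length,
    nonredundant_length = nonredundant_length(map),
    gc = attr(gc, "genome_gc"),
    gc_lsc = gc$gc[gc$region == "LSC"][1],
    gc_ir = if ("IR" %in% gc$region) gc$gc[gc$region == "IR"][1] else NA,
    repeat_content_e6 = prof$content[prof$threshold == 6],
    repeat_slope = sl$slope))
  profiles <- rbind(profiles, cbind(genome = nm, prof))
  slopes <- rbind(slopes, data.frame(genome = nm, slope = sl$slope,
                                     ci_lo = sl$ci95[1], ci_hi = sl$ci95[2],
                                     r2 = sl$r2))
  jr <- junction_report(g$record, map)
  message(sprintf("%s: IR %.1f kb, non-redundant %.1f kb, GC %.1f%%; JLB %s|%s",
                  nm, map$ir_length / 1000,
                  nonredundant_length(map) / 1000,
                  100 * attr(gc, "genome_gc"),
                  jr$upstream[jr$junction == "JLB"],
                  jr$downstream[jr$junction == "JLB"]))
}
d <- results_dir()
write.table(struct, file.path(d, "structure_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(profiles, file.path(d, "repeat_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(slopes, file.path(d, "repeat_slopes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## repeat content vs GC across genomes (the panel is small; the method is
## the point, not the n)
ct <- correlate(struct$gc, struct$repeat_content_e6)
message(sprintf("repeat content vs GC: %s r = %.2f (p = %.3f)",
                ct$method, ct$estimate, ct$p_value))
message(sprintf("the dynamic lineage CPx has the highest repeat content: %s",
                struct$genome[which.max(struct$repeat_content_e6)]))
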