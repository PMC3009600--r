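#!/usr/bin/env Rscript
# Build the synthetic study system: a 100 kb "intergenic genome" evolving
# along the five-taxon sensu-stricto-like phylogeny under reverse-
# complement-symmetric, context-dependent substitution rates, plus an
# occupancy track anti-correlated with A+T content, TSS/exon annotations
# and a strain SNP panel. Everything downstream consumes these files.

suppressPackageStartupMessages(library(compevo))

out <- "results/world"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260923L
genome_length <- 100000L

tree <- sensu_stricto_tree()

# context-dependent truth: elevated C->T before G (with its reverse-
# complement twin G->A after C), a CpG-like mutational texture
mk <- function(f, t3) {
  m <- matrix(0.008, 4, 4)
  m[2, 4] <- if (t3 == 3) 0.10 else 0.03
  m[3, 1] <- if (f == 2) 0.10 else 0.03
  diag(m) <- 0
  diag(m) <- 1 - rowSums(m)
  m
}
rates <- rc_average(context_rates_from(tree$lineages, mk))

tss <- sort(sample.int(genome_length, 60))
exons <- data.frame(start = seq(5000, 95000, by = 10000),
                    end = seq(5000, 95000, by = 10000) + 1500)

world <- synthetic_world(genome_length, tree,
                         iid_root_model(c(0.325, 0.175, 0.175, 0.325)),
                         rates,
                         tss_positions = tss, exon_intervals = exons,
                         seed = seed)
sim <- gen_alignment(world)
track <- gen_occupancy_track(sim$sequences$Scer, window = 20, coupling = 1,
                             noise_sd = 0.4, calibrate = TRUE, seed = seed + 1)

panel <- gen_snp_panel(n_strains = 39, n_snps = 26000,
                       class_selection = c(AT_gain = 0, AT_loss = -6,
                                           AT_conserving = 0),
                       seed = seed + 2)

write_fasta_seqs(sim, file.path(out, "node_sequences.fa"))
write_newick(tree, file.path(out, "tree.nwk"))
write_bedgraph(track, file.path(out, "occupancy.bedgraph"))
write_bed(exons, file.path(out, "exons.bed"))
write.table(data.frame(tss = tss), file.path(out, "tss.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(sim$events, file.path(out, "true_events.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write_rates_tsv(rates, file.path(out, "true_rates.tsv"))
write.table(panel, file.path(out, "snp_panel.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("world written to", out, "\n")
cat("  genome:", genome_length, "bp;",
    nrow(sim$events), "realized substitution events across",
    length(tree$lineages), "lineages\n")
cat(sprintf("  extant Scer G+C: %.3f; root G+C: %.3f\n",
            mean(is_gc(sim$sequences$Scer)), mean(is_gc(sim$sequences$root))))
cat(sprintf("  occupancy track: %.1f%% low (< -2.5), %.1f%% high (> 0.4)\n",
            100 * mean(track < -2.5), 100 * mean(track > 0.4)))
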