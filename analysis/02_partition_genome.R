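#!/usr/bin/env Rscript
# Partition the synthetic genome by nucleosome occupancy and TSS proximity
# and compute the composition statistics: window G+C spectra against the
# binomial reference, and trinucleotide frequencies by occupancy class.

suppressPackageStartupMessages(library(compevo))

world_dir <- "results/world"
out <- "results/partition"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seqs <- read_fasta_seqs(file.path(world_dir, "node_sequences.fa"))
scer <- seqs$Scer
L <- length(scer)
track <- read_bedgraph(file.path(world_dir, "occupancy.bedgraph"), L)
tss <- read.table(file.path(world_dir, "tss.tsv"), header = TRUE)$tss
exons_bed <- read.table(file.path(world_dir, "exons.bed"),
                        col.names = c("chrom", "start", "end"))
exons <- data.frame(start = exons_bed$start + 1L, end = exons_bed$end)

occ <- classify_occupancy(track, low_thr = -2.5, high_thr = 0.4)
bins10 <- bin_occupancy(track, 10)
prox <- classify_proximity(L, tss, exons, d = 200)

classes <- data.frame(pos = seq_len(L), occupancy = occ, bin10 = bins10,
                      proximity = prox)
write.table(classes, file.path(out, "position_classes.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

# window G+C spectrum vs the matched binomial reference
win <- gc_windows(scer, w = 20)
p_hat <- mean(win)
ref <- rbinom(50000, 20, p_hat) / 20
lr <- gc_distribution_logratio(win, ref)
write.table(lr, file.path(out, "gc_window_logratio.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

# trinucleotide spectra by occupancy class (intergenic only)
intergenic <- prox != "excluded"
tri <- data.frame(class = character(0), trinuc = character(0),
                  freq = numeric(0))
for (cl in c("low", "high")) {
  mask <- intergenic & occ == cl
  f <- trinuc_freqs(scer, mask)
  tri <- rbind(tri, data.frame(class = cl, trinuc = names(f), freq = f))
}
write.table(tri, file.path(out, "trinuc_freqs.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

gc_by_class <- vapply(c("low", "mid", "high"), function(cl)
  mean(is_gc(scer[occ == cl & intergenic])), numeric(1))
cat("partition written to", out, "\n")
cat(sprintf("  class sizes: low %.1f%%, mid %.1f%%, high %.1f%% of positions\n",
            100 * mean(occ == "low"), 100 * mean(occ == "mid"),
            100 * mean(occ == "high")))
cat(sprintf("  intergenic G+C by occupancy: low %.3f, mid %.3f, high %.3f\n",
            gc_by_class[1], gc_by_class[2], gc_by_class[3]))
cat(sprintf("  TSS-proximal %.1f%%, distal %.1f%%, exonic %.1f%%\n",
            100 * mean(prox == "proximal"), 100 * mean(prox == "distal"),
            100 * mean(prox == "excluded")))
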