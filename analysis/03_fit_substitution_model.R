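#!/usr/bin/env Rscript
# Infer lineage- and context-dependent substitution rates from the leaf
# alignment by loopy-BP EM, compare them to the generating truth, average
# reverse complements, summarize A/T gain and loss rates, and cross-check
# with parsimony. Also compares ancestral vs extant G+C by occupancy bin.

suppressPackageStartupMessages(library(compevo))

world_dir <- "results/world"
out <- "results/rates"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tree <- lineage_tree(ape::read.tree(file.path(world_dir, "tree.nwk")))
seqs <- read_fasta_seqs(file.path(world_dir, "node_sequences.fa"))
leaves <- tree$nodes[tree$is_leaf]
aln <- do.call(rbind, seqs[leaves])
truth <- read_rates_tsv(file.path(world_dir, "true_rates.tsv"))
L <- ncol(aln)
track <- read_bedgraph(file.path(world_dir, "occupancy.bedgraph"), L)

t0 <- Sys.time()
fit <- estimate_rates(aln, tree,
                      em_opts = em_options(min_columns = 200, tol = 5e-4,
                                           max_iter = 8))
fit_rc <- rc_average(fit)
cat(sprintf("EM: %d iterations in %s (%d flagged low-data contexts)\n",
            attr(fit, "n_iter"), format(Sys.time() - t0, digits = 3),
            nrow(attr(fit, "flags"))))
write_rates_tsv(fit_rc, file.path(out, "fitted_rates_rc.tsv"))

# recovery accuracy on well-supported entries of the focal lineage
tr <- truth$Scer; es <- fit_rc$Scer
sel <- tr >= 0.03 & slice.index(tr, 1) != slice.index(tr, 4)
rel <- abs(es[sel] - tr[sel]) / tr[sel]
cat(sprintf("Scer rate recovery (entries >= 0.03): median rel err %.1f%%, max %.1f%%\n",
            100 * median(rel), 100 * max(rel)))

agg <- aggregate_gain_loss(fit_rc)
write.table(agg$overall, file.path(out, "gain_loss_overall.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(agg$per_context, file.path(out, "gain_loss_by_context.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("context-averaged A/T gain vs loss rates per lineage:\n")
print(agg$overall, row.names = FALSE)

# parsimony cross-check (context-independent rates, focal lineage)
ps <- parsimony_substitutions(aln, tree)
pgl <- parsimony_gain_loss(ps)
write.table(pgl, file.path(out, "parsimony_gain_loss.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("parsimony: %d ambiguous columns excluded\n", ps$n_ambiguous))

# ancestral vs extant G+C in 10 occupancy bins (ancestor of Scer/Spar)
post <- infer_posteriors(aln, tree, fit_rc, attr(fit, "root_model"))
abin <- ancestral_gc_by_bin(post, "n1", seqs$Scer, track = track, k = 10)
write.table(abin, file.path(out, "ancestral_gc_by_bin.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("ancestral vs extant G+C by occupancy bin (bin 1 = lowest):\n")
print(abin[, c("bin", "n", "extant_gc", "ancestral_gc")], row.names = FALSE)
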