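# Shared fixture builders: small trees, rate sets and synthetic worlds.

tree3 <- function() lineage_tree("((A,B)u,C)root;")
tree2 <- function() lineage_tree("(A,B)root;")

# reverse-complement symmetric context-dependent rate set with elevated
# C->T before G (and its rc twin G->A after C), for recovery experiments
cpg_like_rates <- function(lineages, base = 0.01, hot = 0.12, warm = 0.04) {
  mk <- function(f, t3) {
    m <- matrix(base, 4, 4)
    m[2, 4] <- ifelse(t3 == 3, hot, warm)   # C->T, elevated before G
    m[3, 1] <- ifelse(f == 2, hot, warm)    # G->A, elevated after C
    diag(m) <- 0
    diag(m) <- 1 - rowSums(m)
    m
  }
  rc_average(context_rates_from(lineages, mk))
}

# context-free rates whose stationary distribution is pi0, scaled to an
# expected substitution probability p_tot away from stationarity
stationary_cf_rates <- function(lineages, pi0 = c(0.3, 0.2, 0.2, 0.3),
                                nu = 0.1) {
  m <- (1 - nu) * diag(4) + nu * matrix(pi0, 4, 4, byrow = TRUE)
  context_rates_from(lineages, m)
}

small_world <- function(L = 5000, seed = 1, p_sub = 0.05, tree = tree3()) {
  synthetic_world(L, tree, iid_root_model(),
                  uniform_context_rates(tree$lineages, p_sub), seed = seed)
}
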