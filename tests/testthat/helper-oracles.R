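# Independent oracles used to validate the implementation. These are kept
# deliberately naive (enumeration / closed forms) and share no code with
# the package internals they check.

# Exact per-site posterior for a context-free model by brute-force
# enumeration over all internal-node labelings. `branch_M` is a named list
# of 4x4 matrices P(child | parent) per lineage; `root_prior` a length-4
# distribution (iid root). Returns per-site marginals for internal nodes
# and per-lineage (parent, child) pair joints.
oracle_posterior_enum <- function(aln, tree, branch_M, root_prior) {
  leaves <- tree$nodes[tree$is_leaf]
  internals <- tree$nodes[!tree$is_leaf]
  n_int <- length(internals)
  int_idx <- setNames(seq_along(internals), internals)
  A <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  colnames(A) <- internals
  L <- ncol(aln)
  node_marg <- lapply(internals, function(nm) matrix(0, L, 4))
  names(node_marg) <- internals
  pair <- lapply(tree$lineages, function(nm) array(0, c(L, 4, 4)))
  names(pair) <- tree$lineages
  root_name <- tree$nodes[tree$root]
  for (j in seq_len(L)) {
    w <- root_prior[A[, int_idx[[root_name]]]]
    for (nm in tree$lineages) {
      v <- match(nm, tree$nodes)
      par_states <- A[, int_idx[[tree$nodes[tree$parent[v]]]]]
      child_states <- if (tree$is_leaf[v]) {
        obs <- aln[nm, j]
        if (is.na(obs)) NULL else rep(obs, nrow(A))
      } else A[, int_idx[[nm]]]
      if (!is.null(child_states)) {
        w <- w * branch_M[[nm]][cbind(par_states, child_states)]
      }
    }
    w <- w / sum(w)
    for (nm in internals) {
      for (x in 1:4) node_marg[[nm]][j, x] <- sum(w[A[, int_idx[[nm]]] == x])
    }
    for (nm in tree$lineages) {
      v <- match(nm, tree$nodes)
      par_states <- A[, int_idx[[tree$nodes[tree$parent[v]]]]]
      if (tree$is_leaf[v]) {
        obs <- aln[nm, j]
        if (!is.na(obs)) {
          for (p in 1:4) pair[[nm]][j, p, obs] <- sum(w[par_states == p])
        }
      } else {
        child_states <- A[, int_idx[[nm]]]
        for (p in 1:4) for (cc in 1:4) {
          pair[[nm]][j, p, cc] <- sum(w[par_states == p & child_states == cc])
        }
      }
    }
  }
  list(node_marginals = node_marg, pair = pair)
}

# Exact p-value of the coupling bootstrap null by convolving the two
# hypergeometric draws.
oracle_coupling_p <- function(cnt) {
  cnt <- lapply(cnt, function(x) as.integer(round(x)))
  G <- cnt$N_gain_in_gainctx + cnt$N_gain_in_lossctx
  Lt <- cnt$N_loss_in_gainctx + cnt$N_loss_in_lossctx
  obs <- cnt$N_gain_in_lossctx + cnt$N_loss_in_gainctx
  px <- dhyper(0:G, cnt$n_CG_in_lossctx, cnt$n_CG_in_gainctx, G)
  py <- dhyper(0:Lt, cnt$n_AT_in_gainctx, cnt$n_AT_in_lossctx, Lt)
  p <- 0
  for (x in 0:G) for (y in 0:Lt) if (x + y >= obs) p <- p + px[x + 1] * py[y + 1]
  p
}

# Classic Fitch bottom-up pass: minimal number of substitutions for one
# column on a rooted tree (state-set recursion, no branch assignment).
oracle_fitch_count <- function(col, tree) {
  sets <- vector("list", length(tree$nodes))
  cost <- integer(length(tree$nodes))
  for (v in rev(tree$order)) {
    if (tree$is_leaf[v]) {
      sets[[v]] <- col[[tree$nodes[v]]]
      cost[v] <- 0L
    } else {
      kids <- which(tree$parent == v)
      s <- sets[[kids[1]]]
      cst <- sum(cost[kids])
      for (k in kids[-1]) {
        inter <- intersect(s, sets[[k]])
        if (length(inter)) s <- inter
        else { s <- union(s, sets[[k]]); cst <- cst + 1L }
      }
      sets[[v]] <- s
      cost[v] <- cst
    }
  }
  cost[tree$root]
}

# Brute-force stationary mean G+C of the full Wright-Fisher chain with
# population-composition states (counts of individuals per G/C-count
# class). Feasible for small N and L.
oracle_wf_mean_gc <- function(N, L, mu_to_AT, mu_to_GC, fit) {
  # per-individual G-count transition under mutation (exact convolution)
  Pmut <- matrix(0, L + 1, L + 1)
  for (n in 0:L) {
    for (down in 0:n) for (up in 0:(L - n)) {
      Pmut[n + 1, n - down + up + 1] <- Pmut[n + 1, n - down + up + 1] +
        dbinom(down, n, mu_to_AT) * dbinom(up, L - n, mu_to_GC)
    }
  }
  # enumerate compositions of N over L+1 classes
  comps <- list()
  rec <- function(prefix, left, slots) {
    if (slots == 1) { comps[[length(comps) + 1]] <<- c(prefix, left); return() }
    for (k in 0:left) rec(c(prefix, k), left - k, slots - 1)
  }
  rec(integer(0), N, L + 1)
  comps <- do.call(rbind, comps)
  ns <- nrow(comps)
  Tm <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    x <- comps[i, ]
    wpar <- x * fit
    q <- as.vector((wpar / sum(wpar)) %*% Pmut)  # offspring class distribution
    for (k in seq_len(ns)) {
      Tm[i, k] <- dmultinom(comps[k, ], prob = q)
    }
  }
  ev <- eigen(t(Tm))
  i1 <- which.min(abs(ev$values - 1))
  pi_s <- Re(ev$vectors[, i1])
  pi_s <- pi_s / sum(pi_s)
  gc_of_state <- comps %*% (0:L) / (N * L)
  sum(pi_s * gc_of_state)
}

# batch-means standard error for an autocorrelated trajectory
batch_se <- function(x, n_batches = 20) {
  n <- length(x)
  bs <- floor(n / n_batches)
  if (bs < 1) return(sd(x) / sqrt(n))
  means <- vapply(seq_len(n_batches), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  sd(means) / sqrt(n_batches)
}
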