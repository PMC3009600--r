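# Ancestral inference and rate estimation for the context-dependent
# substitution model: loopy BP (E step) and generalized EM (M step).

#' Options for the belief-propagation engine
#'
#' @param tol convergence tolerance on the maximum message change.
#' @param max_iter maximum BP iterations per block.
#' @param damping message damping in `[0, 1)`.
#' @param block_size sites per block (blocks overlap by `overlap` sites on
#'   each side to preserve flanking context across block edges).
#' @param overlap block overlap in sites.
#' @param on_nonconvergence "error" (default) or "warn".
#' @return a list of class `bp_options`.
#' @export
bp_options <- function(tol = 1e-6, max_iter = 200, damping = 0.2,
                       block_size = 10000, overlap = 2,
                       on_nonconvergence = c("error", "warn")) {
  structure(list(tol = tol, max_iter = max_iter, damping = damping,
                 block_size = as.integer(block_size),
                 overlap = as.integer(overlap),
                 on_nonconvergence = match.arg(on_nonconvergence)),
            class = "bp_options")
}

#' Options for the generalized EM rate estimator
#'
#' @param min_columns minimum expected informative sites per (lineage,
#'   context); contexts below it keep their initial rates and are flagged.
#' @param tol EM convergence tolerance (maximum absolute change of any
#'   conditional probability between iterations).
#' @param max_iter maximum EM iterations.
#' @return a list of class `em_options`.
#' @export
em_options <- function(min_columns = 200, tol = 1e-3, max_iter = 30) {
  structure(list(min_columns = min_columns, tol = tol,
                 max_iter = as.integer(max_iter)), class = "em_options")
}

# rate array [p, five, three, c] -> flat 256 with layout a + 4p + 16b + 64c
flatten_rate_table <- function(tab) as.vector(aperm(tab, c(2L, 1L, 3L, 4L)))

unflatten_counts <- function(flat) {
  aperm(array(flat, rep(4L, 4L)), c(2L, 1L, 3L, 4L))  # -> [p, a, b, c]
}

# Normalize an alignment argument into an integer matrix (leaves x sites),
# and compute the column mask (any non-ACGT symbol masks the whole column).
prepare_alignment <- function(aln, tree) {
  leaves <- tree$nodes[tree$is_leaf]
  if (inherits(aln, "synthetic_alignment")) aln <- leaf_matrix(aln)
  if (is.list(aln)) aln <- do.call(rbind, aln[leaves])
  if (is.null(rownames(aln))) {
    if (nrow(aln) != length(leaves)) stop("alignment rows do not match leaves")
    rownames(aln) <- leaves
  }
  missing <- setdiff(leaves, rownames(aln))
  if (length(missing)) stop("alignment lacks leaves: ",
                            paste(missing, collapse = ", "))
  m <- aln[leaves, , drop = FALSE]
  storage.mode(m) <- "integer"
  bad <- is.na(m) | m < 1L | m > 4L
  masked_cols <- apply(bad, 2, any)
  m[, masked_cols] <- NA_integer_
  list(mat = m, masked = masked_cols)
}

#' Infer ancestral posteriors by loopy belief propagation
#'
#' Runs sum-product message passing on the factor graph coupling each child
#' site to its parent site and the parent's two flanking sites, with a
#' second-order Markov prior along the root. Columns containing any
#' non-ACGT leaf symbol are masked and carry no likelihood. With
#' context-free rates and an iid root the result coincides with exact
#' per-site (Felsenstein pruning) inference.
#'
#' @param aln alignment: integer matrix (leaves x sites, codes 1..4,
#'   anything else masks its column), named list of leaf sequences, or a
#'   `synthetic_alignment`.
#' @param tree a `lineage_tree`.
#' @param rates a `context_rates` covering every lineage.
#' @param root_model a `root_model`.
#' @param opts a `bp_options`.
#' @return an object of class `ancestral_posterior`: `node_marginals` (per
#'   internal node, sites x 4), `pair_marginals` (per lineage, sites x 16;
#'   column `p + 4*(c-1)` holds P(parent = p, child = c); masked sites are
#'   `NA`), expected context `counts` per lineage (arrays
#'   `[parent, five, three, child]`), `root_counts`, and convergence
#'   diagnostics.
#' @export
infer_posteriors <- function(aln, tree, rates, root_model,
                             opts = bp_options()) {
  stopifnot(inherits(tree, "lineage_tree"), inherits(rates, "context_rates"),
            inherits(root_model, "root_model"))
  missing_lin <- setdiff(tree$lineages, names(rates))
  if (length(missing_lin)) stop("no rates for lineage(s): ",
                                paste(missing_lin, collapse = ", "))
  prep <- prepare_alignment(aln, tree)
  mat <- prep$mat
  L <- ncol(mat)
  if (L < 3) stop("alignment must have at least 3 columns")

  leaves <- tree$nodes[tree$is_leaf]
  internals <- tree$nodes[!tree$is_leaf]
  int_idx <- setNames(seq_along(internals), internals)
  int_parent <- vapply(internals, function(nm) {
    p <- tree$parent[node_index(tree, nm)]
    if (is.na(p)) -1L else int_idx[[tree$nodes[p]]] - 1L
  }, integer(1))
  leaf_parent <- vapply(leaves, function(nm) {
    int_idx[[tree$nodes[tree$parent[node_index(tree, nm)]]]] - 1L
  }, integer(1))

  rate_leaf <- vapply(leaves, function(nm) flatten_rate_table(rates[[nm]]),
                      numeric(256))
  rate_int <- vapply(internals, function(nm) {
    if (nm %in% names(rates)) flatten_rate_table(rates[[nm]])
    else numeric(256)  # root column, unused
  }, numeric(256))
  rt <- as.vector(root_model$trans)
  ri <- as.vector(root_model$init2)

  obs0 <- mat
  obs0[is.na(obs0)] <- 0L
  obs0 <- obs0 - 1L   # C++ codes 0..3, masked -> -1

  node_marg <- lapply(internals, function(nm) matrix(NA_real_, L, 4))
  names(node_marg) <- internals
  pair_marg <- lapply(tree$lineages, function(nm) matrix(NA_real_, L, 16))
  names(pair_marg) <- tree$lineages
  counts <- lapply(tree$lineages, function(nm) array(0, rep(4L, 4L)))
  names(counts) <- tree$lineages
  root_tr_counts <- array(0, rep(4L, 3L))
  root_init_counts <- matrix(0, 4, 4)
  n_iter <- 0L
  traces <- list()

  starts <- seq.int(1L, L, by = opts$block_size)
  for (s in starts) {
    e <- min(L, s + opts$block_size - 1L)
    bs <- max(1L, s - opts$overlap)
    be <- min(L, e + opts$overlap)
    if (be - bs + 1L < 3L) { bs <- max(1L, be - 2L) }
    res <- bp_block(obs0[, bs:be, drop = FALSE], leaf_parent, int_parent,
                    rate_leaf, rate_int, rt, ri,
                    as.integer(prep$masked[bs:be]),
                    s - bs, e - bs, opts$tol, opts$max_iter, opts$damping,
                    TRUE)
    if (!res$converged) {
      msg <- sprintf(
        "BP did not converge in block [%d, %d]: %d iterations, last delta %.3g",
        s, e, res$iters, tail(res$trace, 1))
      if (opts$on_nonconvergence == "error") {
        cond <- simpleError(msg)
        cond$trace <- res$trace
        stop(cond)
      } else warning(msg)
    }
    n_iter <- max(n_iter, res$iters)
    traces[[length(traces) + 1L]] <- res$trace
    core <- (s - bs + 1L):(e - bs + 1L)
    nb <- be - bs + 1L
    for (vi in seq_along(internals)) {
      rows <- (vi - 1L) * nb + core
      node_marg[[internals[vi]]][s:e, ] <- res$node_marg[rows, , drop = FALSE]
    }
    for (vi in seq_along(internals)) {
      nm <- internals[vi]
      if (nm %in% tree$lineages) {
        pair_marg[[nm]][s:e, ] <- res$pair_int[[vi]][core, , drop = FALSE]
        counts[[nm]] <- counts[[nm]] + unflatten_counts(res$counts_int[, vi])
      }
    }
    for (wi in seq_along(leaves)) {
      nm <- leaves[wi]
      pair_marg[[nm]][s:e, ] <- res$pair_leaf[[wi]][core, , drop = FALSE]
      counts[[nm]] <- counts[[nm]] + unflatten_counts(res$counts_leaf[, wi])
    }
    root_tr_counts <- root_tr_counts + array(res$counts_root, rep(4L, 3L))
    root_init_counts <- root_init_counts + matrix(res$counts_root_init, 4, 4)
  }

  structure(list(node_marginals = node_marg, pair_marginals = pair_marg,
                 counts = counts, root_trans_counts = root_tr_counts,
                 root_init_counts = root_init_counts,
                 masked = prep$masked, tree = tree,
                 converged = TRUE, iters = n_iter, traces = traces),
            class = "ancestral_posterior")
}

#' Pair marginal as a 4x4 (parent x child) matrix at one position
#' @param posterior an `ancestral_posterior`.
#' @param lineage lineage name.
#' @param pos position.
#' @return 4x4 matrix P(parent, child) with A,C,G,T names.
#' @export
pair_matrix <- function(posterior, lineage, pos) {
  m <- matrix(posterior$pair_marginals[[lineage]][pos, ], 4, 4,
              dimnames = list(parent = NUC, child = NUC))
  m
}

#' Estimate context-dependent substitution rates by generalized EM
#'
#' Alternates ancestral inference (E step, loopy BP) with row-normalized
#' expected-count updates of every lineage's 16 context tables and the root
#' model (M step). Contexts whose expected informative-site count stays
#' below `min_columns` keep their initial rates and are flagged.
#'
#' @param aln alignment (see [infer_posteriors()]).
#' @param tree a `lineage_tree`.
#' @param init initial `context_rates` (default: context-free 5%
#'   divergence on every lineage).
#' @param root_init initial `root_model` (default: estimated from the leaf
#'   sequences).
#' @param em_opts an `em_options`.
#' @param bp_opts a `bp_options`.
#' @param verbose print per-iteration progress.
#' @return a `context_rates` with attributes `flags` (data frame of
#'   insufficient-data contexts), `n_iter`, `root_model`, `q_trace`
#'   (expected complete-data log-likelihood per iteration) and `converged`.
#' @export
estimate_rates <- function(aln, tree, init = NULL, root_init = NULL,
                           em_opts = em_options(), bp_opts = bp_options(),
                           verbose = FALSE) {
  stopifnot(inherits(tree, "lineage_tree"))
  prep <- prepare_alignment(aln, tree)
  if (is.null(init)) init <- uniform_context_rates(tree$lineages, 0.05)
  if (is.null(root_init)) {
    leaf_seqs <- lapply(seq_len(nrow(prep$mat)), function(i) prep$mat[i, ])
    root_init <- root_model_from_seqs(leaf_seqs)
  }
  all_flagged <- function() {
    do.call(rbind, lapply(tree$lineages, function(nm)
      data.frame(lineage = nm,
                 five = rep(NUC, each = 4), three = rep(NUC, 4),
                 stringsAsFactors = FALSE)))
  }
  if (ncol(prep$mat) < 3 || all(prep$masked)) {
    out <- init
    attr(out, "flags") <- all_flagged()
    attr(out, "n_iter") <- 0L
    attr(out, "root_model") <- root_init
    attr(out, "converged") <- FALSE
    return(out)
  }

  rates <- init
  rootm <- root_init
  q_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    post <- infer_posteriors(prep$mat, tree, rates, rootm, bp_opts)
    new_tabs <- list()
    flags <- list()
    q <- 0
    for (nm in tree$lineages) {
      cnt <- post$counts[[nm]]     # [p, a, b, c]
      tab <- rates[[nm]]
      for (a in 1:4) for (b in 1:4) {
        ctx_n <- sum(cnt[, a, b, ])
        if (ctx_n < em_opts$min_columns) {
          flags[[length(flags) + 1L]] <- data.frame(
            lineage = nm, five = NUC[a], three = NUC[b],
            stringsAsFactors = FALSE)
          next   # hold at current (initial) value
        }
        for (p in 1:4) {
          rs <- sum(cnt[p, a, b, ])
          if (rs > 0) tab[p, a, b, ] <- cnt[p, a, b, ] / rs
        }
      }
      ok <- cnt > 0 & tab > 0
      q <- q + sum(cnt[ok] * log(tab[ok]))
      new_tabs[[nm]] <- tab
    }
    new_rates <- context_rates(new_tabs)
    # root model M step (light smoothing keeps transitions proper)
    tr_cnt <- post$root_trans_counts + 1e-6
    new_trans <- tr_cnt / array(rep(apply(tr_cnt, c(1, 2), sum), 4), rep(4L, 3L))
    ini_cnt <- post$root_init_counts + 1e-6
    new_rootm <- root_model(ini_cnt / sum(ini_cnt), new_trans)
    q <- q + sum(post$root_trans_counts * log(new_trans))
    q_trace <- c(q_trace, q)

    delta <- max(vapply(tree$lineages, function(nm)
      max(abs(new_rates[[nm]] - rates[[nm]])), numeric(1)))
    if (verbose) {
      message(sprintf("EM iter %d: Q = %.2f, max rate change = %.2e",
                      it, q, delta))
    }
    rates <- new_rates
    rootm <- new_rootm
    if (delta < em_opts$tol) { converged <- TRUE; break }
    if (it >= em_opts$max_iter) break
  }
  flags_df <- if (length(flags)) do.call(rbind, flags) else
    data.frame(lineage = character(0), five = character(0),
               three = character(0))
  attr(rates, "flags") <- flags_df
  attr(rates, "n_iter") <- it
  attr(rates, "root_model") <- rootm
  attr(rates, "q_trace") <- q_trace
  attr(rates, "converged") <- converged
  rates
}
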