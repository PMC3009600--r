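# Synthetic-data generator: every input the analysis consumes, with the
# statistical structure the downstream stages assume, plus planted ground
# truth for recovery tests.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specify a synthetic evolutionary world
#'
#' Bundles everything needed to simulate a genome, its evolution along a
#' fixed phylogeny, an occupancy track anti-correlated with A+T content, and
#' annotations. Positions are 1-based; intervals are closed `[start, end]`.
#'
#' @param genome_length genome length in bp (>= 3).
#' @param tree a `lineage_tree`.
#' @param root_model a `root_model` (second-order Markov over the root).
#' @param rates a `context_rates` with a table for every lineage.
#' @param occupancy_coupling strength of the (positive) coupling between
#'   windowed G+C and occupancy score; 0 decouples them.
#' @param noise_sd standard deviation of Gaussian noise added to the track.
#' @param occupancy_window window (bp) for the G+C average behind the track.
#' @param tss_positions integer positions of annotated TSSs.
#' @param exon_intervals data frame with `start`, `end` (1-based closed) or
#'   NULL.
#' @param seed integer seed driving all randomness derived from this world.
#' @return an object of class `synthetic_world`.
#' @export
synthetic_world <- function(genome_length, tree, root_model, rates,
                            occupancy_coupling = 1, noise_sd = 0.3,
                            occupancy_window = 20,
                            tss_positions = integer(0),
                            exon_intervals = NULL, seed = 1L) {
  stopifnot(inherits(tree, "lineage_tree"), inherits(root_model, "root_model"),
            inherits(rates, "context_rates"))
  if (genome_length < 3) stop("genome_length must be >= 3")
  missing_lin <- setdiff(tree$lineages, names(rates))
  if (length(missing_lin)) {
    stop("no rate table for lineage(s): ", paste(missing_lin, collapse = ", "))
  }
  if (length(tss_positions) &&
      (min(tss_positions) < 1 || max(tss_positions) > genome_length)) {
    stop("tss_positions outside [1, genome_length]")
  }
  if (!is.null(exon_intervals)) {
    stopifnot(all(c("start", "end") %in% names(exon_intervals)))
    if (any(exon_intervals$start < 1) || any(exon_intervals$end > genome_length) ||
        any(exon_intervals$start > exon_intervals$end)) {
      stop("exon intervals must be non-empty and lie within [1, genome_length]")
    }
  }
  structure(list(genome_length = as.integer(genome_length), tree = tree,
                 root_model = root_model, rates = rates,
                 occupancy_coupling = occupancy_coupling, noise_sd = noise_sd,
                 occupancy_window = occupancy_window,
                 tss_positions = as.integer(tss_positions),
                 exon_intervals = exon_intervals, seed = as.integer(seed)),
            class = "synthetic_world")
}

# Real K-th root of a row-stochastic matrix via eigendecomposition, clipped
# and renormalized. Valid for the diagonally dominant tables used here.
stochastic_kth_root <- function(M, K) {
  if (K == 1L) return(M)
  e <- eigen(M)
  lam <- as.complex(e$values)^(1 / K)
  R <- Re(e$vectors %*% diag(lam, nrow = 4) %*% solve(e$vectors))
  R[R < 0] <- 0
  R / rowSums(R)
}

# Per-branch sub-step transition lookup. Returns list(tab = 64 x 4 matrix
# indexed by five + 4*(parent-1) + 16*(three-1), K = number of sub-steps).
branch_step_tables <- function(tab, step_max = 0.01) {
  qmax <- 0
  for (f in 1:4) for (t3 in 1:4) {
    M <- tab[, f, t3, ]
    qmax <- max(qmax, max(1 - diag(M)))
  }
  K <- max(1L, as.integer(ceiling(qmax / step_max)))
  step <- matrix(0, 64, 4)
  for (f in 1:4) for (t3 in 1:4) {
    Ms <- stochastic_kth_root(tab[, f, t3, ], K)
    for (p in 1:4) step[f + 4L * (p - 1L) + 16L * (t3 - 1L), ] <- Ms[p, ]
  }
  list(tab = step, K = K)
}

# Evolve one branch: K sub-steps; within a sub-step every site draws its
# child state from the sub-step table conditioned on its current flanks.
evolve_branch <- function(parent_seq, tab, step_max = 0.01) {
  L <- length(parent_seq)
  st <- branch_step_tables(tab, step_max)
  s <- parent_seq
  inner <- 2:(L - 1L)
  for (k in seq_len(st$K)) {
    a <- s[inner - 1L]
    p <- s[inner]
    b <- s[inner + 1L]
    pr <- st$tab[a + 4L * (p - 1L) + 16L * (b - 1L), , drop = FALSE]
    u <- runif(L - 2L)
    c1 <- pr[, 1L]; c2 <- c1 + pr[, 2L]; c3 <- c2 + pr[, 3L]
    snew <- 1L + (u > c1) + (u > c2) + (u > c3)
    # boundary sites: flank-averaged tables
    s1 <- boundary_draw(st$tab, p = s[1L], b = s[2L], side = "left")
    sL <- boundary_draw(st$tab, p = s[L], a = s[L - 1L], side = "right")
    s <- c(s1, snew, sL)
  }
  s
}

boundary_draw <- function(step_tab, p, a = NULL, b = NULL, side) {
  if (side == "left") {
    rows <- (1:4) + 4L * (p - 1L) + 16L * (b - 1L)   # average over 5' flank
  } else {
    rows <- a + 4L * (p - 1L) + 16L * (0:3)          # average over 3' flank
  }
  pr <- colMeans(step_tab[rows, , drop = FALSE])
  u <- runif(1L)
  cp <- cumsum(pr)
  1L + sum(u > cp[1:3])
}

#' Simulate aligned sequences for all nodes of the phylogeny
#'
#' The root is drawn from the world's second-order Markov model; each
#' descendant is then simulated from its parent with the lineage's
#' context-dependent substitution table, using many small sub-steps so that
#' per-step substitution probabilities stay below `step_max` while flanking
#' contexts are allowed to drift. Sub-step tables are exact matrix K-th
#' roots, so under context-free rates the realized one-branch transition
#' probabilities equal the specified tables.
#'
#' @param spec a `synthetic_world`.
#' @param step_max maximum per-sub-step substitution probability.
#' @return an object of class `synthetic_alignment`: list with `sequences`
#'   (named list of integer-coded sequences, one per tree node), `events`
#'   (data frame branch/pos/from/to of realized end-of-branch differences),
#'   `tree`, and `spec`. Gapless by construction: leaf rows form the
#'   alignment.
#' @export
gen_alignment <- function(spec, step_max = 0.01) {
  stopifnot(inherits(spec, "synthetic_world"))
  with_seed(spec$seed, {
    tree <- spec$tree
    seqs <- vector("list", length(tree$nodes))
    names(seqs) <- tree$nodes
    seqs[[tree$root]] <- sample_root(spec$root_model, spec$genome_length)
    events <- list()
    for (v in tree$order) {
      if (v == tree$root) next
      nm <- tree$nodes[v]
      par <- seqs[[tree$parent[v]]]
      child <- evolve_branch(par, spec$rates[[nm]], step_max)
      seqs[[nm]] <- child
      d <- which(child != par)
      if (length(d)) {
        events[[nm]] <- data.frame(branch = nm, pos = d, from = par[d],
                                   to = child[d], stringsAsFactors = FALSE)
      }
    }
    events <- if (length(events)) do.call(rbind, c(events, make.row.names = FALSE))
              else data.frame(branch = character(0), pos = integer(0),
                              from = integer(0), to = integer(0))
    structure(list(sequences = seqs, events = events, tree = tree, spec = spec),
              class = "synthetic_alignment")
  })
}

#' Leaf alignment as an integer matrix
#' @param sim a `synthetic_alignment`.
#' @return integer matrix (leaves x positions), rownames = leaf names.
#' @export
leaf_matrix <- function(sim) {
  stopifnot(inherits(sim, "synthetic_alignment"))
  leaves <- sim$tree$nodes[sim$tree$is_leaf]
  do.call(rbind, setNames(sim$sequences[leaves], leaves))
}

#' Generate a nucleosome-occupancy-like track from a sequence
#'
#' The score is an affine, strictly increasing function of windowed G+C
#' content plus optional Gaussian noise, emulating the anti-correlation of
#' occupancy with A+T content. With `calibrate = TRUE` the track is passed
#' through a monotone affine map fixing its 14% and 79% quantiles at the
#' classification thresholds -2.5 and 0.4, so that the "low"/"high" classes
#' occupy the bottom 14% / top 21% of positions.
#'
#' @param sequence integer-coded sequence (1..4).
#' @param window centered window (bp) for the G+C average; must not exceed
#'   the sequence length.
#' @param coupling coupling strength (slope scale); > 0 means occupancy
#'   increases with G+C.
#' @param noise_sd Gaussian noise standard deviation (0 = deterministic).
#' @param calibrate logical; apply the two-quantile affine calibration.
#' @param seed optional integer seed.
#' @return numeric vector of per-position scores.
#' @export
gen_occupancy_track <- function(sequence, window = 20, coupling = 1,
                                noise_sd = 0.3, calibrate = FALSE,
                                seed = NULL) {
  L <- length(sequence)
  if (window < 1) stop("window must be >= 1")
  if (window > L) stop("window exceeds sequence length")
  with_seed(seed, {
    gc <- as.numeric(is_gc(sequence))
    h1 <- floor((window - 1) / 2)
    h2 <- ceiling((window - 1) / 2)
    cs <- c(0, cumsum(gc))
    lo <- pmax(seq_len(L) - h1, 1L)
    hi <- pmin(seq_len(L) + h2, L)
    gcw <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    score <- coupling * 6 * (gcw - 0.5)
    if (noise_sd > 0) score <- score + rnorm(L, 0, noise_sd)
    if (calibrate) {
      q <- quantile(score, c(0.14, 0.79), names = FALSE, type = 7)
      if (q[2] - q[1] < 1e-12) {
        stop("degenerate score distribution: cannot calibrate quantiles")
      }
      score <- -2.5 + (0.4 - (-2.5)) * (score - q[1]) / (q[2] - q[1])
    }
    score
  })
}

#' Plant compensatory (A/T-loss, A/T-gain) substitution pairs
#'
#' Positive control for the spatial coupling test: inserts extra pairs of an
#' A/T-losing and an A/T-gaining substitution on the same terminal branch
#' within `horizon` bp of each other, at a number proportional to `excess`
#' (rounded `excess` pairs per kb). Pair members are previously conserved
#' sites; each planted pair is recorded.
#'
#' @param sim a `synthetic_alignment`.
#' @param branch name of a terminal branch (leaf) to modify.
#' @param horizon maximum distance (bp, >= 1) between the pair members.
#' @param excess planted pairs per kb (>= 0; 0 leaves the alignment
#'   unchanged).
#' @param seed integer seed.
#' @return the modified `synthetic_alignment`, with a `planted_pairs` data
#'   frame (`position_loss`, `position_gain`, `branch`) attached.
#' @export
plant_compensatory_events <- function(sim, branch, horizon = 5, excess,
                                      seed = 1L) {
  stopifnot(inherits(sim, "synthetic_alignment"))
  if (excess < 0) stop("excess must be >= 0")
  if (horizon < 1) stop("horizon must be >= 1")
  tree <- sim$tree
  v <- node_index(tree, branch)
  if (!tree$is_leaf[v]) stop("planting is supported on terminal branches only")
  pp0 <- data.frame(position_loss = integer(0), position_gain = integer(0),
                    branch = character(0))
  if (excess == 0) {
    sim$planted_pairs <- pp0
    return(sim)
  }
  par <- sim$sequences[[tree$parent[v]]]
  child <- sim$sequences[[branch]]
  L <- length(child)
  n_pairs <- max(0L, round(excess * L / 1000))
  with_seed(seed, {
    conserved <- child == par
    elig_loss <- which(conserved & par %in% AT_CODES)
    elig_gain <- which(conserved & par %in% GC_CODES)
    if (!length(elig_loss) || !length(elig_gain)) {
      stop("no eligible sites for planting compensatory pairs")
    }
    used <- logical(L)
    out <- vector("list", n_pairs)
    made <- 0L
    tries <- 0L
    while (made < n_pairs && tries < 50L * n_pairs) {
      tries <- tries + 1L
      jl <- elig_loss[sample.int(length(elig_loss), 1L)]
      if (used[jl]) next
      cand <- elig_gain[abs(elig_gain - jl) <= horizon & elig_gain != jl]
      cand <- cand[!used[cand]]
      if (!length(cand)) next
      jg <- cand[sample.int(length(cand), 1L)]
      used[c(jl, jg)] <- TRUE
      child[jl] <- sample(GC_CODES, 1L)
      child[jg] <- sample(AT_CODES, 1L)
      made <- made + 1L
      out[[made]] <- data.frame(position_loss = jl, position_gain = jg,
                                branch = branch, stringsAsFactors = FALSE)
    }
    if (made < n_pairs) {
      stop("could not place ", n_pairs, " pairs (placed ", made, ")")
    }
    sim$sequences[[branch]] <- child
    d <- which(child != par)
    sim$events <- rbind(
      sim$events[sim$events$branch != branch, , drop = FALSE],
      data.frame(branch = branch, pos = d, from = par[d], to = child[d],
                 stringsAsFactors = FALSE))
    sim$planted_pairs <- if (made) do.call(rbind, out[seq_len(made)]) else pp0
    sim
  })
}

# Folded, selection-tilted site-frequency-spectrum weight at derived
# frequency x with scaled selection coefficient S = 2Ns (diffusion form;
# S -> 0 gives the neutral 1/x spectrum).
sfs_weight <- function(x, S) {
  if (abs(S) < 1e-8) return(1 / x)
  (-expm1(-S * (1 - x))) / ((-expm1(-S)) * x * (1 - x))
}

#' Generate a biallelic SNP panel with class-specific selection
#'
#' Minor-allele counts are drawn from a folded frequency spectrum tilted by
#' each class's scaled selection coefficient (neutral: folded 1/x; selected:
#' the standard diffusion form, negative coefficients shifting mass toward
#' rare alleles). Alleles, flanking context and occupancy class are assigned
#' consistently with the intended classification.
#'
#' @param n_strains number of strains in the panel (>= 2).
#' @param n_snps number of SNPs to generate.
#' @param class_selection named numeric vector of scaled selection
#'   coefficients (2Ns), keyed by direction class, e.g.
#'   `c(AT_gain = 0, AT_loss = -4, AT_conserving = 0)`. Must be non-empty
#'   and finite.
#' @param min_called,max_called range of per-site called-strain counts
#'   (uniform); defaults keep every site past the >20-strains filter.
#' @param seed integer seed.
#' @return data frame with columns pos, a1, a2, count1, count2, n_called,
#'   flank5, flank3, occupancy, intergenic, class_true.
#' @export
gen_snp_panel <- function(n_strains = 39, n_snps = 1000, class_selection,
                          min_called = NULL, max_called = NULL, seed = 1L) {
  if (n_strains < 2) stop("n_strains must be >= 2")
  if (length(class_selection) == 0) stop("class_selection must be non-empty")
  if (is.null(names(class_selection)) || any(!nzchar(names(class_selection)))) {
    stop("class_selection must be named by direction class")
  }
  if (any(!is.finite(class_selection))) {
    stop("selection coefficients must be finite")
  }
  if (is.null(min_called)) min_called <- min(n_strains, 21L)
  if (is.null(max_called)) max_called <- n_strains
  stopifnot(min_called >= 2, max_called <= n_strains, min_called <= max_called)
  with_seed(seed, {
    cls <- sample(names(class_selection), n_snps, replace = TRUE)
    n_called <- if (min_called == max_called) rep(min_called, n_snps)
                else sample(seq.int(min_called, max_called), n_snps, TRUE)
    minor <- integer(n_snps)
    for (i in seq_len(n_snps)) {
      n <- n_called[i]
      x <- seq_len(n - 1L) / n
      w <- vapply(x, sfs_weight, numeric(1), S = class_selection[[cls[i]]])
      k <- sample.int(n - 1L, 1L, prob = w)
      minor[i] <- min(k, n - k)
    }
    pick <- function(codes) codes[sample.int(length(codes), n_snps, TRUE)]
    a_major <- integer(n_snps); a_minor <- integer(n_snps)
    gain <- cls == "AT_gain"; loss <- cls == "AT_loss"
    other <- !(gain | loss)
    a_major[gain] <- sample(GC_CODES, sum(gain), TRUE)
    a_minor[gain] <- sample(AT_CODES, sum(gain), TRUE)
    a_major[loss] <- sample(AT_CODES, sum(loss), TRUE)
    a_minor[loss] <- sample(GC_CODES, sum(loss), TRUE)
    if (any(other)) {
      # conserving: both alleles in the same composition class
      at_side <- runif(sum(other)) < 0.5
      maj <- ifelse(at_side, sample(AT_CODES, sum(other), TRUE),
                    sample(GC_CODES, sum(other), TRUE))
      mnr <- ifelse(maj %in% AT_CODES,
                    AT_CODES[1] + AT_CODES[2] - maj,   # the other A/T base
                    GC_CODES[1] + GC_CODES[2] - maj)   # the other C/G base
      a_major[other] <- maj
      a_minor[other] <- mnr
    }
    data.frame(
      pos = seq_len(n_snps),
      a1 = NUC[a_major], a2 = NUC[a_minor],
      count1 = n_called - minor, count2 = minor,
      n_called = n_called,
      flank5 = NUC[sample.int(4L, n_snps, TRUE)],
      flank3 = NUC[sample.int(4L, n_snps, TRUE)],
      occupancy = sample(c("low", "high"), n_snps, TRUE),
      intergenic = TRUE,
      class_true = cls,
      stringsAsFactors = FALSE
    )
  })
}
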