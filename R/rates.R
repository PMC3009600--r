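# Per-lineage, flanking-context-dependent substitution probabilities.
#
# A context_rates object is a named list (one element per lineage). Each
# element is a 4x4x4x4 array indexed [parent, five, three, child]:
# P(child | parent, 5' flank, 3' flank), rows over `child` summing to 1.
# Flanking context is read from the parent (ancestral) sequence.

CONTEXT_DIMNAMES <- list(parent = NUC, five = NUC, three = NUC, child = NUC)

#' Construct a context-dependent substitution rate set
#'
#' @param tables named list, one 4x4x4x4 array per lineage, indexed
#'   `[parent, five, three, child]` with `P(child | parent, five, three)`.
#' @return an object of class `context_rates`.
#' @export
context_rates <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  for (nm in names(tables)) {
    a <- tables[[nm]]
    if (!is.array(a) || !identical(dim(a), rep(4L, 4L))) {
      stop("rate table for lineage ", nm, " must be a 4x4x4x4 array")
    }
    dimnames(tables[[nm]]) <- CONTEXT_DIMNAMES
    rs <- apply(a, c(1, 2, 3), sum)
    if (any(abs(rs - 1) > 1e-10)) {
      stop("rate rows for lineage ", nm, " must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
    }
    if (any(a < -1e-12 | a > 1 + 1e-12)) {
      stop("rate entries for lineage ", nm, " must lie in [0, 1]")
    }
  }
  structure(tables, class = "context_rates")
}

#' Context-free rate set with a common substitution probability
#'
#' All 16 flanking contexts share the same conditional table, with
#' off-diagonal probability `p_sub / 3` per target nucleotide.
#'
#' @param lineages character vector of lineage names.
#' @param p_sub total per-site substitution probability (split evenly over
#'   the three alternative nucleotides). May be a named vector per lineage.
#' @return a `context_rates` object.
#' @export
uniform_context_rates <- function(lineages, p_sub = 0.05) {
  p <- if (length(p_sub) == 1L) setNames(rep(p_sub, length(lineages)), lineages)
       else p_sub[lineages]
  tabs <- lapply(lineages, function(nm) {
    m <- matrix(p[[nm]] / 3, 4, 4)
    diag(m) <- 1 - p[[nm]]
    a <- array(0, rep(4L, 4L))
    for (f in 1:4) for (t3 in 1:4) a[, f, t3, ] <- m
    a
  })
  context_rates(setNames(tabs, lineages))
}

#' Rate set from per-context 4x4 matrices
#'
#' @param lineages character vector of lineage names.
#' @param fun function `(five, three)` -> 4x4 row-stochastic matrix, or a
#'   single 4x4 matrix used for every context.
#' @return a `context_rates` object.
#' @export
context_rates_from <- function(lineages, fun) {
  tabs <- lapply(lineages, function(nm) {
    a <- array(0, rep(4L, 4L))
    for (f in 1:4) for (t3 in 1:4) {
      m <- if (is.function(fun)) fun(f, t3) else fun
      a[, f, t3, ] <- m
    }
    a
  })
  context_rates(setNames(tabs, lineages))
}

#' Average each rate with its reverse complement
#'
#' Each conditional probability P(child | parent, five, three) is replaced
#' by the arithmetic mean of itself and its reverse-complement counterpart
#' P(rc(child) | rc(parent), rc(three), rc(five)): e.g. the CAT->CCT rate is
#' averaged with the ATG->AGG rate. The operation is idempotent and the
#' result satisfies r(x->y | a,b) = r(rc(x)->rc(y) | rc(b),rc(a)) exactly.
#'
#' @param rates a `context_rates` object.
#' @return a `context_rates` object with reverse-complement-symmetric rates.
#' @export
rc_average <- function(rates) {
  stopifnot(inherits(rates, "context_rates"))
  out <- lapply(unclass(rates), function(a) {
    b <- a
    for (p in 1:4) for (f in 1:4) for (t3 in 1:4) for (ch in 1:4) {
      b[p, f, t3, ch] <-
        (a[p, f, t3, ch] + a[RC[p], RC[t3], RC[f], RC[ch]]) / 2
    }
    b
  })
  context_rates(out)
}

#' Aggregate rates into A/T-gaining and A/T-losing summaries
#'
#' A/T-gaining substitutions are C->A, C->T, G->A, G->T; A/T-losing
#' substitutions are A->C, A->G, T->C, T->G (any flanking context). The
#' per-context summary averages the four substitution types of each class;
#' the overall summary additionally averages over the 16 contexts.
#'
#' @param rates a `context_rates` object (conventionally reverse-complement
#'   averaged first).
#' @return a list with `per_context` (data frame: lineage, five, three,
#'   gain_rate, loss_rate) and `overall` (data frame: lineage, gain_rate,
#'   loss_rate).
#' @export
aggregate_gain_loss <- function(rates) {
  stopifnot(inherits(rates, "context_rates"))
  gain_pairs <- rbind(c(2, 1), c(2, 4), c(3, 1), c(3, 4))  # C->A C->T G->A G->T
  loss_pairs <- rbind(c(1, 2), c(1, 3), c(4, 2), c(4, 3))  # A->C A->G T->C T->G
  rows <- list()
  for (nm in names(rates)) {
    a <- rates[[nm]]
    for (f in 1:4) for (t3 in 1:4) {
      g <- mean(a[cbind(gain_pairs[, 1], f, t3, gain_pairs[, 2])])
      l <- mean(a[cbind(loss_pairs[, 1], f, t3, loss_pairs[, 2])])
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = nm, five = NUC[f], three = NUC[t3],
        gain_rate = g, loss_rate = l, stringsAsFactors = FALSE)
    }
  }
  per_context <- do.call(rbind, rows)
  overall <- do.call(rbind, lapply(split(per_context, per_context$lineage),
    function(d) data.frame(lineage = d$lineage[1],
                           gain_rate = mean(d$gain_rate),
                           loss_rate = mean(d$loss_rate))))
  rownames(overall) <- NULL
  list(per_context = per_context, overall = overall)
}

# ---------------------------------------------------------------------------
# Second-order Markov root model: joint distribution of the first two root
# nucleotides plus P(x_j | x_{j-2}, x_{j-1}) for j >= 3.

#' Construct a second-order Markov root sequence model
#'
#' @param init2 4x4 matrix, joint distribution of the first two nucleotides
#'   (rows = first, columns = second); must sum to 1.
#' @param trans 4x4x4 array, `trans[a, b, c] = P(x_j = c | x_{j-2} = a,
#'   x_{j-1} = b)`; slices over `c` must sum to 1.
#' @return an object of class `root_model`.
#' @export
root_model <- function(init2, trans) {
  stopifnot(identical(dim(init2), c(4L, 4L)), identical(dim(trans), rep(4L, 3L)))
  if (abs(sum(init2) - 1) > 1e-12) stop("init2 must sum to 1")
  rs <- apply(trans, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-12)) stop("trans rows must sum to 1 +/- 1e-12")
  structure(list(init2 = init2, trans = trans), class = "root_model")
}

#' Memoryless (iid) root model with given base composition
#'
#' @param p numeric length-4 base distribution over A, C, G, T.
#' @return a `root_model` whose second-order transitions ignore the history.
#' @export
iid_root_model <- function(p = c(0.3, 0.2, 0.2, 0.3)) {
  stopifnot(length(p) == 4, abs(sum(p) - 1) < 1e-12, all(p >= 0))
  trans <- array(rep(p, each = 16), dim = rep(4L, 3L))
  root_model(init2 = outer(p, p), trans = trans)
}

#' Estimate a second-order Markov root model from sequences
#'
#' Counts overlapping nucleotide triples (with add-one smoothing) across the
#' supplied encoded sequences.
#'
#' @param seqs list of integer-coded sequences (codes 1..4; others skipped).
#' @param pseudo pseudocount added to every triple.
#' @return a `root_model`.
#' @export
root_model_from_seqs <- function(seqs, pseudo = 1) {
  if (!is.list(seqs)) seqs <- list(seqs)
  tri <- array(pseudo, rep(4L, 3L))
  pair <- matrix(pseudo, 4, 4)
  for (s in seqs) {
    n <- length(s)
    ok <- !is.na(s) & s >= 1 & s <= 4
    if (n >= 3) {
      i <- seq_len(n - 2L)
      keep <- ok[i] & ok[i + 1L] & ok[i + 2L]
      # column-major array layout: first index (the 5'-most base) fastest
      flat <- s[i][keep] + (s[i + 1L][keep] - 1L) * 4L +
        (s[i + 2L][keep] - 1L) * 16L
      tri <- tri + array(tabulate(flat, 64L), rep(4L, 3L))
    }
    if (n >= 2) {
      i <- seq_len(n - 1L)
      keep2 <- ok[i] & ok[i + 1L]
      flat2 <- (s[i][keep2] - 1L) * 4L + s[i + 1L][keep2]
      pair <- pair + matrix(tabulate(flat2, 16L), 4, 4, byrow = TRUE)
    }
  }
  trans <- tri / array(rep(apply(tri, c(1, 2), sum), 4), rep(4L, 3L))
  root_model(init2 = pair / sum(pair), trans = trans)
}

#' Sample a root sequence from a second-order Markov model
#'
#' @param model a `root_model`.
#' @param L sequence length (>= 2).
#' @return integer-coded sequence of length `L`.
#' @export
sample_root <- function(model, L) {
  stopifnot(inherits(model, "root_model"), L >= 2)
  s <- integer(L)
  first2 <- sample.int(16L, 1L, prob = as.vector(model$init2))
  s[1L] <- ((first2 - 1L) %% 4L) + 1L       # row index (first base)
  s[2L] <- ((first2 - 1L) %/% 4L) + 1L      # column index (second base)
  if (L >= 3) {
    u <- runif(L - 2L)
    for (j in 3:L) {
      p <- model$trans[s[j - 2L], s[j - 1L], ]
      cp <- cumsum(p)
      s[j] <- 1L + sum(u[j - 2L] > cp[1:3])
    }
  }
  s
}
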