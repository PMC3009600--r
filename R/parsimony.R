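# Parsimony-based validation of substitution-rate estimates, and the
# ancestral-vs-extant G+C comparison by occupancy bin.

#' Small-parsimony substitution counts on a fixed tree
#'
#' For every alignment column, enumerates all internal-node labelings,
#' keeps the minimum-substitution ones, and assigns substitutions to
#' branches when that assignment is unique. Columns with several equally
#' parsimonious substitution placements are excluded from rate counts and
#' tallied as ambiguous; columns with non-ACGT symbols are masked. Rates
#' are substitutions over parent-state opportunity counts.
#'
#' @param aln alignment (see [infer_posteriors()]); needs >= 3 leaves.
#' @param tree a `lineage_tree`.
#' @return list with `subs` (per lineage 4x4 parent-to-child substitution
#'   count matrices), `opportunity` (per lineage parent-state counts),
#'   `rates` (counts / opportunities), `events` (data frame pos, branch,
#'   from, to), `status` (per-column factor ok/ambiguous/masked) and
#'   `n_ambiguous`.
#' @export
parsimony_substitutions <- function(aln, tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  if (sum(tree$is_leaf) < 3) stop("parsimony needs at least 3 leaves")
  prep <- prepare_alignment(aln, tree)
  mat <- prep$mat
  L <- ncol(mat)
  leaves <- tree$nodes[tree$is_leaf]
  internals <- tree$nodes[!tree$is_leaf]
  n_int <- length(internals)
  int_idx <- setNames(seq_along(internals), internals)

  # all internal labelings (rows) over the 4-letter alphabet
  A <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  colnames(A) <- internals
  edges <- lapply(tree$lineages, function(nm) {
    v <- node_index(tree, nm)
    list(child = nm, parent = tree$nodes[tree$parent[v]],
         child_leaf = tree$is_leaf[v])
  })

  status <- factor(rep("ok", L), levels = c("ok", "ambiguous", "masked"))
  status[prep$masked] <- "masked"
  keep <- which(!prep$masked)
  pat_key <- apply(mat[, keep, drop = FALSE], 2, paste, collapse = ",")
  uniq <- !duplicated(pat_key)
  upat <- mat[, keep[uniq], drop = FALSE]
  ukey <- pat_key[uniq]

  subs <- lapply(tree$lineages, function(nm) matrix(0, 4, 4,
    dimnames = list(parent = NUC, child = NUC)))
  names(subs) <- tree$lineages
  opp <- lapply(tree$lineages, function(nm) setNames(numeric(4), NUC))
  names(opp) <- tree$lineages
  events <- list()
  pat_res <- vector("list", ncol(upat))

  for (pi in seq_len(ncol(upat))) {
    col <- upat[, pi]
    nsub <- numeric(nrow(A))
    for (ed in edges) {
      par_states <- A[, int_idx[[ed$parent]]]
      child_states <- if (ed$child_leaf) col[[ed$child]] else
        A[, int_idx[[ed$child]]]
      nsub <- nsub + (par_states != child_states)
    }
    best <- which(nsub == min(nsub))
    profiles <- vapply(best, function(r) {
      paste(vapply(edges, function(ed) {
        p <- A[r, int_idx[[ed$parent]]]
        ch <- if (ed$child_leaf) col[[ed$child]] else A[r, int_idx[[ed$child]]]
        if (p == ch) "=" else paste0(ed$child, ":", p, ">", ch)
      }, ""), collapse = ";")
    }, "")
    if (length(unique(profiles)) > 1L) {
      pat_res[pi] <- list(NULL)   # ambiguous placement
    } else {
      r <- best[1L]
      pat_res[[pi]] <- lapply(edges, function(ed) {
        p <- unname(A[r, int_idx[[ed$parent]]])
        ch <- if (ed$child_leaf) unname(col[[ed$child]]) else
          unname(A[r, int_idx[[ed$child]]])
        c(parent = p, child = ch)
      })
    }
  }
  names(pat_res) <- ukey

  match_idx <- match(pat_key, ukey)
  for (pi in seq_len(ncol(upat))) {
    cols <- keep[match_idx == pi]
    res <- pat_res[[pi]]
    if (is.null(res)) {
      status[cols] <- "ambiguous"
      next
    }
    n_cols <- length(cols)
    for (ei in seq_along(edges)) {
      nm <- edges[[ei]]$child
      p <- res[[ei]][["parent"]]
      ch <- res[[ei]][["child"]]
      opp[[nm]][p] <- opp[[nm]][p] + n_cols
      if (p != ch) {
        subs[[nm]][p, ch] <- subs[[nm]][p, ch] + n_cols
        events[[length(events) + 1L]] <- data.frame(
          pos = cols, branch = nm, from = p, to = ch, stringsAsFactors = FALSE)
      }
    }
  }
  rates <- lapply(tree$lineages, function(nm) {
    r <- subs[[nm]] / ifelse(opp[[nm]] > 0, opp[[nm]], NA)
    r
  })
  names(rates) <- tree$lineages
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(pos = integer(0), branch = character(0), from = integer(0),
               to = integer(0))
  events <- events[order(events$pos), , drop = FALSE]
  rownames(events) <- NULL
  list(subs = subs, opportunity = opp, rates = rates, events = events,
       status = status, n_ambiguous = sum(status == "ambiguous"))
}

#' A/T gain and loss rates from parsimony counts
#'
#' Context-independent rates per lineage: gain = C/G -> A/T substitutions
#' over C/G opportunities, loss = A/T -> C/G over A/T opportunities.
#'
#' @param ps result of [parsimony_substitutions()].
#' @return data frame with lineage, gain_rate, loss_rate.
#' @export
parsimony_gain_loss <- function(ps) {
  do.call(rbind, lapply(names(ps$subs), function(nm) {
    s <- ps$subs[[nm]]; o <- ps$opportunity[[nm]]
    gain <- sum(s[GC_CODES, AT_CODES]) / sum(o[GC_CODES])
    loss <- sum(s[AT_CODES, GC_CODES]) / sum(o[AT_CODES])
    data.frame(lineage = nm, gain_rate = gain, loss_rate = loss)
  }))
}

#' Ancestral vs extant G+C content by occupancy bin
#'
#' The ancestral G+C at a position is the posterior probability of G or C
#' at the designated ancestor node; the extant G+C comes from the focal
#' leaf. Both are averaged within occupancy-rank bins.
#'
#' @param posterior an `ancestral_posterior`.
#' @param ancestor name of the ancestor node to read (e.g. the common
#'   ancestor of the focal species and its sister).
#' @param extant_seq integer-coded focal leaf sequence.
#' @param bins integer bin index per position (e.g. from [bin_occupancy()]),
#'   or NULL with `track`/`k` supplied.
#' @param track occupancy track used to compute bins when `bins` is NULL.
#' @param k number of occupancy bins (default 10).
#' @param include optional logical vector of positions to use (e.g.
#'   intergenic only).
#' @return data frame with bin, n, extant_gc, ancestral_gc (empty bins get
#'   `NA` and are flagged in the `empty` column).
#' @export
ancestral_gc_by_bin <- function(posterior, ancestor, extant_seq, bins = NULL,
                                track = NULL, k = 10, include = NULL) {
  nm <- posterior$node_marginals[[ancestor]]
  if (is.null(nm)) stop("no marginals for ancestor node ", ancestor)
  L <- nrow(nm)
  stopifnot(length(extant_seq) == L)
  if (is.null(bins)) {
    if (is.null(track)) stop("supply bins or an occupancy track")
    bins <- bin_occupancy(track, k)
  }
  stopifnot(length(bins) == L)
  use <- !is.na(extant_seq) & extant_seq >= 1 & extant_seq <= 4 &
    !is.na(nm[, 1])
  if (!is.null(include)) use <- use & include
  anc_gc <- nm[, 2] + nm[, 3]
  ext_gc <- as.numeric(is_gc(extant_seq))
  out <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- use & bins == b
    n <- sum(sel)
    data.frame(bin = b, n = n,
               extant_gc = if (n) mean(ext_gc[sel]) else NA_real_,
               ancestral_gc = if (n) mean(anc_gc[sel]) else NA_real_,
               empty = n == 0)
  }))
  out
}
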