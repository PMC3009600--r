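# Spatial coupling between A/T-gaining and A/T-losing substitutions:
# per-position expected events, horizon-window divergence contexts,
# conditional rates, and the bootstrap significance test.

#' Expected A/T gain and loss events per position
#'
#' From branch (parent, child) pair posteriors on the focal lineage:
#' g(j) sums posterior mass with parent in C/G and child in A/T (gain),
#' l(j) the reciprocal (loss); conserved and within-class pairs contribute
#' zero. Also returns the posterior-weighted probability that the ancestral
#' base is A/T or C/G (the opportunity weights).
#'
#' @param pair_marg sites x 16 pair-marginal matrix for the focal lineage
#'   (`pair_marginals[[lineage]]` of an [infer_posteriors()] result;
#'   column `p + 4*(c-1)` = P(parent p, child c)), or an
#'   `ancestral_posterior` together with `lineage`.
#' @param lineage focal lineage name when `pair_marg` is a posterior
#'   object.
#' @return object of class `substitution_expectation`: data frame with g,
#'   l, p_at, p_cg and a `masked` logical (positions lacking posteriors).
#' @export
expected_events <- function(pair_marg, lineage = NULL) {
  if (inherits(pair_marg, "ancestral_posterior")) {
    if (is.null(lineage)) stop("supply the focal lineage name")
    pair_marg <- pair_marg$pair_marginals[[lineage]]
    if (is.null(pair_marg)) stop("unknown lineage: ", lineage)
  }
  stopifnot(is.matrix(pair_marg), ncol(pair_marg) == 16)
  col_of <- function(p, ch) p + 4L * (ch - 1L)
  gain_cols <- as.vector(outer(GC_CODES, AT_CODES, col_of))
  loss_cols <- as.vector(outer(AT_CODES, GC_CODES, col_of))
  at_cols <- as.vector(outer(AT_CODES, 1:4, col_of))
  cg_cols <- as.vector(outer(GC_CODES, 1:4, col_of))
  masked <- is.na(pair_marg[, 1])
  g <- rowSums(pair_marg[, gain_cols, drop = FALSE])
  l <- rowSums(pair_marg[, loss_cols, drop = FALSE])
  p_at <- rowSums(pair_marg[, at_cols, drop = FALSE])
  p_cg <- rowSums(pair_marg[, cg_cols, drop = FALSE])
  structure(data.frame(g = ifelse(masked, NA_real_, g),
                       l = ifelse(masked, NA_real_, l),
                       p_at = ifelse(masked, NA_real_, p_at),
                       p_cg = ifelse(masked, NA_real_, p_cg),
                       masked = masked),
            class = c("substitution_expectation", "data.frame"))
}

#' Expectations from known (simulated) parent and child sequences
#'
#' Point-mass version of [expected_events()] for synthetic ground truth.
#'
#' @param parent_seq,child_seq integer-coded sequences of equal length.
#' @return a `substitution_expectation`.
#' @export
expected_events_from_truth <- function(parent_seq, child_seq) {
  stopifnot(length(parent_seq) == length(child_seq))
  par_at <- parent_seq %in% AT_CODES
  par_cg <- parent_seq %in% GC_CODES
  ch_at <- child_seq %in% AT_CODES
  ch_cg <- child_seq %in% GC_CODES
  masked <- !(par_at | par_cg) | !(ch_at | ch_cg)
  structure(data.frame(
    g = ifelse(masked, NA_real_, as.numeric(par_cg & ch_at)),
    l = ifelse(masked, NA_real_, as.numeric(par_at & ch_cg)),
    p_at = ifelse(masked, NA_real_, as.numeric(par_at)),
    p_cg = ifelse(masked, NA_real_, as.numeric(par_cg)),
    masked = masked),
    class = c("substitution_expectation", "data.frame"))
}

#' Windowed A/T divergence over the preceding horizon
#'
#' Gain_h(j) and Loss_h(j) sum the expected gains and losses over the `h`
#' positions strictly preceding j (masked positions contribute 0); the net
#' divergence is D = Gain_h - Loss_h. Positions whose window is truncated
#' by the sequence start are flagged.
#'
#' @param expect a `substitution_expectation`.
#' @param horizon window length in bp (default 5, >= 1).
#' @return data frame with gain_h, loss_h, D and `short_window`.
#' @export
window_divergence <- function(expect, horizon = 5) {
  if (horizon < 1) stop("horizon must be >= 1")
  g <- ifelse(is.na(expect$g), 0, expect$g)
  l <- ifelse(is.na(expect$l), 0, expect$l)
  n <- length(g)
  csg <- c(0, cumsum(g))
  csl <- c(0, cumsum(l))
  j <- seq_len(n)
  lo <- pmax(j - horizon, 1L)
  gain_h <- csg[j] - csg[lo]
  loss_h <- csl[j] - csl[lo]
  data.frame(gain_h = gain_h, loss_h = loss_h, D = gain_h - loss_h,
             short_window = j <= horizon)
}

#' Label positions by their preceding-window divergence context
#'
#' D > thr: "gaining"; D < -thr: "losing"; conserved windows
#' (Gain_h + Loss_h < 1 - thr): "background". Everything else - mixed
#' windows and truncated windows - is "other" and excluded from the
#' conditional-rate strata.
#'
#' @param div result of [window_divergence()].
#' @param thr divergence threshold (default 0.9, > 0).
#' @return factor with levels gaining/losing/background/other.
#' @export
label_contexts <- function(div, thr = 0.9) {
  if (thr <= 0) stop("thr must be > 0")
  lab <- rep("other", nrow(div))
  lab[div$D > thr] <- "gaining"
  lab[div$D < -thr] <- "losing"
  lab[div$gain_h + div$loss_h < (1 - thr)] <- "background"
  lab[div$short_window] <- "other"
  factor(lab, levels = c("gaining", "losing", "background", "other"))
}

#' Conditional gain/loss rates given divergence context
#'
#' rate(gain | ctx) = sum of expected gains at ctx positions divided by the
#' posterior-weighted count of ancestral C/G sites there; rate(loss | ctx)
#' likewise over ancestral A/T sites. Each unit of posterior substitution
#' mass is counted in exactly one stratum. Optionally stratified by
#' occupancy bin.
#'
#' @param labels context labels (from [label_contexts()]).
#' @param expect a `substitution_expectation`.
#' @param bins optional integer occupancy-bin vector (e.g. 5 bins).
#' @return data frame with bin (0 when unstratified), context, n_at, n_cg,
#'   gain_rate, loss_rate; empty opportunity classes yield `NA` with
#'   `undefined = TRUE`.
#' @export
conditional_rates <- function(labels, expect, bins = NULL) {
  stopifnot(length(labels) == nrow(expect))
  if (is.null(bins)) bins <- rep(0L, length(labels))
  stopifnot(length(bins) == length(labels))
  out <- list()
  for (b in sort(unique(bins))) {
    for (ctx in c("gaining", "losing", "background")) {
      sel <- which(bins == b & labels == ctx & !expect$masked)
      n_at <- sum(expect$p_at[sel])
      n_cg <- sum(expect$p_cg[sel])
      gain <- if (n_cg > 0) sum(expect$g[sel]) / n_cg else NA_real_
      loss <- if (n_at > 0) sum(expect$l[sel]) / n_at else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        bin = b, context = ctx, n_sites = length(sel),
        n_at = n_at, n_cg = n_cg,
        gain_rate = gain, loss_rate = loss,
        undefined = (n_cg == 0) || (n_at == 0))
    }
  }
  do.call(rbind, out)
}

#' Coupling counts for the bootstrap test
#'
#' Expected numbers of gains and losses in the gaining and losing contexts,
#' and the corresponding A/T and C/G opportunity-site counts.
#'
#' @param labels context labels.
#' @param expect a `substitution_expectation`.
#' @param bins,bin optional: restrict to one occupancy bin.
#' @return list of class `coupling_counts` with N_gain_in_gainctx,
#'   N_loss_in_gainctx, N_gain_in_lossctx, N_loss_in_lossctx,
#'   n_AT_in_gainctx, n_AT_in_lossctx, n_CG_in_gainctx, n_CG_in_lossctx.
#' @export
coupling_counts <- function(labels, expect, bins = NULL, bin = NULL) {
  sel_g <- labels == "gaining" & !expect$masked
  sel_l <- labels == "losing" & !expect$masked
  if (!is.null(bins) && !is.null(bin)) {
    sel_g <- sel_g & bins == bin
    sel_l <- sel_l & bins == bin
  }
  structure(list(
    N_gain_in_gainctx = sum(expect$g[sel_g]),
    N_loss_in_gainctx = sum(expect$l[sel_g]),
    N_gain_in_lossctx = sum(expect$g[sel_l]),
    N_loss_in_lossctx = sum(expect$l[sel_l]),
    n_AT_in_gainctx = sum(expect$p_at[sel_g]),
    n_AT_in_lossctx = sum(expect$p_at[sel_l]),
    n_CG_in_gainctx = sum(expect$p_cg[sel_g]),
    n_CG_in_lossctx = sum(expect$p_cg[sel_l])
  ), class = "coupling_counts")
}

#' Bootstrap test for compensatory spatial coupling
#'
#' The observed statistic counts compensatory events: gains in losing
#' contexts plus losses in gaining contexts. Under the null the total gains
#' are reassigned to contexts by sampling, without replacement, from the
#' pooled C/G opportunity sites of the two contexts (and losses likewise
#' from pooled A/T sites), preserving event totals and context sizes while
#' breaking the context-direction association. The p-value is the add-one
#' fraction of resamples whose statistic is >= the observed one, so
#' p >= 1/(B+1). Expected (fractional) counts are rounded to integers for
#' resampling.
#'
#' @param counts a `coupling_counts` (or compatible list).
#' @param B number of resamples (default 100000).
#' @param seed integer seed.
#' @return list of class `coupling_test` with observed, B, p_value, seed,
#'   and the null-statistic mean.
#' @export
bootstrap_coupling_test <- function(counts, B = 100000, seed = 1L) {
  cnt <- lapply(counts[c("N_gain_in_gainctx", "N_loss_in_gainctx",
                         "N_gain_in_lossctx", "N_loss_in_lossctx",
                         "n_AT_in_gainctx", "n_AT_in_lossctx",
                         "n_CG_in_gainctx", "n_CG_in_lossctx")],
                function(x) as.integer(round(x)))
  if (any(vapply(cnt, length, 1L) != 1L) || any(is.na(unlist(cnt)))) {
    stop("invalid coupling counts")
  }
  if (cnt$n_AT_in_gainctx <= 0 || cnt$n_AT_in_lossctx <= 0 ||
      cnt$n_CG_in_gainctx <= 0 || cnt$n_CG_in_lossctx <= 0) {
    stop("all opportunity counts must be positive")
  }
  gains_tot <- cnt$N_gain_in_gainctx + cnt$N_gain_in_lossctx
  losses_tot <- cnt$N_loss_in_gainctx + cnt$N_loss_in_lossctx
  if (gains_tot + losses_tot == 0) stop("no events to test")
  observed <- cnt$N_gain_in_lossctx + cnt$N_loss_in_gainctx
  with_seed(seed, {
    x <- if (gains_tot > 0) {
      rhyper(B, m = cnt$n_CG_in_lossctx, n = cnt$n_CG_in_gainctx,
             k = gains_tot)
    } else rep(0L, B)
    y <- if (losses_tot > 0) {
      rhyper(B, m = cnt$n_AT_in_gainctx, n = cnt$n_AT_in_lossctx,
             k = losses_tot)
    } else rep(0L, B)
    stat <- x + y
    structure(list(observed = observed, B = B,
                   p_value = (1 + sum(stat >= observed)) / (B + 1),
                   null_mean = mean(stat), seed = seed),
              class = "coupling_test")
  })
}

#' @export
print.coupling_test <- function(x, ...) {
  cat("compensatory coupling bootstrap test\n")
  cat("  observed compensatory events:", x$observed, "\n")
  cat("  null mean:", format(x$null_mean, digits = 4),
      " resamples:", x$B, "\n")
  cat("  p-value:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
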