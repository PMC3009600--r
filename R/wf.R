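# Wright-Fisher forward model of selection on G+C content and its analytic
# birth-death stationary approximation.
#
# Genomes are binary sequences over {A, G} of length L; fitness depends only
# on the number of G's. Mutation pushes toward A (the faster direction), the
# landscape may push back; substitutions are fixations of the population
# major allele relative to a tracked reference genome.

#' Wright-Fisher model parameters
#'
#' Defaults give a population-scaled mutation rate theta = 2*N*max(mu) =
#' 0.014 (below the 0.04 drift-domination bound) and a neutral stationary
#' G+C content of mu_to_GC / (mu_to_AT + mu_to_GC) = 0.30.
#'
#' @param N (effective) population size (>= 2).
#' @param L genome size in sites (>= 1).
#' @param mu_to_AT per-site per-generation G/C -> A/T mutation rate.
#' @param mu_to_GC per-site per-generation A/T -> G/C mutation rate.
#' @return an object of class `wf_params` (includes `theta`).
#' @export
wf_params <- function(N = 10000, L = 20, mu_to_AT = 7e-7, mu_to_GC = 3e-7) {
  stopifnot(N >= 2, L >= 1)
  if (mu_to_AT <= 0 || mu_to_AT >= 1 || mu_to_GC <= 0 || mu_to_GC >= 1) {
    stop("mutation rates must lie in (0, 1)")
  }
  structure(list(N = as.integer(N), L = as.integer(L),
                 mu_to_AT = mu_to_AT, mu_to_GC = mu_to_GC,
                 theta = 2 * N * max(mu_to_AT, mu_to_GC)),
            class = "wf_params")
}

#' Fitness landscape over G/C counts
#'
#' The "goal" landscape is log-quadratic and symmetric about the optimum:
#' f(n) = exp(-eta * (n - n_opt)^2). The "threshold" landscape is flat (f =
#' 1) for n <= n_opt and decays exponentially above: moves toward fewer G/C
#' are never deleterious. Both are strictly positive and reduce to
#' neutrality at eta = 0.
#'
#' @param kind "goal" or "threshold".
#' @param n_opt optimal (or threshold) G/C count.
#' @param eta selection intensity (>= 0).
#' @return an object of class `fitness_landscape`.
#' @export
fitness_landscape <- function(kind = c("goal", "threshold"), n_opt, eta) {
  kind <- match.arg(kind)
  stopifnot(eta >= 0, n_opt >= 0)
  structure(list(kind = kind, n_opt = n_opt, eta = eta),
            class = "fitness_landscape")
}

#' Evaluate landscape fitness at a G/C count
#'
#' @param landscape a `fitness_landscape`.
#' @param n G/C count(s), each in `[0, L]`.
#' @param L genome size.
#' @return numeric vector of strictly positive fitness values.
#' @export
fitness <- function(landscape, n, L) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  if (any(n < 0 | n > L)) stop("n out of [0, L]")
  with(landscape, switch(kind,
    goal = exp(-eta * (n - n_opt)^2),
    threshold = ifelse(n <= n_opt, 1, exp(-eta * (n - n_opt)))
  ))
}

#' Kimura fixation probability of a new mutation (haploid diffusion form)
#'
#' u(s) = (1 - exp(-2s)) / (1 - exp(-2Ns)), with the s -> 0 limit 1/N
#' handled analytically and overflow-safe branches for strong selection.
#'
#' @param s marginal fitness change of the mutation (f_new/f_old - 1).
#' @param N population size.
#' @return fixation probabilities (same length as `s`).
#' @export
fixation_probability <- function(s, N) {
  out <- numeric(length(s))
  tiny <- abs(s) < 1e-12
  out[tiny] <- 1 / N
  big_neg <- !tiny & (2 * N * s < -700)
  # denominator ~ -exp(-2Ns): u ~ -num * exp(2Ns), vanishingly small
  out[big_neg] <- (exp(-2 * s[big_neg]) - 1) * exp(2 * N * s[big_neg])
  rest <- !tiny & !big_neg
  out[rest] <- expm1(-2 * s[rest]) / expm1(-2 * N * s[rest])
  out
}

#' Run the Wright-Fisher forward simulation
#'
#' Implements the initialize / sample-a-new-generation / update-reference
#' procedure: identical starting population, multinomial resampling
#' proportional to fitness, per-site mutation, and substitution counting
#' against a reference genome updated whenever a site's major allele
#' frequency exceeds `fix_thr` and differs from the reference. Exposure and
#' fixation counters start after a burn-in of
#' `burn_in_coalescents * N` generations.
#'
#' @param params a `wf_params`.
#' @param landscape a `fitness_landscape`.
#' @param generations total generations to simulate (> burn-in).
#' @param burn_in_coalescents burn-in length in units of N generations
#'   (default 4).
#' @param fix_thr fixation frequency threshold (default 0.95; must be >
#'   0.5).
#' @param seed integer seed.
#' @param thin record the population mean G+C every `thin` generations.
#' @param init_n G/C count of the identical starting sequences (default:
#'   the neutral stationary composition, rounded).
#' @return list with per-site substitution-rate estimates `r_gain`
#'   (G/C -> A/T) and `r_loss` (A/T -> G/C), `mean_gc` after burn-in, raw
#'   `counters` (N_A, N_G in individual-site-generations; N_A_to_G,
#'   N_G_to_A fixation events), the exposure-per-genome normalization used,
#'   and the `trajectory` of mean G+C.
#' @export
run_wf <- function(params, landscape, generations,
                   burn_in_coalescents = 4, fix_thr = 0.95, seed = 1L,
                   thin = 100L, init_n = NULL) {
  stopifnot(inherits(params, "wf_params"),
            inherits(landscape, "fitness_landscape"))
  if (fix_thr <= 0.5) stop("fix_thr must be > 0.5")
  burn_in <- as.integer(burn_in_coalescents * params$N)
  if (generations <= burn_in) {
    stop("generations (", generations, ") must exceed the burn-in (",
         burn_in, ")")
  }
  fit_tab <- fitness(landscape, 0:params$L, params$L)
  if (any(!is.finite(fit_tab)) || any(fit_tab <= 0)) {
    stop("fitness must be strictly positive and finite on 0..L")
  }
  if (is.null(init_n)) {
    # start at the neutral stationary composition to shorten the transient
    init_n <- round(params$L * params$mu_to_GC /
                      (params$mu_to_AT + params$mu_to_GC))
  }
  res <- with_seed(seed, {
    wf_core(params$N, params$L, params$mu_to_AT, params$mu_to_GC,
            fit_tab, as.integer(generations), burn_in, fix_thr,
            as.integer(thin), as.integer(init_n))
  })
  gens_counted <- generations - burn_in
  # exposure per genome (site-generations of the population-average genome)
  exp_G <- res$N_G / params$N
  exp_A <- res$N_A / params$N
  list(
    r_gain = if (exp_G > 0) res$N_G_to_A / exp_G else NA_real_,
    r_loss = if (exp_A > 0) res$N_A_to_G / exp_A else NA_real_,
    mean_gc = res$N_G / (res$N_G + res$N_A),
    counters = res[c("N_A", "N_G", "N_A_to_G", "N_G_to_A")],
    n_fix_gain = res$N_G_to_A, n_fix_loss = res$N_A_to_G,
    exposure_gain = exp_G, exposure_loss = exp_A,
    generations_counted = gens_counted,
    trajectory = res$trajectory,
    theta = params$theta
  )
}

#' Analytic birth-death stationary approximation
#'
#' In the drift-dominated regime (theta small) the population is summarized
#' by a single G/C count n performing a birth-death walk with up-rate
#' lambda_up(n) = N * mu_to_GC * (L - n) * u(s_up) and down-rate
#' lambda_dn(n) = N * mu_to_AT * n * u(s_dn), where s is the marginal
#' fitness change of the move and u the Kimura fixation probability. The
#' stationary distribution follows from detailed balance; per-site
#' substitution rates are expected fixations per exposed site-generation,
#' matching the simulator's estimators.
#'
#' @param params a `wf_params`.
#' @param landscape a `fitness_landscape`.
#' @return list with `pi` (stationary distribution over n = 0..L),
#'   `mean_gc`, `r_gain`, `r_loss`, and the chain rates `lambda_up`,
#'   `lambda_dn`.
#' @export
analytic_stationary <- function(params, landscape) {
  stopifnot(inherits(params, "wf_params"),
            inherits(landscape, "fitness_landscape"))
  if (params$theta > 0.1) {
    warning("theta = ", signif(params$theta, 3),
            " is large; the drift-dominated approximation may be poor")
  }
  N <- params$N; L <- params$L
  f <- fitness(landscape, 0:L, L)
  n <- 0:L
  s_up <- f[pmin(n + 1, L) + 1L] / f[n + 1L] - 1      # n -> n+1 (defined for n < L)
  s_dn <- f[pmax(n - 1, 0) + 1L] / f[n + 1L] - 1      # n -> n-1 (defined for n > 0)
  lam_up <- N * params$mu_to_GC * (L - n) * fixation_probability(s_up, N)
  lam_dn <- N * params$mu_to_AT * n * fixation_probability(s_dn, N)
  lam_up[L + 1L] <- 0
  lam_dn[1L] <- 0
  if (all(lam_up == 0) && all(lam_dn == 0)) stop("degenerate chain: all rates 0")
  # detailed balance: pi(n+1)/pi(n) = lam_up(n)/lam_dn(n+1); an up-rate that
  # underflows to 0 is an absorbing wall - states above it carry no mass
  logpi <- numeric(L + 1L)
  for (i in 1:L) {
    if (lam_up[i] == 0) {           # states above i are unreachable
      logpi[(i + 1L):(L + 1L)] <- -Inf
      break
    }
    if (lam_dn[i + 1L] == 0) {      # states at or below i are transient
      logpi[1:i] <- -Inf
      logpi[i + 1L] <- 0
    } else {
      logpi[i + 1L] <- logpi[i] + log(lam_up[i]) - log(lam_dn[i + 1L])
    }
  }
  logpi <- logpi - max(logpi)
  pi_n <- exp(logpi) / sum(exp(logpi))
  mean_gc <- sum(pi_n * n) / L
  r_gain <- sum(pi_n * lam_dn) / sum(pi_n * n)          # per G/C site
  r_loss <- sum(pi_n * lam_up) / sum(pi_n * (L - n))    # per A/T site
  list(pi = pi_n, mean_gc = mean_gc, r_gain = r_gain, r_loss = r_loss,
       lambda_up = lam_up, lambda_dn = lam_dn)
}

#' Sweep selection intensities
#'
#' Evaluates the analytic stationary chain over a grid of selection
#' intensities (optionally adding Wright-Fisher simulated points) for a
#' given landscape shape.
#'
#' @param params a `wf_params`.
#' @param kind landscape kind ("goal" or "threshold").
#' @param n_opt landscape optimum / threshold.
#' @param eta_grid sorted non-negative selection intensities.
#' @param simulate logical: also run the forward simulator at each eta.
#' @param sim_args list of arguments passed to [run_wf()] (e.g.
#'   `generations`, `seed`).
#' @return data frame with eta, r_gain, r_loss, mean_gc (analytic) and, if
#'   simulated, sim_r_gain, sim_r_loss, sim_mean_gc.
#' @export
sweep_intensities <- function(params, kind, n_opt, eta_grid,
                              simulate = FALSE, sim_args = list()) {
  stopifnot(!is.unsorted(eta_grid), all(eta_grid >= 0))
  rows <- lapply(eta_grid, function(eta) {
    ls <- fitness_landscape(kind, n_opt, eta)
    an <- analytic_stationary(params, ls)
    row <- data.frame(eta = eta, r_gain = an$r_gain, r_loss = an$r_loss,
                      mean_gc = an$mean_gc)
    if (simulate) {
      sim <- do.call(run_wf, c(list(params = params, landscape = ls), sim_args))
      row$sim_r_gain <- sim$r_gain
      row$sim_r_loss <- sim$r_loss
      row$sim_mean_gc <- sim$mean_gc
      row$sim_n_fix_gain <- sim$n_fix_gain
      row$sim_n_fix_loss <- sim$n_fix_loss
      row$sim_exposure_gain <- sim$exposure_gain
      row$sim_exposure_loss <- sim$exposure_loss
    }
    row
  })
  do.call(rbind, rows)
}

#' Desk-scale rescaling preserving N*mu and N*s
#'
#' Divides the population size by `k` while multiplying mutation rates and
#' the selection intensity by `k`, preserving theta = 2*N*mu and the scaled
#' selection N*eta, so stationary behavior is unchanged while simulation
#' cost drops by ~k.
#'
#' @param params a `wf_params`.
#' @param landscape a `fitness_landscape`.
#' @param k rescaling factor (> 1 shrinks the population).
#' @return list with rescaled `params` and `landscape`.
#' @export
rescale_wf <- function(params, landscape, k) {
  stopifnot(k >= 1, params$N / k >= 2)
  list(
    params = wf_params(N = params$N / k, L = params$L,
                       mu_to_AT = params$mu_to_AT * k,
                       mu_to_GC = params$mu_to_GC * k),
    landscape = fitness_landscape(landscape$kind, landscape$n_opt,
                                  landscape$eta * k)
  )
}
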