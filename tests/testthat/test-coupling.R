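# Spatial gain/loss coupling: expectations, divergence windows, labels,
# conditional rates and the bootstrap test.

point_mass_pairs <- function(parent, child) {
  # build a pair-marginal matrix with mass 1 on (parent, child) per site
  L <- length(parent)
  pm <- matrix(0, L, 16)
  pm[cbind(seq_len(L), parent + 4L * (child - 1L))] <- 1
  pm
}

test_that("expected events implement the gain/loss delta table", {
  # parent A child G: loss; parent C child T: gain; conserved pairs: zero
  pm <- point_mass_pairs(parent = c(1L, 2L, 1L, 2L),
                         child = c(3L, 4L, 1L, 2L))
  ee <- expected_events(pm)
  expect_equal(ee$l, c(1, 0, 0, 0))
  expect_equal(ee$g, c(0, 1, 0, 0))
  expect_equal(ee$p_at, c(1, 0, 1, 0))
  expect_equal(ee$p_cg, c(0, 1, 0, 1))
})

test_that("transversions within a composition class carry no gain/loss mass", {
  pm <- point_mass_pairs(parent = c(1L, 2L), child = c(4L, 3L))  # A->T, C->G
  ee <- expected_events(pm)
  expect_equal(ee$g, c(0, 0))
  expect_equal(ee$l, c(0, 0))
})

test_that("window divergence sums the preceding horizon only", {
  ee <- expected_events_from_truth(
    parent_seq = c(1L, 2L, 1L, 1L, 1L, 1L),
    child_seq  = c(1L, 4L, 1L, 1L, 1L, 1L))   # C->T gain at position 2
  div <- window_divergence(ee, horizon = 5)
  expect_equal(div$D[6], 1)     # position 6 sees the gain at position 2
  expect_equal(div$D[2], 0)     # own position never included
  expect_true(div$short_window[1])
  expect_equal(div$gain_h[1], 0)
  # horizon 1 variant only sees the immediate predecessor
  div1 <- window_divergence(ee, horizon = 1)
  expect_equal(div1$D[3], 1)
  expect_equal(div1$D[4], 0)
  expect_error(window_divergence(ee, horizon = 0), "horizon")
})

test_that("context labels follow the +/-0.9 thresholds and conserved background", {
  div <- data.frame(gain_h = c(0.95, 0, 0, 0.5, 0),
                    loss_h = c(0, 0.95, 0, 0.5, 0.05),
                    D = c(0.95, -0.95, 0, 0, -0.05),
                    short_window = FALSE)
  lab <- label_contexts(div, 0.9)
  expect_equal(as.character(lab),
               c("gaining", "losing", "background", "other", "background"))
  # truncated windows are never labeled
  div$short_window <- TRUE
  expect_true(all(label_contexts(div) == "other"))
})

test_that("conditional rates match a hand tally on a toy case", {
  g <- c(0, 0, 1, 0, 0.5, 0, 0, 0, 0, 0)
  l <- c(0, 1, 0, 0, 0, 0, 0.5, 0, 0, 0)
  p_cg <- c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0)
  p_at <- 1 - p_cg
  ee <- structure(data.frame(g = g, l = l, p_at = p_at, p_cg = p_cg,
                             masked = FALSE),
                  class = c("substitution_expectation", "data.frame"))
  lab <- factor(c("other", "other", "losing", "losing", "losing",
                  "gaining", "gaining", "background", "background", "background"),
                levels = c("gaining", "losing", "background", "other"))
  cr <- conditional_rates(lab, ee)
  # losing ctx: positions 3,4,5: gains 1.5 over 2 C/G sites; losses 0 over 1 A/T
  expect_equal(cr$gain_rate[cr$context == "losing"], 1.5 / 2)
  expect_equal(cr$loss_rate[cr$context == "losing"], 0)
  # gaining ctx: positions 6,7: loss 0.5 over 1 A/T site; gain 0 over 1 C/G
  expect_equal(cr$loss_rate[cr$context == "gaining"], 0.5)
  expect_equal(cr$gain_rate[cr$context == "gaining"], 0)
  # background: positions 8,9,10: no events
  expect_equal(cr$gain_rate[cr$context == "background"], 0)
})

test_that("zero expectations give background contexts and zero rates", {
  ee <- expected_events_from_truth(rep(c(1L, 3L), 50), rep(c(1L, 3L), 50))
  div <- window_divergence(ee)
  lab <- label_contexts(div)
  expect_true(all(lab[!div$short_window] == "background"))
  cr <- conditional_rates(lab, ee)
  bg <- cr[cr$context == "background", ]
  expect_equal(bg$gain_rate, 0)
  expect_equal(bg$loss_rate, 0)
})

test_that("every unit of substitution mass lands in exactly one stratum", {
  w <- small_world(8000, seed = 14, p_sub = 0.15)
  sim <- gen_alignment(w)
  ee <- expected_events_from_truth(sim$sequences$u, sim$sequences$A)
  div <- window_divergence(ee)
  lab <- label_contexts(div)
  cr <- conditional_rates(lab, ee)
  labeled_gain <- sum(vapply(c("gaining", "losing", "background"), function(ctx) {
    r <- cr[cr$context == ctx, ]
    if (is.na(r$gain_rate)) 0 else r$gain_rate * r$n_cg
  }, numeric(1)))
  direct <- sum(ee$g[!ee$masked & lab != "other"])
  expect_equal(labeled_gain, direct, tolerance = 1e-12)
})

test_that("bootstrap p-value matches the exact enumeration oracle", {
  cases <- list(
    list(N_gain_in_gainctx = 0, N_gain_in_lossctx = 5, N_loss_in_gainctx = 5,
         N_loss_in_lossctx = 0, n_AT_in_gainctx = 10, n_AT_in_lossctx = 10,
         n_CG_in_gainctx = 10, n_CG_in_lossctx = 10),
    list(N_gain_in_gainctx = 2, N_gain_in_lossctx = 3, N_loss_in_gainctx = 4,
         N_loss_in_lossctx = 1, n_AT_in_gainctx = 12, n_AT_in_lossctx = 9,
         n_CG_in_gainctx = 8, n_CG_in_lossctx = 15),
    list(N_gain_in_gainctx = 4, N_gain_in_lossctx = 0, N_loss_in_gainctx = 0,
         N_loss_in_lossctx = 4, n_AT_in_gainctx = 20, n_AT_in_lossctx = 20,
         n_CG_in_gainctx = 20, n_CG_in_lossctx = 20))
  for (cnt in cases) {
    B <- 100000
    bt <- bootstrap_coupling_test(cnt, B = B, seed = 5)
    p0 <- oracle_coupling_p(cnt)
    se <- sqrt(max(p0 * (1 - p0), 0) / B)
    expect_lt(abs(bt$p_value - p0), 3 * se + 2 / B)
  }
})

test_that("a minimal observed statistic gives p = 1 and p is never below 1/(B+1)", {
  cnt <- list(N_gain_in_gainctx = 5, N_gain_in_lossctx = 0,
              N_loss_in_gainctx = 0, N_loss_in_lossctx = 5,
              n_AT_in_gainctx = 500, n_AT_in_lossctx = 500,
              n_CG_in_gainctx = 500, n_CG_in_lossctx = 500)
  bt <- bootstrap_coupling_test(cnt, B = 2000, seed = 2)
  expect_equal(bt$observed, 0)
  expect_equal(bt$p_value, 1)
  # extreme coupling: p floored at 1/(B+1)
  cnt2 <- list(N_gain_in_gainctx = 0, N_gain_in_lossctx = 40,
               N_loss_in_gainctx = 40, N_loss_in_lossctx = 0,
               n_AT_in_gainctx = 500, n_AT_in_lossctx = 500,
               n_CG_in_gainctx = 500, n_CG_in_lossctx = 500)
  bt2 <- bootstrap_coupling_test(cnt2, B = 2000, seed = 2)
  expect_gte(bt2$p_value, 1 / 2001)
  expect_lt(bt2$p_value, 0.01)
  # degenerate inputs
  expect_error(bootstrap_coupling_test(list(
    N_gain_in_gainctx = 0, N_gain_in_lossctx = 0, N_loss_in_gainctx = 0,
    N_loss_in_lossctx = 0, n_AT_in_gainctx = 5, n_AT_in_lossctx = 5,
    n_CG_in_gainctx = 5, n_CG_in_lossctx = 5)), "no events")
  expect_error(bootstrap_coupling_test(list(
    N_gain_in_gainctx = 1, N_gain_in_lossctx = 0, N_loss_in_gainctx = 0,
    N_loss_in_lossctx = 0, n_AT_in_gainctx = 0, n_AT_in_lossctx = 5,
    n_CG_in_gainctx = 5, n_CG_in_lossctx = 5)), "positive")
})
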