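# Synthetic-data generator: sequence evolution, occupancy tracks, planted
# compensatory pairs, SNP panels.

test_that("all-zero off-diagonal rates leave every node identical to the root", {
  tree <- tree3()
  w <- synthetic_world(500, tree, iid_root_model(),
                       uniform_context_rates(tree$lineages, 0), seed = 3)
  sim <- gen_alignment(w)
  for (nm in tree$nodes) {
    expect_identical(sim$sequences[[nm]], sim$sequences$root)
  }
  expect_equal(nrow(sim$events), 0)
})

test_that("context-free branch simulation realizes the specified substitution probability", {
  tree <- tree2()
  p_sub <- 0.08
  w <- synthetic_world(30000, tree, iid_root_model(rep(0.25, 4)),
                       uniform_context_rates(tree$lineages, p_sub), seed = 11)
  sim <- gen_alignment(w)
  for (nm in c("A", "B")) {
    phat <- mean(sim$sequences[[nm]] != sim$sequences$root)
    se <- sqrt(p_sub * (1 - p_sub) / w$genome_length)
    expect_lt(abs(phat - p_sub), 3 * se)
  }
})

test_that("a stationary process conserves G+C from root to extant leaves", {
  tree <- tree3()
  pi0 <- c(0.3, 0.2, 0.2, 0.3)
  w <- synthetic_world(40000, tree, iid_root_model(pi0),
                       stationary_cf_rates(tree$lineages, pi0, nu = 0.15),
                       seed = 5)
  sim <- gen_alignment(w)
  gc_root <- mean(is_gc(sim$sequences$root))
  se <- sqrt(0.4 * 0.6 / w$genome_length)
  for (nm in c("A", "B", "C")) {
    expect_lt(abs(mean(is_gc(sim$sequences[[nm]])) - gc_root), 3 * se)
  }
})

test_that("generation is bit-identical for identical spec and seed", {
  w <- small_world(2000, seed = 99)
  s1 <- gen_alignment(w)
  s2 <- gen_alignment(w)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$events, s2$events)
})

test_that("occupancy track is a deterministic increasing function of windowed G+C", {
  seq_ga <- c(rep(3L, 50), rep(1L, 50))
  tr <- gen_occupancy_track(seq_ga, window = 10, coupling = 1, noise_sd = 0)
  tr2 <- gen_occupancy_track(seq_ga, window = 10, coupling = 1, noise_sd = 0)
  expect_identical(tr, tr2)
  # windows with identical G+C get identical scores
  expect_equal(tr[5], tr[6])
  # all-G strictly above all-A
  g_track <- gen_occupancy_track(rep(3L, 100), 10, 1, 0)
  a_track <- gen_occupancy_track(rep(1L, 100), 10, 1, 0)
  expect_true(all(g_track > a_track))
  expect_error(gen_occupancy_track(rep(1L, 5), window = 10), "window")
})

test_that("occupancy track correlates strongly with windowed G+C at low noise", {
  w <- small_world(50000, seed = 2)
  sim <- gen_alignment(w)
  s <- sim$sequences$A
  tr <- gen_occupancy_track(s, 20, coupling = 1, noise_sd = 0.1, seed = 4)
  base <- gen_occupancy_track(s, 20, coupling = 1, noise_sd = 0)
  expect_gt(cor(tr, base), 0.9)
})

test_that("calibrated track matches the requested low/high class fractions", {
  w <- small_world(50000, seed = 8)
  sim <- gen_alignment(w)
  tr <- gen_occupancy_track(sim$sequences$A, 20, 1, 0.3, calibrate = TRUE,
                            seed = 9)
  cls <- classify_occupancy(tr)
  expect_lt(abs(mean(cls == "low") - 0.14), 0.01)
  expect_lt(abs(mean(cls == "high") - 0.21), 0.01)
})

test_that("planting compensatory pairs honors excess, distance and eligibility", {
  w <- small_world(20000, seed = 21)
  sim <- gen_alignment(w)
  same <- plant_compensatory_events(sim, "A", horizon = 5, excess = 0)
  expect_identical(same$sequences, sim$sequences)
  expect_equal(nrow(same$planted_pairs), 0)

  planted <- plant_compensatory_events(sim, "A", horizon = 5, excess = 2,
                                       seed = 7)
  pp <- planted$planted_pairs
  expect_equal(nrow(pp), round(2 * 20000 / 1000))
  expect_true(all(abs(pp$position_gain - pp$position_loss) <= 5))
  expect_true(all(pp$position_gain != pp$position_loss))
  # planted events present in the modified child sequence
  expect_true(all(planted$sequences$A[pp$position_loss] %in% GC_CODES))
  expect_true(all(planted$sequences$A[pp$position_gain] %in% AT_CODES))

  # no eligible sites: an all-A/T conserved genome has no C/G gain sites
  tree <- tree2()
  wat <- synthetic_world(300, tree, iid_root_model(c(0.5, 0, 0, 0.5)),
                         uniform_context_rates(tree$lineages, 0), seed = 1)
  simat <- gen_alignment(wat)
  expect_error(plant_compensatory_events(simat, "A", 5, excess = 2),
               "eligible")
})

test_that("SNP panel: two strains give only 50/50 sites; classes respect the map", {
  panel <- gen_snp_panel(n_strains = 2, n_snps = 200,
                         class_selection = c(AT_gain = 0, AT_loss = 0),
                         min_called = 2, max_called = 2, seed = 1)
  expect_true(all(panel$count2 / panel$n_called == 0.5))
  expect_error(gen_snp_panel(2, 10, class_selection = numeric(0)), "non-empty")
  expect_error(gen_snp_panel(1, 10, class_selection = c(a = 0)), "n_strains")
  expect_error(gen_snp_panel(5, 10, class_selection = c(a = Inf)), "finite")
})

test_that("selection tilts the minor-allele spectrum toward rare alleles", {
  panel <- gen_snp_panel(39, 8000,
                         class_selection = c(AT_loss = -6, AT_conserving = 0),
                         seed = 12)
  cl <- classify_snps(filter_snps(panel))
  rf <- rare_fraction(cl, by = "direction")
  f_loss <- rf$fraction[rf$direction == "AT_loss"]
  f_neut <- rf$fraction[rf$direction == "AT_conserving"]
  expect_gt(f_loss, f_neut)
})

test_that("neutral classes have statistically equal rare fractions", {
  panel <- gen_snp_panel(39, 8000,
                         class_selection = c(AT_gain = 0, AT_loss = 0),
                         seed = 13)
  cl <- classify_snps(filter_snps(panel))
  rf <- rare_fraction(cl, by = "direction")
  res <- compare_classes(rf[rf$direction == "AT_gain", ],
                         rf[rf$direction == "AT_loss", ])
  expect_gt(res$p_value, 0.01)
})
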