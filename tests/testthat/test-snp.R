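# SNP filtering, classification and rare-allele-fraction comparisons.

snp_row <- function(a1, a2, c1, c2, n, f5 = "A", f3 = "A",
                    occ = "low", inter = TRUE, nall = 2L) {
  data.frame(pos = 1L, a1 = a1, a2 = a2, count1 = c1, count2 = c2,
             n_called = n, flank5 = f5, flank3 = f3, occupancy = occ,
             intergenic = inter, n_alleles = nall, stringsAsFactors = FALSE)
}

test_that("filters keep intergenic biallelic sites called in more than 20 strains", {
  recs <- rbind(
    snp_row("C", "T", 10, 9, 19),            # too few strains
    snp_row("C", "T", 15, 10, 25, nall = 3L), # triallelic
    snp_row("C", "T", 20, 10, 30),            # kept
    snp_row("C", "T", 20, 10, 30, inter = FALSE),  # genic
    snp_row("C", "T", 21, 0, 21))             # monomorphic calls
  kept <- filter_snps(recs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$n_called, 30)
  # exactly 21 called strains passes the strict > 20 filter
  expect_equal(nrow(filter_snps(snp_row("A", "G", 11, 10, 21))), 1)
  expect_equal(nrow(filter_snps(snp_row("A", "G", 10, 10, 20))), 0)
})

test_that("direction and context classification follow the major/minor rule", {
  cl <- classify_snps(rbind(
    snp_row("C", "T", 25, 10, 35),            # major C, minor T: AT_gain
    snp_row("T", "G", 20, 5, 25),             # major T, minor G: AT_loss
    snp_row("A", "T", 18, 9, 27),             # both A/T: conserving
    snp_row("C", "G", 22, 8, 30),             # both C/G: conserving
    snp_row("C", "A", 12, 12, 24),            # tie: excluded
    snp_row("G", "T", 19, 7, 26, f5 = "G", f3 = "C")))
  expect_equal(attr(cl, "n_ties"), 1)
  expect_equal(nrow(cl), 5)
  expect_equal(cl$direction,
               c("AT_gain", "AT_loss", "AT_conserving", "AT_conserving",
                 "AT_gain"))
  expect_equal(cl$context[6 - 1], "GC_flanked")
  expect_equal(cl$context[1], "non_GC")
})

test_that("classification is invariant under strand complement", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  recs <- filter_snps(gen_snp_panel(
    39, 300, class_selection = c(AT_gain = 0, AT_loss = -2,
                                 AT_conserving = 0), seed = 6))
  cl <- classify_snps(recs)
  flipped <- recs
  flipped$a1 <- unname(comp[recs$a1]); flipped$a2 <- unname(comp[recs$a2])
  flipped$flank5 <- unname(comp[recs$flank3])
  flipped$flank3 <- unname(comp[recs$flank5])
  cl2 <- classify_snps(flipped)
  expect_equal(cl$direction, cl2$direction)
  expect_equal(cl$context, cl2$context)
})

test_that("rare fractions use a strict threshold on per-site frequencies", {
  recs <- rbind(
    snp_row("C", "T", 27, 3, 30),    # maf 0.10
    snp_row("C", "T", 30, 10, 40),   # maf 0.25
    snp_row("C", "T", 34, 6, 40))    # maf 0.15
  cl <- classify_snps(recs)
  rf <- rare_fraction(cl, threshold = 0.20, by = "direction")
  expect_equal(rf$fraction, 2 / 3)
  # folding bound: every minor frequency is below 0.5
  rf5 <- rare_fraction(cl, threshold = 0.5, by = "direction")
  expect_equal(rf5$fraction, 1)
  # robustness thresholds are runnable
  expect_equal(rare_fraction(cl, 0.14, by = "direction")$fraction, 1 / 3)
  expect_equal(rare_fraction(cl, 0.30, by = "direction")$fraction, 1)
  expect_error(rare_fraction(cl, 0.6), "threshold")
})

test_that("direction classes partition the filtered SNPs", {
  panel <- gen_snp_panel(39, 2000,
                         class_selection = c(AT_gain = 0, AT_loss = -1,
                                             AT_conserving = 1), seed = 9)
  kept <- filter_snps(panel)
  cl <- classify_snps(kept)
  rf <- rare_fraction(cl, by = "direction")
  expect_equal(sum(rf$n_snps) + attr(cl, "n_ties"), nrow(kept))
})

test_that("the 2x2 chi-squared comparison matches the Pearson formula", {
  pearson <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  a <- list(n_snps = 100, n_rare = 50)
  b <- list(n_snps = 100, n_rare = 20)
  res <- compare_classes(a, b)
  expect_equal(res$statistic, pearson(rbind(c(50, 50), c(20, 80))),
               tolerance = 1e-12)
  expect_equal(res$statistic, 19.78022, tolerance = 1e-6)
  expect_equal(res$df, 1L)
  # identical proportions: statistic 0, p 1
  res0 <- compare_classes(list(n_snps = 100, n_rare = 30),
                          list(n_snps = 200, n_rare = 60))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(compare_classes(list(n_snps = 0, n_rare = 0), a), "non-empty")
  # tiny counts flag low expected cells
  res_small <- compare_classes(list(n_snps = 3, n_rare = 1),
                               list(n_snps = 2, n_rare = 0))
  expect_true(res_small$low_expected)
})
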