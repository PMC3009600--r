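# Polymorphism classification and rare-allele-fraction comparisons.
#
# A SNP table is a data frame with columns: pos, a1, a2 (alleles, letters),
# count1, count2 (strain counts), n_called, flank5, flank3 (reference
# flanking bases), occupancy (class label), intergenic (logical). The
# generator in gen_snp_panel() produces this layout.

#' Filter SNPs to informative sites
#'
#' Keeps intergenic, biallelic sites (both alleles observed) with sequence
#' data from more than `min_strains` strains.
#'
#' @param records SNP data frame.
#' @param min_strains strict lower bound on called strains (default 20).
#' @return the filtered data frame (possibly empty).
#' @export
filter_snps <- function(records, min_strains = 20) {
  keep <- records$intergenic &
    records$n_called > min_strains &
    records$count1 >= 1 & records$count2 >= 1
  if ("n_alleles" %in% names(records)) keep <- keep & records$n_alleles == 2
  records[keep, , drop = FALSE]
}

#' Classify SNPs by A/T direction, flanking context and occupancy
#'
#' The major allele is the more abundant one. Direction: a C/G major with
#' an A/T minor is "AT_gain" (the minor allele is a candidate A/T-gaining
#' mutation on a C/G background); the reciprocal is "AT_loss"; all other
#' SNPs are "AT_conserving". Context is "GC_flanked" iff both
#' reference flanks are G or C. Sites with an exact 50/50 allele-count tie
#' have no major allele and are excluded (tallied in the `n_ties`
#' attribute).
#'
#' @param records filtered SNP data frame.
#' @return the data frame with added columns major, minor, minor_count,
#'   maf, direction, context; attribute `n_ties` counts excluded ties.
#' @export
classify_snps <- function(records) {
  tie <- records$count1 == records$count2
  out <- records[!tie, , drop = FALSE]
  maj_is_1 <- out$count1 > out$count2
  out$major <- ifelse(maj_is_1, out$a1, out$a2)
  out$minor <- ifelse(maj_is_1, out$a2, out$a1)
  out$minor_count <- pmin(out$count1, out$count2)
  out$maf <- out$minor_count / out$n_called
  maj_gc <- out$major %in% c("C", "G")
  min_gc <- out$minor %in% c("C", "G")
  out$direction <- ifelse(maj_gc & !min_gc, "AT_gain",
                   ifelse(!maj_gc & min_gc, "AT_loss", "AT_conserving"))
  out$context <- ifelse(out$flank5 %in% c("C", "G") &
                          out$flank3 %in% c("C", "G"),
                        "GC_flanked", "non_GC")
  attr(out, "n_ties") <- sum(tie)
  out
}

#' Fraction of rare alleles per SNP class
#'
#' A SNP is rare when its minor-allele frequency (minor count over called
#' strains) is strictly below `threshold`.
#'
#' @param classified output of [classify_snps()].
#' @param threshold rare-allele frequency threshold in (0, 0.5]
#'   (default 0.20; 0.14 and 0.3 are the usual robustness alternatives).
#' @param by grouping columns (default direction, context, occupancy).
#' @return data frame with the grouping columns, n_snps, n_rare, fraction
#'   (`NA` and flagged for empty classes).
#' @export
rare_fraction <- function(classified, threshold = 0.20,
                          by = c("direction", "context", "occupancy")) {
  if (threshold <= 0 || threshold > 0.5) stop("threshold must be in (0, 0.5]")
  by <- intersect(by, names(classified))
  rare <- classified$maf < threshold
  key <- interaction(classified[by], drop = FALSE, sep = "|")
  lev <- levels(key)
  res <- do.call(rbind, lapply(lev, function(k) {
    sel <- key == k
    n <- sum(sel)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    row <- as.data.frame(as.list(parts), stringsAsFactors = FALSE)
    names(row) <- by
    row$n_snps <- n
    row$n_rare <- sum(rare[sel])
    row$fraction <- if (n > 0) sum(rare[sel]) / n else NA_real_
    row$empty <- n == 0
    row
  }))
  rownames(res) <- NULL
  res
}

#' Chi-squared comparison of rare-allele fractions between two classes
#'
#' Pearson 2x2 test (rare vs non-rare by class), one degree of freedom,
#' without continuity correction. A warning flag is attached when any
#' expected cell count falls below 1.
#'
#' @param summaryA,summaryB single rows of a [rare_fraction()] table (or
#'   any lists with `n_snps` and `n_rare`).
#' @return list with statistic, df, p_value, expected counts and
#'   `low_expected` flag.
#' @export
compare_classes <- function(summaryA, summaryB) {
  nA <- summaryA$n_snps; rA <- summaryA$n_rare
  nB <- summaryB$n_snps; rB <- summaryB$n_rare
  if (!nA || !nB) stop("both classes must be non-empty")
  tab <- rbind(c(rA, nA - rA), c(rB, nB - rB))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (identical(tab[1, ] / nA, tab[2, ] / nB) ||
      all(abs(tab[1, ] / nA - tab[2, ] / nB) < .Machine$double.eps)) {
    return(list(statistic = 0, df = 1L, p_value = 1,
                expected = expected, low_expected = any(expected < 1)))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L,
       p_value = unname(ct$p.value), expected = expected,
       low_expected = any(expected < 1))
}
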