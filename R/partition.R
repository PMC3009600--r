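# Classify genomic positions by nucleosome occupancy and TSS proximity and
# compute sequence-composition statistics (window G+C spectra, trinucleotide
# frequencies).

#' Threshold classification of an occupancy track
#'
#' Scores below `low_thr` are "low", above `high_thr` "high", otherwise
#' "mid". Comparisons are strict, so boundary values fall in "mid".
#'
#' @param track numeric vector of per-position occupancy scores (log scale,
#'   genome-mean centered). Must be finite.
#' @param low_thr,high_thr class thresholds (default -2.5 and 0.4);
#'   `low_thr < high_thr` required.
#' @return factor with levels low/mid/high, one per position.
#' @export
classify_occupancy <- function(track, low_thr = -2.5, high_thr = 0.4) {
  if (!(low_thr < high_thr)) stop("low_thr must be < high_thr")
  if (any(!is.finite(track))) stop("occupancy scores must be finite")
  cls <- rep("mid", length(track))
  cls[track < low_thr] <- "low"
  cls[track > high_thr] <- "high"
  factor(cls, levels = c("low", "mid", "high"))
}

#' Equal-sized occupancy-rank bins
#'
#' Partitions positions into `k` occupancy-quantile bins whose sizes differ
#' by at most one (lowest scores in bin 1). Ties are broken by genomic
#' coordinate for reproducibility.
#'
#' @param track numeric vector of scores.
#' @param k number of bins (2 <= k <= length(track)).
#' @return integer vector of bin indices in 1..k.
#' @export
bin_occupancy <- function(track, k) {
  n <- length(track)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of positions")
  ord <- order(track, seq_len(n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  bins <- integer(n)
  bins[ord] <- rep.int(seq_len(k), sizes)
  bins
}

#' TSS-proximity classification
#'
#' Non-exonic positions within `d` bp (inclusive) of an annotated TSS are
#' "proximal"; other non-exonic positions are "distal"; exonic positions are
#' "excluded". Distance is to the TSS coordinate, strand-agnostic.
#'
#' @param genome_length total number of positions (1-based coordinates).
#' @param tss_positions integer TSS coordinates in `[1, genome_length]`.
#' @param exon_intervals data frame with 1-based closed `start`, `end`
#'   columns, or NULL.
#' @param d proximity distance in bp (default 200).
#' @return factor with levels proximal/distal/excluded, one per position.
#' @export
classify_proximity <- function(genome_length, tss_positions,
                               exon_intervals = NULL, d = 200) {
  L <- as.integer(genome_length)
  if (length(tss_positions) &&
      (min(tss_positions) < 1 || max(tss_positions) > L)) {
    stop("TSS coordinates outside the genome")
  }
  exonic <- logical(L)
  if (!is.null(exon_intervals) && nrow(exon_intervals)) {
    for (i in seq_len(nrow(exon_intervals))) {
      exonic[exon_intervals$start[i]:exon_intervals$end[i]] <- TRUE
    }
  }
  near <- logical(L)
  for (t in unique(as.integer(tss_positions))) {
    near[max(1L, t - as.integer(d)):min(L, t + as.integer(d))] <- TRUE
  }
  cls <- ifelse(exonic, "excluded", ifelse(near, "proximal", "distal"))
  factor(cls, levels = c("proximal", "distal", "excluded"))
}

#' G+C fraction in non-overlapping windows
#'
#' @param sequence integer-coded sequence (1..4).
#' @param w window width in bp (>= 1). A trailing partial window is dropped.
#' @return numeric vector of window G+C fractions in `[0, 1]`.
#' @export
gc_windows <- function(sequence, w = 20) {
  if (!length(sequence)) stop("empty sequence")
  if (w < 1) stop("w must be >= 1")
  n_win <- length(sequence) %/% w
  if (n_win == 0) stop("sequence shorter than one window")
  gc <- as.numeric(is_gc(sequence[seq_len(n_win * w)]))
  colMeans(matrix(gc, nrow = w))
}

#' Binned log-ratio of two window-G+C densities
#'
#' Compares the empirical density of observed window G+C values against a
#' reference sample on a shared set of bins.
#'
#' @param observed_windows,reference_windows numeric vectors of window G+C
#'   fractions (both non-empty).
#' @param breaks bin breaks on `[0, 1]` (default 21 equal bins, matching
#'   20 bp windows).
#' @return data frame with `mid` (bin midpoint), `density_obs`,
#'   `density_ref` and `log_ratio`; bins with zero reference density get
#'   `NA` log-ratio and are flagged in the `zero_reference` column.
#' @export
gc_distribution_logratio <- function(observed_windows, reference_windows,
                                     breaks = seq(-1 / 40, 1 + 1 / 40,
                                                  length.out = 22)) {
  if (!length(observed_windows) || !length(reference_windows)) {
    stop("both window samples must be non-empty")
  }
  breaks[1] <- min(breaks[1], min(observed_windows, reference_windows) - 1e-9)
  breaks[length(breaks)] <- max(breaks[length(breaks)],
                                max(observed_windows, reference_windows) + 1e-9)
  co <- tabulate(cut(observed_windows, breaks, labels = FALSE),
                 length(breaks) - 1)
  cr <- tabulate(cut(reference_windows, breaks, labels = FALSE),
                 length(breaks) - 1)
  if (!any(co > 0 & cr > 0)) stop("observed and reference densities do not overlap")
  d_obs <- co / sum(co)
  d_ref <- cr / sum(cr)
  lr <- ifelse(cr > 0, log(d_obs / d_ref), NA_real_)
  lr[cr > 0 & co == 0] <- -Inf
  data.frame(mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
             density_obs = d_obs, density_ref = d_ref,
             log_ratio = lr, zero_reference = cr == 0)
}

# The 32 reverse-complement trinucleotide equivalence classes, named by the
# lexicographically smaller member, e.g. "AAA/TTT".
trinuc_classes <- function() {
  all_tri <- apply(expand.grid(NUC, NUC, NUC)[, 3:1], 1, paste, collapse = "")
  rc_of <- vapply(all_tri, function(t) decode_seq(revcomp(encode_seq(t))), "")
  key <- ifelse(all_tri <= rc_of, all_tri, rc_of)
  classes <- sort(unique(key))
  list(all = all_tri, key = key, classes = classes)
}

#' Reverse-complement-averaged trinucleotide frequencies
#'
#' Counts every overlapping trinucleotide fully inside the masked region and
#' merges reverse-complement pairs into 32 equivalence classes.
#'
#' @param sequence integer-coded sequence (1..4).
#' @param mask optional logical vector (TRUE = position included); only
#'   trinucleotides whose three positions are all included are counted.
#' @return named numeric vector of 32 class frequencies summing to 1; names
#'   are "XYZ/rc(XYZ)" with the lexicographically smaller member first.
#' @export
trinuc_freqs <- function(sequence, mask = NULL) {
  L <- length(sequence)
  if (is.null(mask)) mask <- rep(TRUE, L)
  stopifnot(length(mask) == L)
  i <- seq_len(max(0L, L - 2L))
  keep <- mask[i] & mask[i + 1L] & mask[i + 2L] &
    !is.na(sequence[i]) & !is.na(sequence[i + 1L]) & !is.na(sequence[i + 2L])
  if (!any(keep)) stop("masked region shorter than 3 positions")
  flat <- sequence[i][keep] + (sequence[i + 1L][keep] - 1L) * 4L +
    (sequence[i + 2L][keep] - 1L) * 16L
  counts64 <- tabulate(flat, 64L)
  tc <- trinuc_classes()
  # column-major flat index: first base fastest; reconstruct each trinuc name
  names(counts64) <- apply(expand.grid(NUC, NUC, NUC), 1, function(r)
    paste0(r[1], r[2], r[3]))
  cls <- vapply(names(counts64), function(t) {
    rc <- decode_seq(revcomp(encode_seq(t)))
    cname <- if (t <= rc) paste(t, rc, sep = "/") else paste(rc, t, sep = "/")
    cname
  }, "")
  out <- tapply(counts64, cls, sum)
  res <- setNames(as.numeric(out), names(out))
  res / sum(res)
}
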