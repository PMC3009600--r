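# Plain-text interchange: FASTA via Biostrings, Newick via ape, tracks and
# tables as bedGraph/BED/TSV. Alignments are exchanged as aligned FASTA
# (synthetic alignments are gapless single-block).

#' Write node sequences as FASTA
#' @param seqs named list of integer-coded sequences, or a
#'   `synthetic_alignment` (all node sequences are written).
#' @param path output file.
#' @export
write_fasta_seqs <- function(seqs, path) {
  if (inherits(seqs, "synthetic_alignment")) seqs <- seqs$sequences
  x <- Biostrings::DNAStringSet(vapply(seqs, decode_seq, ""))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into integer-coded sequences
#' @param path FASTA file.
#' @return named list of integer-coded sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(lapply(as.character(x), encode_seq), names(x))
}

#' Write an occupancy track as bedGraph
#' @param track numeric per-position scores.
#' @param path output file.
#' @param chrom chromosome name.
#' @export
write_bedgraph <- function(track, path, chrom = "chrS") {
  df <- data.frame(chrom = chrom, start = seq_along(track) - 1L,
                   end = seq_along(track), score = track)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph occupancy track into a per-position vector
#' @param path bedGraph file.
#' @param genome_length track length (positions without a record get NA).
#' @return numeric vector.
#' @export
read_bedgraph <- function(path, genome_length) {
  df <- read.table(path, sep = "\t", col.names = c("chrom", "start", "end",
                                                   "score"))
  track <- rep(NA_real_, genome_length)
  for (i in seq_len(nrow(df))) {
    track[(df$start[i] + 1L):df$end[i]] <- df$score[i]
  }
  track
}

#' Write intervals as BED (0-based half-open on disk)
#' @param intervals data frame with 1-based closed `start`, `end`.
#' @param path output file.
#' @param chrom chromosome name.
#' @export
write_bed <- function(intervals, path, chrom = "chrS") {
  df <- data.frame(chrom = chrom, start = intervals$start - 1L,
                   end = intervals$end)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tree as Newick
#' @param tree a `lineage_tree`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' Write a rate set as a long-format TSV
#'
#' Columns: lineage, five, three, from, to, rate.
#' @param rates a `context_rates`.
#' @param path output file.
#' @export
write_rates_tsv <- function(rates, path) {
  rows <- list()
  for (nm in names(rates)) {
    a <- rates[[nm]]
    grid <- expand.grid(from = 1:4, five = 1:4, three = 1:4, to = 1:4)
    rows[[nm]] <- data.frame(
      lineage = nm, five = NUC[grid$five], three = NUC[grid$three],
      from = NUC[grid$from], to = NUC[grid$to],
      rate = a[as.matrix(grid[, c("from", "five", "three", "to")])])
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rate set from the long-format TSV
#' @param path TSV written by [write_rates_tsv()].
#' @return a `context_rates`.
#' @export
read_rates_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "character",
                                  "character", "character", "numeric"))
  tabs <- lapply(split(df, df$lineage), function(d) {
    a <- array(0, rep(4L, 4L))
    a[cbind(match(d$from, NUC), match(d$five, NUC), match(d$three, NUC),
            match(d$to, NUC))] <- d$rate
    a
  })
  context_rates(tabs)
}
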