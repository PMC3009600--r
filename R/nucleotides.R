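#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @useDynLib compevo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois rbinom rhyper setNames quantile sd
#'   chisq.test ks.test
#' @importFrom utils head tail write.table read.table
## usethis namespace: end
NULL

# Nucleotide alphabet used throughout: integer codes 1..4 = A, C, G, T.
NUC <- c("A", "C", "G", "T")
RC <- c(4L, 3L, 2L, 1L)         # A<->T, C<->G
GC_CODES <- c(2L, 3L)           # C, G
AT_CODES <- c(1L, 4L)           # A, T

#' Encode a nucleotide string as integer codes
#'
#' @param x a character scalar (e.g. "ACGT") or character vector of single
#'   letters. Case-insensitive. Characters outside A/C/G/T map to `NA`.
#' @return integer vector with codes 1..4 (A, C, G, T).
#' @export
encode_seq <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) {
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  }
  match(toupper(x), NUC)
}

#' Decode integer nucleotide codes to a string
#'
#' @param x integer vector of codes 1..4.
#' @return a character scalar.
#' @export
decode_seq <- function(x) {
  paste(ifelse(is.na(x), "N", NUC[x]), collapse = "")
}

#' Reverse complement of an encoded sequence
#' @param x integer vector of codes 1..4.
#' @return integer vector, reverse-complemented.
#' @export
revcomp <- function(x) rev(RC[x])

#' G+C indicator of an encoded sequence
#' @param x integer vector of codes 1..4.
#' @return logical vector, `TRUE` where the base is G or C.
#' @export
is_gc <- function(x) x %in% GC_CODES

gc_fraction <- function(x) mean(is_gc(x))
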