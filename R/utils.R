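#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange left_join group_by summarise
#'   ungroup bind_rows row_number n rename relocate distinct pull across
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_chr map_lgl pmap imap list_rbind
#' @importFrom stats quantile rnorm rpois runif t.test pnorm pt qnorm sd setNames
#' @importFrom utils head tail
NULL

# Single place for the DNA alphabet used by the simulators.
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] so that
#' every strand flip in the package goes through one audited path.
#'
#' @param x Character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return Character vector of reverse-complemented, uppercased sequences.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# Split a sequence string into single characters.
str_bases <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Deterministic sub-seed derivation: one user seed fans out to per-stage
# streams without reuse.  Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9973) %% 2147483629) + 1L
}

# Interval overlap length for 1-based inclusive coordinates (0 when disjoint).
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

assert_scalar_interval <- function(start, end, what = "interval") {
  if (length(start) != 1 || length(end) != 1 || is.na(start) || is.na(end) ||
      start < 1 || end < start) {
    abort(sprintf("invalid %s: start=%s end=%s", what, start, end))
  }
  invisible(TRUE)
}
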