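CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Count compensatory basepair changes in a structural alignment
#'
#' For each basepair `(i, j)` of the consensus structure, collects the set of
#' canonical pair types (AU, UA, GC, CG, GU, UG) realised across the aligned
#' sequences, ignoring rows gapped at `i` or `j`.  A pair is compensatory
#' when at least two distinct canonical types occur — the partners substitute
#' jointly while preserving pairing, the classic signature of structural
#' selection.  Pairs with no canonical realisation are reported separately
#' as inconsistent.
#'
#' @param seqs Character vector of aligned RNA (or DNA; `T` is read as `U`)
#'   sequences of equal length, gaps `-`.
#' @param structure Consensus structure: a dot-bracket string or a
#'   [parse_dot_bracket()] result of the alignment length.
#' @return Object of class `covariation_report`: list with `n_pairs`,
#'   `n_compensatory`, `n_inconsistent` and a per-pair tibble `pairs`
#'   (`i`, `j`, `types`, `n_types`, `compensatory`).
#' @examples
#' count_compensatory(c("GAAAC", "CAAAG"), "(...)")
#' @export
count_compensatory <- function(seqs, structure) {
  if (is.character(structure)) structure <- parse_dot_bracket(structure)
  seqs <- chartr("tT", "uU", toupper(seqs))
  seqs <- chartr("u", "U", seqs)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) abort("aligned sequences must have equal length")
  if (lens != structure$length) {
    abort("alignment length does not match structure length")
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  pair_row <- function(i, j) {
    left <- mat[, i]; right <- mat[, j]
    keep <- left != "-" & right != "-"
    types <- unique(paste0(left[keep], right[keep]))
    canonical <- sort(intersect(types, CANONICAL_PAIRS))
    tibble(i = i, j = j, types = list(canonical),
           n_types = length(canonical),
           compensatory = length(canonical) >= 2,
           inconsistent = length(canonical) == 0)
  }
  pairs <- if (nrow(structure$pairs) == 0) {
    tibble(i = integer(0), j = integer(0), types = list(),
           n_types = integer(0), compensatory = logical(0),
           inconsistent = logical(0))
  } else {
    list_rbind(map(seq_len(nrow(structure$pairs)), function(k) {
      pair_row(structure$pairs$i[k], structure$pairs$j[k])
    }))
  }
  res <- list(
    n_pairs = nrow(pairs),
    n_compensatory = sum(pairs$compensatory),
    n_inconsistent = sum(pairs$inconsistent),
    pairs = pairs
  )
  class(res) <- "covariation_report"
  res
}

#' @export
print.covariation_report <- function(x, ...) {
  cat(sprintf("<covariation_report> %d pairs, %d compensatory, %d inconsistent\n",
              x$n_pairs, x$n_compensatory, x$n_inconsistent))
  invisible(x)
}

#' @export
tidy.covariation_report <- function(x, ...) x$pairs

#' @export
glance.covariation_report <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_compensatory = x$n_compensatory,
         n_inconsistent = x$n_inconsistent)
}

#' Basepairs shared between a pairwise and a multi-genome structure
#'
#' Maps every basepair of the pairwise-alignment consensus structure into
#' multi-alignment columns and counts how many also pair in the multi-genome
#' consensus.  The reported fraction uses the pairwise structure's pair count
#' as denominator (so it is bounded by 1), and is 0 when the pairwise
#' structure has no pairs.
#'
#' @param pairwise_structure,multi_structure Dot-bracket strings or
#'   [parse_dot_bracket()] results.
#' @param column_map Integer vector, one entry per pairwise-alignment column,
#'   giving the corresponding multi-alignment column (`NA` = unmappable;
#'   such pairs are skipped and counted in `n_skipped`).
#' @return List with `n_shared`, `fraction`, `n_pairwise`, `n_skipped`.
#' @export
shared_pairs <- function(pairwise_structure, multi_structure, column_map) {
  if (is.character(pairwise_structure)) {
    pairwise_structure <- parse_dot_bracket(pairwise_structure)
  }
  if (is.character(multi_structure)) {
    multi_structure <- parse_dot_bracket(multi_structure)
  }
  if (length(column_map) != pairwise_structure$length) {
    abort("column_map must have one entry per pairwise-alignment column")
  }
  pw <- pairwise_structure$pairs
  n_pw <- nrow(pw)
  if (n_pw == 0) {
    return(list(n_shared = 0L, fraction = 0, n_pairwise = 0L, n_skipped = 0L))
  }
  multi_keys <- paste(multi_structure$pairs$i, multi_structure$pairs$j)
  mi <- column_map[pw$i]
  mj <- column_map[pw$j]
  skipped <- is.na(mi) | is.na(mj)
  keys <- paste(pmin(mi, mj), pmax(mi, mj))
  shared <- sum(!skipped & keys %in% multi_keys)
  list(n_shared = as.integer(shared), fraction = shared / n_pw,
       n_pairwise = as.integer(n_pw), n_skipped = as.integer(sum(skipped)))
}
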