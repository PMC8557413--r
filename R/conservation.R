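#' Map an interval between genomes through an offset map
#'
#' Translates a 1-based inclusive interval of genome A into genome B (or the
#' reverse) using the blockwise coordinate correspondence of an
#' [offset_map()].  The interval maps through the single block covering the
#' largest share of it; if that share is below `min_cover` the interval is
#' unmappable.  Reverse-orientation blocks flip the interval and strand.
#'
#' @param map An [offset_map()].
#' @param start,end Interval to map.
#' @param direction `"a_to_b"` (default) or `"b_to_a"`.
#' @param min_cover Minimum fraction of the interval a block must cover;
#'   default 0.5.
#' @return One-row tibble with `start`, `end`, `flipped` (logical),
#'   `cover` (fraction of the interval inside the block) and `straddle`
#'   (TRUE when a second block also overlapped the interval), or a zero-row
#'   tibble when unmappable.
#' @export
map_coordinates <- function(map, start, end, direction = c("a_to_b", "b_to_a"),
                            min_cover = 0.5) {
  direction <- match.arg(direction)
  assert_scalar_interval(start, end)
  if (direction == "a_to_b") {
    src_s <- map$a_start; src_e <- map$a_end
    dst_s <- map$b_start; dst_e <- map$b_end
  } else {
    src_s <- map$b_start; src_e <- map$b_end
    dst_s <- map$a_start; dst_e <- map$a_end
  }
  ov <- overlap_len(start, end, src_s, src_e)
  empty <- tibble(start = integer(0), end = integer(0), flipped = logical(0),
                  cover = double(0), straddle = logical(0))
  if (all(ov == 0)) return(empty)
  best <- which.max(ov)
  cover <- ov[best] / (end - start + 1)
  if (cover < min_cover) return(empty)
  if (map$orientation[best] == "+") {
    new_s <- dst_s[best] + (start - src_s[best])
    new_e <- dst_s[best] + (end - src_s[best])
    flipped <- FALSE
  } else {
    new_s <- dst_e[best] - (end - src_s[best])
    new_e <- dst_e[best] - (start - src_s[best])
    flipped <- TRUE
  }
  tibble(start = as.integer(new_s), end = as.integer(new_e),
         flipped = flipped, cover = cover,
         straddle = sum(ov > 0) > 1)
}

# TRUE iff every base of [start, end] has depth >= min_depth in a sparse
# coverage tibble (absent positions count as depth 0).
interval_covered <- function(coverage, start, end, min_depth = 1) {
  if (is.null(coverage)) return(NA)
  sel <- coverage$pos >= start & coverage$pos <= end &
    coverage$depth >= min_depth
  length(unique(coverage$pos[sel])) == (end - start + 1)
}

#' Call conserved asRNAs between two lineages
#'
#' A pair of asRNAs is conserved when, after mapping lineage A coordinates
#' into lineage B, both the start and the end coordinates agree within
#' `max_offset` nt (the orthology rule for syntenic endosymbiont genomes),
#' and — when per-base coverage vectors are supplied — every base of each
#' sRNA has read depth at least `min_depth` (continuous-coverage check).
#' Each sRNA enters at most one conserved pair: candidate pairs are accepted
#' greedily by smallest total offset, ties broken by sRNA ids.
#'
#' @param srna_a,srna_b Classified sRNA tables for the two lineages.
#' @param map [offset_map()] from genome A to genome B.
#' @param coverage_a,coverage_b Optional coverage tibbles (`pos`, `depth`).
#' @param max_offset Maximum |start delta| and |end delta| in nt; default 15.
#' @param min_depth Minimum depth for the continuity check; default 1.
#' @param ends `"both"` (default) applies the rule to start and end;
#'   `"start"` to the start coordinate only.
#' @param min_cover Passed to [map_coordinates()].
#' @return Tibble of conserved pairs: `srna_a`, `srna_b`, `start_offset`,
#'   `end_offset`, `coverage_ok_a`, `coverage_ok_b`, `verdict`.
#' @export
call_conserved <- function(srna_a, srna_b, map,
                           coverage_a = NULL, coverage_b = NULL,
                           max_offset = 15, min_depth = 1,
                           ends = c("both", "start"), min_cover = 0.5) {
  ends <- match.arg(ends)
  empty <- tibble(srna_a = character(0), srna_b = character(0),
                  start_offset = integer(0), end_offset = integer(0),
                  coverage_ok_a = logical(0), coverage_ok_b = logical(0),
                  verdict = character(0))
  if (nrow(srna_a) == 0 || nrow(srna_b) == 0) return(empty)

  cand <- list()
  for (i in seq_len(nrow(srna_a))) {
    mapped <- map_coordinates(map, srna_a$start[i], srna_a$end[i],
                              min_cover = min_cover)
    if (nrow(mapped) == 0) next
    d_start <- abs(srna_b$start - mapped$start)
    d_end <- abs(srna_b$end - mapped$end)
    ok <- if (ends == "both") d_start <= max_offset & d_end <= max_offset
          else d_start <= max_offset
    for (j in which(ok)) {
      cov_a <- interval_covered(coverage_a, srna_a$start[i], srna_a$end[i],
                                min_depth)
      cov_b <- interval_covered(coverage_b, srna_b$start[j], srna_b$end[j],
                                min_depth)
      if (isFALSE(cov_a) || isFALSE(cov_b)) next
      cand[[length(cand) + 1]] <- tibble(
        srna_a = srna_a$srna_id[i], srna_b = srna_b$srna_id[j],
        start_offset = as.integer(d_start[j]), end_offset = as.integer(d_end[j]),
        coverage_ok_a = cov_a, coverage_ok_b = cov_b)
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- list_rbind(cand) |>
    mutate(total = .data$start_offset + .data$end_offset) |>
    arrange(.data$total, .data$srna_a, .data$srna_b)
  used_a <- character(0); used_b <- character(0); keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$srna_a[k] %in% used_a || cand$srna_b[k] %in% used_b) next
    keep[k] <- TRUE
    used_a <- c(used_a, cand$srna_a[k])
    used_b <- c(used_b, cand$srna_b[k])
  }
  cand[keep, ] |>
    select(-"total") |>
    mutate(verdict = "conserved") |>
    arrange(.data$srna_a)
}

#' One-sided z-proportion test for sRNA conservation
#'
#' Tests whether the proportion of conserved sRNAs exceeds the background
#' proportion of sRNAs per CDS: `p_hat = n_conserved / n_srna` against
#' `p0 = n_srna / n_cds`, with
#' `z = (p_hat - p0) / sqrt(p0 (1 - p0) / n_srna)` and an upper-tail normal
#' P-value.  No continuity correction is applied.
#'
#' @param n_conserved Number of conserved sRNAs.
#' @param n_srna Total sRNAs in the lineage.
#' @param n_cds Number of CDSs in the genome.
#' @return An `htest` object (works with `broom::tidy()`).
#' @examples
#' z_proportion_test(11, 36, 196)
#' @export
z_proportion_test <- function(n_conserved, n_srna, n_cds) {
  stopifnot(n_conserved <= n_srna, n_srna > 0, n_cds > 0)
  p0 <- n_srna / n_cds
  if (p0 >= 1) abort("degenerate null: n_srna / n_cds >= 1")
  p_hat <- n_conserved / n_srna
  z <- (p_hat - p0) / sqrt(p0 * (1 - p0) / n_srna)
  structure(list(
    statistic = c(z = z),
    p.value = pnorm(z, lower.tail = FALSE),
    estimate = c(p_hat = p_hat),
    null.value = c(p0 = p0),
    parameter = c(n = n_srna),
    alternative = "greater",
    method = "One-sided z-proportion test (conserved sRNAs vs sRNAs per CDS)",
    data.name = sprintf("%d conserved of %d sRNAs over %d CDSs",
                        n_conserved, n_srna, n_cds)
  ), class = "htest")
}
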