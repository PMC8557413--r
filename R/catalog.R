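#' Classify sRNAs relative to a genome annotation
#'
#' Bins each predicted sRNA transcript into one of three categories, the
#' standard trichotomy for bacterial small RNAs:
#'
#' * `antisense` — at least `min_overlap` nt of overlap with a CDS on the
#'   opposite strand; the target is the CDS with maximal overlap (ties break
#'   to the lexicographically smallest `feature_id`).
#' * `utr` — no antisense overlap, lies within `utr_flank` nt of a
#'   same-strand CDS without overlapping any same-strand CDS.
#' * `intergenic` — everything else.
#'
#' @param srna_tbl sRNA table (see [read_srna_table()]); all rows must lie on
#'   `genome`.
#' @param genome A [genome_record()].
#' @param utr_flank Same-strand flank (nt) defining the UTR zone; default 50.
#' @param min_overlap Minimum opposite-strand overlap (nt) to call antisense;
#'   default 1 (most inclusive).
#' @return The input tibble with `category` filled in plus `target_cds`
#'   (feature id or `NA`) and `overlap_len` (nt) columns.
#' @export
classify_srnas <- function(srna_tbl, genome, utr_flank = 50, min_overlap = 1) {
  srna_tbl <- as_tibble(srna_tbl)
  glen <- nchar(genome$sequence)
  if (nrow(srna_tbl) == 0) {
    return(mutate(srna_tbl, target_cds = character(0), overlap_len = integer(0)))
  }
  if (any(srna_tbl$end > glen) || any(srna_tbl$start < 1)) {
    abort("sRNA outside genome bounds")
  }
  f <- genome$features
  # feature_id order breaks target ties deterministically
  f <- arrange(f, .data$feature_id)
  srna_ir <- IRanges::IRanges(srna_tbl$start, srna_tbl$end)
  cds_ir <- IRanges::IRanges(f$start, f$end)
  hits <- IRanges::findOverlaps(srna_ir, cds_ir)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- overlap_len(srna_tbl$start[q], srna_tbl$end[q], f$start[s], f$end[s])
  opposite <- srna_tbl$strand[q] != f$strand[s]

  new_cat <- rep("intergenic", nrow(srna_tbl))
  new_target <- rep(NA_character_, nrow(srna_tbl))
  best_ov <- rep(NA_integer_, nrow(srna_tbl))

  # antisense: maximal opposite-strand overlap >= min_overlap
  anti <- which(opposite & ov >= min_overlap)
  if (length(anti) > 0) {
    # rows of f are id-sorted, so for equal overlap the first index wins
    ord <- anti[order(q[anti], -ov[anti], s[anti])]
    keep <- !duplicated(q[ord])
    idx <- ord[keep]
    new_cat[q[idx]] <- "antisense"
    new_target[q[idx]] <- f$feature_id[s[idx]]
    best_ov[q[idx]] <- ov[idx]
  }

  # utr: near (but not overlapping) a same-strand CDS, and not antisense
  unresolved <- which(new_cat == "intergenic")
  if (length(unresolved) > 0 && nrow(f) > 0) {
    same_overlap <- tapply(ov[!opposite], q[!opposite], max)
    overlapped_same <- as.integer(names(same_overlap))[same_overlap > 0]
    for (i in setdiff(unresolved, overlapped_same)) {
      same <- f[f$strand == srna_tbl$strand[i], ]
      if (nrow(same) == 0) next
      gap <- pmax(same$start - srna_tbl$end[i], srna_tbl$start[i] - same$end)
      if (any(gap > 0 & gap <= utr_flank)) new_cat[i] <- "utr"
    }
  }

  mutate(srna_tbl, category = new_cat, target_cds = new_target,
         overlap_len = best_ov)
}

#' Upper-quantile normalisation of a count matrix
#'
#' Scales each sample (column) so that its upper quartile (75th percentile of
#' the sample's nonzero counts) equals the across-sample reference, the mean
#' of the per-sample upper quartiles.  This is the library-size normalisation
#' used by bacterial RNA-seq transcript callers.
#'
#' @param counts Nonnegative numeric matrix, features x samples; every sample
#'   must have at least one nonzero count.
#' @return Normalised matrix with attribute `uq_factors` (the per-sample
#'   divisors).
#' @export
upper_quantile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be nonnegative")
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) abort("all-zero sample cannot be normalized")
    quantile(nz, 0.75, names = FALSE)
  })
  ref <- mean(uq)
  factors <- uq / ref
  out <- sweep(counts, 2, factors, "/")
  attr(out, "uq_factors") <- factors
  out
}

#' Filter differential-expression candidates
#'
#' Applies the two screening thresholds used for endosymbiont sRNA
#' differential expression: FDR-adjusted q-value at most `q_max` and mean raw
#' read count across replicates at least `min_mean_reads`.  The DE statistic
#' itself is consumed, not computed.
#'
#' @param srna_tbl sRNA table.
#' @param counts Matrix of raw read counts, rows aligned to `srna_tbl`
#'   (replicate columns).
#' @param qvalues Numeric vector of externally supplied q-values, one per row.
#' @param q_max,min_mean_reads Thresholds; defaults 0.05 and 9.
#' @return The rows of `srna_tbl` passing both filters, with `q_value` and
#'   `mean_reads` columns appended.
#' @export
filter_de_candidates <- function(srna_tbl, counts, qvalues,
                                 q_max = 0.05, min_mean_reads = 9) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(srna_tbl) || length(qvalues) != nrow(srna_tbl)) {
    abort("replicate count matrix / q-values do not match the sRNA table")
  }
  mean_reads <- rowMeans(counts)
  keep <- !is.na(qvalues) & qvalues <= q_max & mean_reads >= min_mean_reads
  out <- mutate(as_tibble(srna_tbl), q_value = qvalues, mean_reads = mean_reads)
  out[keep, , drop = FALSE]
}

#' Tally pathways targeted by antisense sRNAs
#'
#' Counts the distinct functional pathways whose CDSs are targeted by at
#' least one asRNA, and the subset of those pathways tied to essential
#' amino-acid biosynthesis.
#'
#' @param srna_tbl Classified sRNA table (needs `category` and `target_cds`).
#' @param pathway_map Data frame with columns `cds_id`, `pathway`,
#'   `essential_aa` (0/1 flag); `(cds_id, pathway)` pairs must be unique.
#' @return Object of class `pathway_tally`: list with `n_pathways`,
#'   `n_essential_aa`, `pathways` (per-pathway tibble with CDS lists) and
#'   `unmapped` (targeted CDS ids absent from the map).
#' @export
tally_pathways <- function(srna_tbl, pathway_map) {
  pathway_map <- as_tibble(pathway_map)
  stopifnot(all(c("cds_id", "pathway", "essential_aa") %in% names(pathway_map)))
  if (anyDuplicated(pathway_map[, c("cds_id", "pathway")]) > 0) {
    abort("pathway_map has duplicated (cds_id, pathway) pairs")
  }
  targets <- unique(srna_tbl$target_cds[srna_tbl$category == "antisense"])
  targets <- targets[!is.na(targets)]
  hit <- filter(pathway_map, .data$cds_id %in% targets)
  per_pathway <- if (nrow(hit) == 0) {
    tibble(pathway = character(0), essential_aa = logical(0),
           cds_ids = list(), n_cds = integer(0))
  } else hit |>
    group_by(.data$pathway) |>
    summarise(essential_aa = as.logical(max(.data$essential_aa)),
              cds_ids = list(sort(unique(.data$cds_id))),
              n_cds = length(cds_ids[[1]]), .groups = "drop") |>
    arrange(.data$pathway)
  unmapped <- setdiff(targets, pathway_map$cds_id)
  structure(list(
    n_pathways = nrow(per_pathway),
    n_essential_aa = sum(per_pathway$essential_aa),
    pathways = per_pathway,
    unmapped = unmapped
  ), class = "pathway_tally")
}

#' @export
print.pathway_tally <- function(x, ...) {
  cat(sprintf("<pathway_tally> %d pathways, %d essential-amino-acid pathways\n",
              x$n_pathways, x$n_essential_aa))
  if (length(x$unmapped) > 0) {
    cat("  unmapped CDSs:", paste(x$unmapped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.pathway_tally <- function(x, ...) {
  select(x$pathways, "pathway", "essential_aa", "n_cds", "cds_ids")
}

#' @export
glance.pathway_tally <- function(x, ...) {
  tibble(n_pathways = x$n_pathways, n_essential_aa = x$n_essential_aa,
         n_unmapped_cds = length(x$unmapped))
}

#' Pathway map of Carsonella asRNA target CDSs
#'
#' The packaged transcription of the published GO pathway table for the two
#' Carsonella lineages (BC from *Bactericera cockerelli*, DC from
#' *Diaphorina citri*): each row maps one targeted CDS to one pathway, with a
#' flag for essential-amino-acid biosynthesis pathways.
#'
#' @param lineage `"BC"` or `"DC"`.
#' @return Tibble with columns `cds_id`, `pathway`, `essential_aa`.
#' @export
carsonella_pathway_map <- function(lineage = c("BC", "DC")) {
  lineage <- match.arg(lineage)
  path <- system.file("extdata", "carsonella_pathway_map.tsv",
                      package = "srnacons", mustWork = TRUE)
  tbl <- readr::read_tsv(path, col_types = "ccci", progress = FALSE)
  tbl |>
    filter(.data$lineage == !!lineage) |>
    select("cds_id", "pathway", "essential_aa")
}
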