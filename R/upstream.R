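# Upstream-region extraction -------------------------------------------------

#' Extract strand-aware upstream regions
#'
#' Pulls the `length`-nt region immediately 5' of each feature's start on its
#' own strand (reverse-complemented for minus-strand features).  A region is
#' excluded with reason `"genome_edge"` when it would run off the chromosome,
#' and with reason `"cds_overlap"` when it intersects any annotated CDS other
#' than the feature's own exempt CDS.  For an asRNA the exempt CDS is its
#' target (an asRNA's upstream region lies inside its target by
#' construction); for a CDS it is the CDS itself.
#'
#' @param genome A [genome_record()].
#' @param features Data frame with columns `source_id`, `start`, `end`,
#'   `strand`, and optionally `exempt_cds` (defaults to `source_id`).
#' @param length Region length in nt; default 61.
#' @param check_overlap Apply the CDS-overlap exclusion rule; default TRUE.
#' @return Tibble with `source_id`, genomic `start`/`end` of the region,
#'   `strand`, `sequence` (5'→3' on the feature strand; position 1 of the
#'   window convention is the *last* character), `excluded`, `reason`.
#' @export
extract_upstream <- function(genome, features, length = 61,
                             check_overlap = TRUE) {
  features <- as_tibble(features)
  stopifnot(all(c("source_id", "start", "end", "strand") %in% names(features)))
  if (!"exempt_cds" %in% names(features)) {
    features$exempt_cds <- features$source_id
  }
  glen <- nchar(genome$sequence)
  cds <- genome$features
  rows <- map(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    if (f$strand == "+") {
      rs <- f$start - length; re <- f$start - 1
    } else {
      rs <- f$end + 1; re <- f$end + length
    }
    if (rs < 1 || re > glen) {
      return(tibble(source_id = f$source_id, start = NA_integer_,
                    end = NA_integer_, strand = f$strand,
                    sequence = NA_character_, excluded = TRUE,
                    reason = "genome_edge"))
    }
    excluded <- FALSE; reason <- NA_character_
    if (check_overlap && nrow(cds) > 0) {
      other <- cds[cds$feature_id != f$exempt_cds | is.na(f$exempt_cds), ]
      if (nrow(other) > 0 &&
          any(overlap_len(rs, re, other$start, other$end) > 0)) {
        excluded <- TRUE; reason <- "cds_overlap"
      }
    }
    seq <- feature_seq(genome, rs, re, f$strand)
    tibble(source_id = f$source_id, start = as.integer(rs),
           end = as.integer(re), strand = f$strand, sequence = seq,
           excluded = excluded, reason = reason)
  })
  list_rbind(rows)
}

# Composition statistics ------------------------------------------------------

#' GC percent and GC skew of nucleotide strings
#'
#' `gc_percent(x)` is `100 * (#G + #C) / length`; `gc_skew(x)` is
#' `(#C - #G) / (#C + #G)`, defined as 0 when the window has no G or C at all
#' (common in AT-rich genomes; dropping such windows would bias profiles).
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Numeric vector.
#' @examples
#' gc_percent("CCGGAAT")
#' gc_skew("CCCAAAA")
#' @export
gc_percent <- function(x) {
  x <- toupper(x)
  if (any(grepl("[^ACGT]", x))) abort("non-ACGT character in sequence")
  100 * (stringr::str_count(x, "G") + stringr::str_count(x, "C")) / nchar(x)
}

#' @rdname gc_percent
#' @export
gc_skew <- function(x) {
  x <- toupper(x)
  if (any(grepl("[^ACGT]", x))) abort("non-ACGT character in sequence")
  c_n <- stringr::str_count(x, "C")
  g_n <- stringr::str_count(x, "G")
  ifelse(c_n + g_n == 0, 0, (c_n - g_n) / (c_n + g_n))
}

#' Sliding-window scan of an upstream region
#'
#' Windows are indexed by distance from the feature start: window `w` covers
#' upstream positions `w .. w + window - 1`, where position 1 is the
#' nucleotide immediately 5' of the start.  Since [extract_upstream()] stores
#' sequences 5'→3', window `w` corresponds to string positions
#' `L + 2 - w - window .. L + 1 - w`.  A 61-nt region with 7-nt windows
#' yields exactly 55 values.
#'
#' @param sequence Upstream-region string (5'→3' on the feature strand).
#' @param stat `"gc_percent"` or `"gc_skew"`.
#' @param window Window size in nt; default 7.
#' @return Named numeric vector of `nchar(sequence) - window + 1` values
#'   (`w1`, `w2`, ...), `w1` nearest the start.
#' @export
window_scan <- function(sequence, stat = c("gc_percent", "gc_skew"),
                        window = 7) {
  stat <- match.arg(stat)
  L <- nchar(sequence)
  if (L < window) abort("region shorter than the window")
  n_win <- L - window + 1
  subs <- substring(sequence, L + 2 - seq_len(n_win) - window,
                    L + 1 - seq_len(n_win))
  f <- if (stat == "gc_percent") gc_percent else gc_skew
  setNames(f(subs), paste0("w", seq_len(n_win)))
}

# Permutation null ------------------------------------------------------------

# One mononucleotide (Fisher-Yates) or dinucleotide-preserving shuffle.
# The dinucleotide shuffle uses the classic rejection construction: permute
# each base's successor list and accept walks that use every edge.
shuffle_seq <- function(sequence, method = c("mono", "dinucleotide")) {
  method <- match.arg(method)
  chars <- str_bases(sequence)
  if (method == "mono") return(paste(sample(chars), collapse = ""))
  n <- length(chars)
  for (try in 1:200) {
    succ <- split(chars[-1], chars[-n])
    succ <- lapply(succ, sample)
    idx <- lapply(succ, function(x) 1L)
    out <- character(n)
    out[1] <- chars[1]
    ok <- TRUE
    for (k in 2:n) {
      cur <- out[k - 1]
      i <- idx[[cur]]
      if (is.null(i) || i > length(succ[[cur]])) { ok <- FALSE; break }
      out[k] <- succ[[cur]][i]
      idx[[cur]] <- i + 1L
    }
    if (ok && all(vapply(names(succ),
                         function(b) idx[[b]] == length(succ[[b]]) + 1L,
                         logical(1)))) {
      return(paste(out, collapse = ""))
    }
  }
  warn("dinucleotide shuffle did not converge; returning mononucleotide shuffle")
  paste(sample(chars), collapse = "")
}

#' Per-window GC-percent test against a sequence-reshuffle null
#'
#' For every non-excluded upstream region, the observed per-window GC percent
#' is compared with the mean of `n_shuffle` random permutations of that
#' region's sequence (each permutation preserves the region's nucleotide
#' multiset, so the null carries the region's own composition).  Per window,
#' a paired two-sided t-test across regions compares observed GC percent with
#' the per-region null means; windows with `p < alpha` are flagged, with the
#' direction of the deviation.
#'
#' @param regions Tibble from [extract_upstream()]; excluded rows are
#'   dropped.  At least 3 usable regions are required.
#' @param n_shuffle Permutations per region; default 100.
#' @param window Window size in nt; default 7.
#' @param alpha Per-window significance threshold; default 0.05.
#' @param shuffle `"mono"` (default) or `"dinucleotide"`.
#' @param p_adjust Optional multiple-testing correction passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`, matching per-window
#'   testing.
#' @param seed Optional integer seed for the permutation stream.
#' @return A `window_profile` tibble: `window`, `n_regions`, `mean_stat`,
#'   `se_stat`, `null_mean`, `t_stat`, `p_value`, `significant`, `direction`.
#' @export
gc_permutation_test <- function(regions, n_shuffle = 100, window = 7,
                                alpha = 0.05, shuffle = c("mono", "dinucleotide"),
                                p_adjust = "none", seed = NULL) {
  shuffle <- match.arg(shuffle)
  if (!is.null(seed)) withr::local_seed(seed)
  seqs <- regions$sequence[!regions$excluded]
  n_reg <- length(seqs)
  if (n_reg < 3) abort("need at least 3 non-excluded regions")
  L <- unique(nchar(seqs))
  if (length(L) != 1) abort("regions must share one length")
  n_win <- L - window + 1

  obs <- t(vapply(seqs, window_scan, numeric(n_win),
                  stat = "gc_percent", window = window, USE.NAMES = FALSE))
  null_mean <- t(vapply(seqs, function(s) {
    perms <- vapply(seq_len(n_shuffle),
                    function(i) shuffle_seq(s, shuffle), character(1))
    colMeans(t(vapply(perms, window_scan, numeric(n_win),
                      stat = "gc_percent", window = window,
                      USE.NAMES = FALSE)))
  }, numeric(n_win), USE.NAMES = FALSE))

  stats_tbl <- map(seq_len(n_win), function(w) {
    d <- obs[, w] - null_mean[, w]
    if (sd(d) == 0) {
      t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- t.test(obs[, w], null_mean[, w], paired = TRUE)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    tibble(window = w, n_regions = n_reg,
           mean_stat = mean(obs[, w]),
           se_stat = sd(obs[, w]) / sqrt(n_reg),
           null_mean = mean(null_mean[, w]),
           t_stat = t_stat, p_value = p)
  }) |> list_rbind()
  stats_tbl$p_value <- stats::p.adjust(stats_tbl$p_value, method = p_adjust)
  stats_tbl <- mutate(stats_tbl,
                      significant = .data$p_value < alpha,
                      direction = sign(.data$mean_stat - .data$null_mean))
  new_window_profile(stats_tbl, stat = "gc_percent", alpha = alpha)
}

new_window_profile <- function(tbl, stat, alpha = NA_real_) {
  class(tbl) <- c("window_profile", class(tbl))
  attr(tbl, "stat") <- stat
  attr(tbl, "alpha") <- alpha
  tbl
}

#' Mean GC-skew profiles of asRNA and CDS upstream regions
#'
#' Per-window mean and standard error of GC skew for the two sets of
#' upstream regions, emitted side by side for qualitative comparison (when
#' the entire population of qualifying regions is analysed, no sampling
#' inference is involved).
#'
#' @param asrna_regions,cds_regions Tibbles from [extract_upstream()];
#'   excluded rows are dropped.  Both sets must be nonempty.
#' @param window Window size in nt; default 7.
#' @return A `window_profile` tibble with a `set` column
#'   (`"asRNA"`/`"CDS"`) and `window`, `n_regions`, `mean_stat`, `se_stat`.
#' @export
skew_profiles <- function(asrna_regions, cds_regions, window = 7) {
  profile_one <- function(regions, label) {
    seqs <- regions$sequence[!regions$excluded]
    if (length(seqs) == 0) abort(sprintf("empty %s region set", label))
    n_win <- unique(nchar(seqs)) - window + 1
    vals <- t(vapply(seqs, window_scan, numeric(n_win),
                     stat = "gc_skew", window = window, USE.NAMES = FALSE))
    tibble(set = label, window = seq_len(n_win),
           n_regions = length(seqs),
           mean_stat = colMeans(vals),
           se_stat = apply(vals, 2, sd) / sqrt(length(seqs)))
  }
  out <- bind_rows(profile_one(asrna_regions, "asRNA"),
                   profile_one(cds_regions, "CDS"))
  new_window_profile(out, stat = "gc_skew")
}

# Motif scanning --------------------------------------------------------------

#' Scan upstream regions for an IUPAC motif
#'
#' Counts occurrences of a user-supplied IUPAC-degenerate motif (e.g. the
#' Pribnow box `TANAAT`) in each region's 5'→3' sequence, and reports the
#' fraction of regions containing at least one match.  De novo motif
#' discovery is out of scope; use [export_regions_fasta()] to hand the
#' regions to an external discovery tool.
#'
#' @param regions Tibble from [extract_upstream()]; excluded rows dropped.
#' @param motif IUPAC nucleotide string.
#' @return List with `fraction` (regions with >= 1 hit), `n_regions` and
#'   `hits` (tibble `source_id`, `n_hits`).
#' @export
scan_motif <- function(regions, motif) {
  motif <- toupper(motif)
  legal <- names(Biostrings::IUPAC_CODE_MAP)
  if (nchar(motif) == 0 || !all(str_bases(motif) %in% legal)) {
    abort(sprintf("malformed IUPAC motif: '%s'", motif))
  }
  keep <- !regions$excluded
  seqs <- Biostrings::DNAStringSet(regions$sequence[keep])
  hits <- Biostrings::vcountPattern(motif, seqs, fixed = FALSE)
  list(fraction = mean(hits >= 1),
       n_regions = sum(keep),
       hits = tibble(source_id = regions$source_id[keep], n_hits = hits))
}

#' Export upstream regions as FASTA for external motif discovery
#'
#' @param regions Tibble from [extract_upstream()]; excluded rows dropped.
#' @param path Output FASTA path.
#' @param positions Optional window-position interval `c(from, to)` (position
#'   1 adjacent to the start) restricting the exported subsequence.
#' @return Invisibly, the path.
#' @export
export_regions_fasta <- function(regions, path, positions = NULL) {
  keep <- !regions$excluded
  seqs <- regions$sequence[keep]
  if (!is.null(positions)) {
    L <- nchar(seqs)
    # upstream positions from..to map to 5'->3' string coords
    seqs <- substr(seqs, L + 1 - positions[2], L + 1 - positions[1])
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, regions$source_id[keep])), path)
  invisible(path)
}
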