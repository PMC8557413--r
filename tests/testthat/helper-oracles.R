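# Independent brute-force oracles and fixture builders used across tests.
# Every oracle is written from the definitions directly, without touching the
# package's implementation paths.

random_seq <- function(n, gc = 0.16) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

toy_genome <- function(sequence, features) {
  genome_record("toy", sequence, features)
}

make_srna_tbl <- function(start, end, strand, genome_id = "toy",
                          ids = NULL) {
  n <- length(start)
  tibble::tibble(
    srna_id = ids %||% sprintf("s%02d", seq_len(n)),
    genome_id = genome_id,
    start = as.integer(start), end = as.integer(end), strand = strand,
    category = "unset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain-loop interval overlap (1-based inclusive).
oracle_overlap <- function(s1, e1, s2, e2) {
  lo <- max(s1, s2); hi <- min(e1, e2)
  if (hi >= lo) hi - lo + 1 else 0
}

# Exhaustive re-statement of the classification rule.
oracle_classify_one <- function(s, e, strand, features, utr_flank = 50) {
  best_id <- NA_character_; best_ov <- 0
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (f$strand == strand) next
    ov <- oracle_overlap(s, e, f$start, f$end)
    if (ov > best_ov || (ov == best_ov && ov > 0 &&
                         f$feature_id < best_id)) {
      best_ov <- ov; best_id <- f$feature_id
    }
  }
  if (best_ov >= 1) {
    return(list(category = "antisense", target = best_id, ov = best_ov))
  }
  same <- features[features$strand == strand, ]
  overlaps_same <- FALSE
  near_same <- FALSE
  for (i in seq_len(nrow(same))) {
    f <- same[i, ]
    if (oracle_overlap(s, e, f$start, f$end) > 0) overlaps_same <- TRUE
    gap <- max(f$start - e, s - f$end)
    if (gap > 0 && gap <= utr_flank) near_same <- TRUE
  }
  if (!overlaps_same && near_same) {
    return(list(category = "utr", target = NA_character_, ov = NA))
  }
  list(category = "intergenic", target = NA_character_, ov = NA)
}

# Brute-force one-to-one pairing by smallest total offset (unique offsets).
oracle_greedy_pairs <- function(cand) {
  cand <- cand[order(cand$total, cand$srna_a, cand$srna_b), ]
  used_a <- character(0); used_b <- character(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$srna_a[k] %in% used_a || cand$srna_b[k] %in% used_b) next
    keep[k] <- TRUE
    used_a <- c(used_a, cand$srna_a[k]); used_b <- c(used_b, cand$srna_b[k])
  }
  cand[keep, ]
}

# Direct per-window statistic: window w covers the nucleotides w..w+win-1
# upstream of the start; in the stored 5'->3' string the nucleotide p nt
# upstream sits at string index L + 1 - p.
oracle_window_stat <- function(sequence, w, win = 7, stat = "gc_percent") {
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  idx <- vapply(w:(w + win - 1), function(p) L + 1 - p, 1)
  s <- chars[idx]
  g <- sum(s == "G"); cc <- sum(s == "C")
  if (stat == "gc_percent") return(100 * (g + cc) / win)
  if (g + cc == 0) 0 else (cc - g) / (cc + g)
}

# IUPAC motif scan by explicit expansion to all concrete words.
oracle_motif_hit <- function(sequence, motif) {
  map <- Biostrings::IUPAC_CODE_MAP
  sets <- lapply(strsplit(motif, "")[[1]],
                 function(ch) strsplit(map[[ch]], "")[[1]])
  words <- Reduce(function(a, b) as.vector(outer(a, b, paste0)), sets)
  any(vapply(words, function(w) grepl(w, sequence, fixed = TRUE), TRUE))
}

# Per-column enumeration of canonical pair types for covariation counting.
oracle_compensatory <- function(seqs, pairs) {
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  mat <- do.call(rbind, strsplit(chartr("T", "U", toupper(seqs)), ""))
  n_comp <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    types <- character(0)
    for (r in seq_len(nrow(mat))) {
      if (mat[r, i] == "-" || mat[r, j] == "-") next
      types <- union(types, paste0(mat[r, i], mat[r, j]))
    }
    if (length(intersect(types, canonical)) >= 2) n_comp <- n_comp + 1
  }
  n_comp
}

# Synthetic stand-in tables for the paired two-lineage comparison; the
# builder lives in the package (see ?synthetic_carsonella_srnas).
synthetic_carsonella_tables <- function(seed = 42, max_jitter = 8) {
  synthetic_carsonella_srnas(seed = seed, max_jitter = max_jitter)
}
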