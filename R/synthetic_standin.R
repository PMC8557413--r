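#' Synthetic stand-in for the paired Carsonella asRNA coordinate tables
#'
#' A fully synthetic reconstruction of the two-lineage asRNA comparison at
#' published scale: 36 lineage-A ("BC") and 32 lineage-B ("DC") asRNAs on a
#' shared coordinate frame with an identity offset map, of which 11 pairs
#' are planted as orthologs — jittered within the 15-nt rule — covering the
#' genes reported as conserved (aroC, atpA twice, atpD, carA-carB, carB,
#' clpX, gidA, grpE, leuC, prfA).  Every other asRNA is placed far from any
#' counterpart.  The coordinates are constructed, not transcribed from any
#' supplementary data; the object exists so that the conserved-pair caller
#' can be exercised at realistic scale without external inputs.
#'
#' @param seed Integer seed for placements and jitter.
#' @param max_jitter Maximum |endpoint jitter| in nt for planted orthologs
#'   (must stay below the 15-nt rule); default 8.
#' @return List with `srna_a`, `srna_b` (sRNA tables), `map` (identity
#'   [offset_map()]), `conserved_genes` (length 11) and `n_conserved`.
#' @export
synthetic_carsonella_srnas <- function(seed = 42, max_jitter = 8) {
  stopifnot(max_jitter < 15)
  set.seed(seed)
  genes <- c("aroC", "atpA", "atpA", "atpD", "carA-carB", "carB", "clpX",
             "dnaK", "gidA", "grpE", "hisD", "ilvE", "leuC", "lysA", "prfA",
             "putA", "tktA", "aroA", "purA", "dapF", "argH", "ilvD", "leuD",
             "lysC", "atpB", "rpoB", "rpoC", "rplB", "rpsC", "tufA", "fusA",
             "infB", "secA", "dnaE", "gyrA", "recA")
  conserved_genes <- c("aroC", "atpA", "atpA", "atpD", "carA-carB", "carB",
                       "clpX", "gidA", "grpE", "leuC", "prfA")
  starts <- sort(sample(seq(500, 160000, by = 450), 36))
  len <- sample(80:160, 36, replace = TRUE)
  strands <- sample(c("+", "-"), 36, replace = TRUE)
  a <- tibble(
    srna_id = sprintf("BC_%s_%02d", genes, seq_len(36)),
    genome_id = "Carsonella-BC-synthetic",
    start = as.integer(starts), end = as.integer(starts + len - 1),
    strand = strands, category = "antisense")
  cons_idx <- sort(c(which(genes %in% setdiff(conserved_genes, "atpA")),
                     which(genes == "atpA")))
  jit <- function(n) sample(seq(-max_jitter, max_jitter), n, replace = TRUE)
  b_cons <- tibble(
    srna_id = sprintf("DC_%s_%02d", genes[cons_idx], seq_along(cons_idx)),
    genome_id = "Carsonella-DC-synthetic",
    start = as.integer(a$start[cons_idx] + jit(length(cons_idx))),
    end = as.integer(a$end[cons_idx] + jit(length(cons_idx))),
    strand = a$strand[cons_idx], category = "antisense")
  b_spec_start <- sort(sample(seq(162000, 172000, by = 450), 21))
  b_len <- sample(80:160, 21, replace = TRUE)
  b_spec <- tibble(
    srna_id = sprintf("DC_spec_%02d", seq_len(21)),
    genome_id = "Carsonella-DC-synthetic",
    start = as.integer(b_spec_start),
    end = as.integer(b_spec_start + b_len - 1),
    strand = sample(c("+", "-"), 21, replace = TRUE),
    category = "antisense")
  b <- bind_rows(b_cons, b_spec)
  list(srna_a = a, srna_b = b,
       map = offset_map(tibble(a_start = 1L, a_end = 174000L,
                               b_start = 1L, b_end = 174000L,
                               orientation = "+")),
       conserved_genes = genes[cons_idx],
       n_conserved = length(cons_idx))
}
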