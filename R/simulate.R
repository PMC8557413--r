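# Synthetic paired symbiont-like genomes with planted signals, so every
# analysis stage is testable end to end without any external download.

#' Simulation configuration for paired symbiont-like genomes
#'
#' Defaults emulate a Carsonella-like comparison: a gene-dense chromosome of
#' 196 CDSs averaging 850 nt at 16% GC (~84% AT), 36 antisense sRNAs in
#' lineage A and 32 in lineage B of which 11 are orthologous, amino-acid
#' divergence 0.4 substitutions/site outside conserved sRNA footprints and
#' 0.05 inside, saturated synonymous sites, and upstream regions carrying a
#' GC-percent dip (windows 33-48), a GC-skew bump (windows 46-54) and a
#' Pribnow-box motif.
#'
#' @param seed Integer seed; identical configs produce identical output.
#' @param n_cds Number of CDSs.
#' @param mean_cds_len Mean CDS length in nt.
#' @param genome_gc Genome GC fraction.
#' @param n_asrna asRNAs in lineage A.
#' @param n_asrna_b asRNAs in lineage B (default: same as `n_asrna`).
#' @param frac_conserved Fraction of lineage-A asRNAs with a lineage-B
#'   ortholog.
#' @param coord_jitter_sd SD (nt) of the truncated-normal coordinate jitter
#'   applied to orthologous asRNA endpoints in lineage B.  Jitter is
#'   truncated at ±2.5 SD (and at the CDS bounds), which keeps planted pairs
#'   within the 15-nt orthology rule for `coord_jitter_sd <= 6`.
#' @param aa_div_outside,aa_div_inside Expected amino-acid substitutions per
#'   codon outside / inside conserved sRNA footprints (±15 nt);
#'   `aa_div_inside <= aa_div_outside`.
#' @param syn_rate Per-codon probability of synonymous scrambling; the
#'   default 0.9 saturates synonymous divergence, mirroring the regime where
#'   only amino-acid divergence is informative.
#' @param upstream_dip_band Window interval (7-nt windows, window 1 nearest
#'   the start) carrying the planted GC-percent dip.
#' @param dip_depth GC-fraction decrement inside the dip band.
#' @param skew_bump_band Window interval carrying the planted GC-skew
#'   deviation.
#' @param bump_height Target GC skew inside the bump band.
#' @param motif IUPAC motif planted upstream; `motif_prob` the per-region
#'   insertion probability; `motif_offset` the upstream position (nt from
#'   the start) of the motif's 3' end.
#' @param motif_prob,motif_offset See `motif`.
#' @param coverage_depth Mean read depth for [simulate_coverage()].
#' @param upstream_len Upstream region length (nt).
#' @param window Window size (nt) used to convert window bands to positions.
#' @param genome_len Optional fixed genome length; an error is raised when
#'   the CDS layout does not fit ("infeasible packing").
#' @param genome_id_a,genome_id_b Labels for the two lineages.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cds = 196,
                              mean_cds_len = 850,
                              genome_gc = 0.16,
                              n_asrna = 36,
                              n_asrna_b = NULL,
                              frac_conserved = 11 / 36,
                              coord_jitter_sd = 3,
                              aa_div_outside = 0.4,
                              aa_div_inside = 0.05,
                              syn_rate = 0.9,
                              upstream_dip_band = c(33, 48),
                              dip_depth = 0.10,
                              skew_bump_band = c(46, 54),
                              bump_height = 0.5,
                              motif = "TANAAT",
                              motif_prob = 0.5,
                              motif_offset = 8,
                              coverage_depth = 50,
                              upstream_len = 61,
                              window = 7,
                              genome_len = NULL,
                              genome_id_a = "lineageA",
                              genome_id_b = "lineageB") {
  cfg <- list(seed = as.integer(seed), n_cds = n_cds,
              mean_cds_len = mean_cds_len, genome_gc = genome_gc,
              n_asrna = n_asrna, n_asrna_b = n_asrna_b %||% n_asrna,
              frac_conserved = frac_conserved,
              coord_jitter_sd = coord_jitter_sd,
              aa_div_outside = aa_div_outside, aa_div_inside = aa_div_inside,
              syn_rate = syn_rate, upstream_dip_band = upstream_dip_band,
              dip_depth = dip_depth, skew_bump_band = skew_bump_band,
              bump_height = bump_height, motif = toupper(motif),
              motif_prob = motif_prob, motif_offset = motif_offset,
              coverage_depth = coverage_depth, upstream_len = upstream_len,
              window = window, genome_len = genome_len,
              genome_id_a = genome_id_a, genome_id_b = genome_id_b)
  fracs <- c(genome_gc = genome_gc, frac_conserved = frac_conserved,
             syn_rate = syn_rate, motif_prob = motif_prob)
  if (any(fracs < 0 | fracs > 1)) {
    abort(sprintf("fractions must lie in [0, 1]: %s",
                  paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", ")))
  }
  if (aa_div_inside > aa_div_outside) {
    abort("aa_div_inside must not exceed aa_div_outside")
  }
  if (n_asrna > n_cds || cfg$n_asrna_b > n_cds) {
    abort("cannot place more asRNAs than CDSs")
  }
  class(cfg) <- "simulation_config"
  cfg
}

# Sample n random bases at the configured GC fraction.
random_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Random coding sequence: ATG + (n_codons - 2) non-stop codons + TAA.
random_cds_seq <- function(n_codons, gc) {
  stopifnot(n_codons >= 3)
  m <- n_codons - 2
  codons <- paste0(random_bases(m, gc), random_bases(m, gc),
                   random_bases(m, gc))
  gc_tab <- codon_table()
  while (any(bad <- gc_tab[codons] == "*")) {
    k <- sum(bad)
    codons[bad] <- paste0(random_bases(k, gc), random_bases(k, gc),
                          random_bases(k, gc))
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# Single-nt nonsynonymous neighbours of a codon (excluding stops), cached.
nonsyn_neighbours <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- codon_table()
    out <- lapply(names(gc), function(codon) {
      if (gc[codon] == "*") return(character(0))
      alts <- character(0)
      for (pos in 1:3) {
        for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
          alt <- codon
          substr(alt, pos, pos) <- b
          if (gc[alt] != "*" && gc[alt] != gc[codon]) alts <- c(alts, alt)
        }
      }
      alts
    })
    names(out) <- names(gc)
    cache <<- out
    cache
  }
})

# Full synonymous class per codon (including the codon itself): resampling
# from the whole class with composition weights is exactly stationary.
syn_class <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- codon_table()
    out <- lapply(names(gc), function(codon) names(gc)[gc == gc[codon]])
    names(out) <- names(gc)
    cache <<- out
    cache
  }
})

# Composition weight of a codon: product of base probabilities at the
# genome's GC fraction.  Substitution choices are weighted by it so that
# evolved sequences keep the AT-biased stationary composition (unweighted
# choices would pull a 16%-GC genome toward 50% GC within one round of
# synonymous saturation).
codon_weights <- function(gc) {
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codons <- names(codon_table())
  vapply(codons, function(cd) {
    prod(pb[strsplit(cd, "")[[1]]])
  }, numeric(1))
}

# Evolve one coding sequence: per internal codon, a nonsynonymous single-nt
# change with probability ns_rate[i], then synonymous scrambling with
# probability syn_rate; both choices composition-weighted.  Start and stop
# codons are kept fixed.
evolve_cds <- function(coding_seq, ns_rate, syn_rate, gc = 0.16) {
  n <- nchar(coding_seq) / 3
  codons <- substring(coding_seq, seq(1, nchar(coding_seq), 3),
                      seq(3, nchar(coding_seq), 3))
  ns_nb <- nonsyn_neighbours()
  syn_cl <- syn_class()
  w <- codon_weights(gc)
  stopifnot(length(ns_rate) == n)
  for (i in 2:(n - 1)) {
    if (runif(1) < ns_rate[i]) {
      alts <- ns_nb[[codons[i]]]
      if (length(alts) > 0) {
        codons[i] <- if (length(alts) == 1) alts else
          sample(alts, 1, prob = w[alts])
      }
    }
    if (runif(1) < syn_rate) {
      cl <- syn_cl[[codons[i]]]
      if (length(cl) > 1) codons[i] <- sample(cl, 1, prob = w[cl])
    }
  }
  paste(codons, collapse = "")
}

# Truncated-normal integer jitter: |j| <= min(2.5 sd, hard), rounded.
jitter_nt <- function(sd, hard = Inf) {
  if (sd <= 0) return(0L)
  lim <- min(2.5 * sd, hard)
  repeat {
    j <- rnorm(1, 0, sd)
    if (abs(j) <= lim) return(as.integer(round(j)))
  }
}

#' Simulate a pair of symbiont-like genomes with orthologous asRNAs
#'
#' Generates two syntenic, gene-dense, AT-rich genomes.  Lineage B CDS
#' sequences derive from lineage A by codon-level substitution: synonymous
#' scrambling at `syn_rate` (saturating dS) plus single-nt nonsynonymous
#' changes at `aa_div_outside` per codon, lowered to `aa_div_inside` within
#' conserved asRNA footprints ±15 nt.  asRNAs sit antisense within CDSs;
#' conserved asRNAs share footprints up to a truncated-normal coordinate
#' jitter.  The offset map is exact by construction (one collinear block per
#' CDS).
#'
#' @param config A [simulation_config()].
#' @return List with `genome_a`, `genome_b` ([genome_record()]s), `srna_a`,
#'   `srna_b` (sRNA tables, category `"unset"`), `offset_map`, `truth`
#'   (ground-truth tibble: ids, pairing, footprints, planted flags) and
#'   `config`.
#' @export
simulate_genome_pair <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_cds
  gc <- config$genome_gc

  n_codons <- pmax(60L, as.integer(round(rnorm(n, config$mean_cds_len / 3,
                                               config$mean_cds_len / 12))))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  cds_len <- n_codons * 3L

  layout <- function(gaps_lead, gaps) {
    starts <- integer(n); ends <- integer(n)
    pos <- gaps_lead + 1L
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + cds_len[i] - 1L
      pos <- ends[i] + 1L + gaps[i]
    }
    list(starts = starts, ends = ends, total = pos - 1L + 70L)
  }
  lay_a <- layout(sample(70:120, 1), sample(5:25, n, replace = TRUE))
  lay_b <- layout(sample(70:120, 1), sample(5:25, n, replace = TRUE))
  if (!is.null(config$genome_len) &&
      max(lay_a$total, lay_b$total) > config$genome_len) {
    abort(sprintf("infeasible packing: CDS layout needs %d bp > genome_len %d",
                  max(lay_a$total, lay_b$total), config$genome_len))
  }

  coding_a <- vapply(n_codons, random_cds_seq, character(1), gc = gc)

  # asRNA placement on lineage A (one per chosen CDS)
  fp_len <- sample(90:150, config$n_asrna, replace = TRUE)
  eligible <- which(cds_len >= max(fp_len) + 40L)
  if (length(eligible) < config$n_asrna) {
    abort("infeasible packing: too few CDSs long enough to host asRNA footprints")
  }
  host_a <- sample(eligible, config$n_asrna)
  fp_start_gene <- map_int(seq_len(config$n_asrna), function(k) {
    lo <- 19L
    hi <- cds_len[host_a[k]] - fp_len[k] - 18L
    as.integer(sample(lo:hi, 1))
  })
  n_cons <- as.integer(round(config$frac_conserved * config$n_asrna))
  conserved <- sort(sample(config$n_asrna, n_cons))

  # lineage B coding sequences: lowered nonsynonymous rate inside conserved
  # footprints ±15 nt
  ns_rates <- map(seq_len(n), function(i) rep(config$aa_div_outside, n_codons[i]))
  for (k in conserved) {
    i <- host_a[k]
    lo_nt <- max(1L, fp_start_gene[k] - 15L)
    hi_nt <- min(cds_len[i], fp_start_gene[k] + fp_len[k] - 1L + 15L)
    c1 <- ceiling(lo_nt / 3); c2 <- ceiling(hi_nt / 3)
    ns_rates[[i]][c1:c2] <- config$aa_div_inside
  }
  coding_b <- vapply(seq_len(n), function(i) {
    evolve_cds(coding_a[i], ns_rates[[i]], config$syn_rate, gc)
  }, character(1))

  assemble <- function(lay, coding) {
    glen <- lay$total
    seqv <- random_bases(glen, gc)
    for (i in seq_len(n)) {
      s <- coding[i]
      if (strands[i] == "-") s <- revcomp(s)
      seqv[lay$starts[i]:lay$ends[i]] <- str_bases(s)
    }
    paste(seqv, collapse = "")
  }
  ids <- sprintf("cds_%03d", seq_len(n))
  mk_genome <- function(gid, lay, coding) {
    genome_record(gid, assemble(lay, coding),
                  tibble(feature_id = ids, start = lay$starts,
                         end = lay$ends, strand = strands))
  }
  genome_a <- mk_genome(config$genome_id_a, lay_a, coding_a)
  genome_b <- mk_genome(config$genome_id_b, lay_b, coding_b)

  # gene-coordinate interval -> genomic interval on a strand-aware CDS
  gene_to_genomic <- function(lay, i, g1, g2) {
    if (strands[i] == "+") {
      c(lay$starts[i] + g1 - 1L, lay$starts[i] + g2 - 1L)
    } else {
      c(lay$ends[i] - g2 + 1L, lay$ends[i] - g1 + 1L)
    }
  }
  anti <- function(s) if (s == "+") "-" else "+"

  srna_a <- list_rbind(map(seq_len(config$n_asrna), function(k) {
    i <- host_a[k]
    gi <- gene_to_genomic(lay_a, i, fp_start_gene[k],
                          fp_start_gene[k] + fp_len[k] - 1L)
    tibble(srna_id = sprintf("%s_as%03d", config$genome_id_a, k),
           genome_id = config$genome_id_a,
           start = gi[1], end = gi[2], strand = anti(strands[i]),
           category = "unset")
  }))

  # conserved partners in B (jittered), plus lineage-B-specific asRNAs
  srna_b_rows <- list()
  truth_b_id <- rep(NA_character_, config$n_asrna)
  for (idx in seq_along(conserved)) {
    k <- conserved[idx]
    i <- host_a[k]
    g1 <- fp_start_gene[k]; g2 <- g1 + fp_len[k] - 1L
    j1 <- jitter_nt(config$coord_jitter_sd)
    j2 <- jitter_nt(config$coord_jitter_sd)
    g1b <- min(max(1L, g1 + j1), cds_len[i] - 30L)
    g2b <- max(min(cds_len[i], g2 + j2), g1b + 30L)
    gi <- gene_to_genomic(lay_b, i, g1b, g2b)
    bid <- sprintf("%s_as%03d", config$genome_id_b, idx)
    truth_b_id[k] <- bid
    srna_b_rows[[length(srna_b_rows) + 1]] <-
      tibble(srna_id = bid, genome_id = config$genome_id_b,
             start = gi[1], end = gi[2], strand = anti(strands[i]),
             category = "unset")
  }
  n_b_extra <- config$n_asrna_b - length(conserved)
  if (n_b_extra > 0) {
    free <- setdiff(eligible, host_a)
    if (length(free) < n_b_extra) abort("not enough CDSs for lineage-B asRNAs")
    host_b <- sample(free, n_b_extra)
    fp_len_b <- sample(90:150, n_b_extra, replace = TRUE)
    for (k in seq_len(n_b_extra)) {
      i <- host_b[k]
      g1 <- as.integer(sample(19L:(cds_len[i] - fp_len_b[k] - 18L), 1))
      gi <- gene_to_genomic(lay_b, i, g1, g1 + fp_len_b[k] - 1L)
      srna_b_rows[[length(srna_b_rows) + 1]] <-
        tibble(srna_id = sprintf("%s_as%03d", config$genome_id_b,
                                 length(conserved) + k),
               genome_id = config$genome_id_b,
               start = gi[1], end = gi[2], strand = anti(strands[i]),
               category = "unset")
    }
  }
  srna_b <- list_rbind(srna_b_rows)

  # nominal replicate expression values
  add_expr <- function(tbl) {
    m <- nrow(tbl)
    mutate(tbl,
           expr_1 = round(stats::rlnorm(m, log(50), 0.5), 1),
           expr_2 = round(stats::rlnorm(m, log(50), 0.5), 1),
           expr_3 = round(stats::rlnorm(m, log(50), 0.5), 1))
  }
  srna_a <- add_expr(srna_a)
  srna_b <- add_expr(srna_b)

  map <- offset_map(tibble(a_start = lay_a$starts, a_end = lay_a$ends,
                           b_start = lay_b$starts, b_end = lay_b$ends,
                           orientation = "+"))

  truth <- tibble(
    srna_a_id = srna_a$srna_id,
    srna_b_id = truth_b_id,
    cds = ids[host_a],
    conserved = seq_len(config$n_asrna) %in% conserved,
    fp_start_gene = fp_start_gene,
    fp_len = fp_len,
    start_a = srna_a$start,
    end_a = srna_a$end
  )

  list(genome_a = genome_a, genome_b = genome_b,
       srna_a = srna_a, srna_b = srna_b,
       offset_map = map, truth = truth, config = config)
}

#' Plant upstream composition signals into a genome
#'
#' Rewrites the 61-nt upstream region of each asRNA on the feature strand:
#' inside the dip band the expected GC fraction drops to
#' `genome_gc - dip_depth`; inside the skew band G/C bases are rebalanced
#' toward C so that the expected GC skew equals `bump_height`; the IUPAC
#' motif is realised and written at a fixed offset with probability
#' `motif_prob`.  All edits are confined to the upstream regions.
#'
#' @param genome A [genome_record()] (typically lineage A of
#'   [simulate_genome_pair()]).
#' @param srna_tbl sRNA table whose upstream regions receive the signals.
#' @param config A [simulation_config()].
#' @return The modified genome, with attribute `"planted"`: a tibble of
#'   `srna_id` and `motif_inserted`.
#' @export
plant_upstream_signals <- function(genome, srna_tbl, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$dip_depth > config$genome_gc) {
    abort("dip_depth exceeds genome_gc")
  }
  set.seed(derive_seed(config$seed, 2L))
  L <- config$upstream_len
  win <- config$window
  glen <- nchar(genome$sequence)
  seqv <- str_bases(genome$sequence)
  band_positions <- function(band) {
    if (is.null(band)) integer(0) else seq(band[1], band[2] + win - 1)
  }
  dip_pos <- band_positions(config$upstream_dip_band)
  skew_pos <- band_positions(config$skew_bump_band)
  motif_inserted <- logical(nrow(srna_tbl))

  for (r in seq_len(nrow(srna_tbl))) {
    s <- srna_tbl$start[r]; e <- srna_tbl$end[r]
    strand <- srna_tbl$strand[r]
    if (strand == "+") { rs <- s - L; re <- s - 1 } else { rs <- e + 1; re <- e + L }
    if (rs < 1 || re > glen) {
      abort(sprintf("upstream region of %s lies outside the genome",
                    srna_tbl$srna_id[r]))
    }
    region <- feature_seq(genome, rs, re, strand)  # 5'->3' on feature strand
    x <- str_bases(region)
    # upstream position p (1 = adjacent to start) -> string index L + 1 - p
    if (config$dip_depth > 0) {
      gc_p <- config$genome_gc - config$dip_depth
      for (p in dip_pos) {
        x[L + 1 - p] <- sample(DNA_BASES, 1,
                               prob = c((1 - gc_p) / 2, gc_p / 2,
                                        gc_p / 2, (1 - gc_p) / 2))
      }
    }
    if (config$bump_height > 0) {
      p_c <- (1 + config$bump_height) / 2
      for (p in skew_pos) {
        i <- L + 1 - p
        if (x[i] %in% c("C", "G")) {
          x[i] <- if (runif(1) < p_c) "C" else "G"
        }
      }
    }
    if (config$motif_prob > 0 && runif(1) < config$motif_prob) {
      motif_chars <- str_bases(config$motif)
      realized <- vapply(motif_chars, function(ch) {
        sample(str_bases(Biostrings::IUPAC_CODE_MAP[[ch]]), 1)
      }, character(1))
      k <- length(realized)
      o <- config$motif_offset
      idx <- (L + 2 - o - k):(L + 1 - o)   # motif written 5'->3'
      if (min(idx) >= 1) {
        x[idx] <- realized
        motif_inserted[r] <- TRUE
      }
    }
    edited <- paste(x, collapse = "")
    if (strand == "-") edited <- revcomp(edited)
    seqv[rs:re] <- str_bases(edited)
  }
  out <- genome_record(genome$genome_id, paste(seqv, collapse = ""),
                       genome$features)
  attr(out, "planted") <- tibble(srna_id = srna_tbl$srna_id,
                                 motif_inserted = motif_inserted)
  out
}

#' Simulate per-base read coverage over sRNA intervals
#'
#' Poisson(`depth`) counts at every base of every sRNA interval (plus
#' optional Poisson background elsewhere).  Chosen sRNAs can receive a
#' zero-coverage gap punched into their middle, as negative controls for the
#' continuous-coverage check.
#'
#' @param genome A [genome_record()] (used only for bounds).
#' @param srna_tbl sRNA table.
#' @param depth Mean read depth over sRNA intervals (>= 0).
#' @param background Mean depth elsewhere; 0 (default) emits no rows there.
#' @param gap_srnas Character vector of `srna_id`s to receive a gap.
#' @param gap_len Gap length in nt; default 5.
#' @param seed Optional seed.
#' @return Coverage tibble (`pos`, `depth`), sparse outside sRNA intervals.
#' @export
simulate_coverage <- function(genome, srna_tbl, depth, background = 0,
                              gap_srnas = NULL, gap_len = 5, seed = NULL) {
  stopifnot(depth >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  glen <- nchar(genome$sequence)
  rows <- map(seq_len(nrow(srna_tbl)), function(r) {
    pos <- srna_tbl$start[r]:srna_tbl$end[r]
    d <- rpois(length(pos), depth)
    if (srna_tbl$srna_id[r] %in% gap_srnas) {
      mid <- floor(length(pos) / 2)
      lo <- max(1, mid - floor(gap_len / 2))
      d[lo:min(length(pos), lo + gap_len - 1)] <- 0L
    }
    tibble(pos = as.integer(pos), depth = as.integer(d))
  })
  cov <- list_rbind(rows)
  if (background > 0) {
    rest <- setdiff(seq_len(glen), cov$pos)
    cov <- bind_rows(cov, tibble(pos = as.integer(rest),
                                 depth = rpois(length(rest), background)))
  }
  cov |> group_by(.data$pos) |>
    summarise(depth = as.integer(max(.data$depth)), .groups = "drop") |>
    arrange(.data$pos)
}

#' Simulate a structural alignment with known compensatory pairs
#'
#' Builds a hairpin consensus structure (`n_pairs` stem pairs around a loop)
#' realised across `n_seq` sequences; the first `n_compensatory` stem pairs
#' alternate between two canonical pair types across sequences (a planted
#' compensatory signal), the rest keep one type.
#'
#' @param n_seq Number of aligned sequences.
#' @param n_pairs Stem pairs.
#' @param n_compensatory Pairs with planted covariation
#'   (`<= n_pairs`).
#' @param loop_len Loop length; default 4.
#' @param seed Optional seed.
#' @return List with `seqs` (character vector), `structure` (dot-bracket
#'   string) and `truth` (`n_pairs`, `n_compensatory`).
#' @export
simulate_structure_alignment <- function(n_seq, n_pairs, n_compensatory,
                                         loop_len = 4, seed = NULL) {
  stopifnot(n_compensatory <= n_pairs, n_seq >= 2)
  if (!is.null(seed)) withr::local_seed(seed)
  len <- 2 * n_pairs + loop_len
  structure_str <- paste0(strrep("(", n_pairs), strrep(".", loop_len),
                          strrep(")", n_pairs))
  types <- list(c("A", "U"), c("G", "C"), c("U", "A"), c("C", "G"),
                c("G", "U"), c("U", "G"))
  base_type <- sample(length(types), n_pairs, replace = TRUE)
  alt_type <- vapply(base_type, function(t) {
    sample(setdiff(seq_along(types), t), 1)
  }, integer(1))
  loop <- sample(c("A", "U"), loop_len, replace = TRUE)
  seqs <- vapply(seq_len(n_seq), function(s) {
    x <- character(len)
    x[(n_pairs + 1):(n_pairs + loop_len)] <- loop
    for (k in seq_len(n_pairs)) {
      use_alt <- k <= n_compensatory && s > n_seq / 2
      tp <- types[[if (use_alt) alt_type[k] else base_type[k]]]
      x[k] <- tp[1]
      x[len + 1 - k] <- tp[2]
    }
    paste(x, collapse = "")
  }, character(1))
  list(seqs = seqs, structure = structure_str,
       truth = list(n_pairs = n_pairs, n_compensatory = n_compensatory))
}
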