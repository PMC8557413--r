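small_cfg <- function(seed = 3, ...) {
  simulation_config(seed = seed, n_cds = 40, mean_cds_len = 600,
                    n_asrna = 10, n_asrna_b = 9, frac_conserved = 0.5, ...)
}

test_that("identical configs produce byte-identical outputs", {
  s1 <- simulate_genome_pair(small_cfg())
  s2 <- simulate_genome_pair(small_cfg())
  expect_identical(s1$genome_a$sequence, s2$genome_a$sequence)
  expect_identical(s1$genome_b$sequence, s2$genome_b$sequence)
  expect_identical(s1$srna_a, s2$srna_a)
  expect_identical(s1$srna_b, s2$srna_b)
  expect_identical(as.data.frame(s1$offset_map), as.data.frame(s2$offset_map))
  # and a different seed produces different genomes
  s3 <- simulate_genome_pair(small_cfg(seed = 4))
  expect_false(identical(s1$genome_a$sequence, s3$genome_a$sequence))
})

test_that("full conservation with zero jitter maps to identical coordinates", {
  cfg <- simulation_config(seed = 5, n_cds = 30, mean_cds_len = 600,
                           n_asrna = 8, frac_conserved = 1,
                           coord_jitter_sd = 0)
  sim <- simulate_genome_pair(cfg)
  expect_equal(nrow(sim$srna_b), 8)
  for (k in seq_len(8)) {
    mapped <- map_coordinates(sim$offset_map, sim$srna_a$start[k],
                              sim$srna_a$end[k])
    expect_equal(mapped$start, sim$srna_b$start[k])
    expect_equal(mapped$end, sim$srna_b$end[k])
  }
})

test_that("simulated genome composition tracks the configured GC", {
  cfg <- simulation_config(seed = 6, n_cds = 80, mean_cds_len = 700,
                           n_asrna = 10, genome_gc = 0.16)
  sim <- simulate_genome_pair(cfg)
  expect_gt(nchar(sim$genome_a$sequence), 50000)
  expect_lt(abs(gc_percent(sim$genome_a$sequence) - 16), 1)
  expect_lt(abs(gc_percent(sim$genome_b$sequence) - 16), 1)
})

test_that("lineage-B sequences diverge at the configured amino-acid rates", {
  cfg <- small_cfg(seed = 7, aa_div_outside = 0.4, aa_div_inside = 0.05)
  sim <- simulate_genome_pair(cfg)
  f <- sim$genome_a$features
  # a CDS without any asRNA: overall mismatch fraction near the outside rate
  free <- setdiff(f$feature_id, sim$truth$cds)[1]
  fa <- f[f$feature_id == free, ]
  fb <- sim$genome_b$features[sim$genome_b$features$feature_id == free, ]
  aa_a <- translate_codons(feature_seq(sim$genome_a, fa$start, fa$end, fa$strand))
  aa_b <- translate_codons(feature_seq(sim$genome_b, fb$start, fb$end, fb$strand))
  expect_lt(abs(mean(aa_a != aa_b) - 0.4), 0.12)
  # synonymous positions are fully randomized between the lineages: the
  # mismatch fraction sits near its compositional ceiling, so only
  # amino-acid divergence is informative (the uniform-equilibrium JC
  # correction plateaus rather than diverging at AT-rich stationarity)
  ds <- estimate_synonymous_divergence(
    feature_seq(sim$genome_a, fa$start, fa$end, fa$strand),
    feature_seq(sim$genome_b, fb$start, fb$end, fb$strand))
  expect_gt(ds$pS, 0.45)
  expect_gt(ds$dS, 0.8)
})

test_that("the conserved-pair caller recovers ground truth exactly", {
  for (sd in c(3, 5)) {
    cfg <- simulation_config(seed = 40 + sd, n_cds = 60, mean_cds_len = 700,
                             n_asrna = 20, n_asrna_b = 18,
                             frac_conserved = 0.5, coord_jitter_sd = sd)
    sim <- simulate_genome_pair(cfg)
    pairs <- call_conserved(sim$srna_a, sim$srna_b, sim$offset_map)
    truth <- sim$truth[sim$truth$conserved, ]
    expect_setequal(paste(pairs$srna_a, pairs$srna_b),
                    paste(truth$srna_a_id, truth$srna_b_id))
  }
})

test_that("planting with zero depths and probabilities is the identity", {
  cfg <- small_cfg(seed = 8, dip_depth = 0, bump_height = 0, motif_prob = 0)
  sim <- simulate_genome_pair(cfg)
  planted <- plant_upstream_signals(sim$genome_a, sim$srna_a, cfg)
  expect_identical(planted$sequence, sim$genome_a$sequence)
})

test_that("planted edits stay inside the 61-nt upstream regions", {
  cfg <- small_cfg(seed = 9, dip_depth = 0.1, bump_height = 0.5,
                   motif_prob = 1)
  sim <- simulate_genome_pair(cfg)
  planted <- plant_upstream_signals(sim$genome_a, sim$srna_a, cfg)
  diff_pos <- which(strsplit(planted$sequence, "")[[1]] !=
                      strsplit(sim$genome_a$sequence, "")[[1]])
  allowed <- integer(0)
  for (r in seq_len(nrow(sim$srna_a))) {
    if (sim$srna_a$strand[r] == "+") {
      allowed <- c(allowed, (sim$srna_a$start[r] - 61):(sim$srna_a$start[r] - 1))
    } else {
      allowed <- c(allowed, (sim$srna_a$end[r] + 1):(sim$srna_a$end[r] + 61))
    }
  }
  expect_true(all(diff_pos %in% allowed))
})

test_that("a planted dip lowers in-band GC by about its depth", {
  cfg <- simulation_config(seed = 10, n_cds = 210, mean_cds_len = 450,
                           n_asrna = 200, n_asrna_b = 0,
                           frac_conserved = 0, dip_depth = 0.10,
                           bump_height = 0, motif_prob = 0)
  sim <- simulate_genome_pair(cfg)
  planted <- plant_upstream_signals(sim$genome_a, sim$srna_a, cfg)
  feats <- dplyr::transmute(sim$srna_a, source_id = srna_id, start, end,
                            strand)
  regs <- extract_upstream(planted, feats, check_overlap = FALSE)
  # dip band windows 33..48 edit upstream positions 33..54
  chars <- strsplit(regs$sequence, "")
  pos_gc <- function(p) {
    mean(vapply(chars, function(x) x[62 - p] %in% c("G", "C"), TRUE))
  }
  in_band <- mean(vapply(33:54, pos_gc, 1))
  out_band <- mean(vapply(1:26, pos_gc, 1))
  expect_lt(abs((out_band - in_band) - 0.10), 0.025)
})

test_that("motif probability one plants a match in every region", {
  cfg <- small_cfg(seed = 11, dip_depth = 0, bump_height = 0, motif_prob = 1)
  sim <- simulate_genome_pair(cfg)
  planted <- plant_upstream_signals(sim$genome_a, sim$srna_a, cfg)
  feats <- dplyr::transmute(sim$srna_a, source_id = srna_id, start, end,
                            strand)
  regs <- extract_upstream(planted, feats, check_overlap = FALSE)
  expect_equal(scan_motif(regs, cfg$motif)$fraction, 1)
  expect_true(all(attr(planted, "planted")$motif_inserted))
  # the realised motif sits at the fixed offset: positions 8..13 upstream
  for (s in regs$sequence) {
    expect_true(oracle_motif_hit(substr(s, 61 + 1 - 13, 61 + 1 - 8), "TANAAT"))
  }
})

test_that("planting validates its preconditions", {
  cfg <- small_cfg(seed = 12, dip_depth = 0.5)
  sim <- simulate_genome_pair(small_cfg(seed = 12))
  expect_error(plant_upstream_signals(sim$genome_a, sim$srna_a, cfg),
               "dip_depth")
  expect_error(simulation_config(frac_conserved = 1.4), "fractions")
  expect_error(simulation_config(aa_div_inside = 0.5, aa_div_outside = 0.1),
               "aa_div_inside")
  expect_error(simulate_genome_pair(simulation_config(
    n_cds = 50, mean_cds_len = 900, genome_len = 10000)), "infeasible")
})

test_that("simulated coverage has Poisson depth over sRNA intervals", {
  sim <- simulate_genome_pair(small_cfg(seed = 13))
  zero <- simulate_coverage(sim$genome_a, sim$srna_a, 0, seed = 1)
  expect_true(all(zero$depth == 0))
  cov <- simulate_coverage(sim$genome_a, sim$srna_a, 50, seed = 2)
  one <- cov$depth[cov$pos >= sim$srna_a$start[1] & cov$pos <= sim$srna_a$end[1]]
  n <- length(one)
  expect_lt(abs(mean(one) - 50), 3 * sqrt(50 / n))
  # a punched gap breaks the downstream continuity check
  gap <- simulate_coverage(sim$genome_a, sim$srna_a, 50,
                           gap_srnas = sim$srna_a$srna_id[2], seed = 2)
  expect_true(srnacons:::interval_covered(gap, sim$srna_a$start[1],
                                          sim$srna_a$end[1]))
  expect_false(srnacons:::interval_covered(gap, sim$srna_a$start[2],
                                           sim$srna_a$end[2]))
})

test_that("structure alignment simulator plants the advertised covariation", {
  aln <- simulate_structure_alignment(8, 6, 3, seed = 21)
  expect_equal(nchar(aln$structure), nchar(aln$seqs[1]))
  rep <- count_compensatory(aln$seqs, aln$structure)
  expect_equal(rep$n_pairs, 6)
  expect_equal(rep$n_compensatory, 3)
})
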