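upstream_genome <- function(seq_len = 800) {
  toy_genome(random_seq(seq_len, gc = 0.3),
             tibble::tibble(feature_id = c("t1", "t2"),
                            start = c(80L, 450L), end = c(260L, 620L),
                            strand = c("-", "+")))
}

test_that("upstream extraction is strand-aware with edge exclusion", {
  set.seed(91)
  g <- toy_genome(random_seq(800), tibble::tibble(
    feature_id = character(0), start = integer(0), end = integer(0),
    strand = character(0)))
  feats <- tibble::tibble(source_id = c("plus", "minus", "edge"),
                          start = c(100L, 440L, 30L),
                          end = c(180L, 500L, 90L),
                          strand = c("+", "-", "+"))
  out <- extract_upstream(g, feats)
  # plus strand starting at 100: genomic 39..99 read forward
  expect_equal(out$start[1], 39L)
  expect_equal(out$end[1], 99L)
  expect_equal(out$sequence[1], substr(g$sequence, 39, 99))
  # minus strand ending at 500: genomic 501..561 reverse-complemented
  expect_equal(out$start[2], 501L)
  expect_equal(out$end[2], 561L)
  expect_equal(out$sequence[2], revcomp(substr(g$sequence, 501, 561)))
  # too close to the origin
  expect_true(out$excluded[3])
  expect_equal(out$reason[3], "genome_edge")
})

test_that("regions overlapping a non-exempt CDS are dropped", {
  set.seed(92)
  g <- upstream_genome()
  # an asRNA inside t1: upstream region stays within its own target -> kept
  asrna <- tibble::tibble(source_id = "as1", start = 120L, end = 190L,
                          strand = "+", exempt_cds = "t1")
  expect_false(extract_upstream(g, asrna)$excluded)
  # same region but the target exemption names the other CDS -> dropped
  other <- dplyr::mutate(asrna, exempt_cds = "t2")
  out <- extract_upstream(g, other)
  expect_true(out$excluded)
  expect_equal(out$reason, "cds_overlap")
  # a CDS's own upstream region: exempt itself, clear of t1 -> kept
  cds_feats <- tibble::tibble(source_id = "t2", start = 450L, end = 620L,
                              strand = "+")
  expect_false(extract_upstream(g, cds_feats)$excluded)
  expect_false(extract_upstream(g, other, check_overlap = FALSE)$excluded)
})

test_that("gc_percent and gc_skew follow their conventions", {
  expect_equal(gc_percent("CCGGAAT"), 400 / 7)
  expect_equal(gc_skew("CCGGAAT"), 0)
  expect_equal(gc_skew("CCCAAAA"), 1)
  expect_equal(gc_skew("GGGAAAA"), -1)
  expect_equal(gc_skew("AAAATTT"), 0)   # zero-denominator convention
  expect_equal(gc_percent("acgt"), 50)
  expect_error(gc_percent("ACGN"), "non-ACGT")
  # gc + at = 100 always; skew flips sign under C<->G exchange
  set.seed(93)
  for (i in 1:50) {
    s <- random_seq(sample(7:61, 1), gc = runif(1, 0.05, 0.9))
    expect_equal(gc_percent(s) + 100 * (stringr::str_count(s, "[AT]")) /
                   nchar(s), 100)
    expect_equal(gc_skew(chartr("CG", "GC", s)), -gc_skew(s))
    expect_gte(gc_skew(s), -1)
    expect_lte(gc_skew(s), 1)
  }
})

test_that("a 61-nt region scans into exactly 55 windows", {
  s <- random_seq(61)
  expect_length(window_scan(s), 55)
  expect_length(window_scan(s, "gc_skew"), 55)
  const <- strrep("A", 61)
  expect_equal(unname(window_scan(const)), rep(0, 55))
  expect_error(window_scan("ACGT"), "shorter")
})

test_that("window 1 sits immediately upstream of the start", {
  # position 1 = last character of the 5'->3' region string
  s <- paste0(strrep("A", 60), "C")
  sk <- window_scan(s, "gc_skew")
  expect_equal(unname(sk[1]), 1)
  expect_equal(unname(sk[-1]), rep(0, 54))
  gp <- window_scan(s, "gc_percent")
  expect_equal(unname(gp[1]), 100 / 7)
  expect_equal(unname(gp[-1]), rep(0, 54))
})

test_that("window scans equal direct recomputation on random regions", {
  set.seed(94)
  for (i in 1:100) {
    s <- random_seq(61, gc = runif(1, 0.1, 0.6))
    got_gc <- window_scan(s, "gc_percent")
    got_sk <- window_scan(s, "gc_skew")
    for (w in sample(1:55, 8)) {
      expect_equal(unname(got_gc[w]), oracle_window_stat(s, w, 7, "gc_percent"))
      expect_equal(unname(got_sk[w]), oracle_window_stat(s, w, 7, "gc_skew"))
    }
  }
})

test_that("shuffles preserve the nucleotide multiset", {
  set.seed(95)
  s <- random_seq(61, 0.2)
  for (i in 1:100) {
    p <- srnacons:::shuffle_seq(s, "mono")
    expect_equal(sort(strsplit(p, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
  # dinucleotide shuffle additionally preserves dinucleotide counts
  dinuc_counts <- function(x) {
    ch <- strsplit(x, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  for (i in 1:20) {
    p <- srnacons:::shuffle_seq(s, "dinucleotide")
    expect_equal(as.list(dinuc_counts(p)), as.list(dinuc_counts(s)))
  }
})

test_that("the permutation test needs >= 3 regions and is reproducible", {
  set.seed(96)
  regs <- tibble::tibble(source_id = c("a", "b"),
                         sequence = c(random_seq(61), random_seq(61)),
                         excluded = FALSE)
  expect_error(gc_permutation_test(regs), "3")
  regs10 <- tibble::tibble(source_id = paste0("r", 1:10),
                           sequence = vapply(1:10, function(i)
                             random_seq(61, 0.2), ""),
                           excluded = FALSE)
  p1 <- gc_permutation_test(regs10, seed = 7)
  p2 <- gc_permutation_test(regs10, seed = 7)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(nrow(p1), 55)
  expect_equal(unique(p1$n_regions), 10)
  expect_true(all(p1$se_stat >= 0))
})

test_that("a planted GC dip is flagged with negative direction", {
  cfg <- simulation_config(seed = 14, n_cds = 60, mean_cds_len = 600,
                           n_asrna = 30, n_asrna_b = 30,
                           frac_conserved = 0.5, dip_depth = 0.10,
                           bump_height = 0, motif_prob = 0)
  sim <- simulate_genome_pair(cfg)
  planted <- plant_upstream_signals(sim$genome_a, sim$srna_a, cfg)
  ca <- classify_srnas(sim$srna_a, planted)
  feats <- dplyr::transmute(ca, source_id = srna_id, start, end, strand,
                            exempt_cds = target_cds)
  regs <- extract_upstream(planted, feats)
  prof <- gc_permutation_test(regs, seed = 15)
  in_band <- prof$window >= 33 & prof$window <= 48
  expect_gt(mean(prof$significant[in_band]), 0.8)
  expect_true(all(prof$direction[in_band & prof$significant] < 0))
  out_band <- prof$window <= 20
  expect_lt(mean(prof$significant[out_band]), 0.3)
})

test_that("skew profiles compare asRNA and CDS sets per window", {
  set.seed(97)
  regs <- tibble::tibble(source_id = paste0("r", 1:8),
                         sequence = vapply(1:8, function(i)
                           random_seq(61, 0.25), ""),
                         excluded = FALSE)
  same <- skew_profiles(regs, regs)
  a <- dplyr::filter(same, set == "asRNA")
  b <- dplyr::filter(same, set == "CDS")
  expect_equal(a$mean_stat, b$mean_stat)
  expect_equal(a$se_stat, b$se_stat)
  # all-AT regions give flat zero profiles
  at <- regs
  at$sequence <- strrep("A", 61)
  flat <- skew_profiles(at, at)
  expect_equal(unique(flat$mean_stat), 0)
  expect_error(skew_profiles(regs[0, ], regs), "empty")
})

test_that("a planted skew bump raises the asRNA profile inside the band", {
  cfg <- simulation_config(seed = 16, n_cds = 60, mean_cds_len = 600,
                           n_asrna = 30, n_asrna_b = 30,
                           frac_conserved = 0.5, dip_depth = 0,
                           bump_height = 0.8, motif_prob = 0)
  sim <- simulate_genome_pair(cfg)
  planted <- plant_upstream_signals(sim$genome_a, sim$srna_a, cfg)
  ca <- classify_srnas(sim$srna_a, planted)
  feats <- dplyr::transmute(ca, source_id = srna_id, start, end, strand,
                            exempt_cds = target_cds)
  as_regs <- extract_upstream(planted, feats)
  cds_feats <- dplyr::select(planted$features, source_id = feature_id,
                             start, end, strand)
  cds_regs <- extract_upstream(planted, cds_feats)
  prof <- skew_profiles(as_regs, cds_regs)
  wide <- tidyr::pivot_wider(as_tibble(prof)[, c("set", "window", "mean_stat")],
                             names_from = "set", values_from = "mean_stat")
  in_band <- wide$window >= 46 & wide$window <= 54
  expect_true(all(wide$asRNA[in_band] > wide$CDS[in_band]))
})

test_that("IUPAC motif scanning matches brute-force expansion", {
  regs1 <- tibble::tibble(source_id = "x",
                          sequence = paste0(strrep("G", 20), "TACAAT",
                                            strrep("G", 35)),
                          excluded = FALSE)
  expect_equal(scan_motif(regs1, "TANAAT")$fraction, 1)
  expect_equal(scan_motif(regs1, "TTTTTT")$fraction, 0)
  expect_error(scan_motif(regs1, "TAXAAT"), "malformed")
  set.seed(98)
  regs <- tibble::tibble(source_id = paste0("r", 1:50),
                         sequence = vapply(1:50, function(i)
                           random_seq(61, 0.16), ""),
                         excluded = FALSE)
  for (motif in c("TANAAT", "WWGCWW", "TATYTT")) {
    got <- scan_motif(regs, motif)
    want <- vapply(regs$sequence, oracle_motif_hit, TRUE, motif = motif)
    expect_equal(got$fraction, mean(want), label = motif)
    expect_equal(got$hits$n_hits >= 1, unname(want))
  }
})

test_that("region FASTA export honours the position window", {
  regs <- tibble::tibble(source_id = c("a", "b"),
                         sequence = c(random_seq(61), random_seq(61)),
                         excluded = c(FALSE, TRUE))
  p <- withr::local_tempfile(fileext = ".fasta")
  export_regions_fasta(regs, p)
  back <- Biostrings::readDNAStringSet(p)
  expect_equal(names(back), "a")   # excluded region not exported
  expect_equal(as.character(back[[1]]), regs$sequence[1])
  # positions 1..7 = the 7 nt adjacent to the start = last 7 characters
  export_regions_fasta(regs, p, positions = c(1, 7))
  sub <- Biostrings::readDNAStringSet(p)
  expect_equal(as.character(sub[[1]]), substr(regs$sequence[1], 55, 61))
})
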