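# End-to-end orchestration: simulate (optional) -> classify -> conserve ->
# divergence -> covary -> upstream, with per-stage TSV outputs, structured
# logging, and a run manifest.

#' Pipeline configuration
#'
#' Bundles every threshold of the analysis with its standard default:
#' conservation coordinate rule 15 nt, divergence-region flank 15 nt,
#' DE filters q <= 0.05 and mean reads >= 9, window size 7 nt, step 1 nt,
#' upstream length 61 nt, 100 reshuffles, significance cutoffs 0.05
#' (composition) and 0.01 (conservation).  Thresholds are serialised into
#' the run manifest of every output directory.
#'
#' @param seed Integer seed for the whole run.
#' @param conservation_nt,flank_nt,q_max,min_mean_reads,p_composition,
#'   p_conservation,n_shuffle,window,step,upstream_len Thresholds as above.
#' @param simulation A [simulation_config()] used when the pipeline
#'   simulates its inputs (defaults to `simulation_config(seed = seed)`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            conservation_nt = 15,
                            flank_nt = 15,
                            q_max = 0.05,
                            min_mean_reads = 9,
                            p_composition = 0.05,
                            p_conservation = 0.01,
                            n_shuffle = 100,
                            window = 7,
                            step = 1,
                            upstream_len = 61,
                            simulation = NULL) {
  cfg <- list(seed = as.integer(seed), conservation_nt = conservation_nt,
              flank_nt = flank_nt, q_max = q_max,
              min_mean_reads = min_mean_reads,
              p_composition = p_composition,
              p_conservation = p_conservation,
              n_shuffle = n_shuffle, window = window, step = step,
              upstream_len = upstream_len,
              simulation = simulation %||% simulation_config(seed = seed))
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(log_con, stage, msg, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(msg, ...))
  message(line)
  if (!is.null(log_con)) writeLines(line, log_con)
  invisible(line)
}

# Gene-coordinate sRNA interval within its host CDS (both genomes share gene
# coordinates because the simulated CDSs are codon-aligned by construction).
srna_gene_interval <- function(srna_row, cds_row) {
  if (cds_row$strand == "+") {
    c(srna_row$start - cds_row$start + 1L, srna_row$end - cds_row$start + 1L)
  } else {
    c(cds_row$end - srna_row$end + 1L, cds_row$end - srna_row$start + 1L)
  }
}

#' Run the full comparative asRNA analysis on simulated inputs
#'
#' Executes every stage in order on a simulated genome pair: classification
#' of both lineages' sRNAs, conserved-pair calling through the offset map
#' with simulated coverage, the sliding-window amino-acid conservation test
#' for each conserved pair, compensatory-change counting on a simulated
#' structural alignment per conserved pair, and the upstream composition
#' analysis (GC-percent permutation test, GC-skew profiles, motif scan).
#' Per-stage TSVs, a summary report and a JSON run manifest are written to
#' `outdir`; a stage failure halts the run with a stage-named error, keeping
#' partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with every stage's result tables.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(outdir, "pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  # ---- simulate ----
  sim <- run_stage("simulate", {
    s <- simulate_genome_pair(config$simulation)
    # keep the un-planted genome for the coding-sequence analyses: planting
    # composition signals rewrites upstream regions that sit inside target
    # CDSs and would otherwise confound the divergence stage
    s$genome_a_coding <- s$genome_a
    s$genome_a <- plant_upstream_signals(s$genome_a, s$srna_a,
                                         config$simulation)
    s$coverage_a <- simulate_coverage(s$genome_a, s$srna_a,
                                      config$simulation$coverage_depth,
                                      seed = derive_seed(config$seed, 31L))
    s$coverage_b <- simulate_coverage(s$genome_b, s$srna_b,
                                      config$simulation$coverage_depth,
                                      seed = derive_seed(config$seed, 32L))
    s
  })
  stage_log(log_con, "simulate", "genomes %s (%d bp) / %s (%d bp), %d + %d asRNAs",
            sim$genome_a$genome_id, nchar(sim$genome_a$sequence),
            sim$genome_b$genome_id, nchar(sim$genome_b$sequence),
            nrow(sim$srna_a), nrow(sim$srna_b))
  write_genome(sim$genome_a, file.path(outdir, "genome_a.fasta"),
               file.path(outdir, "genome_a.gff3"))
  write_genome(sim$genome_b, file.path(outdir, "genome_b.fasta"),
               file.path(outdir, "genome_b.gff3"))
  write_offset_map(sim$offset_map, file.path(outdir, "offset_map.tsv"))

  # ---- classify ----
  class_a <- run_stage("classify", classify_srnas(sim$srna_a, sim$genome_a))
  class_b <- run_stage("classify", classify_srnas(sim$srna_b, sim$genome_b))
  stage_log(log_con, "classify", "lineage A: %d antisense / %d total; lineage B: %d / %d",
            sum(class_a$category == "antisense"), nrow(class_a),
            sum(class_b$category == "antisense"), nrow(class_b))
  write_srna_table(class_a, file.path(outdir, "srna_a_classified.tsv"))
  write_srna_table(class_b, file.path(outdir, "srna_b_classified.tsv"))

  # ---- conserve ----
  pairs <- run_stage("conserve", call_conserved(
    class_a, class_b, sim$offset_map,
    coverage_a = sim$coverage_a, coverage_b = sim$coverage_b,
    max_offset = config$conservation_nt))
  stage_log(log_con, "conserve", "%d conserved pairs of %d/%d asRNAs",
            nrow(pairs), nrow(class_a), nrow(class_b))
  readr::write_tsv(pairs, file.path(outdir, "conserved_pairs.tsv"),
                   progress = FALSE)
  ztest <- z_proportion_test(nrow(pairs), nrow(class_a),
                             nrow(sim$genome_a$features))

  # ---- divergence ----
  divergence <- run_stage("divergence", {
    rows <- map(seq_len(nrow(pairs)), function(k) {
      a_row <- class_a[class_a$srna_id == pairs$srna_a[k], ]
      cds_id <- a_row$target_cds
      cds_a <- sim$genome_a$features[sim$genome_a$features$feature_id == cds_id, ]
      cds_b <- sim$genome_b$features[sim$genome_b$features$feature_id == cds_id, ]
      seq_a <- feature_seq(sim$genome_a_coding, cds_a$start, cds_a$end,
                           cds_a$strand)
      seq_b <- feature_seq(sim$genome_b, cds_b$start, cds_b$end, cds_b$strand)
      gi <- srna_gene_interval(a_row, cds_a)
      res <- sliding_window_conservation_test(
        seq_a, seq_b, gi[1], gi[2], flank = config$flank_nt,
        step = config$step, alpha = config$p_conservation)
      ds <- estimate_synonymous_divergence(seq_a, seq_b)
      mutate(glance(res), srna_a = pairs$srna_a[k], cds = cds_id,
             dS = ds$dS, dS_saturated = ds$saturated)
    })
    relocate(list_rbind(rows), "srna_a", "cds")
  })
  stage_log(log_con, "divergence", "%d/%d regions significantly conserved (P < %.2g)",
            sum(divergence$significant), nrow(divergence),
            config$p_conservation)
  readr::write_tsv(divergence, file.path(outdir, "divergence_windows.tsv"),
                   progress = FALSE)

  # ---- covary ----
  covary <- run_stage("covary", {
    rows <- map(seq_len(nrow(pairs)), function(k) {
      aln <- simulate_structure_alignment(
        n_seq = 11, n_pairs = 8, n_compensatory = sample(2:6, 1),
        seed = derive_seed(config$seed, 40L + k))
      rep <- count_compensatory(aln$seqs, aln$structure)
      tibble(srna_a = pairs$srna_a[k], n_pairs = rep$n_pairs,
             n_compensatory = rep$n_compensatory,
             truth_compensatory = aln$truth$n_compensatory)
    })
    list_rbind(rows)
  })
  stage_log(log_con, "covary", "compensatory changes counted for %d structures",
            nrow(covary))
  readr::write_tsv(covary, file.path(outdir, "covariation.tsv"),
                   progress = FALSE)

  # ---- upstream ----
  upstream <- run_stage("upstream", {
    as_feats <- class_a |>
      filter(.data$category == "antisense") |>
      select(source_id = "srna_id", "start", "end", "strand",
             exempt_cds = "target_cds")
    as_regions <- extract_upstream(sim$genome_a, as_feats,
                                   length = config$upstream_len)
    cds_feats <- sim$genome_a$features |>
      select(source_id = "feature_id", "start", "end", "strand")
    cds_regions <- extract_upstream(sim$genome_a, cds_feats,
                                    length = config$upstream_len)
    gc_prof <- gc_permutation_test(as_regions, n_shuffle = config$n_shuffle,
                                   window = config$window,
                                   alpha = config$p_composition,
                                   seed = derive_seed(config$seed, 50L))
    skew <- skew_profiles(as_regions, cds_regions, window = config$window)
    motif <- scan_motif(as_regions, config$simulation$motif)
    export_regions_fasta(as_regions,
                         file.path(outdir, "asrna_upstream.fasta"))
    list(asrna_regions = as_regions, cds_regions = cds_regions,
         gc_profile = gc_prof, skew_profiles = skew, motif = motif)
  })
  stage_log(log_con, "upstream", "%d asRNA regions (%d excluded), %d significant GC windows, motif in %.0f%%",
            nrow(upstream$asrna_regions),
            sum(upstream$asrna_regions$excluded),
            sum(upstream$gc_profile$significant),
            100 * upstream$motif$fraction)
  readr::write_tsv(as_tibble(upstream$gc_profile),
                   file.path(outdir, "gc_profile.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(upstream$skew_profiles),
                   file.path(outdir, "skew_profiles.tsv"), progress = FALSE)

  # ---- report + manifest ----
  cat_counts <- function(tbl) table(factor(tbl$category,
                                           c("antisense", "utr", "intergenic")))
  report <- c(
    "Comparative asRNA analysis summary",
    "==================================",
    sprintf("Lineage A (%s): %s", sim$genome_a$genome_id,
            paste(sprintf("%s=%d", names(cat_counts(class_a)),
                          cat_counts(class_a)), collapse = " ")),
    sprintf("Lineage B (%s): %s", sim$genome_b$genome_id,
            paste(sprintf("%s=%d", names(cat_counts(class_b)),
                          cat_counts(class_b)), collapse = " ")),
    sprintf("Conserved asRNA pairs (±%d nt rule): %d",
            config$conservation_nt, nrow(pairs)),
    sprintf("z-proportion test: z = %.2f, P = %.3g",
            ztest$statistic, ztest$p.value),
    sprintf("Selection: %d/%d conserved regions significant at P < %.2g",
            sum(divergence$significant), nrow(divergence),
            config$p_conservation),
    sprintf("Upstream GC windows significant at P < %.2g: %d/%d",
            config$p_composition, sum(upstream$gc_profile$significant),
            nrow(upstream$gc_profile)),
    sprintf("Motif '%s' found in %.0f%% of asRNA upstream regions",
            config$simulation$motif, 100 * upstream$motif$fraction))
  writeLines(report, file.path(outdir, "summary.txt"))

  manifest <- list(
    package = "srnacons",
    version = as.character(utils::packageVersion("srnacons")),
    seed = config$seed,
    config = config[setdiff(names(config), "simulation")],
    simulation = unclass(config$simulation),
    config_hash = rlang::hash(config),
    created = "run manifest"
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, classified_a = class_a, classified_b = class_b,
                 conserved = pairs, z_test = ztest, divergence = divergence,
                 covariation = covary, upstream = upstream,
                 report = report, outdir = outdir))
}
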