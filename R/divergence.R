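# Genetic code helpers ------------------------------------------------------

# Standard code (identical amino-acid assignments to the bacterial table).
codon_table <- function() Biostrings::GENETIC_CODE

#' Translate a codon sequence to amino acids
#'
#' @param dna Nucleotide string; length must be a multiple of 3.  Codons
#'   containing a gap (`-`) translate to `NA`.
#' @return Character vector of single-letter amino acids (`*` for stops).
#' @export
translate_codons <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3 != 0) abort("sequence length is not a multiple of 3")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(codon_table()[codons])
  aa[grepl("-", codons, fixed = TRUE)] <- NA_character_
  aa
}

# Per-codon synonymous site counts (NG-style): at each position, the fraction
# of the three single-nt changes that preserve the amino acid; changes to
# stop codons count as nonsynonymous.
syn_site_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- codon_table()
    out <- setNames(numeric(length(gc)), names(gc))
    for (codon in names(gc)) {
      s <- 0
      for (pos in 1:3) {
        for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
          alt <- codon
          substr(alt, pos, pos) <- b
          if (gc[alt] != "*" && gc[alt] == gc[codon]) s <- s + 1 / 3
        }
      }
      out[codon] <- s
    }
    tab <<- out
    tab
  }
})

# Average synonymous/nonsynonymous differences between two codons over all
# mutational pathways, excluding pathways through stop codons (all pathways
# used as a fallback when every one is blocked).
codon_syn_diffs <- function(c1, c2) {
  gc <- codon_table()
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v),
                  function(i) lapply(perms(v[-i]), function(p) c(v[i], p))),
           recursive = FALSE)
  }
  paths <- perms(diff_pos)
  count_path <- function(order) {
    cur <- c1; syn <- 0; blocked <- FALSE
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (gc[nxt] == "*" && nxt != c2) blocked <- TRUE
      if (gc[nxt] == gc[cur]) syn <- syn + 1
      cur <- nxt
    }
    c(syn = syn, blocked = blocked)
  }
  res <- vapply(paths, count_path, c(syn = 0, blocked = 0))
  use <- res["blocked", ] == 0
  if (!any(use)) use <- rep(TRUE, ncol(res))
  syn <- mean(res["syn", use])
  c(syn = syn, nonsyn = k - syn)
}

# Amino-acid ML distance ----------------------------------------------------

#' Maximum-likelihood amino-acid distance (20-state equal-rates model)
#'
#' Closed-form ML distance between two aligned amino-acid sequences under the
#' 20-state equal-exchange-rates model:
#' `d = -(19/20) * ln(1 - (20/19) * p)` with `p` the mismatch fraction over
#' comparable (both non-gap) columns.  When `p >= 19/20` the distance is
#' saturated and reported as `Inf`.
#'
#' @param aa_x,aa_y Equal-length character vectors (or strings) of amino
#'   acids; `-` and `NA` mark gaps.
#' @return Numeric distance with attributes `p` (mismatch fraction) and
#'   `saturated` (logical).
#' @examples
#' aa_ml_distance("MKLV", "MKIV")
#' @export
aa_ml_distance <- function(aa_x, aa_y) {
  if (length(aa_x) == 1 && nchar(aa_x[1]) > 1) aa_x <- str_bases(aa_x)
  if (length(aa_y) == 1 && nchar(aa_y[1]) > 1) aa_y <- str_bases(aa_y)
  if (length(aa_x) != length(aa_y)) abort("sequences must be equal length")
  ok <- !is.na(aa_x) & !is.na(aa_y) & aa_x != "-" & aa_y != "-"
  if (!any(ok)) abort("no comparable columns")
  p <- mean(aa_x[ok] != aa_y[ok])
  aa_ml_distance_from_p(p)
}

#' @rdname aa_ml_distance
#' @param p Mismatch fraction in `[0, 1]`.
#' @export
aa_ml_distance_from_p <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  d <- ifelse(p >= 19 / 20, Inf, -(19 / 20) * log(1 - (20 / 19) * p))
  attr(d, "p") <- p
  attr(d, "saturated") <- !is.finite(d)
  d
}

# Synonymous divergence (saturation screen) ----------------------------------

#' Counting-method synonymous divergence (dS) of a codon alignment
#'
#' Nei–Gojobori-style estimate used here only as a saturation screen:
#' synonymous sites and differences are counted per codon (all mutational
#' pathways averaged, stop-codon pathways excluded) and corrected for
#' multiple hits with the Jukes–Cantor transform
#' `dS = -(3/4) * ln(1 - (4/3) * pS)`.  The `saturated` flag is raised when
#' `dS > 3` or the correction is undefined.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length (gaps `-`
#'   allowed; codon columns containing a gap are dropped).
#' @return Object of class `ds_estimate`: list with `dS`, `pS`, `syn_sites`,
#'   `syn_diffs`, `n_codons` and `saturated`.
#' @export
estimate_synonymous_divergence <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences must be aligned (equal length)")
  n <- nchar(seq_a)
  if (n %% 3 != 0) abort("alignment length is not a multiple of 3")
  ca <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  ok <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0) abort("no comparable codons")
  gc <- codon_table()
  if (any(gc[ca[-length(ca)]] == "*") || any(gc[cb[-length(cb)]] == "*")) {
    warn("internal stop codon in alignment")
  }
  st <- syn_site_table()
  S <- (sum(st[ca]) + sum(st[cb])) / 2
  if (S == 0) abort("no synonymous sites")
  Sd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] != cb[i]) Sd <- Sd + codon_syn_diffs(ca[i], cb[i])[["syn"]]
  }
  pS <- Sd / S
  arg <- 1 - (4 / 3) * pS
  dS <- if (arg <= 0) Inf else -(3 / 4) * log(arg)
  structure(list(dS = dS, pS = pS, syn_sites = S, syn_diffs = Sd,
                 n_codons = length(ca),
                 saturated = !is.finite(dS) || dS > 3),
            class = "ds_estimate")
}

#' @export
print.ds_estimate <- function(x, ...) {
  cat(sprintf("<ds_estimate> dS = %s over %.1f synonymous sites (%d codons)%s\n",
              format(x$dS, digits = 4), x$syn_sites, x$n_codons,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

# Sliding-window conservation test -------------------------------------------

# Mean geometric overlap correlation among sliding windows of length W
# (codons) at the given start offsets; per-codon contributions are treated as
# iid, so the correlation of two window means equals their overlap fraction.
window_mean_correlation <- function(starts, W) {
  n <- length(starts)
  d <- abs(outer(starts, starts, "-"))
  mean(pmax(0, 1 - d / W))
}

#' Sliding-window test for excess conservation of an sRNA-encoding region
#'
#' Tests whether the protein region encoding an asRNA (the sRNA overlap
#' extended by `flank` nt each side, converted to whole codons) is more
#' conserved than the rest of the protein.  A window of the same codon
#' length slides over the full alignment in `step`-codon steps; windows
#' overlapping the region by more than `exclude_overlap_frac` of their length
#' are excluded from the null distribution, as are saturated windows.  The
#' region's amino-acid ML distance is then compared with the window
#' distribution, one-tailed (alternative: region less diverged).
#'
#' `method = "prediction"` (default) treats the region estimate as a single
#' new observation from the window distribution and compares it with the
#' window mean on the mismatch-proportion scale (the ML distance is a
#' monotone transform, so the one-tailed ordering is identical):
#' `t = (p_region - mean(p_w)) / se`, where `se` comes from the binomial
#' codon-mismatch model at the pooled non-region mismatch rate, accounting
#' for the autocorrelation of overlapping windows and for the covariance
#' between the region estimate and windows that share codons with it; the
#' P-value is the lower normal tail.  This form is calibrated under the
#' null, unlike a naive one-sample t-test, which treats the region value as
#' a fixed constant and whose empirical window SD has very few effective
#' degrees of freedom under 1-codon-step overlap.  `method = "one_sample"`
#' is that literal one-sample t-test (kept for comparability), and
#' `method = "welch"` is a Welch two-sample t-test of region-overlapping
#' windows against null windows.
#'
#' @param seq_a,seq_b Aligned coding sequences (equal length, frame anchored
#'   to the CDS start; gaps `-` allowed).
#' @param srna_start,srna_end sRNA overlap interval in gene (nt) coordinates.
#' @param flank Flank in nt added to each side of the sRNA overlap before
#'   converting to codons; default 15.
#' @param step Window step in codons; default 1.
#' @param exclude_overlap_frac Windows overlapping the region by more than
#'   this fraction are excluded from the null; default 0.5.
#' @param method See above.
#' @param alpha Significance threshold for the `significant` flag;
#'   default 0.01.
#' @return Object of class `divergence_window_test` with the region bounds
#'   (codons), region distance, window distances, `t_stat`, `p_value`,
#'   `significant` and `untestable` flags.
#' @export
sliding_window_conservation_test <- function(seq_a, seq_b, srna_start, srna_end,
                                             flank = 15, step = 1,
                                             exclude_overlap_frac = 0.5,
                                             method = c("prediction",
                                                        "one_sample", "welch"),
                                             alpha = 0.01) {
  method <- match.arg(method)
  assert_scalar_interval(srna_start, srna_end, "sRNA interval")
  aa_a <- translate_codons(seq_a)
  aa_b <- translate_codons(seq_b)
  C <- length(aa_a)
  if (srna_end > C * 3) abort("sRNA interval outside the gene")

  rs <- max(1, srna_start - flank)
  re <- min(C * 3, srna_end + flank)
  c1 <- ceiling(rs / 3)
  c2 <- ceiling(re / 3)
  W <- c2 - c1 + 1

  comparable <- !is.na(aa_a) & !is.na(aa_b) & aa_a != "-" & aa_b != "-"
  mismatch <- comparable & aa_a != aa_b
  # window mismatch fractions via cumulative sums
  cm <- c(0, cumsum(mismatch))
  cu <- c(0, cumsum(comparable))
  win_p_interval <- function(s, e) {
    u <- cu[e + 1] - cu[s]
    if (u == 0) return(NA_real_)
    (cm[e + 1] - cm[s]) / u
  }
  region_p <- win_p_interval(c1, c2)
  region_d <- if (is.na(region_p)) NA_real_ else
    as.numeric(aa_ml_distance_from_p(region_p))

  starts <- seq(1, C - W + 1, by = step)
  wp <- vapply(starts, function(s) win_p_interval(s, s + W - 1), numeric(1))
  wd <- ifelse(is.na(wp) | wp >= 19 / 20, NA_real_,
               -(19 / 20) * log(pmax(1e-300, 1 - (20 / 19) * wp)))
  region_overlap <- overlap_len(starts, starts + W - 1, c1, c2) / W
  in_null <- region_overlap <= exclude_overlap_frac & !is.na(wd)
  windows <- tibble(start_codon = as.integer(starts), p = wp, distance = wd,
                    region_overlap = region_overlap, in_null = in_null)

  null_d <- wd[in_null]
  n <- length(null_d)
  untestable <- n < 3 || is.na(region_d) || !is.finite(region_d)
  t_stat <- NA_real_; p_value <- NA_real_
  if (!untestable) {
    m <- mean(null_d)
    if (method == "prediction") {
      # Null variance from the binomial codon-mismatch model (delta method):
      # overlapping 1-codon-step windows leave the empirical window SD with
      # too few effective degrees of freedom to be usable, while the pooled
      # null mismatch fraction estimates the marginal variance with high
      # precision under among-codon homogeneity.
      region_cod <- seq(c1, c2)
      null_cod <- setdiff(seq_len(C), region_cod)
      q <- sum(mismatch[null_cod]) / max(1, sum(comparable[null_cod]))
      if (q >= 19 / 20) {
        untestable <- TRUE
      } else {
        # The comparison runs on the mismatch-proportion scale (the ML
        # transform is monotone, so the ordering and one-tailed P agree);
        # the variance comes from the binomial codon-mismatch model, which
        # has far more effective degrees of freedom than the empirical SD
        # of heavily overlapping windows.
        wc_null <- (cu[starts[in_null] + W] - cu[starts[in_null]])
        wc_region <- cu[c2 + 1] - cu[c1]
        m_p <- mean(wp[in_null])
        V <- window_mean_correlation(starts[in_null], W)
        # windows sharing codons with the region covary with its estimate
        ov_codons <- region_overlap[in_null] * W
        cov_rw <- sum(ov_codons) / (n * wc_region * mean(wc_null))
        var_frac <- 1 / wc_region + V / mean(wc_null) - 2 * cov_rw
        se <- sqrt(q * (1 - q) * pmax(var_frac, 0.1 / wc_region))
        if (se == 0) {
          t_stat <- if (region_p == m_p) 0 else sign(region_p - m_p) * Inf
        } else {
          t_stat <- (region_p - m_p) / se
        }
        p_value <- pnorm(t_stat)
      }
    } else if (method == "one_sample") {
      s <- sd(null_d)
      if (s == 0) {
        t_stat <- if (region_d == m) 0 else sign(region_d - m) * Inf
        p_value <- pnorm(t_stat)
      } else {
        tt <- t.test(null_d, mu = region_d, alternative = "greater")
        t_stat <- -unname(tt$statistic)   # negative = region more conserved
        p_value <- tt$p.value
      }
    } else {
      region_windows <- wd[region_overlap > exclude_overlap_frac & !is.na(wd)]
      if (length(region_windows) < 2 || sd(region_windows) + sd(null_d) == 0) {
        untestable <- TRUE
      } else {
        tt <- t.test(region_windows, null_d, alternative = "less")
        t_stat <- unname(tt$statistic)
        p_value <- tt$p.value
      }
    }
  }
  structure(list(
    region_bounds = c(start_codon = c1, end_codon = c2),
    region_distance = region_d,
    windows = windows,
    n_null_windows = n,
    t_stat = t_stat,
    p_value = p_value,
    significant = isTRUE(p_value < alpha),
    untestable = untestable,
    method = method,
    alpha = alpha
  ), class = "divergence_window_test")
}

#' @export
print.divergence_window_test <- function(x, ...) {
  cat(sprintf(
    "<divergence_window_test> region codons %d-%d: d = %s vs %d windows; t = %s, P = %s%s\n",
    x$region_bounds[1], x$region_bounds[2],
    format(x$region_distance, digits = 3), x$n_null_windows,
    format(x$t_stat, digits = 3), format(x$p_value, digits = 3),
    if (x$untestable) " [untestable]"
    else if (x$significant) " [significantly more conserved]" else ""))
  invisible(x)
}

#' @export
tidy.divergence_window_test <- function(x, ...) x$windows

#' @export
glance.divergence_window_test <- function(x, ...) {
  tibble(region_start_codon = x$region_bounds[[1]],
         region_end_codon = x$region_bounds[[2]],
         region_distance = x$region_distance,
         mean_window_distance = mean(x$windows$distance[x$windows$in_null]),
         n_null_windows = x$n_null_windows,
         t_stat = x$t_stat, p_value = x$p_value,
         significant = x$significant, untestable = x$untestable,
         method = x$method)
}
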