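---
title: "Methods: comparative asRNA conservation and promoter-region analysis"
author: "srnacons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative asRNA conservation and promoter-region analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnacons)
```

## The scientific setting

Host-restricted bacterial endosymbionts such as *Carsonella ruddii* carry
tiny (~160–175 kb), gene-dense, extremely AT-rich (~84% AT) chromosomes
that stay syntenic over tens of millions of years.  Those properties make
them a natural system for studying the evolution of *cis*-encoded antisense
small RNAs (asRNAs): homologous genomic positions are identifiable across
lineages, and asRNAs — transcripts overlapping a CDS on the opposite strand
with perfect complementarity — dominate the small-RNA repertoire because
almost no intergenic space remains.

srnacons implements the comparative analysis of such a system as a tested,
reusable pipeline over five questions:

1. **Catalogue** — which predicted sRNAs are antisense, UTR-associated, or
   intergenic, and which biosynthetic pathways do the asRNA targets sit in?
2. **Conservation** — which asRNAs of two lineages are expressed from
   orthologous positions?
3. **Selection** — is the protein region encoding a conserved asRNA more
   conserved at the amino-acid level than the rest of its protein?
4. **Structure** — do consensus secondary structures show compensatory
   basepair changes?
5. **Promoters** — do the 61-nt regions upstream of asRNAs carry
   composition signals (GC dips, GC-skew deviations, motifs)?

Transcript prediction, read processing, whole-genome alignment, RNA folding
and de novo motif discovery are out of scope: the pipeline consumes their
outputs (coordinate tables, offset maps, dot-bracket structures) in plain
text formats.

## Coordinate and orientation conventions

All genomic intervals are 1-based inclusive (the GFF3 dialect) at every
interface.  Genomes are treated as linear; upstream regions that would wrap
the origin are excluded as `genome_edge` rather than silently wrapped, so
results are reproducible without origin bookkeeping.  Ambiguity codes are
rejected by default (`ambiguity = "mask"` replaces them with `A`, the
AT-rich prior, with a warning).

Upstream regions are read on the feature's strand; *position 1 is the
nucleotide immediately 5' of the start*, position 61 the farthest upstream.
Window *w* of the 7-nt/1-nt-step scan covers positions *w..w+6*, so a 61-nt
region yields exactly 55 windows and window 1 abuts the transcription
start.  Published figures of this kind of analysis describe the
window-index-to-position mapping inconsistently; srnacons fixes the
convention above and documents it rather than reverse-engineering figure
axes.

## Classification rules

An sRNA is **antisense** when it overlaps a CDS on the opposite strand by
at least 1 nt (the most inclusive threshold; its target is the CDS with
maximal overlap, ties broken to the lexicographically smallest feature id,
so runs are reproducible).  It is **UTR** when it overlaps no CDS on its
own strand but lies within 50 nt (configurable) of a same-strand CDS —
the field does not quantify "within the untranslated region", and in
Carsonella-like genomes the choice is inert because no UTR sRNAs survive
the density of coding sequence.  Everything else is **intergenic**.

Differential-expression screening consumes externally computed q-values
(the upstream transcript caller's test is not reimplemented) and keeps rows
with q ≤ 0.05 and a mean of ≥ 9 raw reads across replicates.
Upper-quantile normalisation scales each library so its 75th percentile of
nonzero counts matches the across-sample mean of those percentiles.

## Conserved-pair calling

Lineage-A asRNA coordinates are translated into lineage B through a
blockwise offset map (the consumable form of a whole-genome alignment; an
interval maps through the block covering the largest share of it, flagged
when it straddles blocks).  A pair is orthologous when both mapped start
and end coordinates agree within 15 nt — "coordinates", plural, is read as
both endpoints; a start-only mode is available — and, when per-base
coverage is supplied, every base of each sRNA has depth ≥ 1 (the
continuous-coverage check; published work verified continuity visually, so
the numerical criterion is this package's own and can be switched off).
Each sRNA joins at most one pair, chosen greedily by smallest total offset
with deterministic tie-breaks; on small instances the greedy pairing
coincides with exhaustive minimal-offset matching whenever offsets are
unique, which the test suite verifies.

Whether more asRNAs are conserved than expected is assessed with a
one-sided z-proportion test of `p_hat = n_conserved / n_srna` against
`p0 = n_srna / n_cds`, `z = (p_hat − p0) / sqrt(p0 (1 − p0) / n_srna)`,
with no continuity correction.  Note that for the published count
combinations this formula yields z ≈ 1.89 (36 sRNAs, 196 CDSs) and
z ≈ 2.73 (33 sRNAs, 207 CDSs); the package reports what the formula
computes.

## The sliding-window conservation test

Synonymous sites between deeply diverged AT-rich genomes are saturated, so
only amino-acid divergence is informative.  Divergence is measured as the
maximum-likelihood distance under the 20-state equal-rates model, which has
the closed form

$$d = -\tfrac{19}{20}\,\ln\!\bigl(1 - \tfrac{20}{19}\,p\bigr),$$

with *p* the amino-acid mismatch fraction over comparable columns
(saturated at *p* ≥ 19/20).  Empirical-matrix ML is an extension point; the
equal-rates model is fast, dependency-free, and sufficient because absolute
distances are not the inferential target — the *contrast* between the
asRNA-encoding region and the rest of the protein is.

The region of interest is the sRNA overlap extended 15 nt on each side,
converted to whole codons (length *W*).  A window of length *W* slides over
the alignment in 1-codon steps; windows overlapping the region by more than
50% of their length are excluded from the null set (both the step and the
exclusion fraction are configurable; neither is standardised in the
field).

**Why the default test is not a plain one-sample t-test.**  Comparing "the
region's estimate against the window distribution with a one-sample
t-test" treats the region value as a fixed constant; under the null the
region estimate is itself a draw from (approximately) the window
distribution, so that construction rejects at a rate inflated by roughly
√(number of windows) and is useless as a calibrated test.  Overlapping
1-codon-step windows pose a second problem: their empirical standard
deviation has only about (gene length / region length) effective degrees of
freedom.  The default (`method = "prediction"`) therefore compares the
region mismatch proportion with the mean of the window proportions — the
ML transform is monotone, so the one-tailed ordering is unchanged — and
takes the standard error from the binomial codon-mismatch model at the
pooled non-region mismatch rate, with two analytic corrections: the
variance of the window mean under the geometric overlap-correlation of
sliding windows, and the covariance between the region estimate and
windows that share codons with it.  The P-value is the lower normal tail;
significance is declared at P < 0.01.  The acceptance script measures the
size of this test under a no-signal simulation (rejection ≈ 1% at
P < 0.01) and its power under a strong planted contrast (inside rate 0.05
vs outside 0.4 substitutions/site, footprints ≥ 30 codons).  The literal
one-sample form (`method = "one_sample"`) and a Welch two-sample form
(`method = "welch"`) remain available for comparison.  The test reports
`untestable` when fewer than 3 usable null windows remain (e.g. the region
covers the whole gene) or the region is saturated.

The model assumes mismatches are independent and identically distributed
across codons outside the region; genuine among-site rate heterogeneity in
real proteins would widen the window distribution beyond the binomial
model and make the test anti-conservative to an unknown degree.  That
limitation is inherited from treating a single pairwise alignment as the
unit of analysis.

**Synonymous saturation screen.**  dS is estimated by Nei–Gojobori-style
counting (all mutational pathways averaged, stop-codon pathways excluded)
with the Jukes–Cantor correction, flagged `saturated` when dS > 3 or the
correction is undefined.  A caveat worth stating explicitly: the JC
correction assumes uniform equilibrium base frequencies.  Between genomes
at an AT-biased stationary composition, the synonymous mismatch fraction
plateaus near its compositional ceiling (~0.6 at 16% GC) even at infinite
time, which the correction maps to dS ≈ 1.2, not > 3 — printed dS ≫ 3
values in the literature come from ML estimators with composition
parameters.  The screen is therefore interpreted as "synonymous signal
exhausted", and the synthetic generator places the data in exactly that
regime (fully randomized synonymous positions) rather than chasing a
number no counting method can produce there.

## Structure covariation

For each basepair (i, j) of a consensus structure over an alignment, the
set of canonical pair types (AU, UA, GC, CG, GU, UG — GU wobble counts)
realised across rows (ignoring rows gapped at i or j) is collected; a pair
is **compensatory** when at least two distinct canonical types occur, i.e.
the partners substituted jointly while preserving pairing.  Pairs with no
canonical realisation are reported separately as inconsistent rather than
silently dropped.  When comparing a pairwise-alignment structure with a
multi-genome structure, shared pairs are counted after translating columns
through an explicit column map, and the reported fraction uses the
pairwise pair count as denominator, which bounds it by 1.  Folding itself
(and ΔG) is external.

## Upstream composition analysis

For each non-excluded 61-nt upstream region the observed per-window GC
percent is compared against a permutation null: 100 uniform (Fisher–Yates)
permutations of that region's own 61-mer, i.e. a mononucleotide shuffle
(a dinucleotide-preserving shuffle via the Altschul–Erickson edge-walk
construction is available).  Per window, a paired two-sided t-test across
regions compares observed GC percent with each region's null mean;
windows at P < 0.05 are flagged with the direction of the deviation.  No
multiple-testing correction is applied by default, matching per-window
starring practice; Benjamini–Hochberg is available behind `p_adjust`.

Because every permutation preserves the region's composition, the null
mean of *every* window equals the region's overall GC percent.  A genuine
local GC dip therefore has two unavoidable consequences: dip windows test
negative, and the remaining windows of the same regions read as relatively
GC-*enriched*.  Recovery of a planted dip is accordingly measured
directionally (dip windows flagged negative; non-dip windows not flagged
negative), and significant positive windows outside a dip are a property
of the null, not an error.

GC skew, (C − G)/(C + G), is defined as 0 for windows with no G or C —
common at 84% AT, and dropping them would bias profiles.  Skew profiles of
asRNA and CDS upstream sets are compared descriptively (mean ± SE per
window, no hypothesis test): when the entire qualifying population is
analysed there is no sampling inference to make.  The CDS-overlap
exclusion rule differs by analysis, as it must in a gene-dense genome: an
asRNA's upstream region is excluded when it intersects any CDS *other
than its own target* (it lies inside the target by construction; a literal
any-CDS rule would exclude every asRNA), while a CDS's upstream region is
excluded when it intersects any CDS other than itself.

Motif handling is split: regions are exported as FASTA for external de
novo discovery, and a user-supplied IUPAC motif (e.g. the Pribnow box
`TANAAT`) is scanned internally with degenerate matching.

## The synthetic-data generator

`simulate_genome_pair()` produces the paired study the analyses assume:
two syntenic genomes of orthologous CDSs (default 196 CDSs of mean 850 nt
at 16% GC, giving a ~170-kb chromosome), lineage-B coding sequences derived
from lineage A by codon-level substitution, asRNAs placed antisense within
CDSs (36 in A, 32 in B, 11 orthologous by default), and an exact offset
map.  Key modelling choices:

* **Nonsynonymous process** — with probability equal to the configured
  rate (0.4/codon outside conserved footprints, 0.05 inside the footprint
  ± 15 nt), a codon takes a single-nucleotide amino-acid-changing
  substitution.  Substitution targets are weighted by the genome's base
  composition: unweighted choices would drag a 16%-GC genome toward 50%
  GC within one round of synonymous saturation, violating the composition
  the generator exists to emulate.
* **Synonymous process** — with probability 0.9 a codon is resampled from
  its full synonymous class with composition weights.  This exactly
  preserves the generator's conditional codon distribution (stationarity)
  while destroying synonymous identity — the "only amino acids are
  informative" regime.
* **Coordinate jitter** — orthologous asRNA endpoints in lineage B are
  jittered by a truncated normal (SD 3 nt by default, truncated at
  ± 2.5 SD and at the CDS bounds), keeping planted pairs inside the 15-nt
  rule for SD ≤ 6 so that recovery of ground truth is a sharp test.
* **Planted upstream signals** — within the dip band (windows 33–48) bases
  are resampled at GC = genome GC − 0.10; within the skew band (windows
  46–54) G/C bases are rebalanced toward C to a target skew; the motif is
  written at a fixed offset (3' end 8 nt upstream) with probability 0.5.
  Edits are confined to the 61-nt regions.  Because an asRNA's upstream
  region lies inside its target CDS, planting corrupts coding sequence
  there; the pipeline therefore runs coding-sequence analyses on the
  pre-planting genome.
* **Coverage** — Poisson per-base counts over sRNA intervals, with
  optional punched zero-coverage gaps as negative controls for the
  continuity check.

All randomness flows from one integer seed through deterministic
per-module sub-streams; identical configurations give byte-identical
output.

What the generator does **not** emulate: indels and rearrangements
(symbiont genomes are syntenic; the offset map machinery still supports
shifted and inverted blocks for real inputs), read-level sequencing noise,
operon structure, expression dynamics, and among-site rate heterogeneity
within a gene outside the planted footprint.  Passing the recovery tests
therefore shows the statistics behave correctly under their stated model,
not that real data meet that model.

## Problem sizes and numerical choices

The test suite and acceptance script use simulation sizes chosen to make
binomial noise small relative to the bands they check: 200 replicate
36-region sets for the composition null (flag rate ≈ 5% at P < 0.05),
2,500 no-signal genes of 250 codons for the conservation-test null
(rejection ≈ 1% at P < 0.01), 120 genes for power, 200 regions for dip
recovery (per-window power saturates there; at 36 regions a 10-point dip
in a 7-nt window is only borderline detectable), and paper-scale
(36 + 32 asRNA) simulations for caller precision/recall.  Degenerate
inputs resolve explicitly: zero-variance t statistics are 0 with P = 0.5
when the region equals the null mean and ± ∞ otherwise; skew of G+C-free
windows is 0; pathway tallies of empty tables are 0; regions shorter than
the genome edge allows are excluded, not truncated.

## Known limitations

* The binomial variance model of the conservation test assumes within-gene
  rate homogeneity outside the region (see above).
* The NG-style dS screen cannot register dS > 3 at AT-biased stationarity;
  it answers "is synonymous signal exhausted", not "how large is dS".
* The 15-nt orthology rule presumes transcript-boundary prediction noise
  well under 15 nt in both lineages; systematic boundary shifts (e.g.
  different 5'-end calling) would need the start-only mode or a wider
  threshold.
* Upstream analyses treat regions as independent; overlapping upstream
  regions of nested asRNAs are not deduplicated.
* Circular chromosomes are handled as linear sequences; features spanning
  the origin must be re-coordinated upstream of this package.
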