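---
title: "Measuring splice-related purifying selection with lincsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring splice-related purifying selection with lincsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincsel)
```

## The scientific question

Spliced noncoding genes evolve almost as fast as their introns, yet their
splice sites are conserved. `lincsel` asks *where* within such genes
purifying selection acts, and *what* predicts differences in evolutionary
rate between genes. The working hypothesis is that most constraint is
splice-related: exonic splice enhancers (ESEs) — purine-rich hexamers bound
by SR proteins, functional mostly within ~70 bp of splice junctions — should
be dense near junctions, evolve slower than matched non-ESE sequence, and
account for most of the exon/intron rate difference.

The pipeline takes gene models (BED12), per-exon and per-intron pairwise
alignments between a reference species and a second species, an ESE hexamer
list, an FPKM expression table, and ChIP/DNase peak tracks, and produces
region-stratified substitution rates, positional profiles, predictor
correlation reports, stop-codon (NMD) statistics and chromatin density
analyses.

## The model and its assumptions

### Region partition

Each gene is analysed in transcript orientation on ungapped reference
coordinates. Every junction-adjacent exon end claims up to 70 bp of flank
(`flank_bp`); internal exons never let a flank cross the exon midpoint, with
the 5' half taking the extra base for odd lengths, while a terminal exon's
single junction may claim up to the whole exon. The remaining exon sequence
is core; intron cores drop 20 bp (`intron_trim`) at each intron end. Genes
whose concatenated flanks, cores or intron cores fall below 100 bp
(`min_concat`) carry rates but no rate ratios, to keep noisy short
concatenations out of the medians. Transcript ends are not junctions: they
contribute no flank, and single-exon genes are excluded from all
junction-relative analyses.

### ESE annotation

Gaps are removed from the reference row of the stitched exon alignment, the
ungapped sequence is scanned against the hexamer set (overlapping matches
union; `N` never matches), and flags are re-projected onto alignment
columns. Only the reference row is scanned — the hexamer set defines
reference-species enhancers — with `scan_both = TRUE` available. The scan
runs across the concatenated exons, so a hexamer could in principle straddle
a junction; with 70-bp flanks this affects at most five columns per junction
and no result in this package depends on it. ESE density is flagged
nucleotides over summed exon length; `frac70` is flank length over total
exon length.

### Substitution distances

Per column set we count sites (gap- and N-free columns), substitutions,
transitions (`A<->G`, `C<->T`) and transversions, plus each row's GC
fraction. The gene-level distance is

K = −h·ln(1 − P/h − Q) − ½(1 − h)·ln(1 − 2Q), h = θ₁ + θ₂ − 2θ₁θ₂,

with P and Q the transition and transversion proportions and θᵢ the GC
fraction of row *i*. This relaxes the assumption that both lineages share a
substitution pattern: with θ₁ = θ₂ = θ it reduces to the Tamura (1992)
single-lineage correction (h = 2θ(1−θ)), and at θ = 0.5 to the Kimura
two-parameter distance — both identities are enforced to 1e−12 in the test
suite. Saturated inputs (a non-positive logarithm argument) flag the gene
and exclude it from medians rather than producing infinities; the degenerate
h = 0 case falls back to −½·ln(1 − 2P − 2Q) with a warning. Positional
profiles deliberately use the uncorrected p-distance (substitutions/sites)
with a binomial SEM per pooled cell, while gene-level `Ke`, `Ki`, `Kef`,
`Kec`, `Kic` use the corrected distance; ratios are natural logs and are
undefined (never ±Inf) when a denominator rate is zero.

### Composition-matched null

ESEs are purine-rich, so a positional rate difference could be compositional.
For a profile cell we draw, from the pooled concatenated exon alignment,
random column sets with exactly the cell's reference-base counts (without
replacement within a draw) and average their p-distances. The SD of the
per-draw rates is the Monte Carlo SE of a single matched draw, which is the
right yardstick for comparing one observed cell against the null. Matching
uses reference-row bases only, consistent with the scan decision.

### Folding proxy

RNA stability enters the predictor table as the fraction of paired
nucleotides in a predicted structure. The built-in folder is a
Nussinov-style base-pair maximization DP (C++ via Rcpp) with minimum loop
size 3 and GU wobble allowed, with deterministic traceback (pairing branch
preferred, then the smaller partner index). Pair maximization preserves the
monotone intent of the proxy without free-energy parameters; an adapter
contract (`fold_external()`, dot-bracket and `.ct` parsers) plugs in any
minimum-free-energy tool such as ViennaRNA's `RNAfold` where installed.
Folding applies to the spliced transcript; because the DP is cubic, the
pipeline folds a 5' window (`fold_max_len`, default 1000 nt) — a local
folding proxy in the spirit of windowed folders. Note the proxy (and any
in-silico folder) ignores bound protein complexes such as the EJC.

### NMD stop-codon tests

Stop codons (`TAA`, `TAG`, `TGA`) are counted in non-overlapping codons per
frame offset on the ungapped reference, transcript orientation. The paired
penultimate-exon test compares the first and last 50 bp of penultimate exons
longer than 100 bp (sum over the three frames; ties dropped; exact binomial
test against 0.5). The two-exon test compares the windows [−100, −51] and
[−50, −1] relative to the first exon's 3' junction, the latter being the
NMD "shadow" within which stops escape decay. "Fewer than three stops" is
counted as a total across frames by default (a total below three guarantees
a stop-free frame); `mode = "per_frame"` reports windows with at least one
entirely stop-free frame instead. Mononucleotide shuffling preserves exact
base counts per window. The frame-independence closed form
∏ₓ(1 − 3/64)^codons overestimates the true stop-free probability of iid
sequence (frames share letters), so tests compare the shuffle expectation
against it only within the window-sampling Monte Carlo error.

### Chromatin analyses

Peak count density counts raw peak records with ≥1 bp overlap (half-open
intervals) per bp of unspliced gene; coverage density merges peaks first.
Intron density is (exons − 1) per unspliced bp. Flank profiles use
independent 10-kb windows anchored at the gene edges, clipped at contig
bounds (a window must lie fully on-contig to count). Equal-mass binning
ranks genes by unspliced length and greedily closes a bin once it holds
1/n of the total DNA. The activity comparison uses a label-permutation test
on the difference of group medians with the unbiased estimator
p = (n+1)/(m+1) — robust to the many zero-density genes that distort rank
tests. The neighbour-expression profile reports the fraction of overlapping
neighbour genes with nonzero expression per window (expression is treated
as binary), averaging only over focal genes that have neighbours in the
window.

### Correlation screen

Predictors of the gene-level corrected exonic distance are max and median
log₂(FPKM+1), expression breadth (fraction of tissues with FPKM > 0), the
folded fraction, `frac70`, ESE density and GC content. Each predictor gets
a plain Spearman correlation and a full partial correlation: all variables
are rank-transformed, and the partial coefficient comes from the inverse
joint correlation matrix (equal to the recursive closed form for one
control). Bonferroni uses a family size of 14 by default (seven predictors
in each of two gene classes). The leave-some-out control subset used to
probe interaction effects (e.g. removing GC) is exposed through
`partial_correlation()` directly. Local-regression residual comparisons use
an own tricube local-linear fitter with Epanechnikov, Gaussian and uniform
alternatives and spans {0.3, 0.5, 0.75, 1.0}; the uniform kernel at span 1
reduces exactly to ordinary least squares, which anchors the implementation
to `lm()` in the tests.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, so
every stage is testable without genome-scale downloads.

* **Gene geometry** — exon count 1 + Poisson(1.9) (mean ≈ 2.9, ~15%
  single-exon), exon lengths lognormal(log 400, 0.45) clamped to [60, 3000]
  bp, introns lognormal(log 2500, 0.7) clamped to [150, 20000] bp: the
  geometry of a reconstructed human lincRNA catalogue at a size that keeps
  a 500-gene run in seconds. Genes are placed on one synthetic chromosome
  with 120–250 kb spacing so 100-kb neighbourhood analyses have room; ~10%
  are minus-strand to exercise orientation handling.
* **Divergence** — a two-lineage star tree from the ancestral sequence with
  0.07 expected substitutions/site total (human–macaque scale), transition
  bias κ = 2, per-lineage GC targets (0.33, 0.37) biasing the exchange
  matrix so the lineage-heterogeneous distance has something to correct.
  Per-site substitution probability is the neutral rate times the site's
  class multiplier: ESE 0.85, flank non-ESE 1.0, core 1.0, intron 1.0 —
  the lincRNA-like regime in which non-ESE exonic sequence is effectively
  neutral and ESEs evolve 15% slower.
* **ESEs** — the default hexamer set is *synthetic*: all 64 purine-only
  hexamers, mirroring the purine-rich composition of experimentally derived
  ESE sets (supply a real list via `read_hexamers()`). Hexamers are planted
  only within flank regions, never spanning a junction, never overlapping,
  with probability 0.15·exp(−(d−1)/50) per candidate start — producing the
  ~30–40% flank ESE density and junction-proximal decay described for real
  exons.
* **Indels** — Poisson events at 0.002/site, geometric lengths (capped at
  10), realised as deletions in the non-reference row or insertions carried
  by the non-reference row, so the reference's ungapped length always
  matches the gene model. Planted ESEs are avoided by default. There is no
  realignment step: the true alignment is returned.
* **Expression** — per-gene breadth from Beta(1.2, 1.8); tissues expressed
  independently at that probability; expressed entries lognormal FPKM over
  24 tissues. A Gaussian copula (`expr_rate_rho`) can plant a
  breadth–constraint association for recovery tests.
* **Peaks** — CHD1 intensity per bp is `base + slope × intron_density`,
  with a positive slope (0.3) for active genes and a weakly negative one
  for inactive genes, reproducing the sign structure of the remodeller
  analysis; DHS adds flank peaks whose intensity decays exponentially
  (30 kb scale) from the edges of active genes.

What the generator does **not** emulate: splice-site motifs, realignment
error, rate variation along introns, transposable-element insertions in
exon cores, polymorphism, GC isochore structure, and any real ESE sequence
identity. Passing recovery tests therefore demonstrates that the estimators
measure what they claim under the stated model — not that real lincRNAs
behave this way.

## Numerical and design choices

* Coordinates are 0-based half-open (BED) throughout; all sequence analysis
  is in transcript orientation.
* The indel filter removes genes with gap fraction strictly above 15%,
  pooled over exon and intron alignments (`filter_by_gap`).
* The odd-exon midpoint goes to the 5' half; fixed for determinism.
* Junction-distance profiles start at d = 6 by default (`dmin`), avoiding
  the first five positions where a hexamer cannot be fully junction-proximal;
  distances are ungapped-reference, not alignment columns.
* Scanned-ESE parameter recovery is assessed on the generator's *true* site
  classes: rescanning the evolved reference row conditions matched sites on
  having no match-destroying substitutions, which deflates the apparent ESE
  rate (an ascertainment effect inherent to scanning extant sequence). The
  composition-matched-null calibration run therefore simulates no ESE
  structure at all, where the scan is purely compositional and the null is
  exact.
* All randomness flows from one root seed through fixed per-stage
  substreams (models, alignments, expression, peaks), so adding a stage
  never shifts another stage's draws; repeated runs are byte-identical.
* Problem sizes used by the checks: 500 genes for rate-multiplier recovery,
  150 genes for null calibration, 400 genes for chromatin sign recovery,
  500 permutation runs of 999 iterations for p-value uniformity, 200
  sequences of length ≤ 12 against the exhaustive folding oracle — each
  chosen as the smallest run at which the targeted effect is comfortably
  resolved.

## A worked run

```{r, eval = FALSE}
out <- run_all(out_dir = "lincsel_out", seed = 1)
out$medians
```

`run_all()` simulates (or ingests), applies the gap filter, annotates,
estimates rates, and writes per-gene tables, profiles with composition
nulls, the correlation report, the NMD report, chromatin summaries and a
machine-readable manifest recording seed, thresholds and gene attrition.

## Known limitations

* The pairwise distance assumes independent sites and no rate variation
  within a column set; saturation is flagged, not modelled.
* The folding proxy maximizes pair count, not free energy; its absolute
  values are not comparable with MFE folded fractions, only its ranking
  intent is preserved.
* The neighbour-expression statistic treats expression as binary and all
  neighbour gene classes alike.
* With the purine-only synthetic hexamer family, transitions within purines
  never destroy a match, so scan-based ascertainment is milder than it
  would be for a real ESE set; conclusions about scan bias transfer
  qualitatively, not quantitatively.
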