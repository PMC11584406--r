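---
title: "Methods: stripe calling, P–E connectivity and the two-phase model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stripe calling, P-E connectivity and the two-phase model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`cisconn`, the assumptions behind them, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and
the numerical edge-case rules.

## 1. Mappability-normalized stripe calling

High-resolution multi-enzyme contact maps over-represent reads at open
chromatin. The caller's core assumption is **proportionality**: the
mappability-driven over-representation of a locus is the same multiplicative
factor for long-range contacts and for short-range self-ligation pairs.
Self-ligation pairs (distance < 1 kb, inward +/– orientation) carry no
distal-interaction information, so they serve as a pure mappability
readout. Under the assumption, for each 100-bp bin

$$\mathrm{expected} = \frac{\mathrm{long}_{bg}}{\mathrm{short}_{bg}}
  \times \mathrm{short}_{local},$$

with a 2-kb local and a 50-kb background window (both centered on the bin,
sliding at the 100-bp step), cancels the mappability factor. The observed
local long-range count is tested against this expectation with an
upper-tail Poisson probability $P(X \ge \mathrm{obs} \mid \lambda =
\mathrm{expected})$; Benjamini–Hochberg correction is applied over all
mappable bins of a sample jointly (one family per sample — the most
conservative defensible family, since the procedure makes one sweep per
sample). Stripe strength is $\log_{10}((\mathrm{obs}+1)/(\mathrm{expected}+1))$;
base 10 matches the bedGraph-comparison convention of the log-fold-change
track tools this mirrors, and the pseudo-count of 1 keeps empty bins
finite and at exactly zero strength.

Parameters (all configurable via `stripe_params()`): long-range threshold
1.5 kb and short-range threshold 1 kb for calling; the wider mappability
diagnostic (`interaction_fe_track()`) defaults to > 2 kb / < 1.5 kb. The
two threshold pairs are deliberately both exposed rather than reconciled:
they serve different steps (significance calling versus the raw
fold-enrichment track), and each keeps its conventional value. Records in
the dead zone between short and long thresholds belong to neither class.

Edge rules: a bin with `short_bg = 0` has no mappability estimate at all;
rather than inventing a floor, it is marked unmappable (`expected = NA`)
and excluded from testing. Chromosomes shorter than the background window
are skipped with a warning. An empty record stream returns an empty
statistics table.

Consensus: a bin counts a "sample hit" when q < 0.01; bins with ≥ 3 hits
are merged by half-open interval arithmetic, merged windows < 500 bp are
dropped, blacklist overlaps removed, and only listed (autosomal)
chromosomes kept. Per-sample anchor strengths are the mean bin strengths
within the anchor.

## 2. Per-gene P–E connectivity

The promoter interaction zone is [TSS − 1.5 kb, TSS + 0.5 kb), oriented by
strand; enhancer zones are accessible peaks padded by 500 bp; pairing
admits all peaks within 200 kb of the TSS, excluding peaks overlapping the
promoter zone itself. Peaks that are other genes' promoters are retained
(the pairing rule is distance-and-accessibility based) but labelled, so
promoter–promoter contacts can be excluded by the caller if desired.

Raw contacts are extracted on 1-kb bin boundaries (both zones expanded
outward to bin edges) and normalized twice:

* **Mappability** $M_g$: self-ligation reads-per-kb in the promoter zone
  over the same quantity in the 50-kb neighborhood centered on the TSS.
  The promoter zone is excluded from the neighborhood denominator — with
  it included, the ratio is shrunk toward 1 by the promoter's own signal
  (a 2-kb zone is 4% of the window), and the exclusion makes the
  uniform-coverage case exactly 1. The per-million factor of RPKM cancels.
  A zero promoter count is floored at one read; zero neighborhood coverage
  leaves $M_g$ undefined and flags the gene. The neighborhood is centered
  (the natural symmetric choice; nothing in the procedure favors the
  downstream side).
* **Coverage** $D_g$: the density of long-range (> 1.5 kb) contact
  endpoints falling in the 5–50-kb background region flanking the TSS, in
  contacts per 1×1-kb square (90 squares at the default radii). This is a
  per-sample depth-and-local-background normalizer. It is deliberately
  *not* restricted to contacts anchored at the promoter: a
  promoter-anchored density would itself scale with the promoter's
  mappability, and dividing by it (after already dividing by $M_g$) would
  make connectivity *inversely* proportional to mappability bias. With
  the flanking-density definition, raw contacts scale as $b$, $M_g$ as
  $b$, and $D_g$ is bias-free, so $C_g$ is invariant in expectation — the
  property the acceptance checks measure on a planted bias grid.

$C_g = \sum_{\mathrm{peaks}} \mathrm{raw} / M_g / D_g$, with $C_g = 0$ for
genes with no paired peaks. Companion summaries: enhancer accessibility
($\log_{10}$ of the summed fold enrichments of paired peaks), promoter
accessibility, promoter stripe strength and promoter methylation.
"Top two quantiles" for promoter accessibility is genuinely ambiguous; it
is implemented as the mean of the two upper quartile means of per-bp fold
enrichment within the zone, $\log_{10}$-transformed, and kept behind its
own helper so an alternative reading is a one-line change.

Gene filtering across stages removes genes for which *any* of
connectivity, promoter accessibility or promoter stripe strength is
nonpositive in all three stages; surviving missing/negative values become
zero.

## 3. Loops and APA

Loop strength is $\log_{10}((\mathrm{obs}+1)/(\mathrm{exp}+1))$ against the
mean of a donut ring (Chebyshev radii 2–10 bins, excluding the center row
and column) around the anchor-pair pixel; the pseudo-count is applied
unconditionally for determinism. The donut geometry follows the standard
donut-filter convention, since the upstream caller that produced the
published loop lists does not export its radii. Multi-source loop lists
merge in priority order; a candidate is dropped iff *both* anchors overlap
the corresponding anchors of an accepted higher-priority loop, and
candidates within one priority level are screened only against higher
levels so within-list order cannot matter. A loop is stage-positive when
the stage-averaged enrichment *ratio* exceeds 1.2 — the ratio, not the log
strength, because strengths are logs of ratios and "1.2-fold" is a fold.

APA sums windows centered on anchor pairs. Loop mode scores
mean(center 10×10) / mean(bottom-left 100×100). Stripe mode first divides
every pixel by the matrix-wide mean intensity at its genomic separation
(per-diagonal normalization; needed because stripes live near the
diagonal where distance decay dominates) and scores the mean of the ten
center pixels of the anchor column. Windows that leave the matrix are
skipped; zero usable windows is an error. Aggregates are returned raw and
log-transformed only for plotting. When the anchor separation is smaller
than the window span, the window crosses the diagonal and contains
mirrored signal — as in any APA; contract tests therefore use separated
anchors, and cohort comparisons use identical geometry on both sides.

## 4. The two-phase predictive layer

Feature tables combine structural/epigenetic values (initial mode:
baselines; differential mode: log2 fold changes with a pseudo-count of 1
on connectivity and methylation, and on any column containing zeros),
baseline expression and binary TF-indicator columns, each numeric feature
duplicated as its ascending average-tie rank transform. The TF indicators
are synthetic in this package (real ChIP-seq catalog ingestion is a
documented extension), so the total feature count is smaller than a
catalog-derived table would be.

The regressor is a fully-connected network — hidden layers 2048/512/128
with 20% dropout in the reference configuration — trained with Adam on
mean-squared error for up to 50 epochs; the returned model is the epoch
with the lowest held-out MSE on 2,800 randomly held-out genes (seeded
split; the same split is reused when initial and differential models are
compared). The widths are configurable, and the desk-scale experiments in
this package use 64/32/16 on 10,000 genes — at these data sizes the wide
reference network gains nothing and the narrow one trains in seconds; the
architecture-defining elements (three hidden layers, dropout, best-epoch
selection, seeded determinism) are identical.

Attributions are permutation-based: the per-gene attribution of a feature
is the prediction minus its mean under random permutations of that column.
Importance is the mean absolute attribution and directionality the plain
mean, as the summary convention dictates; note that for purely additive
effects the mean attribution is near zero by construction, so the result
table also reports the attribution–value correlation (`association`),
whose sign is the robust readout of effect direction. An exact brute-force
Shapley oracle (reference value function, ≤ 12 features) validates the
per-gene attributions on toy models in the test suite.

Differential calls on synthetic expression use per-gene Welch t-tests on
log2(TPM + 1), BH correction, and the dual gate fold > 1.3 with q < 0.1.
Directionality scores average −1/0/+1 calls across cohorts; direction
prediction is evaluated by ROC (up vs. down, predicted fold change as the
score) and by accuracy within |directionality| bins.

## 5. The synthetic cohort generator

The generator plants: a small genome (default three 8-Mb autosomes);
genes on a jittered grid (10 per Mb) with lognormal latent connectivity
$C$ (median 2, so most genes sit above the saturation point
$C_{sat} = 1$ — the saturated-majority baseline the two-phase picture
assumes) and lognormal expression capacity $\beta$; promoter stripe
anchors with strength proportional to $C$; three distal enhancers per
gene plus decoy peaks; one promoter–enhancer loop per gene and CTCF-like
distal loops; and stage attenuation multipliers (mucosa 1, polyp 0.6,
adenocarcinoma 0.4) on stripe/loop intensity, chosen once to bracket the
reported scale of connectivity loss in early progression, with a much
milder accessibility attenuation (1/0.95/0.88) reflecting that
accessibility loss is marginal compared to connectivity loss.

Contacts mix four components (background 50%, stripes 20%, loops 5%,
self-ligation 25%): a $d^{-\alpha}$ distance-decay background truncated at
2 Mb ($\alpha = 1$ by default — the decay exponent of the underlying
protocol is not established, so it is a free simulation parameter);
stripe contacts from an anchor to uniform positions within a 100-kb reach;
focal loop contacts; and self-ligation pairs at < 1 kb with explicit
inward +/– orientation (encoded, so orientation filtering is testable).
Mappability bias is a piecewise multiplicative factor $b(x) \in [0.3, 3]$:
long-range pairs are thinned with probability
$b(x_1)\,b(x_2)/b_{max}^2$ and self-ligation pairs emitted at a final rate
$\propto b(x)$ — the unique assignment under which long- and short-range
coverage at a locus both scale as $b(x)$, which is precisely the
proportionality assumption the stripe caller relies on. Biased loci in
the invariance experiments are 1 kb wide: narrower than the minimum
long-range distance, so no long-range pair can carry the bias factor at
both ends (wider zones add a small genuine $b^2$ component from
short-distance pairs — visible, and a caveat of the proportionality
assumption at locus scales above the minimum distance, not a property of
the estimator).

Expression follows $E = \beta \min(C \cdot a_{stage}, C_{sat}) + \epsilon$
(TPM), with additive Gaussian noise (s.d. 15% of the saturated level by
default). Methylation plants mostly demethylated promoters (~10%) and a
methylated minority (~60%), with hypermethylation concentrated on
low-connectivity demethylated genes in advanced stages; CpG percentages
are binomial draws at ~30× coverage.

Cohort sizing: the default manifest mirrors a 7/19/7
mucosa/polyp/adenocarcinoma design; the recovery experiments use a
2/2/2 cohort at one million contacts per sample on the 24-Mb genome —
about the per-bp contact density of a deeply sequenced tissue sample —
and the feature-level cohort uses 10,000 genes. These sizes are the
package's reference study conditions and are stated in the tests and the
acceptance script.

**What the generator does not emulate:** polymer physics (no
loop-extrusion dynamics, TADs or compartments), sequence content (no
reads, no enzyme-site geometry), inter-chromosomal contacts, structural
variants, copy-number effects, and the correlation structure of real
multi-omic noise. Passing recovery tests therefore demonstrates the
*estimators' correctness under the stated generative assumptions* —
normalization chains cancel what they should, consensus logic and filter
rules are exact, the predictive layer finds plantable signal — not
end-to-end performance on real tissue libraries.

## 6. Numerical and reproducibility notes

* Coordinates are 0-based half-open everywhere in memory and on disk
  (.pairs, BED, bedGraph); interval arithmetic uses GenomicRanges
  internally (1-based closed) with conversion at the boundary.
* Distances are $|pos_2 - pos_1|$ on pair positions, not fragment
  midpoints; records are canonicalized to $pos_1 \le pos_2$ with strands
  swapped alongside.
* Matrix balancing (KR) is not implemented: the self-ligation fallback is
  the normative normalization path throughout, making the pipeline
  self-contained. An iterative-proportional-fitting balancer
  (`ipf_balance()`) is available for parity experiments only.
* All stochastic steps take explicit integer seeds; per-sample streams are
  derived by hashing the sample id with the base seed, and every function
  restores the caller's RNG state. Identical seeds reproduce contact
  streams, anchors, connectivity tables, train/test splits and selected
  epochs bit-for-bit.
* Ties at merge boundaries resolve by half-open arithmetic; BH families
  are per sample; the pseudo-count is 1 wherever a log or ratio could hit
  zero.

## 7. Known limitations

* The Poisson test treats the expected count as known, but it is itself a
  noisy ratio estimate; at low self-ligation coverage this inflates
  per-sample false positives. The cross-sample consensus (≥ 3 hits)
  absorbs this, which is visible in the tests: per-sample calls are noisy
  while consensus F1 is high.
* The proportionality assumption is asserted, not adjudicated: the
  package exposes the diagnostics (`interaction_fe_track()`, the bias
  grid experiments) but cannot validate the assumption on real data from
  the inside.
* Stripe anchors are 1-D intervals; the 2-D extent (reach) of stripes is
  out of scope, as is loop *detection* — anchors come from planted truth
  or external callers.
* Mean permutation attributions understate directionality for additive
  effects (Section 4); use the `association` column for direction.
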