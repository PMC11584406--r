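# cisconn

Quantifying promoter–enhancer (P–E) connectivity from high-resolution
chromatin contact maps, and relating it to gene dysregulation in early
cancer progression.

## The problem

Multi-enzyme Hi-C protocols resolve chromatin contacts at sub-kilobase
scale, revealing *architectural stripes* (a fixed anchor contacting a
sliding neighborhood) and focal *loops* at active regulatory elements.
Two analysis problems follow:

1. **Signal vs. mappability.** Open chromatin yields more mappable reads,
   so raw long-range coverage at promoters conflates genuine distal
   interactivity with accessibility-driven mappability. cisconn separates
   them using short-range *self-ligation* pairs (< 1 kb, +/– orientation)
   as a distal-interaction-independent mappability proxy: for each 100-bp
   bin the expected long-range count is

   `expected = (long_bg / short_bg) × short_local`

   with 2-kb local and 50-kb background windows, tested by an upper-tail
   Poisson p-value (BH-corrected per sample). Bins significant (q < 0.01)
   in ≥ 3 samples, merged and ≥ 500 bp, become consensus stripe anchors.

2. **Connectivity and its consequences.** Per gene, connectivity is the
   aggregate of normalized contacts between the promoter zone
   [TSS − 1.5 kb, TSS + 0.5 kb) and all accessible distal elements within
   200 kb:

   `C_g = Σ_peaks raw(promoter, peak ± 500 bp) / M_g / D_g`

   where `M_g` is the promoter's self-ligation RPK ratio against its 50-kb
   neighborhood (mappability) and `D_g` is the long-range contact density
   in the 5–50-kb background region (per-sample coverage). The *two-phase
   model* then posits a saturating relation between connectivity and
   expression, `E = β·min(C, C_sat) + ε`: above saturation, connectivity is
   redundant for expression ("stabilization phase"); global connectivity
   loss in disease pushes genes into the rate-limiting "activation phase",
   where baseline connectivity predicts subsequent dysregulation. A
   feed-forward regressor (hidden layers 2048/512/128, 20% dropout,
   best-epoch selection on held-out MSE; width-scalable) implements the
   predictive layer, with permutation-based feature attributions.

Everything is exercisable against planted ground truth: the package ships
a synthetic multi-stage cohort generator (contacts with distance-decay
background, planted stripes/loops, locus-level mappability bias,
self-ligation pairs; peaks, CpG methylation and TPM expression following
the saturating rule, attenuated per stage).

## Worked example

```r
library(cisconn)

truth <- synthetic_truth(seed = 11)          # 3 x 8 Mb genome, planted truth
truth
#> Synthetic cohort truth
#>   genome: 3 chromosome(s), 24.0 Mb total
#>   genes: 240  enhancers: 720  stripe anchors: 288  loops: 261
#>   stage attenuation: mucosa=1.00, polyp=0.60, adenocarcinoma=0.40
#>   decay exponent: 1.00  C_sat: 1.00

manifest <- cohort_manifest(n_mucosa = 2, n_polyp = 2, n_adenocarcinoma = 2)
rec <- simulate_contacts(truth, "M01", depth = 1e6, seed = 3,
                         manifest = manifest)
stripes <- call_sample_stripes(rec, truth$chrom_sizes)
sum(stripes$q < 0.01, na.rm = TRUE)
#> [1] 20210

genes <- gene_models(truth$genes)
peaks <- rbind(truth$enhancers[c("peak_id","gene_id","chrom","start","end")],
               truth$decoys[c("peak_id","gene_id","chrom","start","end")])
pairs <- pair_promoter_enhancers(genes, peaks)
conn <- connectivity(rec, genes, pairs)
head(conn[c("gene_id", "connectivity", "n_pairs", "mappability")], 3)
#>   gene_id connectivity n_pairs mappability
#> 1   g0001     8.434270      11   1.0986775
#> 2   g0002     6.086682      15   1.2358393
#> 3   g0003    14.287405      15   0.9923077
cor(conn$connectivity, truth$genes$c_base, method = "spearman")
#> [1] 0.885
```

`connectivity` is the normalized P–E contact aggregate `C_g` (dimensionless,
depth- and mappability-corrected); its Spearman correlation of 0.885 with
the planted per-gene truth shows the normalization chain recovering the
simulated biology. The two-phase layer on a 10,000-gene feature cohort:

```r
coh <- simulate_feature_cohort(n_genes = 10000, seed = 5)
ft <- build_features("initial", coh$features, target = coh$target)
model <- two_phase_fit(ft, test_n = 2800, epochs = 30,
                       hidden = c(64, 32, 16), seed = 9)
model
#> Two-phase dysregulation model
#>   features: 54  genes: 10000 (2800 held out)
#>   hidden layers: 64-32-16  dropout: 0.20
#>   selected epoch: 26 of 30
#>   held-out r = 0.841, MSE = 0.0281

correlation_shift(coh$conn_by_stage, coh$expr_by_stage)$rho
#>         mucosa          polyp adenocarcinoma
#>          0.101          0.268          0.416
```

The held-out correlation (r = 0.84) shows baseline features predicting
stage fold changes under the saturating rule, and the per-stage Spearman
rho between connectivity and expression among active genes (TPM > 0.5)
increases from mucosa (0.10) through polyp (0.27) to adenocarcinoma
(0.42) — the correlation shift the two-phase model implies.

`run_pipeline(default_config(seed = 1))` chains all stages (simulate →
stripes → consensus → connectivity → methylation → model) and writes BED /
TSV / JSON artifacts plus a reproducibility manifest.

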