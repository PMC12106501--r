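---
title: "Screening for single-exon deletions from SNP-array intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for single-exon deletions from SNP-array intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delscreen)
```

## The problem

Standard genotype calling on SNP arrays ignores most of the information in
probe fluorescence intensities. A germline deletion of a single exon — such
as the 3,538 bp in-frame deletion of *MLH1* exon 16 (GRCh38
3:37044575–37048112), a Finnish founder variant causing Lynch syndrome —
removes one of the two chromosomal copies of every probe target inside the
deleted segment. A heterozygous carrier therefore shows roughly half the
expected total (A + B allele) intensity at every probe set inside the
deletion, while looking entirely normal in its flanks. At biobank scale
(10^5–10^6 genotyped samples, carrier prevalence of order 0.02%), this halving
is detectable by a simple, robust screen, at negligible cost compared to
sequencing.

`delscreen` implements that screen end to end: locus-level intensity
summation, per-locus inverse-normal quantile normalization, two robust
per-sample features, explicit threshold calling, and evaluation against
truth labels — plus a synthetic-cohort simulator so that the whole pipeline
is testable without access to restricted biobank data.

## The method

**Locus summation.** For each sample and each locus, the intensities of
both alleles of all probe sets interrogating that locus are summed into one
total chromosomal signal. The target assay interrogates the deletion with
21 probe sets at 18 unique loci; 50 flanking loci (25 per side in the
default template) provide the within-sample baseline. Because the cohort
mixes two array versions with overlapping content, flanking loci use only
probe sets present on both versions; a sample simply has no record for
probe sets missing from its chip, which yields a missing locus value only
when *none* of a locus's probe sets are present.

**Inverse-normal normalization.** Each locus is normalized independently
*across samples*: the N non-missing totals are ranked (average ranks for
ties) and mapped to standard-normal quantiles, by default with the Hazen
offset `qnorm((r - 0.5) / N)`. This direction — per locus across samples,
never per sample across loci — is essential: it makes every locus's scale
comparable between samples, which is what lets a one-copy drop stand out,
and it is robust to arbitrary monotone distortions of the intensity scale.
The price is rank blindness: any effect shared by *all* samples vanishes. A
cohort in which every sample carried the deletion would show nothing
(`expected_feature_location()` makes this limit explicit, and the test
suite asserts it); the method is a screen for *rare* variants by
construction.

**Features.** Each sample is reduced to the coordinate pair of the cluster
plot:

* `median_difference` — median normalized value over deletion loci minus
  the median over all flanking loci (both flanks pooled). An ideal lone
  carrier among N samples sits near `qnorm(0.5 / N)` (about −3.3 at
  N = 1000, −3.7 at N = 10,000), because its deletion loci occupy the
  lowest rank at every locus.
* `piecewise_mad` — a robust within-sample scatter: absolute deviations of
  each locus value from *its own region's* median (deletion; flanks
  pooled), combined by taking the median of all pooled deviations. The
  piecewise construction matters: a clean carrier is near-constant within
  each region, so its piecewise MAD is small, whereas a plain MAD over all
  loci would be inflated by the deletion step itself (the worked case
  deletion = [−4, −4, −4], flank = [0, 0, 0] gives 0 piecewise but 2
  pooled). Two alternative combination rules (`max`, `weighted`) are
  available behind a switch; the pooled-median default produces one number,
  is exactly piecewise, and keeps carriers low-MAD. No 1.4826
  normal-consistency factor is applied — the feature feeds a threshold,
  not a variance estimate, so the constant would only relabel the axis.

**Calling.** Explicit thresholds rather than a clustering algorithm: a
sample is `ambiguous` when `piecewise_mad > mad_max` (high-variance samples
cannot be trusted in either direction, so ambiguity takes precedence over
the carrier rule), `carrier` when `median_difference <= diff_max`, else
`negative`; missing features give `no_call`. Defaults `diff_max = -2`,
`mad_max = 1.5` sit between the analytic carrier location (≤ −3.3 for any
cohort of 1000+) and the main cluster (difference ≈ 0 ± 0.33, MAD < 1).
`suggest_thresholds()` offers a reproducible, data-driven alternative to
visual cluster inspection (`Q3 + 3·IQR` fence on the MAD axis; a
`median − 5·robust-SD` cut on the difference axis, never above −2); it is
returned for review, never silently applied.

**Evaluation.** `confusion()` scores calls against truth labels, excluding
ambiguous and no-call samples from the 2×2 table but always reporting
them; PPV and sensitivity are reported as undefined (not zero) on empty
denominators. `summarize_run()` reports prevalence and the split of called
carriers into previously-labelled vs novel, rounding half-up at the printed
precision (prevalence to 3 decimals, proportions to whole percent) while
retaining raw fractions.

## The simulator

`simulate_cohort()` generates cohorts with the structure the method
assumes. Per-record model:

```
intensity = baseline(probe set) × sample_scale × copy_factor × allele_split × exp(noise)
```

with `copy_factor = deletion_signal_ratio` (default 0.5, a heterozygous
deletion) for carriers at deletion probe sets and 1 otherwise. All noise is
multiplicative lognormal: fluorescence intensities are positive and
right-skewed, and since the downstream normalization is rank-based, results
are insensitive to the exact noise law. The A/B allele split is a
Beta(2, 2) draw — only the A + B sum matters downstream, but the split
keeps the on-disk schema identical to real extraction output. Structural
defaults mirror the target assay: 18 deletion loci / 21 probe sets, 25
flanking loci per side, 28% of samples on array v1, two deletion probe sets
private to one version each, carrier prevalence 0.024% (an exact
`n_carriers` override exists for planting a fixed count in evaluation
runs). A single RNG stream per cohort, seeded from the config, makes every
cohort byte-reproducible; the caller's RNG state is untouched.

### Noise defaults, and why they look the way they do

The intensities this package consumes have already passed vendor-side
artefact removal, probe summarization and normalization, so residual
*between-sample* scale scatter is small relative to *probe-level* scatter.
Defaults: `sample_scale_sd = 0.03` and `probe_noise_sd = 0.12` on the log
scale, with per-probe-set brightness spread `probe_baseline_sd = 0.4`
(probes differ severalfold in brightness; irrelevant after per-locus
ranking, but realistic in the raw table).

Two geometric constraints pin the interesting corner of this parameter
space, and both follow from the quantile normalization itself:

* *Flank tracking.* A sample's flanking median in normalized units is
  approximately its own scale percentile times
  `sample_scale_sd / locus_total_sd`. Since a carrier's deletion median is
  floored near `qnorm(0.5/N)` ≈ −3.7, a large sample-scale share would let
  low-scale carriers drag their flank median down and shrink the
  difference past the threshold. Probe-level noise must therefore dominate
  the population spread — which it does after upstream normalization.
* *The noisy class must not saturate.* The high-variance minority
  (`noisy_fraction = 0.01`, `noisy_extra_sd = 0.05` added to the record
  noise sd — roughly a doubling of record-noise variance) models degraded
  but hybridized arrays. Because normalized values are bounded by the
  extreme quantiles (±3.7 at N = 10,000), a far larger noise elevation
  drives every locus of a noisy sample to the rank extremes; the resulting
  bimodal profiles occasionally imitate a deletion (deletion-region median
  low by chance, flank median high) while slipping under any MAD fence.
  The real assay's validated 100% precision, with an expected ~1% of
  low-quality samples among >10^5, shows that real noisy samples do not
  mimic carriers — so a simulator whose noisy class routinely does would
  be emulating a different assay. At the default elevation, noisy samples
  form a clearly right-shifted MAD fringe (median ≈ 1.4× the main
  cluster's) without entering the saturation regime.

What the simulator deliberately does **not** emulate: genotype clusters and
B-allele fractions, GC-wave and plate/batch artefacts, spatially correlated
degradation, homozygous deletions, and mosaic fractions. Consequences:
passing tests demonstrate the pipeline's correctness and its behaviour
under the stated noise model, not robustness to structured artefacts of
real arrays — on real data the ambiguous class and completeness report
exist precisely to absorb what the simulator leaves out.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (`length = end − start + 1`,
  matching the printed 3,538 bp for 3:37044575–37048112); the region file
  states this dialect in a comment because BED proper is 0-based.
* Ranking uses average ranks for ties; the Hazen offset `(r − 0.5)/N` is
  symmetric and keeps extreme quantiles finite. Blom and van der Waerden
  offsets are available; the choice is cosmetic at cohort sizes of
  interest.
* Loci with fewer than two non-missing values normalize to all-missing
  with a warning; missing values never enter ranks and are propagated, not
  imputed.
* Samples with an empty region yield missing features and `no_call` — they
  are flagged, never dropped, so cohort accounting stays exact.
* Both array versions are normalized jointly in one pool, as the cohorts
  they emulate are; per-version pooling is a flag away but not the
  default.
* `suggest_thresholds()` refuses degenerate cohorts (zero robust spread)
  and cohorts under 100 samples.
* Percentages in reports are rounded half-up (base `round()` is banker's),
  so printed proportions match conventional reporting.

## Problem sizes used in the test and acceptance suites

Unit tests run on toy fixtures (N ≤ 8 for the brute-force normalization
oracle; cohorts of 20–2000 for behavioural checks). The end-to-end
precision/recall check uses 50 cohorts of 10,000 samples with 8 planted
carriers each — 500,000 screened samples per run — which completes in a few
minutes on one core while putting ~400 carriers and ~5,000 noisy samples
through the full pipeline. The analytic-limit checks (single noiseless
carrier at `qnorm(0.5/N)`; all-carrier cohort finding nothing) run at
N = 1000.

## Known limitations

* Rank-based normalization cannot see population-wide copy-number states;
  the screen targets rare heterozygous deletions only.
* Threshold defaults are validated on simulated cohorts; on real data they
  should be reviewed against the cluster plot (`plot_features()`), or
  `suggest_thresholds()` used as a starting point.
* PPV on simulated truth is an analogue, not a measurement, of clinical
  PPV; sensitivity claims on real cohorts additionally depend on the
  completeness of the truth source used.
* The two-feature screen is specific to a *known* target region; it does
  not discover novel CNVs.
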