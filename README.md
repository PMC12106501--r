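# delscreen

Intensity-based screening for rare single-exon germline deletions in
SNP-array genotyping cohorts.

Genotyping arrays are usually mined for SNP genotypes, but their probe
fluorescence intensities also carry copy-number information. A heterozygous
deletion removes one of two chromosomal copies, halving the expected total
(A + B) intensity of every probe set inside the deleted segment while
leaving the flanks untouched. `delscreen` turns that signal into a
biobank-scale screen for a known target region — the motivating case is the
3,538 bp Finnish founder deletion of *MLH1* exon 16 (GRCh38
3:37044575–37048112), which causes Lynch syndrome at a cohort prevalence of
roughly 0.02% — and ships a synthetic-cohort simulator so the entire
pipeline is testable without restricted biobank data.

The method, per sample *i* and locus *l* (deletion region *D*, pooled
flanks *F*):

1. **Locus totals** — sum both alleles of all probe sets at the locus:
   `s_il = Σ_p Σ_{a∈{A,B}} x_ipa`.
2. **Inverse-normal normalization per locus across samples** —
   `z_il = Φ⁻¹((r_il − ½)/N)` with average ranks for ties; monotone-
   invariant, so arbitrary intensity-scale distortions drop out.
3. **Two features** — `d_i = median_{l∈D}(z_il) − median_{l∈F}(z_il)` and
   the piecewise MAD `m_i = median of |z_il − median of its own region|`
   pooled over both regions.
4. **Threshold calls** — `ambiguous` if `m_i > mad_max` (high-variance,
   unclassifiable; takes precedence), else `carrier` if `d_i ≤ diff_max`,
   else `negative`. Defaults: `diff_max = −2`, `mad_max = 1.5`; an ideal
   lone carrier among N samples sits at `Φ⁻¹(0.5/N)` ≈ −3.7 for N = 10⁴.
5. **Evaluation** — confusion counts, PPV, sensitivity and prevalence
   against truth labels, with ambiguous/no-call samples excluded from the
   2×2 table but always reported.

## Worked example

Simulate a 10,000-sample cohort with 8 planted heterozygous carriers, run
the screen, and score it:

```r
library(delscreen)

cfg <- simulation_config(n_samples = 10000L, n_carriers = 8L, rng_seed = 42L)
cohort <- simulate_cohort(cfg)
res <- screen_cohort(cohort)   # sum -> normalize -> features -> call

print(res$confusion)
#> confusion_summary
#>   tp=8 fp=0 tn=9992 fn=0 (ambiguous excluded: 0, no_call: 0)
#>   PPV:        100.0%
#>   sensitivity: 100.0%

summary(res$features$median_difference[cohort$manifest$truth_label == "carrier"])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  -3.790  -3.493  -3.224  -3.255  -2.938  -2.892
```

All 8 carriers are recovered with no false positives; their
`median_difference` sits near the analytic tail location
`qnorm(0.5/10000) ≈ −3.72`, far left of the main cluster at 0, and their
piecewise MAD stays low — the cluster geometry the screen is built around.
`plot_features(res$features, res$calls)` draws that cluster plot.

The same stages run from the shell on TSV files via the bundled CLI
(`inst/cli/delscreen.R`): `simulate`, `normalize`, `features`, `call`,
`evaluate`, and `run` (full pipeline with a YAML config; byte-identical
reruns).

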