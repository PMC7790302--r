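# pexquant

Quantification and steady-state modelling of **poison-exon inclusion** in
sodium-channel transcripts, for transcriptomicists studying splicing-mediated
regulation of gene dosage (and its failure modes in epileptic
encephalopathy).

A poison exon is an alternatively spliced cassette exon whose inclusion
shifts the reading frame, creates a premature termination codon (PTC) in
the next exon, and routes the transcript into nonsense-mediated decay
(NMD). Because the included isoform is unstable, measuring how often it is
made — and what that costs in functional mRNA — requires estimators that
work on the *stable* pool and a model that connects them. `pexquant`
provides:

* **A coverage statistic**: percent poison-exon usage from per-base depth,

  `usage = 100 × (mean depth over poison-exon bases) / (mean depth over all exon bases)`,

  with exon counting and median-of-ratios size factors for the
  count-resolution variant.
* **qPCR estimators**: ΔCt relative expression (`E^−ΔCt`) and the
  amplicon-ratio inclusion percentage
  `100 × E₂^−Ct₂ / E₃^−Ct₃` (junction assay over total assay), with
  undetectable Cts propagated as bounds, never imputed.
* **A two-allele steady-state model**: each allele transcribes at rate `T`
  and includes the poison exon with propensity `ψ`; included transcripts
  survive NMD with fraction `s`, so the stable pool per allele is
  `T(1−ψ)` excluded plus `Tψs` included. `fit_steady_state()` inverts the
  model from the two observed genotype inclusion levels;
  `ki_fold_increase()` reproduces the additive-model fold arithmetic;
  `predict_total_reduction()` gives the predicted loss of total stable
  mRNA in the heterozygote.
* **Study statistics from formulas**: Kaplan–Meier, Mantel–Cox log-rank,
  Mendelian χ² goodness of fit, Mann–Kendall trend (exact p at small n),
  Spearman inverse-relation with permutation p.
* **A fully seeded synthetic-data generator** for transcript pools, read
  coverage (uniform or 3'-biased), Ct tables, developmental time courses
  and survival cohorts, plus an in-silico PCR engine and a bundled
  Scn1a-like gene model (26 constitutive exons + one 64-nt poison exon)
  whose amplicon geometry reproduces the published product sizes
  (56/120, 96, 111 bp).

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, ggplot2 helpers
(`plot_coverage()`, `plot_timecourse()`, `autoplot()` on Kaplan–Meier
fits).

## Worked example

The headline analysis: brain qPCR reports 0.97% poison-exon inclusion in
wild-type (+/+) animals and 4.8% in knock-in heterozygotes (+/KI). Under
the additive allele model:

```r
library(pexquant)

allele_model(0.97, 4.8)
#>   psi_obs_wt psi_obs_ki per_allele_baseline fold_increase psi_plus      s
#> 1       0.97        4.8               0.485      9.896907 0.241107 0.0308
#>   predicted_total_reduction
#> 1                  47.98845
```

Reading these numbers: each wild-type allele contributes 0.485% inclusion,
so the knock-in allele drives a **9.9-fold** increase in stable
poison-containing transcript; the fitted steady state says the wild-type
allele includes the exon in **24%** of its transcripts of which only
**3.1%** survive decay, and the model predicts a **48%** loss of total
stable mRNA in heterozygotes — matching the independently measured ~50%
reduction.

The same inclusion values come straight from Ct pairs (junction assay vs
total assay):

```r
inclusion_percent_from_ct(c(28.3, 27.0), c(21.6, 22.5))
#>   percent is_bound
#> 1   0.962    FALSE
#> 2   4.42     FALSE
```

And the coverage route, on a simulated heterozygote library from the
bundled gene model (true stable inclusion 4.8%):

```r
gm <- scn1a_gene_model()
pool <- steady_state_pool(
  genotype_spec("+/KI", allele_params(1, 0.241), allele_params(1, 1)),
  nmd_params(s = 0.031)
)
sim <- simulate_reads(pool, gm, library_protocol("uniform", total_reads = 1e5), seed = 1)
poison_usage_percent(sim$track, gm)
#>   usage_percent poison_mean_depth exon_mean_depth mapped_reads
#> 1      4.316224          36.76562        851.8516       1e+05
```

Switching the protocol to `"three_prime"` (a 3'-tag library, with the
poison exon ~2 kb from the 3' end) drives the same statistic to ~0 while
qPCR still reports ~5% — the discordance between the two assay classes
that motivates carrying both.

A complete demo dataset (annotation in GFF3 and BED12, primers, reads,
depth, Ct table, time course, cohort) plus a ready-to-run configuration is
generated by `make_fixtures("demo", seed = 1)` and analysed end to end by
`run_pipeline("demo/config.yml")`. A thin command-line wrapper with the
same stages ships in `inst/scripts/pexquant`.

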