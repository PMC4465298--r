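# degps

Two-step differential expression (DE) analysis for RNA-Seq read-count
matrices, built around the generalized Poisson (GP) distribution.

## The problem

Read counts per transcript within one RNA-Seq library are strongly
overdispersed: the variance far exceeds the mean, so Poisson-based
normalization misstates sequencing depth, and parametric per-gene tests are
unreliable at the sample sizes (2–10 per group) typical of RNA-Seq designs.
`degps` addresses both steps:

1. **Normalization by a fitted GP distribution.** Counts `X` in one sample
   are modeled as

       P(X = x) = θ(θ + xλ)^(x−1) e^(−θ−xλ) / x! ,   θ > 0,  max(−1, −θ/q) ≤ λ ≤ 1

   with mean θ/(1−λ) and variance θ/(1−λ)³; λ = 0 recovers the Poisson and
   λ > 0 encodes overdispersion. The λ MLE solves

       Σᵢ Xᵢ(Xᵢ−1) / (X̄ + (Xᵢ−X̄)λ̂) − nX̄ = 0,   θ̂ = X̄(1−λ̂).

   *GP-Theta* divides each sample by its θ̂ — a dispersion-shrunk library
   size factor; *GP-Quantile* maps each count to its fitted cumulative
   probability P(X < x). Global, quantile, TMM and lowess normalizations
   are included as comparators.

2. **Pooled-permutation testing.** Per transcript, a Welch T statistic

       T = (Mean(X′) − Mean(Y′)) / sqrt(Var(X′)/Nx′ + Var(Y′)/Ny′)

   is referred to one empirical null formed by merging the T statistics of
   *all* transcripts across *all* group-label permutations (exhaustive for
   ≤ 1000 assignments, e.g. all 252 of a 5 + 5 design). Because the pool
   spans the whole transcriptome, p-values are well resolved even with two
   samples per group. Nominal p-values are Benjamini–Hochberg adjusted.

The package also ships the evaluation machinery — an NB count simulator
with random outliers, resampling-based null/shift/scale-shift scenarios,
and type-I-error / FDR / TPR / partial-AUC metrics — so the operating
characteristics can be verified end to end without any external data.

## Worked example

```r
library(degps)

sim <- simulate_nb_counts(scenario_config(n_transcripts = 2000, n_per_group = 5,
                                          de_fraction = 0.1, effect_size = 3,
                                          seed = 42))
res <- run_degps(sim$counts, sim$design, method = "gp-theta", seed = 42)
res
#> deGPS result: 1999 transcripts tested (gp-theta normalization, t statistic)
#>   1 all-zero transcripts filtered before testing
#>   null pool: 501749 statistics from 251 exhaustive permutations
#>   significant at adjusted p < 0.05: 10

head(res$table[order(res$table$p_value), ], 3)
#>        transcript_id   t_stat      p_value p_adjusted significant
#> 895   transcript_896 8.632490 2.391629e-05 0.02689238        TRUE
#> 1112 transcript_1113 8.124102 3.388142e-05 0.02689238        TRUE
#> 603   transcript_604 7.824568 4.384654e-05 0.02689238        TRUE

evaluate_de(res, sim$truth)
#>   type_i_error fdr   tpr     pauc n_called n_true_de
#> 1           NA 0.1 0.045 0.445114       10       200
```

Reading the output: 251 exhaustive permutations of the 10 samples produced
a pooled null of ~500k statistics; 10 transcripts pass BH at 0.05, of
which 1 is a false discovery (observed FDR 0.10, within Monte-Carlo noise
of the 0.05 target for a single replicate), and the normalized partial AUC
of 0.445 means the p-value ranking concentrates true positives far above
chance (0.025) in the FPR < 0.05 window. The per-sample fits
(`attr(res$normalized, "gp_fits")`) show λ̂ ≈ 0.997 here — count data
spanning five decades of abundance are extremely overdispersed, which is
exactly why θ̂ (≈ 4.8) rather than the raw mean (≈ 1500) is the right
depth factor.

## Command line

A launcher is installed with the package:

```sh
DEGPS=$(Rscript -e 'cat(system.file("cli", "degps.R", package = "degps"))')
Rscript $DEGPS test --input counts.tsv --group-a s1,s2,s3 --group-b s4,s5,s6 \
        --normalize gp-theta --max-perms 1000 --fdr 0.05 --seed 1 --output de.tsv
Rscript $DEGPS simulate --config scenario.cfg --replicates 20 --seed 1 --output metrics.tsv
Rscript $DEGPS fit-gp --input counts.tsv --output gp_params.tsv
```

Count matrices are TSV/CSV with transcript ids in the first column and a
header of sample ids; designs are two-column TSV (`sample_id`, `group`) or
inline `--group-a/--group-b` flags.

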