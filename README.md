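# tprf — time-dependent random-effects Poisson random field inference

`tprf` estimates the **distribution of selective effects (DFE)** of
nonsynonymous mutations and the **species divergence time** from per-gene
polymorphism/divergence count tables of two closely related species, without
assuming mutation–selection–drift equilibrium.

## Who this is for

Population geneticists with aligned coding sequences from two sister species
(e.g. *Drosophila melanogaster* polymorphism vs *D. simulans* divergence),
summarized per gene as a generalized 2×3 McDonald–Kreitman table:

| | fixed difference | new polymorphism | legacy polymorphism |
|---|---|---|---|
| silent | `Sf` | `Snp` | `Slp` |
| replacement | `Rf` | `Rnp` | `Rlp` |

where *new* = polymorphic in exactly one sample and *legacy* = polymorphic in
both (surviving ancestral variation). Splitting polymorphism this way makes
divergence time `t_div` estimable jointly with selection.

## The model

Sites evolve independently under a Wright–Fisher diffusion with genic
selection (scaled coefficient γ = N<sub>e</sub>s, time in N<sub>e</sub>
generations): `u_t = x(1-x) u'' + γ x(1-x) u'` with scale function
`s(x) = (1 - e^{-γx})/γ` and speed density `e^{γx}/(x(1-x))`. The six table
counts are independent Poissons whose means combine sampled-configuration
probabilities I/J/K of the transition density (Crank–Nicolson), the
equilibrium ancestral-polymorphism intensity, and a new-mutation fixation
flux. Hierarchy: per-mutation γ ~ N(γ_i, σ_w²) within gene i, γ_i ~
N(μ_γ, σ_b²) across genes; θ_s, θ_r are scaled mutation rates. Inference is
by MCMC: exact Gibbs for mutation rates and for (μ_γ, σ_b), random walks for
γ_i and t_div, and an adaptive-directional adaptive-Metropolis (ADAM) block
that proposes (μ_γ, σ_b, σ_w) jointly along the SVD directions of the
running empirical covariance with an acceptance-tuned jump scale
`exp(2d(δ_k − 0.3))`.

See `vignettes/time-dependent-prf.Rmd` for the full account (formulas,
numerics, design choices, limitations).

## Worked example

Simulate 30 genes at the reference truth
(μ_γ, σ_b, σ_w, t_div) = (−6.82, 3.78, 2.56, 4.38), then refit them
(about five minutes):

```r
library(tprf)
ctrl <- prf_control(grid_points = 120, time_steps = 240,
                    gl_order = 48, gh_order = 16)
sim  <- generate_dataset(sim_design(L = 30, seed = 101), ctrl)
cfg  <- chain_config(n_iter = 150000, burn_in = 75000, thin = 15,
                     seed = 202, n_subchains = 10,
                     proposal_scales = c(gamma_i = 2.5, sigma_w = 0.5,
                                         t_div = 0.2, hyper_iso = 0.2))
fit  <- run_chain(sim$data, prior_config(), cfg, ctrl)
posterior_summary(fit, subchain = "all")[1:4, ]
```

Output (as printed by this run):

```
  parameter    median      lower     upper
1  mu_gamma -6.077245 -20.153199 -2.400454
2   sigma_b  3.639137   1.980431  7.439377
3   sigma_w  2.939881   0.117016  8.560766
4     t_div  4.689418   4.187724  5.253545
```

Reading this: the divergence-time posterior is tight and covers the truth
(median 4.69 vs 4.38, ~7% high); the DFE location/scale parameters are
recovered with wide intervals that cover the truth — the data only weakly
identify σ_b and σ_w, and their point estimates run high along a posterior
ridge, the same behaviour the reference analysis reports. Convert time with
`divergence_time_years(4.69)` → 3.02 million years (0.645 Myr per
N<sub>e</sub> generations, the Drosophila calibration). Per-gene selection
summaries, positively-selected population proportions and per-class
aggregation come from `summary_report(fit)`.

Real data are read with `read_counts_table()` (whitespace/tab-delimited
columns `M N Sf Snp Slp Rf Rnp Rlp Locus Class`, header optional).

## Command line

```sh
Rscript inst/cli/tprf.R simulate --out sim --loci 30 --seed 1
Rscript inst/cli/tprf.R fit --data sim_counts.txt --out fit --iterations 150000 --seed 1
Rscript inst/cli/tprf.R summarize --draws fit_draws.txt --data sim_counts.txt --out summary.txt
```

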