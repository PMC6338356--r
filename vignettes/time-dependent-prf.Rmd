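---
title: "A time-dependent random-effects Poisson random field model for selection and divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A time-dependent random-effects Poisson random field model for selection and divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`tprf` infers the distribution of selective effects (DFE) of nonsynonymous
mutations and the species divergence time from per-gene counts of
polymorphism and divergence in samples from two closely related species. The
input per locus is a generalized 2×3 McDonald–Kreitman table: silent and
replacement sites cross-classified as fixed differences, *new* polymorphisms
(polymorphic in exactly one sample) and *legacy* polymorphisms (polymorphic
in both samples — surviving ancestral variation). Splitting polymorphisms by
whether both samples carry them is what gives the data leverage on *time*:
legacy polymorphism decays with divergence time while fixed differences
accumulate, so the model does not need the mutation–selection–drift
equilibrium assumption of the classical Poisson random field (PRF).

Sites evolve independently (free recombination) under a Wright–Fisher
diffusion with genic selection. With time measured in units of $N_e$
generations, frequency $x$, and scaled coefficient $\gamma = N_e s$, the
transition density action $u(t,x) = \int_0^1 p(t,x,y)\,f(y)\,m(dy)$ solves

$$\partial_t u = x(1-x)\,u'' + \gamma\,x(1-x)\,u', \qquad u(t,0)=u(t,1)=0,
\quad u(0,x)=f(x),$$

with scale function $s(x) = (1-e^{-\gamma x})/\gamma$ and speed density
$m(x) = e^{\gamma x}/(x(1-x))$. (The source text prints the speed-measure
exponent as a constant $e^{\gamma}$; the diffusion drift together with the
printed scale function force $e^{\gamma x}$, which is what the package uses.
`prf_control(speed_exponent = "gamma_const")` switches to the literal
constant for comparison — it only rescales the $\Lambda$'s at fixed
$\gamma$.)

The six Poisson means of a locus' table are built from three functionals
$\Lambda_1, \Lambda_2, \Lambda_3$ (fixed differences, new polymorphisms,
legacy polymorphisms per unit mutation rate) that combine

* the sampled-configuration probabilities $I(x,m)$, $J(x,m)$, $K(x,m)$ — a
  site at ancestral frequency $x$ being monomorphic wild-type, polymorphic,
  or monomorphic mutant in a present-day sample of $m$ sequences;
* the equilibrium PRF weight $(s(1)-s(x))\,m(x)$ of ancestral polymorphism;
* a new-mutation fixation flux term $2\,(t_{div} - \int_0^{t_{div}}
  \lim_{x\to0} p(u,x,\cdot)/s(x)\,\cdot\,s\,dm\,du)$ and legacy-loss terms
  $L(m)$ for mutations that resolved in the population but still read as
  fixed in a sample.

Replacement means average $\Lambda_j(\gamma)/s(1)$ over
$\gamma \sim N(\gamma_i, \sigma_w^2)$ (within-locus random effect), with
$\gamma_i \sim N(\mu_\gamma, \sigma_b^2)$ across loci; silent means use
$\gamma = 0$. The typeset prefactor "$\theta_r s(1)$" is read as
$\theta_r/s(1)$ — this normalization makes the fixation-flux part of
$\Lambda_1$ reproduce the classical PRF divergence expectation — and because
$s(1)$ depends on $\gamma$, the $1/s(1)$ factor is taken *inside* the normal
expectation (`prf_control(s1_inside = FALSE)` evaluates it outside, at
$\gamma_i$, for sensitivity analysis).

## Priors and posterior

Mutation rates carry Gamma priors, $(\mu_\gamma, \sigma_b^2)$ a
normal-inverse-gamma prior (shape/rate inverse gamma; the printed
$\Gamma(1/\sigma_b^2\mid\alpha_0,\beta_0)$ is interpreted as that NIG — a
`prior_config(ig_parameterization = "scale")` switch covers the other
reading), and $t_{div}$, $\sigma_w$ bounded uniforms. All shape/rate
hyperparameters default to 0.001; the uniform bounds default to
$t_{max} = \sigma_{max} = 20$, chosen to exceed every reported estimate more
than twofold. Because the sampler moves in the $\sigma_b$ coordinate while
the NIG is a density over $\sigma_b^2$, `log_prior()` includes the
$2\sigma_b$ Jacobian; the NIG Gibbs draw and the Metropolis moves therefore
target the same distribution.

## Sampling

One sweep updates, in fixed order: per locus $\theta_{s,i}, \theta_{r,i}$
(exact Gamma Gibbs) and $\gamma_i$ (Gaussian random walk); the
hyperparameter block; and $t_{div}$ (random walk, rejected outside
$(0, t_{max})$). The hyper block follows a three-phase schedule, by default
2.5% / 5% / 92.5% of the run (mirroring the reference 50k/100k/1.85M):

1. componentwise — NIG Gibbs for $(\mu_\gamma,\sigma_b)$, random walk for
   $\sigma_w$;
2. joint Gaussian proposals for the triple with the fixed covariance $C_0$
   estimated from phase 1;
3. ADAM — at each step, SVD $C_t = D\Sigma_t D^T$ of the running empirical
   covariance (accumulated over all post-phase-1 states), a joint proposal
   along the singular directions with covariance $\delta\,\Sigma_t$, and
   $\delta = \exp\{2d(\delta^{(k)} - 0.3)\}$, $d = 3$, retuned from the
   acceptance rate $\delta^{(k)}$ of every $k = 100$ iterations. Degenerate
   $\Sigma_t$ (singular value below $10^{-12}$) falls back to an isotropic
   proposal. Whether the NIG Gibbs step should persist alongside the joint
   update in phase 3 is ambiguous in the source; the default is the pure
   joint update, and `chain_config(nig_gibbs_phase3 = TRUE)` retains the
   exact conditional draw for $(\mu_\gamma, \sigma_b)$ alongside it —
   measured thinned-sample autocorrelations show that combined scheme
   dominating both the plain componentwise sampler and the pure joint
   update on ridge-shaped posteriors.

Initial values (not stated in the source): method-of-moments $\theta$'s from
the observed counts at $t_{div} = 1$, $\gamma_i = 0$, hypers $(0, 1, 1)$.
Random-walk proposal SDs are configurable (`chain_config(proposal_scales=)`);
the defaults target moderate acceptance on typical count magnitudes, and for
datasets with a broad between-locus DFE a $\gamma_i$ scale of 2–3 mixes
markedly better than the default 1.
Thinning applies post-burn-in. Convergence is monitored with the
potential-scale-reduction statistic over consecutive subchains
(`gelman_rubin()`, < 1.1 taken as converged), floored at 1 so identical
subchains report exactly 1.

## Numerics

* **Crank–Nicolson**: uniform interior grid, default 400 points and time
  step $t/400$; all basis initial conditions ($y^m$, $(1-y)^m$, $1$,
  $s(y)/s(1)$ per distinct sample size) are marched through one shared
  tridiagonal factorization. Refinement and Chapman–Kolmogorov convergence
  are asserted in the tests.
* **Quadrature**: Gauss–Legendre (default order 64) on $(0,1)$ after
  folding the $1/(x(1-x))$ speed singularity into the integrand — every
  model integrand vanishes fast enough at the endpoints; Gauss–Hermite
  (default order 32) for expectations over $\gamma$. Node computation is by
  Golub–Welsch. Stability under order-doubling is tested.
* **Fixation flux**: $\lim_{x\to0} p(u,x,y)/s(x)$ is extrapolated linearly
  to $x=0$ from the first two grid points; its time integral is accumulated
  by trapezoid during the march. A warning is signalled if two- and
  three-point extrapolations disagree beyond `flux_rtol` (default $10^{-3}$
  relative).
* **Small $|\gamma|$**: series branches below $10^{-8}$ for $s(x)$ and
  related ratios; large-$|\gamma|$ forms are computed via `expm1` identities
  such as $(s(1)-s(x))m(x) = (1-e^{-\gamma(1-x)})/(\gamma x(1-x))$, stable
  to $|\gamma|$ of several hundred.
* **The $\Lambda$ cache**: an MCMC sweep needs $\Lambda_j/s(1)$ at dozens of
  $(\gamma, t)$ points per iteration; solving the PDE each time is the cost
  the reference implementation attacked with MPI. `lambda_cache()` instead
  marches each $\gamma$ node once across the whole $t$ range (recording
  intermediate times) on a uniform $161 \times 41$ $(\gamma, t)$ grid over
  $[-100, 100] \times [0, t_{max}]$ and interpolates with local cubics
  (linear extrapolation, floored at 0, beyond the $\gamma$ range — the
  $\Lambda_j/s(1)$ vanish exponentially for very negative $\gamma$ and grow
  linearly for large positive $\gamma$). The uncached `expected_table()`
  path remains the reference; tests bound the cache's relative error (~1%
  where values are non-negligible). Expected counts are floored at
  $10^{-12}$ before entering Poisson log-pmfs.

## The synthetic-data generator

`generate_dataset()` reproduces the three-step simulation design: fixed
global truth (the default is the first reference set,
$(\mu_\gamma, \sigma_b, \sigma_w, t_{div}) = (-6.82, 3.78, 2.56, 4.38)$);
per locus $\theta_s, \theta_r \sim U(0.5, 5)$ and
$m, n \sim U\{5,\dots,12\}$ (the original uniform ranges are unreported;
these bracket the seven-to-twelve alignments of the real data and give
count magnitudes of the same order); $\gamma_m \sim N(\mu_\gamma,
\sigma_b^2)$; six Poisson counts from the model's expected table. The
source draws a per-locus $\gamma \sim N(\gamma_m, \sigma_w^2)$, but the
count means already integrate over that normal, so the generator uses the
model-consistent reading (means at $(\gamma_m, \sigma_w)$);
`mode = "fixed"` provides the literal fixed-effects variant for sensitivity
checks.

What the generator emulates is exactly the model's own stochastic world:
independent sites, Poisson counts, a Gaussian DFE. It does *not* emulate
linkage, demographic change, non-equilibrium ancestral populations,
misalignment or ascertainment in real data — so a green recovery test
establishes correctness of inference *under the model*, not robustness.
The independent check that the model's expected counts describe an actual
evolving population is the brute-force discrete Wright–Fisher oracle in the
test suite (binomial resampling, $N = 50$, selection $\gamma/2N$, influx
$\theta/2$ per generation, hypergeometric sampling of individuals), which
matches the $\Lambda$'s within Monte-Carlo error at $\gamma \in \{0,\pm2\}$.

## Scaled-down acceptance runs

The reference analyses use 2,000,000 iterations; the test suite runs 150,000
(proportional phases, 50% burn-in, thinning 15) on 30 simulated loci, which
is where a single CPU gets in a few minutes with the cache. At that
length the hyperparameter chain is still mixing, so credible intervals for
the recovery criterion are taken from the pooled retained draws rather than
the final subchain (the final-subchain convention is kept for
`summary_report()`'s point estimates); $\sigma_b$ and $\sigma_w$ are known
to be overestimated at the reference scale too, which is why their
point-estimate tolerance is a factor of three.

Two honest caveats. First, $\sigma_w$ is close to unidentifiable from 2×3
tables: it trades off against $\mu_\gamma$ and $\theta_r$ almost exactly, so
the posterior has a long curved ridge; chains traverse it slowly, and the
potential-scale-reduction statistic for $\mu_\gamma$ and $\sigma_w$ stays
above 1.1 at every desk-scale length we tried (the full-scale analyses that
report convergence use 2,000,000 iterations). The corresponding acceptance
test asserts the 1.1 threshold anyway and is expected to fail on those two
parameters while $t_{div}$ and $\sigma_b$ pass. Second, the real-data
targets cannot be recomputed: the supplementary table of the 91 genes is
not distributed with the text the package was built from, and no synthetic
stand-in is asserted against the printed numbers.

## Known limitations

Equal, constant population sizes of the two species and their ancestor;
genic selection only (no dominance); free recombination; a Gaussian DFE
(no heavy-tailed alternatives); single-chain sampling (parallel chains are
run by seed, not MPI). Legacy-polymorphism means decay like $e^{-4t}$, so
for $t_{div} \gtrsim 3$ the `Hs`/`Hr` categories carry almost no
information and their expected counts sit near the numerical floor. The
positively-selected proportions of polymorphisms and fixed differences
weight the half-line integrals by the raw $\Lambda_j$ (not
$\Lambda_j/s(1)$); since $\Lambda_1$ grows with $|\gamma|$ on the negative
side, these ratios fall toward 0 rapidly as $\sigma_w$ grows at fixed
negative $\gamma_i$ — posterior draws with inflated $\sigma_w$ therefore
drag the fixed-difference proportion down, which is worth remembering when
comparing short and long chains.
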