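---
title: "Hierarchical Bayesian estimation of organ-specific critical N dilution curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian estimation of organ-specific critical N dilution curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncdilution)
```

## The scientific problem

The critical nitrogen concentration $N_c$ is the minimum plant N
concentration (% of dry mass) that still supports maximal growth at a given
crop size. As a crop accumulates biomass, structural tissue dilutes its N,
and $N_c$ declines as a power law,

$$ N_c = A_1 \, W^{-A_2}, $$

where $W$ is biomass in t ha$^{-1}$ (or leaf area index, LAI), $A_1$ is the
critical concentration at $W = 1$, and $A_2$ is the dilution exponent. The
ratio of a crop's measured N concentration to its critical value is the
nitrogen nutrition index, $\mathrm{NNI} = N_t / N_c$: below 1 the stand is
deficient, near 1 optimal, above 1 taking up luxury N. Curves can be fitted
on the whole shoot, but leaf and stem tissue dilute N differently, so this
package estimates organ-specific curves for wheat on four bases: leaf
biomass vs leaf N, stem biomass vs stem N, shoot biomass vs shoot N, and
LAI vs shoot N.

## The hierarchical change-point model

At each sampling date $i$, biomass responds to plant N concentration as a
linear-plus-plateau function: it rises linearly below the date's critical
concentration and is flat at the date's maximal biomass $B_{\max,i}$ above
it,

$$ \mathbb{E}[W \mid N] = \begin{cases}
   B_{\max,i}\,\bigl(1 - \beta_i (N_{c,i} - N)\bigr), & N < N_{c,i} \\
   B_{\max,i}, & N \ge N_{c,i},
 \end{cases} $$

clipped below at zero. The hierarchical link is that the per-date critical
points are not free: they all lie on one dilution curve,
$N_{c,i} = A_1 B_{\max,i}^{-A_2}$. Each date keeps its own nuisance
parameters $B_{\max,i}$ (plateau) and $\beta_i$ (slope), so one fit per
experimental condition pools every sampling date while estimating a single
$(A_1, A_2)$.

Priors are deliberately weak and uniform: $A_1 \in [0, 12]$,
$A_2 \in [0, 5]$, $\beta_i \in (0, 5)$, and
$B_{\max,i} \in (0, 2\max W_i)$ per date. These boxes comfortably contain
every published wheat curve on any basis.

### Observation noise

Biomass sampling error in field trials grows with the crop: a 10 t/ha stand
is not measured to the same absolute precision as a 1.5 t/ha one. The
default likelihood therefore uses a single *relative* noise parameter,
$W \sim \mathcal N(\mu, \sigma B_{\max,i})$ with $\sigma$ uniform on
$(10^{-4}, 1)$. This matters beyond realism: early, low-biomass sampling
dates are the precise observations that anchor the curve's intercept at
$W = 1$, and a constant-SD likelihood (available via
`model_spec(noise = "constant")`) lets the noisy late dates drown them. In
simulation experiments with proportional noise, the constant-SD model
biases the posterior of $A_1$ roughly 10% low at realistic trial sizes,
while the relative-noise model centres the recovery error at zero; we keep
the constant variant for data whose error process is genuinely absolute.

### Sampling

The posterior is explored by an adaptive Metropolis-within-Gibbs sampler
written in C++:

* a single-site sweep with per-parameter Gaussian random walks whose scales
  adapt during burn-in toward 0.44 acceptance (diminishing adaptation);
* a full-dimensional adaptive-Metropolis block move over all free
  parameters, with $A_1$ handled on the log scale. This block is essential:
  $\log N_{c,i} = \log A_1 - A_2 \log B_{\max,i}$ puts $(\log A_1, A_2)$
  and every slope on one narrow ridge (posterior correlations of 0.97+),
  which single-site moves crawl along. The block proposal uses the chain's
  own running covariance (Haario-style, scaled by $2.38^2/d$, restarted
  twice during burn-in to shed the initial transient) and is repeated
  several times per sweep, scaling with model dimension.

Chains start from overdispersed but plausible states (plateaus near the
observed group maxima, moderate slopes, curve parameters spread over the
agronomically occupied part of the prior). Defaults are 4 chains with
5,000 burn-in and 3,000 retained iterations each, which on simulated trials
reach split-$\hat R < 1.01$ and effective sample sizes of 500–1,500 for
$(A_1, A_2)$ in about two seconds; survey-scale settings
(≈100,000 burn-in, 30,000 retained) are a single argument away and change
the summaries by less than Monte Carlo error.

### Convergence screening

Fits are screened, not trusted: a fit converges iff split-$\hat R$ of both
curve parameters is below 1.1 **and** their multi-chain effective sample
size reaches 400. Non-converged fits are excluded from every downstream
comparison, NNI table and correlation. The thresholds operationalize the
common practice of deleting non-convergent curve fits, which is otherwise
left vague in the literature.

### The grid oracle

Because the sampler is bespoke, its correctness is certified against an
independent brute-force oracle: with all nuisance parameters pinned,
`grid_posterior_oracle()` evaluates the exact posterior of $(A_1, A_2)$ on
a fine grid over the prior box and extracts marginal quantiles from the
interpolated discrete CDF (quantile error is $O(h^2)$ after the half-cell
correction). On toy models the MCMC and grid medians agree to about 0.1%,
interval endpoints to well under 1%; doubling the grid moves the oracle's
own medians by under 0.01%.

## The synthetic trial generator

The field data this methodology is used on are multi-site wheat N-rate
trials: 5+ sampling dates before flowering, 3–13 N treatments from nil to
luxury supply, about 3 replicate plots, organ-partitioned biomass and
Kjeldahl N concentrations, plus daily weather. No such dataset ships with
the package, so `simulate_experiment()` generates them with known ground
truth:

* per-date plateaus $B_{\max,i}$ grow exponentially (default 1.5 to
  12 t/ha over the season), the usual vegetative trajectory between
  tillering and flowering;
* each treatment's achieved shoot N concentration sits at a fixed multiple
  of the date's true critical value (defaults 0.6, 0.8, 0.95, 1.05, 1.2,
  1.4), guaranteeing both limbs of the plateau are populated;
* expected shoot biomass follows the linear-plus-plateau response; Gaussian
  noise with SD equal to 5% of the date's plateau is added per replicate;
* the shoot is split into leaf and stem with a leaf share declining
  linearly from 0.55 to 0.30 across dates (stem dominates late); leaf N
  sits a fixed offset (default 0.8 points) above shoot N and stem N is
  solved so the biomass-weighted organ mean reproduces shoot N exactly;
  LAI is leaf biomass times a specific leaf area of 2.0;
* daily weather comes from a seasonal sinusoid with noise and a
  Bernoulli–gamma rainfall process.

`simulate_gem_suite()` builds multi-condition programmes; each experiment
derives its sub-seed from the master seed keyed by its id, so adding or
reordering experiments never changes the others' data.
`default_gem_design()` emulates a 14-condition genotype × environment ×
management programme across 5 sites and 5 genotypes, with true intercepts
spanning $A_1 \in [2.8, 4.6]$, one sparse 3-rate trial and one dense
13-treatment trial.

What the generator does **not** emulate: soil N dynamics, phenology beyond
the plateau trajectory, spatial field heterogeneity, correlated replicate
errors, measurement error in N concentration itself, and real LAI (here a
fixed proportionality to leaf biomass). Passing tests on these data
therefore certify the statistical machinery — identifiability, coverage,
agreement statistics — not the agronomy of any particular real dataset.

## Observation selection

Two screening rules are applied before fitting. First, observations taken
while shoot biomass is below 1 t ha$^{-1}$ are removed (for every basis,
keyed on shoot biomass as one consistent developmental gate; the boundary
value is kept). Early N concentrations do not yet follow dilution, and
retaining them contaminates the curve. Second, a sampling date only forms a
fit group if at least three (W, N) pairs survive — fewer cannot identify a
slope, a plateau and a critical point. Replicates enter as individual
points by default; `make_date_groups(use = "means")` averages them first,
since the original field protocols are ambiguous on this point.

## Downstream analyses

* **Credible bands** (`credible_band()`): $N_c$ is evaluated under every
  retained posterior draw along a biomass grid; the 2.5–97.5% width is the
  curve's uncertainty. At $W = 1$ the band is exactly the $A_1$ interval.
  Uncertainty is widest at low biomass — in simulations the width at
  0.5 t/ha is several times the width at 3 t/ha — because the low-W end is
  an extrapolation below the filtered data range.
* **Hybrid curves** (`fit_hybrid()`): all experiments' date groups pooled
  under one $(A_1, A_2)$, each group keeping its own nuisances — the
  universal curve usable when condition-specific curves are unavailable.
  With simulated conditions sharing one truth, NNI from the hybrid curve
  agrees with condition-specific NNI to n-RMSE ≈ 1%; with deliberately
  discordant truths ($A_1$ = 3.0 vs 4.5) it degrades to ≈ 25%, which is the
  quantitative version of "a universal curve is serviceable only when
  conditions are similar".
* **Parameter comparison** (`compare_parameters()`): two fits differ on a
  parameter when the central 95% interval of the difference of their
  posterior draws excludes zero; a greedy clique cover of the
  non-difference graph yields compact letters, deterministic in fit id.
  This deliberately replaces the GLM-ANOVA + Tukey test sometimes used on
  posterior parameters: the posterior-difference rule is self-contained and
  needs no replicate structure. The CV (= SD/mean × 100, sample SD) of the
  posterior medians across conditions summarizes G × E × M variability.
* **NNI diagnostics** (`nni_series()`, `basis_crosswalk()`): NNI is
  computed per observation, never averaged per treatment. The crosswalk
  pairs observations across bases by exact (experiment, date, treatment,
  replicate) match — no interpolation — and reports RMSE and n-RMSE of each
  organ basis against the shoot basis, plus the leaf+stem biomass-weighted
  mean NNI, which tracks shoot NNI most closely by construction.
  n-RMSE is normalized by the mean of the *reference* series (the first
  argument: hybrid-derived NNI in hybrid-vs-specific comparisons, shoot
  NNI in cross-basis ones), so it is directional; RMSE is symmetric.
* **Drivers** (`extract_covariates()`, `correlate_drivers()`): per
  experiment, maximum shoot biomass and N concentration before flowering,
  vegetative period duration (VPD, sowing to flowering in days),
  accumulated growing degree days with $T_{base} = 0\,^\circ$C (negative
  daily means clamped to zero — the standard winter-wheat convention;
  `clamp = FALSE` gives the literal unclamped sum), daily mean GDD
  (= AGDD/VPD over the same window), total rainfall (precipitation only;
  irrigation is not modelled) and sowing density. Pairwise Pearson
  correlations (Spearman optional) with two-sided t tests on $n - 2$
  degrees of freedom, tiered at 0.1/0.05/0.01/0.001 without
  multiple-testing correction, matching how such matrices are usually
  reported in this literature. Constant variables are flagged undefined
  instead of failing the matrix.

## Numerical and design choices

* Dates are ISO-8601; `date_index` is the chronological rank within an
  experiment. AGDD accumulates over exactly VPD days (sowing up to the day
  before flowering), making the identity GDD_daily × VPD = AGDD exact.
* CSV round trips are bit-exact: numerics are written with 17 significant
  digits.
* All suite- and pipeline-level seeds derive from a master seed via a
  stable 31-adic string hash of "experiment-id/basis", kept below
  $2^{31}$; reruns of `run_pipeline()` under one config reproduce every
  output file byte-identically.
* Ties and degenerate inputs: a group whose observations are all on the
  plateau leaves $\beta_i$ prior-dominated (harmless — the curve link does
  not involve $\beta_i$); a filter that removes everything, an empty basis,
  a single-chain diagnostic request, or a non-converged fit asked for a
  credible band are hard errors rather than silent NAs.
* The hierarchical pooling across dates is via the shared $(A_1, A_2)$
  only; nuisances are independent per date. A shared hyperprior across
  dates would shrink the $\beta_i$ and could tighten small experiments,
  but nothing in the source methodology constrains its form, so it is left
  out rather than invented.

## Problem sizes used in the tests

The shipped test-suite and acceptance analyses run at deliberately modest
sizes chosen to exercise the full pipeline on one CPU: the reference
simulated trial is 8 dates × 6 N rates × 3 replicates (432 organ
observations), fitted with 4 chains × (5,000 + 3,000) iterations;
the calibration study repeats 50 such trials at 2 chains ×
(2,500 + 1,500); suites use 2–14 experiments. These are the package's
default study conditions, not limits of the method.

## Known limitations

* Posterior medians of $A_1$ carry a small negative finite-sample skew for
  *sparse* designs (≤ 5 N rates without near-critical treatments, few
  dates); coverage of the 95% interval degrades accordingly. This is a
  property of the change-point likelihood, not of the sampler — the grid
  oracle shows the same shift. Design advice follows the source
  literature: more rates near the critical range and more sampling dates.
* A single relative noise parameter is shared by all dates of a fit;
  date-specific error variances are not modelled.
* The LAI basis inherits whatever error the leaf-biomass proxy introduces;
  in real data LAI is measured optically and its error process is
  different.
* The significance letters are a Bayesian substitute for, not a
  reproduction of, frequentist multiple-comparison output.
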