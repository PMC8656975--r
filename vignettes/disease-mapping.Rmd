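---
title: "Methods: small-area smoothing of admission risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area smoothing of admission risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`carmap` maps the risk of urgent hospital admission across census tracts.
This vignette is the package's own account of the statistical machinery: the
models and their assumptions, the defaults and why they were chosen, what
the synthetic generator does and does not emulate, and the numerical
decisions that a reader of the results should know about.

## 1. Indirect standardization

The observed admissions of tract *i*, sex *s*, are compared with the number
expected if the tract experienced the area-wide age-specific rates:

$$r_{g,s} = \frac{\sum_i O_{i,g,s}}{\sum_i n_{i,g,s}}, \qquad
  E_{i,s} = \sum_g n_{i,g,s}\, r_{g,s}, \qquad
  \mathrm{SAR}_{i,s} = 100\, \frac{O_{i,s}}{E_{i,s}}.$$

Five age groups are used (under 15, 15–39, 40–64, 65–84, 85+). Populations
are treated as constant over the multi-year study window and rates as
cumulative risks over the window, so person-time cancels in the ratio. With
internally derived rates, $\sum_i E_{i,s} = \sum_i O_{i,s}$ per sex — the
defining conservation property, tested to 1e-8 relative. Tracts with
$E = 0$ get an undefined SAR: they are flagged and excluded from maps
rather than imputed, which is the conservative option when the truth is an
empty stratum.

## 2. Smoothing models

Counts are Poisson with the expected count as offset,
$O_i \sim \mathrm{Poisson}(E_i \theta_i)$, and the log relative risk gets a
spatially structured prior. Four priors are implemented:

* **bym** — $\log\theta_i = \alpha + u_i + v_i$ with
  $u \sim \mathrm{ICAR}(\tau_u)$ and $v_i \sim N(0, 1/\tau_v)$. The classic
  (unscaled) convolution model; the package deliberately does not use the
  rescaled BYM2 reparametrization, matching the model family this literature
  fits.
* **icar** — spatial component only.
* **iid** — exchangeable component only (the "no-spatial" reference model).
* **leroux** — one field with precision
  $\tau\,[(1-\lambda) I + \lambda (D - W)]$, interpolating between iid
  ($\lambda = 0$) and the intrinsic CAR ($\lambda = 1$).

The ICAR precision is the graph Laplacian $Q = D - W$ of the tract
adjacency graph, with rank $n - c$ for $c$ connected components. The
impropriety is handled by a sum-to-zero constraint per component, enforced
by centering after every sweep; the intercept carries the level. Isolated
tracts cannot carry an intrinsic spatial effect: the precision builder
refuses them by default, and the fitting functions treat them as purely
unstructured.

Reported per tract: SRR (posterior mean of $100\,\theta_i$; the posterior
median is reported alongside since the field does not standardize on one),
a 95% equal-tailed credible interval, and the exceedance probability
$PP_i = \Pr(\theta_i > 1 \mid \mathrm{data})$ with the conventional
$PP \ge 0.8$ flag. Zero-expected tracts stay in the latent field but are
excluded from the likelihood and reported as `NA`.

### Priors

Hyperpriors default to gamma(shape 1, rate 0.0005) on every precision (the
classical default of the WinBUGS-era disease-mapping literature), a vague
$N(0, 1000)$ intercept, and uniform(0, 1) on the Leroux $\lambda$. All are
overridable through `car_prior()`. The source study does not state its
hyperprior choices, so nothing stronger than common practice is assumed.

### MCMC

Inference is Metropolis-within-Gibbs, coded in C++:

* single-site Gaussian random-walk updates for the field(s) and intercept,
  with per-site proposal standard deviations adapted toward 44% acceptance
  in windows of 50 iterations **during burn-in only** (so the post-burn-in
  kernel is fixed and draws are valid MCMC);
* conjugate gamma updates for precisions, with shape contributions
  $(n - c)/2$ for intrinsic fields and $n/2$ for proper ones;
* logit-scale random walk for $\lambda$, using the exact log-determinant
  from the precomputed eigenvalues of $Q$;
* latent fields are initialized at the centred residual log-SMR
  ($\log((O+0.5)/E) - \hat\alpha$), not at zero. Starting an intrinsic
  field at zero lets the first precision update drive $\tau \to \infty$ and
  lock the field flat — a well-known trap for this sampler family.

Four chains of 5000 iterations (2000 burn-in) are the default. Convergence
is monitored by split-chain R-hat on every hyperparameter with a warning
(not a failure) above 1.1, plus effective sample sizes from Geyer's initial
positive sequence. All randomness flows through R's RNG, so a fixed seed
reproduces results bit for bit, chains included.

In the BYM model only the sum $u_i + v_i$ is likelihood-identified; the
precisions $\tau_u, \tau_v$ can trade off slowly between chains. This shows
up as high R-hat on $\tau_v$ while SRR and PP (functions of the sum) remain
stable — a known property of the unscaled convolution model, worth
remembering before reading hyperparameter posteriors literally.

### Model comparison

DIC uses the plug-in form $p_D = \bar D - D(\bar\theta)$; WAIC uses the
variance-form penalty with log-sum-exp pooling of the pointwise
likelihoods. Both are computed from the retained $\theta$ draws on the
likelihood-included tracts, and both are verified in the tests against
brute-force oracles at machine precision.

## 3. The shared-component joint model

To pool the sexes, one intrinsic field $\delta$ is shared:
$\log\theta_{i,m} = \alpha_m + \kappa\,\delta_i + v_{i,m}$ and
$\log\theta_{i,f} = \alpha_f + \delta_i/\kappa + v_{i,f}$, the simplest
member of the shared-component family and a stand-in for (not a replica of)
the multivariate CAR models used with INLA in this literature. $\kappa > 0$
rescales the common field between sexes and gets a log-normal prior with
median 1 (sdlog 0.5 — weak, but proper, which $\kappa$ needs because it is
only identified jointly with the field scale). Two extra joint Metropolis
moves — a field-scale rescale of $\delta$ and a $\kappa$-compensating
rescale that leaves the male predictor invariant — were added because
single-site updates alone mix the $(\kappa, \|\delta\|)$ direction poorly.

The reported cross-sex correlation is the posterior mean (with interval) of
the per-draw Pearson correlation between $\log\theta_m$ and $\log\theta_f$
across tracts. A caveat found in the recovery experiments: with a few
expected events per tract, the 95% credible interval for $\kappa$
concentrates on the *realized* loading ratio of the particular data set,
and its frequentist coverage of the generator value sits below nominal
(roughly 80–90% in the package's 15×15 experiments). Tests therefore use a
replication standard (the property holds in at least 8 of 10 replicates)
rather than per-replicate certainty.

## 4. Cluster detection

Global Moran's $I$ is computed with row-standardized weights by default
(binary available); the permutation test relabels values over tracts, with
the two-sided pseudo p-value $(\#\{|I_{perm}| \ge |I_{obs}|\}+1)/(M+1)$ and
a z-score from the permutation moments. An analytic normal test under
randomization (with kurtosis correction) is provided as an alternative,
since the inference method behind published z-values is often unstated.

Local Moran statistics use Anselin's population-variance scaling, so
$\sum_i I_i = n I$ exactly with row-standardized weights (tested to 1e-10).
LISA p-values come from conditional permutation (hold $x_i$, permute the
rest) and are **two-sided** — twice the smaller tail, capped at 1. The
one-sided convention common in desktop GIS tools has null size near
$2\alpha$; the two-sided version keeps the fraction of significant tracts
near $\alpha$ under spatial randomness, which is what the package's null
calibration tests assert. No multiple-testing correction is applied by
default (matching how these maps are usually published); `fdr = TRUE`
applies Benjamini–Hochberg. Classification uses the quadrant of
$(z_i, \sum_j w_{ij} z_j)$ among significant tracts, so high-high/low-low
always have $I_i > 0$ and high-low/low-high $I_i < 0$. In the pipeline,
clustering runs on the **smoothed** risks, not the raw SAR.

## 5. The synthetic generator

The generator exists so that the full pipeline is testable without the
confidential registry data the real study used. It emulates the *structure*
the analysis assumes:

* geography: a rook/queen lattice; the `asturias-like` preset uses an
  18×31 queen lattice, i.e. 558 tracts. Real census-tract geography is
  irregular; here the irregularity is carried by the population sizes, not
  the polygons.
* populations: per-tract totals negative-binomial around a mean of 1265
  inhabitants with dispersion 4 (coefficient of variation ≈ 0.5, emulating
  the observed heterogeneity of tract sizes), split into 2 sexes × 5 age
  groups by a multinomial draw from an aged urban profile.
* risk: the generative counterpart of the BYM model — an exact ICAR draw
  (sampled on the non-null eigenspace of $Q$, so the sum-to-zero constraint
  holds to 1e-10 per component) with $\tau_u = 1$, shared between the
  sexes, plus sex-specific $N(0, 1/\tau_v)$ noise with $\tau_v = 10$. The
  shared field makes the joint model's recovery well-posed.
* admissions: Poisson per stratum, with age-specific baseline rates rising
  steeply with age (relative weights 0.001 / 0.05 / 1 / 3.5 / 5). Absolute
  rates are free parameters in this literature; the preset calibrates them
  so the expected three-year totals are 3218 events split 64.42% / 35.58%
  male/female under the true risk surface.
* records: an event-level table with ~1.01% of records left spatially
  unassigned, emulating geocoding failure.

What it does **not** emulate: real polygon shapes and contiguity
irregularities, within-tract address structure, migration over the study
window, disease-specific coding detail, or any covariate structure.
Passing tests on this generator therefore demonstrate the correctness and
calibration of the *methods* under the model's own assumptions, not the
epidemiology of any real region.

## 6. Problem sizes and runtime choices

The test suite exercises: exact oracles on 2×2–5-node graphs; permutation
machinery against exhaustive enumeration at $n = 5$; recovery experiments
on 15×15 lattices (20 replicates for the single-sex model, 10 + 10 for the
joint model) with expected counts of 5–15 per tract; model comparison on
10×10 lattices at the study's own scale of 1–5 expected events per tract,
where spatial pooling matters most; and the full 558-tract preset
end-to-end with 2 chains × 2000–3000 iterations, run twice to confirm
byte-identical reruns. These sizes keep a full run in a few minutes while
leaving every statistical property testable at meaningful power.

## 7. Known limitations

* The unscaled BYM precisions are weakly identified (section 2); interpret
  $\tau_u/\tau_v$ posteriors with care.
* Leroux with free $\lambda$ mixes slowly when the data carry little
  spatial signal; $\lambda$ can be fixed for limit checks.
* Credible intervals for $\kappa$ under-cover the generator value at very
  small counts (section 3).
* LISA inference is conditional-permutation based; no account is taken of
  the smoothing-induced correlation between SRR values, which is the
  standard (if imperfect) practice when clustering smoothed maps.
* The pipeline treats populations as fixed denominators; no uncertainty in
  the census is propagated.
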