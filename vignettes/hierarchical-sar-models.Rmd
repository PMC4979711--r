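---
title: "Hierarchical multispecies models for species-area relationships under incomplete sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multispecies models for species-area relationships under incomplete sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A species-area relationship (SAR) describes how species richness grows with
the area of a habitat patch or island.  Observed species lists, however, are
the outcome of *sampling* as much as of ecology: sampling plots or transects
rarely cover a patch completely, and individuals that are exposed to sampling
are detected imperfectly.  Richness computed from raw detections therefore
underestimates true richness, by an amount that typically varies with patch
area and survey effort, and SARs built from such data confound ecological
process with sampling artefact.

`commsar` separates the two.  It treats community assembly as an ensemble of
species-level stochastic processes, places an explicit sampling model on top,
shares strength across species (including rare and even never-detected ones)
through community-level hyperdistributions, and derives richness, community
totals, and SAR curves as posterior functionals of the fitted model.

## The abundance model

For species $i$ in patch $j$ the latent patch-level abundance is

$$z_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
\log \lambda_{ij} = \beta_{0i} + \beta_{1i} \log A_j + x_j'\beta_i + b_{ij},$$

with $A_j$ the patch area in hectares, optional patch covariates $x_j$, and
random site effects $b_{ij} \sim \mathrm{Normal}(0, \sigma_b^2)$ (one shared
$\sigma_b$) absorbing extra-Poisson variation.  $\beta_{0i}$ is log abundance
at 1 ha; $\beta_{1i}$ is the species' density-area relationship (DAR):
$\beta_{1i} = 1$ means constant density, $\beta_{1i} < 1$ a preference for
small patches (an "edge" species).  Species-level coefficients are drawn from
community hyperdistributions,
$\beta_{0i} \sim \mathrm{Normal}(\mu_{\beta_0}, \sigma_{\beta_0}^2)$ and
likewise for $\beta_{1i}$, which is what lets sparse data on rare species
borrow strength from common ones.

Sampling enters in two stages.  Incomplete spatial coverage thins the latent
abundance binomially to the individuals exposed to sampling,
$N_{ij} \sim \mathrm{Binomial}(z_{ij}, \phi_j)$, where $\phi_j$ is the
sampled fraction of patch $j$.  Imperfect detection over $t$ repeat visits is
modeled from encounter frequencies: the vector counting individuals detected
$H = 0, 1, \dots, t$ times is multinomial with cell probabilities
$\binom{t}{H} p_i^H (1-p_i)^{t-H}$, where $p_i$ is the per-visit detection
probability, hierarchical on the logit scale
($\mathrm{logit}(p_i) \sim \mathrm{Normal}(\mu_{lp}, \sigma_{lp}^2)$; the
logit-normal form is our choice of hyperdistribution — it is standard
practice and keeps $p_i \in (0,1)$).  Because the $H = 0$ cell is
unobserved, the likelihood is reparameterized by *conditioning on
encounter*: the number detected at least once is
$n_{ij} \sim \mathrm{Binomial}(N_{ij},\, p_i^* )$ with
$p_i^* = 1 - (1-p_i)^t$, and given $n_{ij}$ the frequencies over
$H \geq 1$ are multinomial on the renormalized cells $\pi_H / (1 - \pi_0)$.
`conditional_encounter_loglik()` implements the decomposition, and the test
suite verifies by exhaustive enumeration ($N \le 6$, $t \le 5$) that it
equals the full multinomial likelihood.  A binomial count model
(`binomial_count_loglik()`) covers simple-count surveys without individual
encounter histories.

## The frequency model

Plant surveys usually record presence/absence in small regular plots.  With
a patch tessellated into $tp_j$ plots of `plot_area_m2` square metres
($tp_j = 10{,}000 A_j$ for 1-m$^2$ plots), the patch-level frequency is

$$z_{ij} \sim \mathrm{Binomial}(tp_j, \psi_{ij}), \qquad
\mathrm{logit}(\psi_{ij}) = \beta_{0i} + \beta_{1i} A_j + x_j'\beta_i + b_{ij},$$

where area enters *linearly*, so $\beta_{1i} = 0$ is the
constant-occurrence-probability null.  Only $ap_j \le tp_j$ plots are
actually sampled; the observed frequency is
$y_{ij} \sim \mathrm{Binomial}(ap_j, \psi_{ij})$, with within-plot detection
assumed perfect, as is usual for plants.  The frequency in the unsurveyed
remainder is $z(tp-ap)_{ij} \sim \mathrm{Binomial}(tp_j - ap_j, \psi_{ij})$
and the patch-level frequency is reconstructed as $y + z(tp-ap)$ — so a
species never seen in the sampled plots can still occupy the patch.  We fit
using the marginal binomial for $y$ and reconstruct $z$
posterior-predictively (`derive_patch_summaries()`); conditioning the fit on
$z = y + z(tp-ap)$ draw-by-draw would be an equivalent augmentation scheme
but adds latent nodes without changing the marginal posterior.

When species fall into ecological groups (say early-successional, mature
forest, exotic), intercepts and slopes get separate per-group normal
hyperdistributions, and group proportions get a Dirichlet prior (flat by
default — the all-ones concentration is configurable via
`fit_config(priors = ...)`); augmented species are assigned to groups
categorically inside the MCMC, and `assign_augmented_groups()` exposes one
such Dirichlet-categorical draw directly.

## Species never detected: data augmentation

The number of species in the regional pool, $S$, exceeds the number detected.
We append $M$ all-zero "potential" species (`augment_dataset()`) and give
every species a community-membership indicator
$w_i \sim \mathrm{Bernoulli}(\Omega)$ with $\Omega \sim \mathrm{Uniform}(0,1)$;
the ecological process becomes zero-inflated,
$z_{ij} \sim \mathrm{Poisson}(w_i \lambda_{ij})$ or
$\mathrm{Binomial}(tp_j, w_i \psi_{ij})$, so $w_i = 0$ makes zeros structural
while $w_i = 1$ leaves them as ordinary sampling zeros.  Estimating $\Omega$
with fixed ceiling $M$ is statistically equivalent to estimating
$S = \sum_i w_i$, which we report per draw (`derive_regional_richness()`),
partitioned into undetected species present on sampled patches versus absent
from all of them.  Detected species have $w_i$ fixed at one — their data force
membership, so fixing it is an exact Rao-Blackwellization, not an
approximation.  $M$ must comfortably exceed the plausible number of missed
species: the fit warns when the upper 95% bound of $\Omega$ approaches one,
and `augment = "none"` fits without augmentation entirely, the right choice
when the species pool is pinned down by expert knowledge (the situation that
arises with small, well-known faunas such as a dozen early-successional
birds).

## Inference

Models are fit by MCMC with JAGS (via `rjags`), the standard engine for this
model family; the model code is generated by the package per dataset
(`fit_abundance_model()`, `fit_frequency_model()`).  JAGS samples the
discrete latent states ($z_{ij}$, $N_{ij}$, $w_i$, group labels) with its
native samplers for unbounded discrete nodes, so no truncation bound on $z$
is imposed.  Defaults: 3 chains, 20,000 iterations with 10,000 burn-in,
thinning 10, community means $\sim \mathrm{Normal}(0, 10^2)$ and standard
deviations $\sim \mathrm{Uniform}(0, 10)$ — deliberately weak; all
configurable through `fit_config()`.  Per-chain RNG seeds derive
deterministically from one master seed, so a fit is exactly reproducible.
`diagnostics()` reports split-$\hat R$ (each chain halved; implemented in the
package) and effective sample sizes (from `coda`), flagging parameters above
the 1.1 threshold.

Fitting the multinomial encounter model requires a single visit count $t$
across patches; datasets with ragged visit counts validate fine but must be
harmonized before fitting.  For the frequency model, area enters the logit
linearly, so very wide area ranges can slow adaptation;
`standardize_area = TRUE` runs the sampler on standardized area and
back-transforms the draws (note the back-transformed intercept hyper-sd
combines the two component sds, since the standardized-scale model treats
intercepts and slopes as independent).

Sampler correctness is tested three ways: a conjugate reduction
(`constant_psi = TRUE` fits one flat Beta(1,1) occurrence probability per
species, checked against the closed-form beta-binomial posterior), a
comparison against independent per-species Poisson GLMs when detection is
nearly perfect, and reduced simulation-based calibration (40 draw-simulate-fit
cycles on a 5-species model with tight hyperpriors shared by generator and
fit; rank statistics checked for uniformity).

## Derived community quantities and null models

All community-level outputs are derived parameters.  Per posterior draw,
patch richness is $\#\{i : z_{ij} > 0\}$ and the community total is
$\sum_i z_{ij}$ (`derive_patch_summaries()`; for sampled patches this
conditions on the patch's own latent states).  `predict_sar_curve()` predicts
for *new* patches over an area grid: per draw it simulates every community
member's latent state at each area and summarizes richness and totals by
median and 95% band.  Site effects for new patches are drawn fresh from
$\mathrm{Normal}(0, \sigma_b^2)$ by default (`site_effects = "marginalize"`);
fixing them to zero is offered but understates predictive spread.  Grid
points below the smallest sampled patch are flagged as extrapolations.
Whether one should condition on or marginalize site effects for *sampled*
patches is genuinely ambiguous; the package keeps the two reports separate
(conditional in `derive_patch_summaries()`, marginal in
`predict_sar_curve()`).

The constant-density null refits the model with every $\beta_{1i}$ fixed (1
for abundance, 0 for frequency) and zero hyper-sd, *retaining* random site
effects so the comparison with the free-slope fit is like for like
(`fit_null_model()`).  The classical random placement model is the
no-site-effect special case of the abundance null, with closed form
$E[S(A)] = \sum_i (1 - e^{-\lambda_i A})$
(`random_placement_expected_richness()`), which doubles as an analytic oracle
for the prediction machinery; the frequency analogue
$\sum_i (1 - (1-\psi_i)^{tp(A)})$ is checked the same way.

## The simulator and the DAR experiment

`simulate_community()` draws from the full generative chain and emits the
observations of the detected species in exactly the package's input format,
keeping the truth for recovery scoring (`score_recovery()`).  Frequency-mode
observations are drawn hypergeometrically given the patch-level frequency (a
random $ap$-subset of the $tp$ plots), whose marginal is the binomial
sampling model — so the simulated $y$, $z$ and $z(tp-ap)$ are mutually
consistent.

Defaults are chosen as realistic survey conditions, and they are the
conditions under which the package's recovery properties are demonstrated:

* abundance mode — 30 species, 15 patches of 0.5-10 ha (log-spaced), 5
  visits, full coverage $\phi = 1$, $\mu_{\beta_0} = 0$,
  $\sigma_{\beta_0} = 1$, $\mu_{\beta_1} = 1$, $\sigma_{\beta_1} = 0.2$,
  mean detection 0.5 ($\mu_{lp} = 0$, $\sigma_{lp} = 0.5$),
  $\sigma_b = 0.2$: a small-patch songbird survey with constant density on
  average.
* frequency mode — 100 species, 10 patches of 1-10 ha, 1-m$^2$ plots at 16
  plots/ha, $\mu_{\beta_1} = 0$, $\sigma_{\beta_1} = 0.2$,
  $\sigma_b = 0.3$, and occurrence probabilities far below one
  ($\mu_{\beta_0} = -4.5$, $\sigma_{\beta_0} = 1.5$): a sparse understorey
  plant survey.
* for regional-richness recovery the plant community is made sparser still
  ($\mu_{\beta_0} = -8$, $\sigma_{\beta_0} = 2.5$, $\sigma_{\beta_1} =
  0.15$), so that of 100 true species only about 40 are detected — the
  regime where augmentation earns its keep; $M = 300$ potential species are
  appended.

The acceptance checks run at deliberately desk-sized scales — 20 replicate
simulate-and-fit cycles per experiment with 2 chains of a few thousand
iterations, a $10^5$-draw Monte-Carlo for distributional closed forms, and
50 replicates per arm of the slope experiment — sizes at which every check
also serves as a worked example.

What passing these simulations shows, and what it does not: the generator
draws from exactly the fitted model family, so recovery demonstrates that
the implementation inverts its own generative process at realistic sizes
(no identifiability pathology, correct propagation of both sampling layers).
Real surveys add features the generator deliberately omits — spatial
autocorrelation among plots within a patch, species interactions,
detection heterogeneity among individuals, covariate-driven variation
beyond area — so good simulation recovery does not certify unbiasedness on
field data, only that failures there would come from model misspecification
rather than from the machinery.

`run_dar_experiment()` asks how the community mixture of species-level DARs
shapes the SAR: a fraction `f_neg` of species have their area coefficient
shifted down by `dar_offset` (defaults 0.5 on the log-abundance scale, 0.3
on the logit-occurrence scale — moderate edge preferences; species-level
hyper-sds around them as in the base designs), and the SAR slope is the OLS
slope of log expected richness on log area, computed on *noise-free*
expected richness to isolate ecology from sampling noise (a sampled-richness
variant is a flag).  Expected richness cannot be negative and the expectation
is monotone in area for non-negative DARs, so the slopes are well defined;
communities richer in edge species show systematically flatter SARs.

## Numerical choices and degenerate inputs

* Latent-state initial values satisfy the ordering constraints
  ($n \le N \le z$) by construction; hyper-sd initials respect the support
  of their (configurable) uniform priors.  Frequency-model chains start
  from data-informed values — species intercepts at their observed logit
  occurrence rates, the intercept hyperparameters at their mean and sd, and
  membership indicators of undetected species at zero with $\Omega$ at the
  detected fraction — which removes a long burn-in transient in sparse
  augmented communities where generic starts leave short chains biased.
* `tp` is rounded to the nearest integer when derived from area; a supplied
  `tp` column always wins.
* Species and patches are keyed by string identifiers and indexed in sorted
  order, so results are invariant to input row order.
* A species supplied as an observed row but detected nowhere is treated as
  augmented-like (membership estimated) with a warning, under
  `augment = "auto"`.
* Degenerate hyper-sds of zero are legal throughout the simulator (they
  yield identical species, used heavily in the oracle tests); $\lambda = 0$
  yields structural-zero abundance.
* Likelihood primitives validate their supports and raise classed
  validation errors naming the offending row, rather than propagating NaNs.

## Known limitations

* The multinomial encounter fit requires equal visit counts across patches.
* The occupancy-style frequency model with imperfect within-plot detection
  is not implemented; detection within plots is assumed perfect.
* No spatial autocorrelation among plots within a patch, and no negative
  binomial alternative to random site effects (site effects already carry
  the extra-Poisson variation; unmodeled-covariate approaches are the more
  productive escalation).
* Group-specific SAR curves are not produced by `predict_sar_curve()`;
  group structure enters the fit and the richness partition only.
* Reversible-jump MCMC as an alternative to data augmentation is out of
  scope.
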