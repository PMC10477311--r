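---
title: "Methods: environmentally-conditioned reference points for multispecies reef fisheries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environmentally-conditioned reference points for multispecies reef fisheries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most multispecies coral reef fisheries are data-poor: there are no stock
assessments, no reliable effort series, and usually a single underwater
visual census per reef. `reefmsy` implements a fisheries-independent way to
obtain sustainable reference points for such fisheries. The whole reef fish
assemblage is treated as one aggregate stock governed by a surplus-production
curve, whose parameters are estimated not from catch-and-effort time series
but from two space-for-time sources: the biomass trajectory of no-take
marine reserves of different ages, and the standing biomass of remote,
effectively unfished reefs. Reference points are expressed as explicit
functions of local environmental conditions, so every surveyed site gets its
own benchmarks.

## Surplus-production model

Production at standing biomass $B$ is modelled within the Pella–Tomlinson
family. The package's default is the Gompertz–Fox form

$$P(B) = \log(B_0)\, r\, B \left(1 - \frac{\log B}{\log B_0}\right)
       = r B (\log B_0 - \log B),$$

with unfished community biomass $B_0$ (t/km²) and community biomass growth
rate $r$ (1/y). Production peaks at $B_{MMSY} = B_0/e$ with maximum
multispecies sustainable yield $MMSY = r B_0 / e$. The general family is
parameterized as

$$P(B) = \frac{r}{n-1} B \left(1 - (B/B_0)^{n-1}\right),$$

chosen because its $n \to 1$ limit reproduces the Gompertz–Fox curve exactly
and $n = 2$ is the Graham–Schaefer (logistic) model peaking at $B_0/2$. The
exponent $n$ is never estimated from data (it is weakly identified in
recovery data of this kind); the package exposes fixed members `fox`,
`schaefer`, and `pella_tomlinson` with user-chosen $n > 1$, and a
cross-validation comparison (`model_compare()`) to rank them.

"Pretty good multispecies yield" (PGMY) is the biomass interval over which
$P(B) \ge f \cdot MMSY$ (default $f = 0.8$). Since $P(B)/MMSY$ depends on
biomass only through the depletion $B/B_0$, the bounds are solved once on
the relative scale by bracketed root-finding (absolute tolerance $10^{-10}$)
and rescaled by $B_0$.

Recovery trajectories solve $dB/dt = P(B)$ in closed form: the Gompertz
curve $B(t) = B_0 \exp(\log(B_{min}/B_0) e^{-rt})$ for the Fox model and the
generalized logistic
$B(t) = B_0 [1 + ((B_0/B_{min})^{n-1} - 1) e^{-rt}]^{-1/(n-1)}$ for the
rest. The test suite verifies these against adaptive ODE integration and
finite-difference derivative checks.

## The joint hierarchical model

Observed biomass is lognormal in all three data subsets, with shared effect
sizes:

* **Reserves** (index $i$): expected log-biomass is the log recovery
  trajectory from a common starting biomass $B_{min}$ towards the site's
  environmentally-conditioned unfished biomass
  $B_{0,i} = \exp(\log B_0 + \beta_1 x_{prod} + \beta_2 x_{SST} +
  \beta_3 x_{atoll} + \beta_4 x_{coral})$, plus sampling-effect terms
  (depth, habitat, census method, sampling area), a reserve-size term, and a
  gravity term. Gravity — surrounding human population over squared travel
  time — absorbs net export of biomass from reserves embedded in depleted
  seascapes: a negative coefficient lowers the achievable reserve biomass
  where human pressure is high.
* **Remote reefs** (index $j$): expected log-biomass is $\log B_{0,j}$ plus
  sampling terms. Remote reefs anchor $B_0$ from above, which indirectly
  identifies $r$ through the gap between $B_{min}$, the reserve asymptote,
  and $B_0$.
* **Fished reefs** (index $z$): a free intercept $\gamma$, sampling and
  gravity terms, and jurisdiction random intercepts
  $u_c \sim N(0, \sigma_u)$. This subset pins down the sampling corrections
  used to marginalize observed biomass, and the gravity effect.

Space-for-time substitution means one common $B_{min}$ and $r$ across all
reserves; there are no per-reserve trajectories. When a reserve was surveyed
in several years, one year is chosen at random (seeded) so each reserve
contributes a single point.

**Covariate standardization.** Continuous covariates are mean-centered and
divided by two standard deviations, making their slopes comparable with the
0/1 dummies (atoll, habitat contrasts against slope, census contrasts
against belt transects). Gravity is deliberately *not* centered: baseline
parameters then refer to average environmental conditions at zero human
pressure. Missing hard-coral cover is imputed at the mean observed cover
before centering.

**Priors.** $\log B_0 \sim N(\log 120, 1)$, $\log r \sim N(-2, 1)$,
$\log B_{min} \sim N(\log 10, 1)$, slopes $\sim N(0, 2)$,
$\gamma \sim N(5, 5)$, and half-Cauchy(0, 1) for all scale parameters
(implemented as a zero-truncated Cauchy).

**Sampling.** The model is fitted by MCMC with JAGS (`rjags`), four chains
by default. Because Gibbs-type samplers autocorrelate more than Hamiltonian
ones, the default retains 1000 draws per chain after 1000
adaptation/burn-in iterations with thinning 10, which on desk-scale
synthetic data reaches the package's convergence targets (split R-hat below
1.01, bulk ESS above 400) in seconds. Chain RNGs are seeded from the master
seed, so identical seeds give identical draws.

**Diagnostics.** `diagnostics()` reports rank-normalized split R-hat and
bulk effective sample size (Geyer-truncated autocorrelation sums) per
parameter, plus posterior contraction $1 - \mathrm{Var}_{post} /
\mathrm{Var}_{prior}$. Contraction is computed on the sampling (log) scale
for positive parameters; the half-Cauchy scales use the analytic prior
variance $\mathrm{Var}(\log|\mathrm{Cauchy}(0,1)|) = \pi^2/4$, because their
natural-scale prior variance is infinite. Jurisdiction random effects carry
no contraction value (their marginal prior variance under the half-Cauchy
hyperprior is undefined). A uniform prior on an export proportion appears in
some statements of this model family but attaches to no likelihood term; it
is not implemented here.

**Model comparison.** `model_compare()` ranks surplus families by
approximate leave-one-out expected log predictive density, computed by
truncated importance sampling (weights capped at
$\bar w \cdot S^{3/4}$) over the pointwise posterior log-likelihood, with
pairwise differences and standard errors.

## Reference points, status, and classification

Posterior draws propagate to site-specific reference points: per draw,
$B_{0,s}$ from the site's environmental covariates (on the fit's
standardization scale; extrapolation beyond the fitted covariate range
warns rather than errors), then $B_{MMSY,s}$, $MMSY_s$, and PGMY bounds
under the chosen family. Observed biomass is *marginalized* to reference
sampling conditions — slope habitat, belt transects, average depth and
sampling area — by subtracting the posterior sampling-effect terms on the
log scale.

Status ratios are computed per draw: biomass status $B_{marg}/B_{MMSY}$,
fishing status $C/MMSY$, surplus at current biomass $P(B_{marg})$, catch
potential $P/MMSY$ (equal to one exactly when biomass sits at $B_{MMSY}$),
and the overfishing indicator $C > P$. The choice to evaluate the surplus
per draw (rather than at the posterior-median biomass) propagates parameter
uncertainty into all derived quantities; a median-plug-in analysis can be
reproduced by passing the median biomass as data. Summaries are posterior
medians with central 90% intervals (5th–95th percentiles; the interval
convention is central throughout).

Categories follow production logic evaluated at posterior medians: *good
condition* ($B \ge B_{MMSY}$, $C \le MMSY$), *warning* ($B \ge B_{MMSY}$,
$C > MMSY$), *recovering* ($B < B_{MMSY}$, $C \le P$), *unsustainable*
($B < B_{MMSY}$, $C > P$). "Below" is strict: a ratio of exactly one counts
as not-below. *Conservation concern* is failing either benchmark; *collapse*
is $B_{marg} \le 0.1\,B_{0,s}$. Uncertainty intervals on headline
percentages come from re-classifying every unit within each posterior draw,
while the point percentages use the median-based classification.

Jurisdiction-level reference points are draw-wise arithmetic means across
member sites, so a single-site jurisdiction inherits that site's posterior
exactly. Jurisdiction biomass is either the mean marginalized biomass of
fished member sites or the MPA-weighted mixture
$\bar B_{marg} (1 - p_{mpa}) + \bar B_{0,s}\, p_{mpa}$, an optimistic
scenario that places the protected fraction of territorial waters at
unfished biomass. Overfishing at the jurisdiction scale plugs the (weighted)
biomass into the jurisdiction surplus curve built from $B_{0,c}$.

## Ecosystem trade-offs

Four ecosystem responses are modelled against the same covariates plus
jurisdiction random intercepts (lme4): lognormal mean fish length and total
species richness, logit-Bernoulli top-predator presence, and
hurdle-lognormal parrotfish scraping potential. The hurdle is an explicit
two-part model — a constant zero probability $\delta_P$ and a lognormal
positive part — whose likelihood factorizes, so the two parts are estimated
independently (a property the tests verify by perturbation). Point
estimates suffice for the package's analyses; a fully Bayesian treatment
would add posterior uncertainty to the trade-off curves but not change
their construction.

Total richness corrects observed richness for the sampling veil: a
zero-truncated Poisson-lognormal species-abundance distribution is fitted
to the per-species counts by maximum likelihood (Gauss–Hermite quadrature,
40 nodes, Golub–Welsch construction), the probability $p_0$ that a species
was missed is estimated, and total richness is $S_{obs}/(1 - p_0)$. Fits
failing a Pearson chi-square test at $\alpha = 0.05$ (abundance classes 1,
2, 3, 4, 5–8, 9+) are flagged rather than silently kept. Parrotfish
scraping potential is the sum over species-size classes of density ×
feeding rate × bite area; the packaged rate table is synthetic (realistic
magnitudes, clearly labelled) and should be replaced with literature rates
for real analyses, with genus-mean fallback for unlisted species.

Trade-off curves marginalize each metric and the observed biomass to
reference conditions (slope, belt transect, non-atoll, average depth, area,
productivity and SST — the gravity-driven fishing gradient is retained,
since it *is* the gradient of interest), then fit penalized cubic
regression splines (mgcv, basis size 10) of metric against biomass, and
report percent changes between the curve values at $B_0$, $B_{MMSY}$, and
the PGMY bounds. Reference biomasses outside the observed biomass support
are truncated to it with a warning rather than extrapolated.

## The synthetic-data generator

`simulate_reef_data()` draws data exactly under the model's assumptions:
covariates from plausible tropical-reef distributions (SST ~ N(28, 1.5) °C,
ocean productivity ~ N(500, 150) mg C m⁻² d⁻¹, coral cover ~ Beta(2, 3),
25% atolls, depths 2–15 m, lognormal sampling areas around 250 m²),
category-specific habitat/census supports (remote reefs exclude flat
habitat and point counts; reserves use belt or point counts), reserve ages
0.5–40 y, lognormal gravity for non-remote sites and zero gravity with
travel times above 20 h for remote sites. Expected log-biomass follows the
three sub-model equations exactly, with lognormal observation noise.

Generating parameter defaults are the package's reference study
conditions, chosen once as field-plausible values: $B_0 = 120$ t/km² and
$B_{min} = 12$ t/km² (the prior medians), $r = 0.15$/y, fished intercept
$\gamma = 3.7$ (about 40 t/km² median fished biomass), effect sizes of
magnitude at most 0.2 on the two-SD scale, a weak negative gravity effect
(−0.02 per gravity unit), residual SDs 0.35/0.30/0.50 for
reserve/remote/fished subsets, and jurisdiction SD 0.3.

Catches are *test scaffolding*, not part of the inferential model: each
fished site catches a lognormal multiple (mixture median 0.8, log-SD 0.6)
of the surplus at its latent biomass, which makes all four fishery
categories arise with realistic frequencies. Missing coral cover is induced
at a 10% rate to exercise the imputation path. Two presets exist: `desk`
(30 reserves / 20 remote / 100 fished across 8 jurisdictions), used by the
test suite and the acceptance script, and `paper` (70/80/1903 across 40),
matching the three-subset structure of the global compilations this class
of analysis is applied to.

What the generator does *not* emulate: spatial autocorrelation and
connectivity, species composition and its turnover, multi-year reserve
time series, observation error in covariates, and catch mis-reporting.
Passing tests therefore demonstrate the correctness and calibration of the
machinery under the model's own assumptions — not robustness to the many
ways real reef data violate them.

## Problem sizes and runtime

All routine analyses use the desk preset: a four-chain fit retains 4000
draws and takes seconds; the full test suite (several fits, a five-pair
model-comparison study, 50 Poisson-lognormal recovery replicates) runs in
about two minutes; the acceptance script is dominated by one desk-scale
fit. The paper-scale preset fits in well under a minute and is available
for larger experiments.

## Known limitations

* The aggregate surplus model ignores winners and losers within the
  assemblage; assemblage-level sustainability does not imply per-species
  sustainability.
* The community growth rate is not an average of species-level intrinsic
  rates, and may shift if assemblages reorganize.
* Gravity conflates fishing with other human impacts; the export
  interpretation is phenomenological.
* Catch generation in the simulator is a modelling convenience; real catch
  statistics carry structural biases the generator does not mimic.
* The Pella-Tomlinson exponent is fixed by the analyst, not estimated.
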