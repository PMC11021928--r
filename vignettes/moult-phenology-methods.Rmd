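---
title: "Methods: individual moult phenology from longitudinal resightings"
author: "moultphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual moult phenology from longitudinal resightings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Colony-based pinniped studies score the visible moult of individually
marked animals repeatedly through a season: on each survey day, the
percentage of the body showing new fur is recorded as an integer 0–100 for
every tagged animal sighted. From such sighting tables one wants, per
animal and year ("moult cycle"): the date the moult started (5% moulted),
its midpoint (50%), end (95%) and duration; the haul-out arrival and
departure dates bracketing it; and population-level quantities — how
synchronous the moult is, how variance in timing partitions between
age-sex categories, years and individuals, and whether late-arriving
animals compress their haul-out ("phenological compensation").

The difficulty is that many cycles are sparsely observed, surveys cover
only part of the season, detection is imperfect, and scores carry observer
noise including rare gross errors (a fully moulted animal recorded as 0%
or vice versa). moultphen addresses these with a hierarchical Bayesian
logistic model, a detection-corrected arrival/departure model, and a
synthetic-colony generator so that every stage is testable against known
truth.

# The moult progression model

Each cycle's latent trajectory is logistic in time:
\[ p_i(t) = \mathrm{logistic}\!\left(\frac{t - t50_i}{s_i}\right), \]
so the 5–95% duration is \(2 s_i \ln 19\) and moult start is
\(t50_i - s_i \ln 19\). All cycles of a model run are fitted jointly with
crossed animal and year effects:
\[ t50_i = \mu_{t50} + a_{\mathrm{animal}(i)} + b_{\mathrm{year}(i)},
   \qquad
   \log s_i = \mu_{\log s} + c_{\mathrm{animal}(i)} + d_{\mathrm{year}(i)}, \]
with zero-mean Normal hyper-distributions on \(a, b, c, d\) and
half-Normal priors on their sds. The hyper-structure pools information so
sparse cycles borrow strength from the population (visible as shrinkage:
sparse cycles get wider, population-pulled posteriors).

**Observation model.** The recorded score is an integer produced by
rounding and clamping a noisy read-out of the latent fraction. We use that
process as the likelihood: score \(k\) has probability
\(\Phi((k/100 + 0.005 - p)/\sigma) - \Phi((k/100 - 0.005 - p)/\sigma)\),
with the tails absorbed into the boundary cells \(k = 0\) and
\(k = 100\), mixed with a fixed 2% uniform contamination over the 101
scores. Two alternatives were measured and rejected:

* a truncated-Normal *density* on the observed fraction halves its
  truncation denominator at \(p \in \{0, 1\}\), so extreme scores attract
  the fitted curve to the boundary; in recovery simulations this biased
  durations low (≈ −0.07 d) and cut 95% CI coverage of the generating
  truth to 80%;
* without the contamination component, 0↔100 flip errors (which the field
  protocol documents and keeps in the data) are essentially impossible
  under a Normal tail; \(\sigma_{obs}\) inflated from ≈0.02 to ≈0.11 and
  recovered durations were biased by more than a day.

The contamination weight is fixed, not estimated (`contamination = 0`
restores the pure censored-Normal model); the flip process itself is
deliberately *not* modelled, matching the field analysis.

**Sampling.** No general MCMC engine is available in the target
environment, so the package ships its own adaptive
Metropolis-within-Gibbs sampler (Rcpp). Scalar random-walk updates (step
sizes adapted toward 0.44 acceptance during warmup) are interleaved with
two exact moves: conjugate Gaussian "translation" draws along the
likelihood-invariant ridges \( \mu \leftrightarrow \) mean of each
random-effect block (without these, the hyper-means drift with split-Rhat
values above 4). Convergence is gated at split-Rhat ≤ 1.05 and ESS ≥ 200
per reported parameter; violations raise a structured warning
(`moultphen_nonconvergence`) naming the offending parameters.

**Priors** are weakly informative: \(\mu_{t50}\) Normal around the
score-weighted midpoint of the data (sd 30 d); \(\mu_{\log s}\) Normal
around the crude per-cycle initial estimates (sd 1.5); half-Normal sds of
10/5 d (animal/year timing), 1/0.5 (log scale), 0.2 (\(\sigma_{obs}\)).
With ≥ 6 observations per cycle spanning the moult these are dominated by
the data.

**Population summaries.** The headline "population mean duration" is the
hyper-distribution mean across individuals at an average year,
\(2\ln 19\, e^{\mu_{\log s} + \sigma_c^2/2}\), whose posterior sd carries
between-individual uncertainty. The year-variance term is excluded from
the headline because with few years \(\sigma_d\) is prior-dominated and
inflates a lognormal mean; a `_with_year` variant and the finite-sample
cycle average are also returned.

# Inclusion rules

Cycles enter the moult model with ≥ 6 observations, at least one score
< 10% and one > 90% (strict inequalities). The haul-out model uses only
cycles whose 95% CI of moult start is strictly narrower than 6 days.
These thresholds are exposed (and logged when overridden) in
`pipeline_config()`.

# Arrival and departure with imperfect detection

The first sighting lags true arrival by however many surveyed days the
animal was present but missed. With latent first-day-ashore \(a\), first
sighting \(f\) and per-survey-day detection probability \(p\), the gap
likelihood is \((1-p)^k\), \(k\) = surveyed days in \([a, f)\), under a
uniform prior on a 30-day window before \(f\) (doubled for
single-sighting cycles, which are flagged). Departure mirrors this after
the last sighting. Only surveyed days count: unsurveyed days carry no
non-detection information.

Detection is modelled separately for the two boundaries, constant within
a season, hierarchical across years: \(p_y \sim
\mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)\) with \(\kappa = 10\) fixed and a
flat hyper-prior on \(\mu\). The gap terms alone cannot identify \(p\), so
the sampler also uses the interior surveyed days between first and last
sighting — when the animal is known to be ashore — as Bernoulli detection
trials (first half of the haul-out informs the arrival probability,
second half the departure probability). Sampling is pure Gibbs
(conjugate Beta updates, exact categorical draws of the latent days) plus
a Metropolis step for \(\mu\).

Day convention: the latent day \(a\) is the first day ashore; continuous
arrival is reported as \(a - 0.5\) and departure as \(d + 0.5\), so the
draw-wise identity duration = departure − arrival holds and the perfect
detection limit returns the first/last sighting days exactly.

# Synchrony

Population curves are empirical cumulative fractions on a daily grid with
half-open day semantics (an individual is present on day \(t\) iff
arrival ≤ \(t\) < departure), which makes cumulative differencing exact.
Peak synchrony is the maximum of the presence (or moulting) curve,
earliest day on ties. The population event window is quantile-based: from
the \((1-c)/2\) quantile of start dates to the \(1-(1-c)/2\) quantile of
end dates (for Normal starts with fixed duration \(d\) this is
\(3.92\sigma + d\) at \(c = 0.95\), and the expected peak fraction is
\(2\Phi(d/2\sigma) - 1\) — both used as closed-form oracles in the tests).
Years are pooled by default; filter the event table for per-year curves.

# Category comparisons and variance partitioning

Positive metrics (durations; start dates shifted to days since 1 March so
a log link applies) are compared with gamma log-link mixed models
(`lme4::glmer`): category fixed effect, random intercepts for individual
and year, all-pairs Tukey-adjusted contrasts at α = 0.05 summarized as
grouping letters. Variance is partitioned from
`metric ~ category * year + (1 | animal)`: fixed component = variance of
the fixed linear predictor across observations; individual = random
intercept variance; residual on the link scale via the lognormal
approximation \(\log(1 + \phi)\) for gamma dispersion \(\phi\). Because
the published convention is ambiguous, shares are reported both with and
without the residual in the denominator. The gaussian/identity variant
exists so a brute-force expected-mean-squares ANOVA oracle can verify the
decomposition on balanced synthetic data.

The compensation regression is gamma log-link duration on arrival within
category (individual random intercept); it reports the per-day slope with
Wald CI and the fitted earliest-vs-latest arrival-decile duration ratio.

The annual-cycle chain orders eight events of a reproductive female's
year. Breeding-season entries are externally sourced constants
(`breeding_constants()`): the defaults — arrival mid January (day 13,
sd 5), birth +6 d, weaning/departure +27 d — are *synthetic stand-ins
labelled `external-constant`*, configuration not computation; the moult
events come from the pipeline.

# The synthetic colony

The generator is the package's stated world, defaults frozen once:

* category means as printed in the field literature: moult starts —
  juvenile males day 118 (28 April), juvenile females +5 d, skip adult
  females +11 d, reproductive adult females +19 d; 5–95% durations
  5.95 / 6.01 / 9.67 / 10.29 d (reproductive, skip, juvenile female,
  juvenile male); duration sds 1.6 / 1.7 / 2.6 / 2.8 d back-computed from
  printed standard errors and sample sizes; pre- and post-moult gaps both
  18 d.
* individual start sd 11.5 d (so the pooled start sd across categories
  ≈ 13.8 d, consistent with the printed 61.4 d population window for
  7.3 d events) — individual effects are drawn once per animal and shared
  across years; year effect sd 1 d, shared across animals and categories
  (year-to-year variation in moult timing is reported as negligible).
* per-year cycle counts ≈ the published annual average (96/16/33/23
  individuals per category × 7 years ≈ 1176 cycles).
* observation process: 75% of season days surveyed; detection 0.7 per
  survey-day (the printed 60% refers to the breeding season; moulting
  animals are described as highly detectable, so a higher value was
  chosen once); observer noise sd 3 points — a calibration, not a printed
  value, chosen to reproduce the duplicate-scorer R² ≈ 0.986; 0↔100 flip
  probability 0.02 ("less than 3%" of extreme scores).
* pre/post-moult gap spread: Normal truncated above 2 d, sd 6.9 d
  (back-computed from the printed s.e. 0.20 at n = 1178). The source
  material does not state the gap distribution; this is the package's
  choice, flagged as such.

**Compensation mechanism.** Arrival is moult start minus the pre-moult
gap; haul-out duration is
\((\mathrm{dur} + 36)\,e^{\beta (A - \bar A) + \eta - c}\), with
\(\eta \sim N(0, 0.1)\) extra noise and \(c\) the centring constant that
keeps the expected haul-out equal to duration + both mean gaps (42 d for
reproductive females). This makes log haul-out duration *exactly* linear
in realized arrival with slope \(\beta\) — the property the downstream
regression estimates. A literal multiplicative scaling of the two gaps
was tried first and rejected: the fixed moult duration in the total
attenuates the realized slope by 15–25%, so the generator would not obey
its own documented slope. Departure is floored at moult end + 0.5 d
(rare, counted).

The default slope \(\beta = -0.017\)/d is a one-time calibration: the
analytic value for an exact earliest/latest-decile ratio of 2.0
(−0.0147 at the default variance structure) leaves realized ratios
straddling 2.0, which cannot simultaneously satisfy "more than twice as
long" and "about half the time"; −0.017 puts the expected fitted ratio
near 2.15 (latest ≈ 46% of the earliest), satisfying both robustly.

**What the generator does not emulate** — and hence what a green test
does not establish: adult males and their summer moult; tag loss and
mis-reads; permanent emigration or movement between colonies; mid-season
at-sea trips; age trends within categories; observer effort varying
within a season; non-logistic moult trajectories. Real-data analyses
should treat the generator-based validation as necessary, not sufficient.

# Numerical choices and degenerate inputs

* Time is continuous day-of-year; observation dates are integers; cycles
  never span a year boundary (the moult season is interior to the year).
* Truncated-Normal draws use rejection sampling; rejected draws are
  counted and reported (`attr(truth, "redraws")`).
* Cycles whose scores are all identical abort the fit with
  `degenerate_cycle`; fewer than two cycles is an error.
* `filter_cycles` criteria are strict inequalities; the CI-width cut for
  the haul-out subset is strict (< 6 d), so a width of exactly 6 d drops.
* Ties in peak synchrony resolve to the earliest day.
* The duplicate-observer simulation applies observer noise but not the
  0↔100 flip process by default: flip errors are validated separately as
  a rate at the extremes, and the printed R² is only attainable without
  them (1220 pairs with ~2% flips at 100-point magnitude would cap R²
  near 0.92).
* Posterior-predictive closeness of a fitted curve to its observations is
  checked with a 2·score_sd band (≈95% of observational noise); a
  1·score_sd band covers only ~68% of mid-curve scores and would fail by
  construction for any well-observed cycle.

# Known limitations

* The sampler is single-chain-sequential random-walk MH; very sparse
  cycles mix slowly (ESS below the 200 gate at default test draw counts
  triggers the warning rather than failing the run). Increase `iter` for
  production runs.
* With few years, year-level hyper-sds are prior-dominated; year effects
  and the `_with_year` population mean should be read accordingly.
* The arrival/departure model assumes constant within-season detection
  per boundary; covariate-dependent detection is out of scope.
* Gamma GLMMs on deterministic (noise-free) metrics are degenerate
  (residual → 0); comparisons should be run on estimated, not latent,
  metrics.
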