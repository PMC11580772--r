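---
title: "Testing whether first interactions predict long-term cooperative relationships"
author: "bondtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing whether first interactions predict long-term cooperative relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When two unfamiliar group-living animals meet for the first time, does the
way they interact predict whether they will go on to form a long-term
cooperative relationship? In female vampire bats, cooperative relationships
are expressed as allogrooming and regurgitated food sharing, and new
relationships can be created experimentally by introducing strangers from
distant capture sites. `bondtrace` implements the statistical machinery for
two complementary designs:

* **Small-cage introductions.** Strangers are co-housed in cages of 2 or 4
  bats, the first hours of affiliative and aggressive interactions are
  scored from video, and cooperation is measured months later as seconds of
  behaviour out of possible observation seconds.
* **Flight-cage introductions with proximity sensors.** Tagged bats from
  several capture sites are released together; pair-wise sensor pings over
  the first 24 h are segmented into encounters and thresholded into
  contacts, and long-term allogrooming is observed as overdispersed counts.

Both designs pose the same inferential problem: dyadic observations are not
independent (every dyad is the joint property of two individuals, and only
some dyads could ever interact), so off-the-shelf regression p-values are
not trustworthy. The package answers with two tools: a *cage-constrained
permutation test* for the small-cage design, and a *Bayesian
negative-binomial multi-membership model* for the sensor design.

## Study-1 machinery: aggregated binomial GLM with a constrained null

Long-term cooperation for a directed dyad is an aggregated binomial: $s$
seconds with the behaviour out of $n$ possible seconds. The model is

$$\mathrm{logit}\,\Pr(\text{behaviour per second}) = \alpha + \beta z,$$

where $z$ is the z-scored seconds of first interactions (affiliative or
aggressive) for that dyad. `fitAggBinomGLM()` returns the
maximum-likelihood $\beta$; a brute-force likelihood-grid oracle in the
test suite confirms the optimum to $10^{-3}$.

Because only cagemates could interact — and each introduced bat had 1–3
potential receivers — the reference distribution for $\beta$ comes from a
null model that respects the cage structure. `permuteWithinCages()`
redraws each event's receiver uniformly among the actor's cagemates,
holding the actor, behaviour class, onset and duration fixed; per-actor
totals are conserved exactly and no event crosses a cage.
`permutationTest()` re-fits the GLM on each permuted dataset (the
predictor is re-standardized within every permuted dataset, since the
permutation changes its distribution) and reports the one-tailed
Monte-Carlo p-value with the add-one convention $p = (1+b)/(1+m)$, which
guarantees $p > 0$ and is standard for Monte-Carlo tests. Upper tail for
affiliative predictors, lower for aggressive, matching the directional
predictions. Non-converged permuted fits (typically separation artifacts)
are dropped from the null and counted, rather than contaminating it.

Two design choices were genuinely open:

* **The exchangeable unit.** Redirecting individual events is the default
  because the null hypothesis is about bats directing *behaviours* at
  random; shuffling dyad totals within cages is available via
  `permUnit = "totals"` as a sensitivity variant. The two agree in location
  and scale on synthetic data.
* **Multiplicity.** The four behaviour-by-response tests are reported
  without adjustment, matching the presentation style of the analysis the
  package reproduces.

Incidence statistics use exact binomial (Clopper–Pearson) intervals
(`incidenceCI()`, via beta quantiles), with reporting rounded to a whole
percent at or above 10% and one decimal below. Mean event durations get a
seeded percentile bootstrap (`meanDurationCI()`).

## Study-2 machinery: contacts and the multi-membership model

`segmentEncounters()` groups a pair's pings into encounters wherever the
inter-ping gap is at most `maxGapS` (default 60 s; ping interval 2 s).
Encounter duration is last ping minus first ping, floored at one ping
interval for singletons. A *contact* is an encounter whose maximum RSSI is
at or above the dataset-wide empirical quantile (`callContacts()`, default
top 5%, close contacts top 1%); ties at the threshold are kept, and the
threshold is computed over all encounters pooled, not per pair.
`firstContactDurations()` accumulates contact minutes per unordered pair
over half-open cumulative windows of 4–24 h; a boundary-straddling
encounter contributes only its intersection. Network density and weighted
categorical assortativity by capture site (`networkMetrics()`) use the
standard mixing-matrix formula with edge weights as multiplicities; the
unweighted case is verified against igraph in the tests. Note that under
random edge placement the expected assortativity is slightly negative in
small groups (within-site pairs number $n(n-1)/2$, not $n^2/2$); the null
simulation in the tests uses groups large enough for this bias to be
negligible.

Long-term allogrooming counts are modelled as

$$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi), \qquad
\log \mu_{ij} = \log(\text{possible minutes}) + \mathbf{x}_{ij}^\top
\boldsymbol\beta + u_i + u_j, \qquad u \sim \mathcal N(0, \sigma^2_{bat}),$$

with fixed effects for standardized first-contact minutes, forced
proximity, pre/post period, and their interaction — the interaction being
the causal reference effect of one week of forced co-housing. Percent
change per SD of contact is $100(e^\beta - 1)$ (`percentChange()`).
Priors are weakly informative: Normal(0, 2.5) on standardized slopes,
Normal(0, 5) on the intercept, half-Student-t(3, 2.5) on $\sigma_{bat}$
and half-t(3, 1) on $1/\sqrt\phi$; all are arguments of
`fitNBMultiMembership()`.

Sampling uses Gibbs/slice MCMC (JAGS) with a *hierarchically centred*
parameterization: the per-bat effects are drawn around half the intercept,
$v_b \sim \mathcal N(\alpha/2, \sigma^2_{bat})$, because every dyad loads
exactly two of them. The non-centred form leaves the intercept and the
random-effect mean additively confounded and mixes an order of magnitude
worse; reported quantities are the identified ones ($\alpha = 2h$,
$u_b = v_b - h$). Convergence is gated: the fit errors if any split-$\hat R$
exceeds `rhatMax` (default 1.05; reduced-scale test runs relax it).
Defaults are 3 chains; the original analysis style (6 chains, long runs)
is available through the arguments and `pipelineConfig(paperScale = TRUE)`.

Model-level choices:

* `x_contact` is standardized over **unfamiliar dyads only**, because the
  grooming models are fitted to unfamiliar pairs.
* Each dyad contributes **two rows** (pre/post treatment period), which is
  what makes the forced-proximity-by-period interaction estimable; a
  pre-treatment-only analysis simply drops the treatment terms from
  `terms` (the "first weeks" post hoc variant).
* The grooming response is the undirected pair total.

Variance explained uses the draw-wise Bayesian $R^2$:
$R^2_d = \mathrm{Var}_k(\mu_{dk}) / (\mathrm{Var}_k(\mu_{dk}) +
\overline{\mu_{dk} + \mu_{dk}^2/\phi_d})$, with the residual variance from
the NB mean–variance relation (`bayesR2()`, hand-oracle tested). The share
of variance attributed to first contacts is the draw-wise difference
between the full model's $R^2$ and that of the model without the contact
term (`r2Partition()`); negative differences are reported as-is, as honest
propagation of posterior uncertainty.

## The synthetic-data generators

`genStudy1()` and `genStudy2()` generate datasets under known parameters
and return a ground-truth ledger (exact per-dyad event seconds, realized
encounter spans, per-row NB means, planted coefficients, per-bat effects),
so every pipeline stage is testable by exact bookkeeping and every fitter
by parameter recovery. Defaults emulate the study conditions: 18 cages of
2 or 4 bats with a 6-h scoring horizon; affiliative events an order of
magnitude more common and longer than aggressive ones (log-normal
durations with mean 252 s; aggressive durations capped near 25 s);
long-term possible minutes spanning roughly 540–1860 per dyad over a
~10-month span; 20 tagged bats from 3 sites (190 pairs, 133 unfamiliar);
forced-proximity trios drawn one bat per site so treated pairs cross
sites; and a planted treatment interaction of $\log(3.38)$ (a 238% rate
increase).

Where the emulated study reports no generative detail, the defaults are
conventions chosen once: dyad-level logit noise SD 0.5; exponential
encounter durations with mean 120 s; encounter max RSSI drawn from a
familiarity-independent Normal(−60, 6) with per-ping noise SD 4, so that
RSSI thresholding acts as a pure measurement filter while familiarity
drives encounter *frequency* (0.5 vs 0.25 encounters per pair-hour);
timestamps are seconds since introduction. Generated encounters closer
than 60 s are merged before pings are emitted, so segmentation at the
default gap reconstructs the ledger exactly — by construction, not by
luck.

What the generators deliberately do **not** emulate: pup presence, deaths
mid-study, the gap between sensor deployment and observation onset,
radio-propagation physics (RSSI does not depend on familiarity or
distance dynamics), and observer error in event scoring. Passing
parameter-recovery tests therefore shows the estimators are correct under
the stated model, not that the model captures every feature of field
data.

## Numerical choices and problem sizes

* Exact binomial intervals come from beta quantiles; the boundary cases
  $k = 0$ and $k = n$ pin the corresponding endpoint at 0 or 1.
* Quantile thresholds use the default (type-7) empirical quantile;
  `callContacts()` keeps ties at the threshold.
* Events straddling the 6-h scoring horizon are truncated at the horizon.
* Degenerate designs error early (zero-variance predictor, rank-deficient
  fixed effects, non-positive exposure); complete separation in the GLM is
  flagged rather than silently reported.
* Test and pipeline defaults are reduced-scale — 500 permutations, 2
  chains of 700–1200 retained iterations, 40-replicate recovery loops,
  calibration over 200 synthetic datasets — sizes chosen so the whole
  suite runs on a laptop-class single core in minutes while keeping
  Monte-Carlo error well inside the asserted bounds. The analysis-scale
  settings (5000 permutations, 6 chains) sit behind
  `pipelineConfig(paperScale = TRUE)` and the MCMC arguments.

## Known limitations

* The permutation null conditions on each actor's event stream; it does
  not model actor-level covariances between behaviour classes.
* The multi-membership model assumes exchangeable per-bat intercepts and
  no spatial or temporal autocorrelation; directed actor–receiver
  decompositions are out of scope (not identifiable in the small-cage
  design).
* Replicating the original coefficient estimates from the deposited field
  data is expected to be close but not bit-identical, because the original
  fits used a different sampler's default priors, which are not fully
  recoverable; `replicateStudy2()` runs the pipeline on deposit-derived
  CSVs when they are available locally.
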