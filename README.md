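# bondtrace

Do first impressions matter? When unfamiliar group-living animals — here,
female vampire bats — meet for the first time, does the way they interact
predict whether they will form a long-term cooperative relationship
(allogrooming, food sharing)? `bondtrace` implements the statistical
machinery to answer that question from two kinds of introduction
experiments, together with a synthetic-data generator so every stage can be
validated by parameter recovery without field data.

The package is aimed at behavioural ecologists and biostatisticians working
with dyadic social data, where observations are interdependent (every dyad
belongs to two individuals) and the sampling design constrains who could
ever interact.

## What it computes

**Small-cage introductions (scored video).** Long-term cooperation of a
directed dyad is an aggregated binomial — *s* seconds of behaviour out of
*n* possible seconds — modelled as

    logit Pr(behaviour/second) = α + β·z,

with *z* the z-scored seconds of first interactions. Because bats could
only interact with their 1–3 cagemates, inference on β uses a
cage-constrained permutation null: each event's receiver is redrawn
uniformly among the actor's cagemates (actor, behaviour, onset, duration
fixed), the model is re-fitted per permutation, and one-tailed Monte-Carlo
p-values use p = (1+b)/(1+m). Incidence proportions carry exact
(Clopper–Pearson) binomial intervals; mean durations carry percentile
bootstrap intervals.

**Flight-cage introductions (proximity sensors).** Pair-wise ping streams
are segmented into encounters (gap ≤ 60 s), thresholded into *contacts*
(encounter max RSSI in the dataset-wide top 5%; top 1% for close contacts),
and accumulated into per-pair first-contact minutes over 4–24-h windows,
with contact-network density and weighted categorical assortativity by
capture site. Long-term allogrooming counts are modelled with a Bayesian
negative-binomial multi-membership regression,

    y_ij ~ NB(μ_ij, φ),   log μ_ij = log(possible minutes) + Xβ + u_i + u_j,

where each dyad loads the random intercepts of both members. Effects are
summarized as percent change per SD, 100(exp(β) − 1), and variance
explained as draw-wise Bayesian R² with the share attributable to first
contacts obtained by differencing full and reduced models
(`r2Partition()`). Sampling is MCMC via JAGS with a hierarchically centred
parameterization and a hard convergence gate on split-R̂.

See `vignettes/methods.Rmd` for the models, priors, design decisions and
limitations, and what the synthetic generators do and do not emulate.

## Worked example

```r
library(bondtrace)

## exact binomial incidence interval: 30 of 35 introduced pairs affiliated
ci <- incidenceCI(30, 35)
cat(sprintf("%s%% [%s%%, %s%%]\n", ci$percent[1], ci$percent[2], ci$percent[3]))
#> 86% [70%, 95%]

## small-cage study with a planted effect of first interactions
d1 <- genStudy1(study1Config(seed = 11, effectAffiliative = 1))
permutationTest(d1$events, d1$cages, d1$longterm,
                behavior = "affiliative", response = "grooming",
                nPerm = 1000, seed = 1)
#> Cage-constrained permutation test
#>   observed slope (logit, standardized x): 1.0464
#>   null 95% quantiles: [0.2012, 0.8386]
#>   one-tailed p (upper tail): 0.000999  (n_perm = 1000, dropped = 0)

## sensor study: contacts, network, and the grooming model
d2 <- genStudy2(study2Config(seed = 11, betaContact = log(1.32)))
enc <- segmentEncounters(d2$pings)
dur <- firstContactDurations(callContacts(enc, 0.95), d2$bats)
m <- networkMetrics(contactNetwork(dur, d2$bats, 24))
cat(sprintf("24-h contact network: density %.2f, site assortativity %.2f\n",
            m$density, m$assortativity))
#> 24-h contact network: density 0.34, site assortativity 0.19

unf <- d2$grooming[d2$grooming$unfamiliar == 1, ]
fit <- fitNBMultiMembership(unf, nChains = 2, nIter = 1200,
                            rhatMax = 1.2, seed = 2)
pc <- percentChange(posteriorDraws(fit, "x_contact")[, 1])
cat(sprintf("contact effect: %+.0f%% per SD [%.0f%%, %.0f%%]\n",
            pc$median, pc$lower, pc$upper))
#> contact effect: +33% per SD [18%, 51%]
```

The observed slope of 1.05 recovers the planted effect of 1.0 and falls
outside the permutation null's 95% quantiles; the note that the null
quantiles sit above zero is expected — permutations inside 2-bat cages are
identities, so the constrained null retains part of a real signal, which is
exactly why the constrained test, not a naive one, is needed. The +33% per
SD contact effect recovers the planted `log(1.32)` (i.e. +32%).

A full synthetic run — generation, all four permutation tests, contact
networks, grooming model, R² partition, manifest — is one call:

```r
runPipeline(pipelineConfig(seed = 1, outDir = "run1"))
```

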