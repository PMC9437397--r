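---
title: "Statistical design of school eye-health cluster surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical design of school eye-health cluster surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sehra)
```

## The estimand and the design

A school eye-health rapid assessment estimates one number per region:
the proportion of school-age children who need eye-care services, the
sum of all-cause vision impairment (presenting acuity below 6/12 in the
better eye) and non-vision-impairing conditions needing care. Because a
simple random sample of children across a region is logistically
impossible, the design is a two-stage cluster survey:

1. **Schools** (the primary sampling units) are drawn from an
   enrollment frame with probability proportionate to size, by the
   cumulative-total systematic method: enrollments are cumulated in
   frame order, the interval is $I = N/k$, a start is drawn uniformly
   on $[0, I)$, and the schools containing the $k$ equally spaced
   points are selected. A school larger than the interval can be hit
   more than once and then fields several clusters.
2. **Children** are drawn within each selected school with a fixed
   quota $m$ (one cluster, default 100 — the number one team can
   examine in a day), by simple random sampling from the roster, spread
   equally across year groups when a year-group breakdown is available.

The fixed quota makes the design *self-weighting*: a child in school
$s$ is included with probability $(k e_s / N)(m / e_s) = k m / N$,
independent of school size, provided $m \le e_s \le I$. Analysis can
therefore use unweighted cluster summaries.

## The sample-size model

For prevalence $P$, confidence multiplier $Z$ and absolute half-width
$d$, the simple-random-sample size is $n = Z^2 P (1-P) / d^2$. Rapid
assessments state precision in relative terms, $d = rP$, so that every
region is estimated to the same *proportional* accuracy; substituting
gives $n = Z^2 (1-P) / (r^2 P)$, which **decreases** in $P$ — rare
conditions are the expensive ones. The chain applied by
`sample_size()` is then

$$n_{\text{final}} = \left\lceil n \cdot \text{DEFF} \cdot (1 + a)
\right\rceil, \qquad k = \lceil n_{\text{final}} / m \rceil,$$

with $a$ the anticipated non-participation and absenteeism fraction.

Parameter defaults, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `z` | 1.96 | two-sided multiplier for alpha = 0.05 |
| `rel_precision` | 0.20 | CI half-width as a fraction of $P$ |
| `deff` | 2.0 | variance inflation from clustering at $m = 100$ |
| `nonresponse_rate` | 0.20 | children selected but not examined |
| `cluster_size` | 100 | examinations per school-day |

Two conventions deserve note, both deliberate:

* **Non-response inflation is multiplicative**, $n(1+a)$, not the
  divisor form $n/(1-a)$. The multiplicative form is what reproduces
  the published regional sizes (e.g. 1126 children at $P = 17\%$);
  the divisor form would give systematically larger values.
* **Ceiling rounding** for children and clusters — the conservative
  convention for sample sizes, and the reason the achieved precision
  reported by `sample_size()` is always at or slightly below the
  requested one.

The quoted "80% power" of the planning context has no term in a
precision-based calculation; it is treated as metadata and never enters
the arithmetic.

### Scenario fixture and known discrepancies

The packaged fixture stores the regional prevalence scenarios as
printed, rounded to 0.1%. The published sample sizes were computed from
unrounded inputs, so `reproduce_tables()` recovers 1126 ($P=17.0\%$)
exactly, 990 vs 988 ($P=18.9\%$, +0.2%) and 5680 vs 5675 ($P=3.9\%$,
+0.09%), while 10 777 is *flagged*: it implies an input prevalence near
2.09%, not the stored 2.0% (the recomputed value is 11 295, ~4.8% off).
The report carries the relative discrepancy and the implied input
prevalence rather than silently asserting agreement.

```{r}
reproduce_tables()
```

## The inverse problem

When fewer schools can be visited than the calculator asks for,
`achievable_precision()` inverts the chain:
$r = Z\sqrt{\text{DEFF}(1+a)(1-P)/(nP)}$. Precision degrades as
$1/\sqrt{n}$; the round-trip property
`achievable_precision(sample_size(p)$n_final, p) <= 0.20` holds for
every scenario and is enforced in the test suite.

## Estimation

The analysis-stage estimator is a declared convention of this package
(field practice varies and no single form is mandated by the design):
the unweighted mean of cluster proportions, with the between-cluster
("ultimate cluster") standard error
$\mathrm{sd}(\hat p_1, \dots, \hat p_c)/\sqrt{c}$ and a Student-$t$
quantile on $c-1$ degrees of freedom, truncated to $[0,1]$. The
unweighted mean is justified by the self-weighting property; when
shortfall schools or absenteeism make cluster sizes unequal,
`weights = "examined"` switches to the pooled ratio estimator with its
linearised variance. The $t$ quantile matters in the realistic
few-cluster regime — at $c = 2$ it produces intervals so wide (achieved
relative precision above 6) that the output itself signals an
unusable survey. `quantile = "normal"` is available for comparisons
against the sizing formula, which uses $Z$.

The empirical design effect of a completed survey is
$\widehat{\text{DEFF}} = se^2 / (\hat p (1 - \hat p)/n)$, the realised
variance relative to what simple random sampling of the same $n$ would
have given.

## The synthetic-population generator

`generate_population()` uses the beta-binomial construction: school
latent prevalences $\pi_s \sim \mathrm{Beta}(\alpha, \beta)$ with
$\alpha = p(1-\rho)/\rho$, $\beta = (1-p)(1-\rho)/\rho$, children
independent Bernoulli($\pi_s$). This gives $E[\pi_s] = p$,
$\mathrm{Var}[\pi_s] = p(1-p)\rho$, and pairwise within-school
correlation exactly $\rho$, hence the equal-cluster-size identity
$\text{DEFF} = 1 + (m-1)\rho$ — the calibration point $\rho = 1/99$
yields DEFF 2.0 at $m = 100$, matching the default design effect. A
logit-normal school-effect model would be an alternative mechanism but
lacks these closed-form moments and is not implemented.

The default enrollment law is lognormal with mean ≈ 500 pupils and
`sdlog = 0.8` (broad dispersion), truncated below at 20, chosen so that
realistic frames exhibit both edge cases the design must handle: very
large schools selected more than once, and schools too small to fill a
cluster (enumerated completely, with the shortfall recorded and
surfaced rather than merged with a neighbour — merging rules would
invent structure the field protocol does not prescribe).

What the generator does *not* emulate: spatial correlation between
nearby schools, school-level refusal (non-response is independent
child-level Bernoulli thinning of the pooled rate), enrollment-frame
errors, and within-school age structure. Passing validation therefore
shows the estimator and the sizing chain are internally coherent under
the stated stochastic model, not that any particular field survey will
achieve nominal coverage.

## Monte-Carlo validation

`monte_carlo_validate()` repeats population generation, survey
simulation and estimation, and reports bias, coverage against the
superpopulation prevalence (not each replicate's realised finite
prevalence — the two differ in small populations), the across-replicate
variance-ratio design effect, and mean achieved relative precision.
Problem sizes used by the package's own validation runs: 1000–2000
replicates of 30-cluster surveys on 40 schools of 250 pupils for the
design-effect and coverage checks (Monte-Carlo error on the variance
ratio ≈ 3–5%), and 500–800 replicates of calculator-sized 12-cluster
surveys with 20% non-response for the precision guarantee. The
precision guarantee holds when the population's true design effect does
not exceed the assumed 2.0; with a larger true ICC the realised
intervals widen beyond the target — the documented caution that
confidence is lower where fewer, more heterogeneous schools are
surveyed.

## Numerical and degenerate-input choices

* Prevalence inputs are accepted at full precision as proportions in
  $(0,1)$; the CLI accepts percent only behind an explicit `--percent`
  flag, never guessing from magnitude.
* Year-group quotas use largest-remainder apportionment of the equal
  split, ties broken in roster order, capped at group size with the
  excess redistributed equally over groups with spare capacity.
* Zero-enrollment schools are retained in the frame (row numbers match
  the source) but have empty spans and can never be selected.
* Single-cluster surveys return a point estimate with the standard
  error flagged `NA` rather than erroring: the field case exists.
* All randomness flows through one seed per invocation, recorded in
  outputs; identical seeds reproduce allocations, rosters and
  estimates byte for byte.

## Limitations

Sample sizes from this calculator target the *overall* service-need
prevalence; condition-specific estimates (e.g. myopia alone) from the
same survey will have much wider intervals, and the calculator is not
intended for epidemiological studies of specific eye diseases. No
finite-population correction is applied, and no stratified (age-group)
allocation is performed.
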