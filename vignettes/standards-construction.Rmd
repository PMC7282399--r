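---
title: "Constructing prescriptive neurodevelopmental standards with ndastandards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing prescriptive neurodevelopmental standards with ndastandards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndastandards)
```

## The problem

Most tools that measure early-childhood neurodevelopment ship *references*:
descriptions of how a particular population, at a particular time, happened
to develop. A *standard* instead prescribes how healthy children should
develop, and is built the way the WHO child-growth standards were built —
by first selecting an optimally healthy, well-nourished, low-risk normative
cohort and only then estimating centiles. `ndastandards` implements that
workflow for the INTER-NDA, a 37-item assessment of cognition, fine and
gross motor skills, language and behaviour in children aged 22–30 months,
together with the validation analyses that justify pooling a multi-site
cohort into a single international normative sample.

## Scoring model

Each item is an ordinal rating on a k-point scale (k = 3 or 5; the default
map has 30 five-point and 6 three-point items, with the one item of
unstated scale treated as five-point). Because raw domain means mix 3- and
5-point items on incompatible supports, every answered item is min-max
normalised to $[0,1]$,

$$u_{j} = \frac{s_{j} - 1}{k_{j} - 1},$$

and a domain's standardised scaled score is $100 \times \bar u$ over the
*answered* items of that domain. This reproduces the $[0,100]$ support of
the published tables (including exact 0 and 100 at the floor and ceiling)
and makes a 3-point and a 5-point item contribute on the same footing. The
exact published scaling formula lives in supplementary material we do not
reproduce; per-item min-max averaging is this package's own documented
choice and should be revisited against that supplement if item-level
compatibility matters for a given application.

Missing responses are prorated (the mean runs over answered items only)
rather than zero-filled: with item-level missingness typically below 2%,
proration avoids penalising a domain for an unanswered item.
`flag_completeness()` marks records whose per-domain answered fraction
falls below a threshold (default 0.8, inclusive at the boundary).

Ordinal scores are encoded 1..k. Raising any single response can only
raise (never lower) the domain score, scores are invariant to item order,
and a record scoring the midpoint of every item scores exactly 50 under
any 3/5-point mix — all property-tested.

## The exclusion cascade

`apply_cascade()` screens a cohort against an ordered rule set:

| rule | default parameter |
|---|---|
| `PRETERM` | gestational age < 37.0 weeks (37+0 retained) |
| `POSTNATAL_NEURO_MORBIDITY` | precomputed boolean flag |
| `MATERNAL_MENTAL_HEALTH` | precomputed boolean flag |
| `INCOMPLETE_ASSESSMENT` | incomplete flag, or both CBCL subscales missing |
| `OUT_OF_AGE_WINDOW` | assessment age outside \[22, 30\] months (inclusive) |
| `CBCL_CLINICAL_RANGE` | either CBCL subscale centile strictly > 97 |

Each excluded child is attributed to the *first* matching rule, mirroring
flow-diagram accounting; the retained set itself is provably independent
of rule order (asserted by test), and the audit satisfies
`n_input = n_retained + sum(per-rule counts)` by construction. Gestational
age is stored as decimal weeks; `ga_weeks("36+6")` parses weeks+days as
`36 + 6/7`. Operationalising "significant morbidity" from raw morbidity
lists is out of scope — the cascade consumes a boolean.

`participant_flow_fixture()` ships a deterministic 1339-child cohort reproducing
the published participant flow (54 preterm, 130 pre-eligibility exclusions
in total, 28 CBCL exclusions among 1209 eligible, 1181 retained). Two
details of that flow are package conventions because the published account
does not determine them: the 40/36 split of the non-preterm pre-eligibility
exclusions, and the site split of the 28 CBCL exclusions. Note also that
the published per-site contributions (147, 305, 296, 301, 160) sum to
1209 — they describe the eligible sample, and the fixture plants them at
that stage.

## Harrell–Davis centiles

Scaled-score distributions show strong skewness and kurtosis, ceiling
plateaus at 100, and no transformation that normalises all domains at
once; smoothing-based centile methods (LMS/GAMLSS) are therefore not used.
Instead the q-th centile is estimated distribution-free as a weighted
average of all order statistics,

$$\hat Q(q) = \sum_{i=1}^{n} w_i\, X_{(i)}, \qquad
w_i = I_{i/n}(a, b) - I_{(i-1)/n}(a, b),$$

with $a = (n+1)q$, $b = (n+1)(1-q)$ and $I_x$ the regularized incomplete
beta function (the Beta CDF). We use the canonical $(n+1)$
parameterisation and full-sample weights (no truncated variant). The
incomplete beta is evaluated with the library special function; weights
sum to 1 within $10^{-12}$, and the whole weight computation is verified
against an independent numerical-integration oracle of the Beta density to
$10^{-8}$ for $n \le 50$ across seven centiles. Tiny negative rounding
residues in the CDF differences are clamped to zero.

Pooling follows the variance-share argument below: one pooled sample per
domain, equal weight per child, no site weighting. The centile set is
configurable because published text and tables use slightly different
sets; the packaged chart uses the table's set
(3, 10, 25, 50, 75, 90, 97). Confidence intervals for centiles are not
provided. Domains with fewer than 20 observations are still estimated but
flagged low-confidence.

Sex comparisons use the two-sided Wilcoxon rank-sum test: exact
enumeration when both groups have at most 10 observations and no ties,
otherwise the normal approximation with mid-rank tie correction and
continuity correction. When every pooled value is tied the rank-sum
variance is zero and the comparison carries no evidence of a shift; the
p-value is reported as 1.

## Thresholds and screening zones

For every domain except negative behaviour, higher scores are better and
the normality threshold is the 10th centile (`score >= c10`, inclusive);
for negative behaviour, lower is better and the threshold is the 90th
(`score <= c90`). The three-zone chart follows: monitor is the band
between the 3rd and 10th centiles (mirrored to the 90th–97th band for
negative behaviour) and urgent lies strictly beyond the 3rd (97th)
centile. The boundary conventions are: the normality threshold is
inclusive, and the extreme boundary value itself belongs to monitor —
urgent requires strictly `< c3` (or `> c97`). The mirrored rule for
lower-is-better domains is an inference from the positive-domain rule;
the published description covers only the positive direction. Where
boundaries coincide (the published negative-behaviour row has
c3 = c10 = 0) the monitor band is empty and classification remains total:
every score in $[0,100]$ maps to exactly one zone, property-tested on
random charts including ties.

The packaged chart (`published_standards()`) encodes the published table
exactly as printed, including the 100.0 plateaus, as a JSON fixture.

## Cohort-normality checks

**Between-site variance.** A one-way random-effects decomposition by ANOVA
method of moments: $\hat\sigma^2_w$ is the pooled within-site mean square
and $\hat\sigma^2_b = \max\{0, (MS_b - MS_w)/n_0\}$ with the standard
unbalanced-design effective group size
$n_0 = (N - \sum_j n_j^2/N)/(k-1)$. The published account reports a
variance-share argument without naming its estimator; method of moments is
this package's choice (negative estimates truncated at zero). The share
$\sigma^2_b/(\sigma^2_b+\sigma^2_w)$ is scale-invariant and, on balanced
designs, the two components approximately partition the total variance.
Sites with fewer than two children are dropped with a warning. No attempt
is made to reproduce the published post-hoc power value (0.84): the test
statistic and group configuration behind it are not stated.

**Vision.** Visual acuity (logMAR) and contrast sensitivity (contrast %)
are both lower-is-better, so `vision_centile_check()` mirrors the centile
*labels*: the value reported at the 90th centile is the 10th quantile of
the raw values, reproducing the decreasing column pattern of a
vision-centile table. The normative ranges shipped in
`inst/extdata/normative_ranges.json` are clearly-labelled editable
placeholders (the Cardiff tests' exact published norms are not
redistributed here); the in-norm verdict compares the estimated median
against whatever range is configured.

**Milestones.** `milestone_window_check()` reports, per WHO gross-motor
milestone, the fraction of reported children achieving it inside the
published window of achievement (inclusive bounds); "never observed"
counts outside, missing reports leave the denominator.

## The synthetic-cohort generator

`generate_cohort()` draws cohorts from a latent-ability threshold model:
for child $c$ and item $j$ of domain $d$,

$$u_{cj} = \mu_d + b_{s(c),d} + \delta_d\,\mathbb{1}[\text{female}]
          + e_{cd} + \varepsilon_{cj},$$

binned by the item's cut-points into an ordinal response. The latent
Gaussian with asymmetric thresholds is the simplest generator producing
the skewness, kurtosis and ceiling effects the real scaled scores show;
thresholds are configuration, so degenerate and symmetric designs are easy
to construct (a zero-variance midpoint configuration scores exactly 50
everywhere, used as a test anchor). Site effects $b_{s,d}$ are drawn once
per site per domain — the same random-intercept structure the
variance-components model assumes.

Defaults define the study conditions and are not tuned per analysis: five
sites of 300 children (a ~1500-child multi-country cohort), 52% girls,
child-effect SD 1, item-noise SD 0.8, site-effect SD targeting a 5%
between-site share of latent variance, small positive cognitive/language
shifts (0.1 SD) for girls and a small positive negative-behaviour shift
for boys, assessment age 24.8 (SD 1.6) months truncated to \[22, 30\] with
0.5% planted outside, and planted exclusion rates of 3.1% preterm, 3.0%
morbidity, 2.7% maternal mental health, 2.1% CBCL clinical range, 0.5%
incomplete. Vision and milestone data are drawn from discrete/truncated
distributions whose medians sit at 0.2 logMAR and 1.5% contrast and inside
the milestone windows.

Ground truth comes from `true_quantile()`: a Monte-Carlo oracle (default
$10^6$ draws; cohorts attach ground truth at a configurable
`gt_draws`, default $2\times10^5$) running the same generative formula
under a fixed oracle seed independent of cohort seeds, conditioning on the
realized site effects of the cohort it describes. For the planted
between-share fixture, `simulate_site_scores()` rescales the drawn site
intercepts to an exact sample variance: with only five sites, the sampling
SD of a random-intercept draw's realized share is far larger than the
recovery tolerance of interest, so an exact-variance plant is the only way
a few-site fixture can carry a known share. The default cohort generator
keeps genuinely random intercepts.

What the generator does *not* emulate: real item content and its
psychometric covariance with other instruments, item-level
dependence beyond the shared domain latent, site-by-sex interactions, and
informative missingness. Passing recovery tests therefore demonstrates
that the estimation pipeline is correct under the assumed random-intercept
threshold model, not that real data satisfy that model.

## Numerical choices and test scale

Weights: `pbeta` differences, tolerance $10^{-12}$ on normalisation,
negative residues clamped. Quantile recovery tests run on 5×500 cohorts
and compare Harrell-Davis estimates against the oracle within a band of
$\pm 3\sqrt{q(1-q)/n}$ in probability (converted to score units through
the oracle's quantile function) plus one item-level score increment
($100/(4m_d)$ for a domain with $m_d$ items) to absorb the lattice nature
of scaled scores. The ground-truth oracle uses $2\times10^5$ draws in
tests, which keeps its own error an order of magnitude below that band.
Tie-breaks: thresholds inclusive as documented above; `findInterval`
assigns a latent value equal to a cut-point to the lower bin.

## Limitations

- The default 37-item domain allocation is a convention (only the 30/6
  scale totals are fixed by the instrument description); supply your own
  map for real data.
- The scaled-score formula is this package's reconstruction; see above.
- Centile uncertainty is not quantified.
- The cascade consumes precomputed morbidity and CBCL inputs; it does not
  score the CBCL (proprietary norms) nor adjudicate morbidity.
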