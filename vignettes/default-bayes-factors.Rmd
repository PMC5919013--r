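---
title: "Quantifying evidence for the absence of a treatment effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying evidence for the absence of a treatment effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfnull)
library(dplyr)
```

## The problem

A clinical trial that fails to reject the null hypothesis has not thereby
demonstrated that the treatment effect is absent. The p-value of a
nonsignificant comparison of proportions says only that the data were not
surprising enough under the null to reject it; it does not measure how
strongly the data *support* the null. Two trials with nearly identical
nonsignificant p-values can differ enormously in how much they actually
tell us — a 33-patient trial leaves the question essentially open, while a
10,000-patient trial with the same p-value can make the absence of an
effect quite compelling.

bfnull quantifies that distinction with a default Bayesian hypothesis test
for m × k contingency tables (rows are treatment arms, columns are outcome
categories) and scales it from one table to whole corpora of published
null results.

## The model

Each arm i has a fixed size $n_i$ (set by design) and its outcome counts
$y_{i1}, \dots, y_{ic}$ are multinomial with probability vector
$\theta_i$. The two hypotheses are:

* $\mathcal{H}_0$ (no association): all arms share one probability vector
  $\theta$, with a symmetric Dirichlet($a$) prior.
* $\mathcal{H}_1$ (association): each arm has its own $\theta_i$, with
  independent symmetric Dirichlet($a$) priors.

With $a = 1$ (the default) the priors are uniform — no combination of
proportions is favored a priori. For a 2 × 2 table this is exactly
two independent uniform priors on the two event rates under
$\mathcal{H}_1$, and one shared uniform rate under $\mathcal{H}_0$.

Both marginal likelihoods are available in closed form. Under
$\mathcal{H}_0$,

$$m_0 = \prod_i \binom{n_i}{y_{i1}\cdots y_{ic}}
  \cdot \frac{\Gamma(ca)}{\Gamma(a)^c}
  \cdot \frac{\prod_j \Gamma(y_{+j} + a)}{\Gamma(N + ca)},$$

and under $\mathcal{H}_1$ the same Dirichlet–multinomial form applies per
row and the results multiply. The Bayes factor in favor of the null is
$\mathrm{BF}_{01} = m_0 / m_1$; multiplying it by prior odds gives
posterior odds (`posterior_odds()`). All evaluation is in natural-log
space via `lgamma()`, so tables with millions of observations are handled
without overflow; raw factorials are never formed.

```{r worked}
jolly <- contingency_2x2(347, 4686, 351, 4679)   # 10,063 patients
carrier <- contingency_2x2(5, 14, 4, 10)         # 33 patients
tidy(bf01(jolly))
tidy(bf01(carrier))
```

Both trials have nonsignificant chi-square p-values of similar size
(`pearson_chi_square()` reports .90 and 1 with Yates' correction), yet the
large trial's BF01 of 77.7 is *very strong* evidence of absence while the
small trial's 2.7 is merely anecdotal.

## Evidence categories

`classify_evidence()` grades BF01 on the conventional Jeffreys-style
bands: anecdotal (1–3), moderate (3–10), strong (10–30), very strong
(30–100), extreme (> 100), mirrored on reciprocals when the data favor the
alternative. The bands are convention, not inference; two choices the
bands themselves do not fix are made explicit here: each boundary value
belongs to the lower band (BF = 3 is anecdotal), and BF = 1 — perfectly
ambiguous data — is anecdotal.

## The frequentist companion

`pearson_chi_square()` implements the classical test of independence with
and without Yates' continuity correction. The corrected deviation
$|O - E| - 1/2$ is floored at zero before squaring, so the correction can
only shrink the statistic; it is honored only for 2 × 2 tables. No exact
(Fisher) test is offered: the corpus this package models was analyzed with
chi-square tests even at n = 33, and the package mirrors that practice.

## Corpus analyses

`read_corpus()` loads a long-format CSV (one cell per line: `study_id`,
0-based `row_index` and `col_index`, `count`), `reanalyze()` computes
BF01, both p-values, and the evidence category per study, and
`summarize_corpus()` reduces them to corpus-level quantities: the BF
range and median, category counts, the correlation between the p-value and
log10 BF01 (reported also as percent of variance explained) and the
correlation between log10 total sample size and log10 BF01.

Two conventions are worth stating. Correlations use log BF because BF
ranges over orders of magnitude; the Pearson correlation is invariant to
the log base, so base 10 is used for display only. And because sources
rarely say whether screened p-values were Yates-corrected, both are
computed per study; the uncorrected one enters the correlation by default,
with `p_value = "yates"` as a switch. Correlations require at least three
studies; with fewer they are reported as `NA` rather than fabricated.

```{r corpus}
corpus <- read_corpus(
  system.file("extdata", "nejm_worked_examples.csv", package = "bfnull")
)
reanalyze(corpus) |> glance()
```

## Synthetic null corpora

The corpora this package was built to reanalyze — published null results
for primary outcomes — exist as tables in journal supplements, not as
machine-readable data. `generate_corpus()` therefore emulates their
statistical structure so the pipeline's qualitative claims are testable
end to end:

* **per-arm size**: log-uniform on 15–5000, so total sample sizes span the
  same decades (a few dozen to about ten thousand) as the published
  corpus;
* **control-arm event rate**: log-uniform on 0.01–0.5, low-to-moderate
  event probabilities typical of mortality and complication endpoints;
* **effect**: a risk difference added to the treatment arm, 0 by default
  (an exact null, matching the premise that reported null effects are
  absent or negligible);
* **nonsignificance screen**: only studies with chi-square p ≥ 0.05 are
  kept (redrawn otherwise), emulating selection on a published "no
  effect" claim; the screening test is the uncorrected chi-square by
  default, switchable to Yates.

The size and rate ranges are plausibility choices anchored at the printed
extremes of the emulated corpus, not estimates of its joint distribution —
the realized (n, rate) pairs of real published null results are unknown
here. Each study draws from its own deterministic substream of the
corpus seed, so enlarging `n_studies` extends a corpus without reshuffling
earlier studies; a study that finds no admissible table in 1000 attempts
raises a generation error. Tables with an empty outcome column (for
example, zero events in both arms, which is common at n = 15 and rate
0.01) are redrawn unconditionally: such a trial could not have reported
the proportion comparison being emulated, and the chi-square screen is
undefined on it. Simulated type-I rates are therefore conditional on
testable tables.

What passing tests on these corpora do show: the pipeline reproduces the
qualitative structure of published-null-result corpora — nearly all
screened studies yield BF01 > 1, evidence strength is highly variable,
and sample size predicts it far better than the p-value does. What they
do not show: agreement with any particular published corpus's numbers
(min/max BF, exact correlations), article-level clustering of multiple
effects per article, m × k tables beyond 2 × 2, or realistic
publication-bias mechanisms beyond the single significance screen.

```{r synthetic}
res <- generate_corpus(synthetic_config(seed = 2026)) |> reanalyze()
summarize_corpus(res)
```

The two plotting helpers show the two relationships directly:

```{r plots, fig.width = 6, fig.height = 4}
plot_evidence_vs_p(res)
plot_evidence_vs_n(res)
```

## Why evidence grows like the square root of n

For an exact null observed exactly (both arms at the same rate,
`fixed_rate_series()`), $m_1$ integrates over rate pairs of which only a
$O(1/\sqrt{n})$-wide diagonal band fits the data, while $m_0$ pays that
penalty once. The ratio therefore grows like $\sqrt{N}$: on the series
with event rate 0.1 and per-arm sizes 40–5120, regressing log10 BF01 on
log10 N over the upper half of the grid gives a slope of 0.5. This is the
mechanism behind the sample-size correlation above — and the reason a
small null trial *cannot* provide compelling evidence of absence, no
matter how close to 1 its p-value is.

## Numerical verification

The closed forms are cross-checked three ways in the test suite, at the
sizes stated so the default run stays fast:

* a quadrature oracle (`bf01_numeric_oracle()`) that integrates the
  product-multinomial likelihood over the priors by Gauss–Legendre
  quadrature in stick-breaking coordinates, with an $x = \sin^2 u$ change
  of variable so the Beta-density endpoint singularities at $a = 1/2$
  vanish; closed form and oracle agree to relative error below $10^{-5}$
  on 20+ small tables across $a \in \{0.5, 1, 2\}$ (2048 nodes for
  two-column tables, a 220 × 220 tensor grid for three-column ones);
* conservation: summed over *all* tables with fixed row totals
  ($n_i \le 6$), each marginal likelihood totals 1 to $10^{-10}$;
* exact factorial evaluation on tiny tables, including the collapse of the
  uniform-prior alternative marginal to $\prod_i 1/(n_i + 1)$ for two
  columns.

Corpus-level properties use 100 corpora of 43 screened studies and one
calibration run of 10,000 unscreened studies — sizes chosen to make the
binomial/seed-to-seed noise small relative to the margins being asserted
while keeping the default test run in minutes.

## Limitations

* Only the fixed-row-totals (independent multinomial) sampling scheme is
  implemented; designs conditioning on both margins or on nothing
  (hypergeometric, Poisson, joint multinomial) yield different default
  Bayes factors and are out of scope.
* The default priors are deliberately uninformed. Substantive prior
  knowledge would change the alternative's predictions and hence the BF;
  elicitation and robustness analysis over prior choices are not
  provided.
* BF01 grades evidence about association; it is not an effect-size
  estimate and carries no credible interval.
* The synthetic generator is a structural stand-in for published corpora,
  not a fitted model of any of them.
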