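---
title: "Methods: health-state utility elicitation, simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: health-state utility elicitation, simulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utilicit)
library(dplyr)
```

## The problem

Cost-utility analyses compare treatments by cost per quality-adjusted life
year (QALY). A patient's expected survival is split into intervals, each
spent in some health state $C_i$ for $T_i$ years; with a utility coefficient
$UC_i \in [0, 1]$ per state (0 = death, 1 = perfect health),

$$\mathrm{QALYs} = \sum_i T_i \cdot UC_i .$$

The utilities themselves must be *elicited* from people. This package
implements the two direct elicitation methods used to value 18 health
states that can follow minimally invasive trans-oral surgery (TORS/TLM) for
oropharyngeal cancer — from first-month surgical recovery, adjuvant (chemo-)
radiotherapy and surgical complications through local/regional/distant
recurrence and palliative care — plus the downstream analysis, an a-priori
sample-size rule, and a synthetic-respondent simulator so that the whole
pipeline is testable without access to raw interview data.

The states are carried with SNOMED CT codes; states with no single
pre-coordinated concept are represented by post-coordination (several
`code|term|` tokens). Validation is purely syntactic
(`validate_snomed_expression()`): the codes are labels here, not a
reasoning substrate, so no terminology server is involved.

## Elicitation procedures

**Rating scale (RS).** The respondent places the state on a 0–100 scale
(0 = death, 100 = perfect health); `rs_elicit()` normalises to $[0,1]$.
RS values are not utilities in the von Neumann–Morgenstern sense (no
uncertainty is involved) but are quick, easy to understand, and serve as
comparators.

**Standard gamble (SG).** The respondent chooses between staying in the
state for sure and a hypothetical treatment that restores perfect health
but kills with probability $p$. At indifference, $UC = 1 - p$. The risk is
titrated adaptively:

* the first proposed risk is $1 - UC_{rs}$, seeding the search with the
  respondent's own rating (this shortens titration considerably compared
  with a fixed 0.5 start);
* each answer updates a bracket on the indifference risk — *accept* at $p$
  implies the indifference risk is $\ge p$, *reject* implies $\le p$ — and
  the next proposal is the bracket midpoint (bisection). Bisection was
  chosen because it is deterministic, never widens the bracket, and
  provably converges in $\lceil \log_2(1/\mathrm{tol}) \rceil$ questions;
* titration stops on an explicit *indifferent* answer, when the bracket
  width reaches `tolerance` (default 0.01, matching the one-point
  granularity of the rating scale), or at `max_steps` (default 30, a
  safety cap never reached under bisection at the default tolerance);
* if the respondent refuses *any* risk of death at the first proposal, the
  gamble is refused outright and the state's utility is exactly 1;
* degenerate starts are clamped: if $1 - UC_{rs} \in \{0, 1\}$ the first
  risk becomes `tolerance` (resp. `1 - tolerance`), since a zero-risk
  gamble asks nothing.

```{r}
s <- sg_start(0.546)         # first proposed risk: 1 - 0.546
s <- sg_step(s, "reject")    # too risky -> bracket [0, 0.454]
s <- sg_step(s, "accept")    # acceptable -> bracket [0.227, 0.454]
glance(s)
```

**Time trade-off (TTO).** `tto_utility(t1, t2) = t2 / t1`: the fraction of
remaining lifespan the respondent would keep in exchange for perfect
health. It is implemented and tested but not part of the default study
pipeline, which administered RS and SG only.

`run_interview()` asks, per state, the RS question and then the SG
titration seeded by that state's own rating, producing exactly two records
per state. A study with 47 respondents and 18 states therefore yields
$47 \times 18 \times 2 = 1692$ utility records.

## Sample size

`min_sample_size()` finds the smallest $n$ whose two-sided $t$ confidence
half-width meets a target margin of error $m$:

$$\min\,\{\,n \ge 2 : t_{1-\alpha/2,\,n-1}\; \sigma/\sqrt{n} \le m\,\}.$$

With $m = 0.05$, $\sigma = 0.15$ and 95% confidence this gives $n = 38$.
The closed-form normal approximation $\lceil (z_{1-\alpha/2}\sigma/m)^2
\rceil$ gives 35 for the same inputs; the iterative $t$ criterion is the
default because it accounts for estimating the SD, and the $z$ variant is
kept behind `method = "z"` for comparison.

## The synthetic-respondent model

Raw per-respondent interview data are generally unavailable, so the
simulator generates interviewees with the statistical structure the
analysis relies on. For respondent $r$ and state $s$:

* **Latent RS utility** $u_{rs} \sim \mathrm{Beta}(\mu_s \kappa,
  (1-\mu_s)\kappa)$. The per-state anchors $\mu_s$ default to the published
  per-state RS means (from 0.072 for palliative care to 0.763 for
  remission). Concentration $\kappa = 6$ gives an SD of about 0.19 at
  $\mu = 0.5$, in line with the observed RS dispersions (~0.13–0.21) after
  allowing for rating noise.
* **Latent SG utility** via the deterministic distortion
  $v = 1 - (1-u)^{1/\gamma}$ with $\gamma \le 1$. For $\gamma < 1$ this
  pushes SG utilities toward 1 while preserving ordering, reproducing the
  strongly right-skewed SG distributions (medians at 1 for most states)
  sitting systematically above the RS values. The default $\gamma = 0.35$
  qualitatively reproduces SG medians of 1 for states with RS mean
  $\gtrsim 0.4$.
* **Refusals**: with probability `refusal_prob` (default 0.2) a respondent
  whose latent SG utility exceeds `refusal_threshold` (default 0.9)
  refuses the gamble outright, contributing an exact 1 — the second
  mechanism behind the SG point mass at 1.
* **Observed rating**: $\mathrm{clamp}(\mathrm{round}(100\,u +
  \varepsilon), 0, 100)$ with $\varepsilon \sim N(0, 5^2)$ on the 0–100
  scale.
* **Gamble answers** threshold on the latent SG utility: *indifferent*
  when $|(1-p) - v| \le \delta$ (default $\delta = 0.01$), otherwise
  *accept* iff $1 - p > v$.

Demographics follow the reference study population: 70% female, education
mix 15/8/77% (secondary/high school/university), ages drawn from a normal
distribution (mean 40.8, SD 14.79) truncated to 21–68 by resampling. The
published tables do not enumerate the profession or marital-status
category sets (only "unemployed", "commercial activities" and "married"
are mentioned), so those lists are configurable with plausible defaults.

All randomness flows from one integer seed; per-respondent and per-state
substreams are derived by stable string hashing of `(seed, purpose,
respondent_id, state_id)`, so results are independent of evaluation order
and reproducible across platforms.

**What the simulator does *not* emulate:** within-respondent correlation
beyond the shared latent draw (e.g. consistently pessimistic raters),
learning or fatigue across the 18 scenarios, interviewer effects,
demographic effects on utilities (ages and sexes are drawn independently
of the latents, so true age–utility correlations are zero), and interview
duration. Passing tests therefore demonstrate correctness of the
procedures and pipeline on data with the assumed structure — not that real
respondents behave this way.

## Analysis conventions

* **Summaries** (`summarize_values()`, `build_table3()`): mean, sample
  (n−1) SD, and min/q1/median/q3/max with quantiles by linear
  interpolation between order statistics (type 7, the default of
  mainstream statistical environments; no convention was stated in the
  source tables). Reported to 3 decimals.
* **Ranking** (`rank_states()`): ascending by mean, ties broken by state
  id (no ties occur in the published means). `rank_concordance()` counts
  same-position agreements and the shared worst-prefix/best-suffix runs;
  on the published means this gives 9/18 matched positions with the 5
  worst and 2 best states ranked identically by SG and RS.
* **Confidence intervals** (`mean_ci()`): normal-approximation
  $\bar{x} \pm 1.959964\,s/\sqrt{n}$, reported to 2 decimals. This
  reproduces the published present-study bounds (the $t$-based interval is
  ~3% wider at $n = 47$ and does not); one upper bound in the published
  comparison table differs by one unit in the last decimal, consistent
  with double rounding in the original report. Bounds are deliberately
  not clipped to $[0,1]$, matching the published presentation (e.g. an
  upper bound of 1.01 for remission).
* **Association tests**: Spearman rank correlation with midranks and the
  t-approximation p-value; Wilcoxon rank-sum two-sided, exact for small
  untied samples and continuity-corrected normal approximation otherwise.
  Both delegate to the standard `stats` implementations behind the
  package's interface, and both are cross-checked in the test suite
  against brute-force oracles (rank-then-Pearson; exact tail
  enumeration). Published p-values computed on the raw interview data
  (e.g. age correlations per state) are not reproducible without that
  data; the pipeline recomputes the same *kind* of statistics on
  simulated data.
* **Smoothing** (`lowess_fit()`): Cleveland's robust locally weighted
  regression — local linear fits with tricube weights over the `span`
  fraction of nearest neighbours (default 2/3) and 3 bisquare robustness
  iterations.
* **QALYs** (`compute_qalys()`): the plain weighted sum by default;
  optional continuous discounting contributes
  $u\,e^{-rt_0}(1 - e^{-rT})/r$ per segment, default off so the
  undiscounted formula holds exactly.

## Worked pipeline

```{r}
res <- run_pipeline(out_dir = NULL, n_respondents = 47, seed = 1)
nrow(res$records)
glance(res$concordance)
res$table3 |> filter(state_id %in% c(12, 18))
```

```{r, fig.width = 5, fig.height = 4}
plot_method_correlation(res$table3)
```

## Problem sizes and numerical choices in the tests

The test suite exercises the titration state machine against a
thresholding answerer on an exhaustive 101-point grid of latent
indifference points; descriptive summaries and Spearman correlations
against brute-force oracles on 1000 random vectors (tolerance 1e−12);
Wilcoxon type-I error over 1000 null replicates at $n = 20$ per group;
and synthetic-population parameter recovery with 200 respondents
(elicited per-state SG means within ±3 Monte-Carlo standard errors of the
closed-form latent means, with refusals and the indifference band
disabled so titration is the only error source). Skew and ordering
properties of the simulator are checked at 120 respondents. These sizes
keep the whole suite under a minute while leaving Monte-Carlo margins
that are wide relative to the effects being checked.

## Limitations

The simulator's parameters are calibrated to published summary statistics,
not fitted to individual data; subgroup analyses (profession, marital
status) on simulated data reflect the generator's assumptions, not
evidence. EQ-5D-style indirect elicitation, multi-user collection
infrastructure, and the downstream decision-tree/Markov cost-utility model
are out of scope; `compute_qalys()` covers only the utility-weighting step
that connects elicited values to that model.
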