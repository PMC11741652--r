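---
title: "Aggregating repeated diagnostic tests: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregating repeated diagnostic tests: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(testfuse)
```

## The statistical model

A binary diagnostic or screening test for a condition with true status
$X \in \{0, 1\}$ is characterized by its sensitivity
$\mathrm{TPR}_i = \Pr(Y_i = 1 \mid X = 1)$ and specificity
$\mathrm{TNR}_i = \Pr(Y_i = 0 \mid X = 0)$. When $n$ tests are
administered to the same subject, the joint result is one of the $2^n$
ordered outcome vectors, and any decision protocol is a Boolean function
mapping each outcome vector to a single $+/-$ call. `testfuse`
represents such a protocol as its *output sequence*: a truth-table
string over the canonical outcome order, which is lexicographic with
`+` before `-` (all-positive first, all-negative last; for two tests:
`(+,+), (+,-), (-,+), (-,-)`). The bijection to bit tuples maps `+` to
1 with test 1 as the most significant bit. Fixing one order is what
makes a rule string like `"+---"` (AND) or `"+++-"` (OR) unambiguous in
every file the package reads or writes.

Under the core modeling assumption — *conditional independence of test
results given the true status* — the aggregated sensitivity of a rule
$S$ is a sum of products,

$$\mathrm{TPR}_S = \sum_{j:\,S_j = +}\ \prod_{i=1}^{n}
  \mathrm{TPR}_i^{\,\delta_{i,+}} (1-\mathrm{TPR}_i)^{\,\delta_{i,-}},$$

and the aggregated specificity sums the mirrored products of
$\mathrm{TNR}_i$ and $1-\mathrm{TNR}_i$ over the outcomes mapped to
$-$. The familiar protocols are special cases: AND (conjunctive,
"believe the negative") multiplies sensitivities; OR (disjunctive,
"believe the positive") multiplies specificities; k-of-n and majority
rules interpolate between them. Series and parallel administration of
the same rule have identical aggregate characteristics — only the
number of tests consumed differs — so the package computes
characteristics from the rule alone.

Conditional independence is the standard reporting assumption of test
manufacturers, but it is an assumption: correlated assays (say, two
antibody tests sensitive to the same immune response) violate it. The
package therefore (i) exposes Boole–Fréchet bounds
(`frechet_bounds()`), which are the best possible bounds on AND/OR/
majority characteristics given only the marginal characteristics and
*no* dependence assumption, and (ii) estimates pairwise dependence
factors $\lambda^{11|1}, \lambda^{00|0}$ (`dependence_factors()`) from
raw cohort data as a diagnostic — $\lambda = 1$ under independence.
Dependence factors never feed back into the aggregation formulas; no
parameterized joint model is fitted, because none is identified by
marginal summaries alone.

## The ROC frontier search

For $n$ tests there are $2^{2^n}$ rules. `roc_frontier()` computes the
$(\mathrm{FPR}, \mathrm{TPR})$ point of every rule (a binary-mask
matrix product against the two outcome-probability vectors), merges
coincident points, and extracts the efficient frontier: the upper-left
convex-hull chain from $(0,0)$ to $(1,1)$, both endpoints always being
achievable by the constant rules. Implementation choices:

* **Enumeration cap.** Full enumeration is allowed for $n \le 4$
  (65,536 rules, well under a second); for $n \ge 5$ the rule space
  ($2^{32}$ and beyond) is refused and a named-family mode (AND, OR,
  k-of-n, projections, user expressions) competes a tractable subset.
* **Hull extraction.** A dominance sweep (sort by FPR, keep strictly
  rising TPR) followed by a concave-chain walk that pops any vertex
  lying on or below the chord of its neighbours. Collinear points
  interior to a hull edge are excluded (strict convex position); all
  rules attaining a retained vertex are reported, sorted by
  truth-table string, the first being the representative — so output
  files are deterministic.
* **Degenerate hulls.** If every non-trivial point is collinear with
  the endpoints (zero-area hull, e.g. duplicated tests straddling the
  diagonal), the frontier falls back to the plain dominance scan.
* **Endpoint snapping.** Sums of $2^n$ outcome probabilities can land
  at $1 - 10^{-16}$; coordinates within $10^{-12}$ of 0 or 1 are
  snapped so the trivial corners are exact.
* **Only achievable rules.** No randomized/interpolated classifiers
  along frontier edges are reported, and no cost-weighted operating
  point is chosen; both are out of scope.

Confidence bars on frontier points come from the Monte Carlo machinery
below, not from interval arithmetic.

## Decision measures and test economy

`ppv()` and `npv()` are the prevalence-dependent post-test
probabilities. Setting them equal gives
$f^2\,\mathrm{TPR}(1-\mathrm{TPR}) = (1-f)^2\,\mathrm{TNR}(1-\mathrm{TNR})$,
so the crossover prevalence returned by `ppv_npv_crossover()` is

$$f^\ast = \frac{\sqrt{\mathrm{TNR}(1-\mathrm{TNR})}}
  {\sqrt{\mathrm{TNR}(1-\mathrm{TNR})} + \sqrt{\mathrm{TPR}(1-\mathrm{TPR})}},$$

which the test suite verifies against a direct root search on
$\mathrm{PPV}(f) - \mathrm{NPV}(f)$.

Series administration defers the second test until the first result
leaves the call undecided, so for a first test with characteristics
$(\mathrm{TPR}_1, \mathrm{TNR}_1)$ at prevalence $f$ the
parallel-to-series test-count ratios are
$2/(1 + f\,\mathrm{TPR}_1 + (1-f)(1-\mathrm{TNR}_1))$ for AND and
$2/(1 + f(1-\mathrm{TPR}_1) + (1-f)\,\mathrm{TNR}_1)$ for OR, both in
$[1, 2]$. They cross at the critical prevalence
$f_c = (2\,\mathrm{TNR}_1 - 1)/(2(\mathrm{TPR}_1 + \mathrm{TNR}_1 - 1))$:
below $f_c$ the series AND protocol saves more tests, above it series
OR does. $f_c$ is meaningful for a first test with
$\mathrm{TNR}_1 \ge 1/2$ and discriminatory power
($\mathrm{TPR}_1 + \mathrm{TNR}_1 > 1$); the mirrored regime with
$\mathrm{TNR}_1 \le 1/2$ is computed but flagged with a warning rather
than special-cased, since such a first test is actively misleading.

## Prevalence correction and severity ratios

A protocol with aggregated characteristics
$(\mathrm{TPR}_S, \mathrm{TNR}_S)$ turns a true prevalence $f$ into an
apparent positivity rate
$f^\ast_S = f\,\mathrm{TPR}_S + (1-f)(1-\mathrm{TNR}_S)$.
`correct_prevalence()` inverts this — a Rogan–Gladen estimator
generalized to any Boolean aggregation:

$$\hat f = \frac{f^\ast_S + \mathrm{TNR}_S - 1}
  {\mathrm{TPR}_S + \mathrm{TNR}_S - 1}.$$

Choices worth knowing:

* **Clamping.** The raw inverse can leave $[0,1]$ (a measured rate
  below the protocol's false-positive floor). The record keeps the raw
  value and the clamped value with a flag; severity ratios use the
  clamped estimate and a warning is logged. A protocol with
  $\mathrm{TPR}_S + \mathrm{TNR}_S = 1$ is non-informative and raises
  an explicit error — as do the degenerate 0/0 cases of PPV/NPV —
  rather than silently returning a limit.
* **Strata.** Age/time strata are opaque labels; characteristics are
  held constant over time (no antibody-waning correction, no
  sampling-bias adjustment).
* **Severity.** `severity_ratio()` divides cumulative fatality or
  hospitalization counts by $\hat f N$. The population $N$ is an
  explicit input: the bundled serosurvey example divides by the whole
  county population (249,614) although the survey sampled the adult
  subpopulation, matching how those figures were originally reported.
* **Reporting.** Percent formatting (one decimal) happens only at the
  I/O boundary; internally everything is a unit-interval proportion.
  Tables report the deterministic point estimate as primary, with
  Monte Carlo medians/CIs alongside where requested — with an
  imperfectly sensitive, perfectly specific AND protocol the
  correction always raises the estimate, and a stratum whose printed
  corrected value reflects an MC median rather than the deterministic
  inverse can differ in the last decimal.

## Uncertainty propagation

Sensitivities, specificities, and prevalences live on $[0,1]$, so
reported `median (95% CI)` summaries are modeled as beta
distributions. `fit_beta()` minimizes the sum of squared differences
between the beta CDF evaluated at the three reported values and the
levels $(0.025, 0.5, 0.975)$, using Nelder–Mead on log-shapes from a
method-of-moments start (mean at the median, sd of CI-width$/3.92$),
with a coarse log-grid restart if the local search stalls. Summaries
touching a boundary (a 100% specificity with CI 98–100%) have their
quantile targets clipped into $[10^{-4}, 1-10^{-4}]$ — a proper beta
cannot put its median exactly at an endpoint — and a zero-width CI is
treated as a fixed constant.

`mc_propagate()` draws each uncertain input independently (across
inputs and across tests — no joint uncertainty model is available from
published summaries), pushes the draws through any vectorized pipeline
quantity, and reports the empirical 2.5/50/97.5 percentiles. Draws on
which the quantity is undefined are discarded and counted, with a flag
past 1%. The default sample count is $10^5$ and every run is seeded;
summaries are bit-reproducible for a fixed seed, and the sample count
is a configuration knob rather than a constant.

## The synthetic cohort generator

`simulate_cohort()` is the package's fixture source: per-subject status
$X \sim \mathrm{Bernoulli}(f)$, then each test result Bernoulli with
success $\mathrm{TPR}_i$ (if $X=1$) or $1-\mathrm{TNR}_i$ (if $X=0$),
independent across tests by default. Optional positive dependence uses
a chain factorization over consecutive test pairs with a single shared
factor $\lambda$: $\Pr(Y_i = 1 \mid Y_{i-1} = 1, X) = \lambda
\Pr(Y_i = 1 \mid X)$, with the complementary conditional chosen to
preserve every marginal. The same factor couples positive results in
both status classes. Infeasible $\lambda$ (implied conditionals outside
$[0,1]$) is rejected with the feasible range in the message.
Missingness is completely at random, emulating panels in which not
every assay is run on every sample; pairwise-complete estimation is
then unbiased.

What the generator emulates — and what it does not: it reproduces the
conditional-Bernoulli measurement model exactly, so closure tests
(empirical characteristics within three binomial standard errors of the
closed forms on $10^5$-subject cohorts, injected $\lambda$ recovered
within three empirical standard errors across replicate cohorts) are
checks of *internal consistency*. Passing them says the estimators and
formulas agree with the generating model; it says nothing about
real-world complications the model excludes — time-varying test
characteristics, biased sampling, structured (non-pairwise, non-adjacent)
dependence, or informative missingness.

## Problem sizes and determinism

The shipped tests exercise full rule enumeration up to $n = 3$
exhaustively (256 rules; the $n=2$ frontier is cross-checked against a
segment-by-segment oracle with no hull machinery) and $n = 4$ through
the closed-form oracle; property sweeps use 100–1000 random panels;
stochastic checks use cohorts of $10^5$–$2\times10^5$ subjects and
Monte Carlo runs of $2\times10^4$ draws — sizes at which binomial and
MC standard errors are small enough for three-sigma assertions to be
discriminating while the whole suite stays fast. All stochastic tests
fix seeds, so the suite is deterministic.

## Known limitations

* Conditional independence is assumed wherever exact characteristics
  are computed; dependence enters only through bounds and diagnostics.
* Fréchet-type bounds are provided for AND/OR/majority only, not for
  arbitrary rules.
* No indeterminate/equivocal result category; tests are strictly
  binary.
* No monetary cost, test-fatigue, or avoidance modeling in the economy
  calculations; no utility-based choice of operating point on the
  frontier.
* Prevalence correction assumes an unbiased, representative sample and
  time-constant test characteristics.
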