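---
title: "Model-averaged equivalence testing for regression curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-averaged equivalence testing for regression curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equivcurve)
library(dplyr)
```

## The problem

Two groups — two treatments, two diets, two patient strata — are observed
at a handful of dose or time points, and the question is not whether their
response curves *differ* but whether they are *equivalent*: is the largest
vertical gap between the two mean curves smaller than a margin
$\varepsilon$ below which the difference is scientifically irrelevant?
Writing $m_1(x)$ and $m_2(x)$ for the group mean curves over the covariate
range $\mathcal{X}$ and

$$d = \max_{x \in \mathcal{X}} |m_1(x) - m_2(x)|,$$

the hypotheses are reversed relative to a superiority test:

$$H_0: d \ge \varepsilon \quad \text{vs.} \quad H_1: d < \varepsilon .$$

Rejecting $H_0$ *establishes* equivalence at level $\alpha$.

Classical curve-based equivalence tests require the analyst to name the
true parametric family for each group.  That assumption is fragile:
fitting the same wrong family to both groups pulls the fitted curves
towards each other and can inflate the type-I error severely (our
simulation reproduction reaches rejection rates around 0.4 at a nominal
0.05 when an exponential model is forced onto both groups), while other
misspecifications destroy power instead.  `equivcurve` removes the
assumption by *model averaging*: each group's curve is a weighted
combination of candidate fits, with data-driven weights.

## Model and estimation

Each group $l = 1, 2$ contributes observations
$y_{lij} = m_l(x_{li}) + e_{lij}$ at $I_l$ distinct covariate levels,
with i.i.d. Gaussian errors of variance $\sigma_l^2$.  Six candidate
families are supported (`curve_families()`): linear, quadratic, emax,
exponential, sigmoid emax (Hill), and the beta model with a fixed scale
$s$.  All are standard in dose-response work and cover monotone and
non-monotone, convex, concave and sigmoid shapes.

Candidates are fitted by bounded least squares.  Families that are linear
in all coefficients are solved in closed form.  For the nonlinear
families the intercept and slope are profiled out analytically, and the
remaining one or two nonlinear coefficients are optimized by a bounded
grid scan (30 points per dimension, log-spaced) with local golden-section
refinement — a multi-start strategy in the spirit of the grid-based
optimizers used by dose-finding software, implemented in C++ because the
bootstrap below repeats it hundreds of thousands of times.  Under
normality the least-squares and maximum-likelihood estimates coincide;
the Gaussian log-likelihood is evaluated at the least-squares
coefficients with the ML variance $\hat\sigma_l^2 = \mathrm{RSS}/n_l$
(divisor $n$, not $n-p$).

The smooth weights are a softmax over an information criterion $I$,

$$w_k = \frac{\exp(-I_k/2)}{\sum_{k'} \exp(-I_{k'}/2)},$$

computed after subtracting $\min_k I_k$ so the softmax is shift-invariant
and overflow-free.  BIC weights are the default: the model-average
estimator with smooth BIC weights is asymptotically normal, which is what
justifies the confidence-interval construction below, and BIC weights
approximate posterior model probabilities.  AIC weights are available
(`weights = "aic"`), and when every candidate has the same parameter
count AIC and BIC weights are *identical*, because the penalty cancels
from the softmax.  Fixed weights — including equal weights — are also
supported, mainly so their inferior robustness can be demonstrated.

## The test

With the averaged curves $\hat m_l(x) = \sum_k w_{lk} m_{lk}(x, \hat\theta_{lk})$
the statistic is the plug-in deviation
$\hat d = \max_{x} |\hat m_1(x) - \hat m_2(x)|$.  Rather than simulating
the null distribution under the constraint $d = \varepsilon$ — a
numerically unpleasant constrained problem that becomes nearly
intractable when weights move with the parameters — the test uses the
duality between confidence intervals and tests: given a one-sided upper
$(1-\alpha)$ confidence bound $u$ for $d$, rejecting when
$\varepsilon > u$ is an $\alpha$-level test.

The bound comes from a parametric bootstrap.  Each replicate draws
$y^*_{lij} \sim N(\hat\mu_{li}, \hat\sigma_l^2)$ at the original design
points, where $\hat\mu_{li}$ is the *averaged* fitted mean and
$\hat\sigma_l^2$ the ML variance of the averaged-curve residuals, then
refits all candidates and recomputes the weights exactly as in the
original analysis (weights are re-estimated in every replicate), giving
$\hat d^*$.  Two bounds are offered:

* **percentile** (`ci = "percentile"`): the
  $\lfloor n_{boot}(1-\alpha) \rfloor$-th order statistic of the
  bootstrap sample — valid but conservative in finite samples;
* **hybrid** (`ci = "hybrid"`, default): $u = \hat d + z_{1-\alpha}\,
  \widehat{se}$, with $\widehat{se}$ the bootstrap standard deviation.
  This uses the asymptotic normality of $\hat d$ (available under smooth
  BIC or fixed weights) but estimates its standard error by bootstrap,
  avoiding the closed-form variance estimator whose validity requires a
  unique, known maximizing point $x_0$ — an assumption that fails
  outright for shifted curves, where the difference is flat in $x$.
  The hybrid bound always satisfies $u \ge \hat d$ for $\alpha < 0.5$.

An asymptotic bound built on that closed-form variance estimator exists
in the literature; it is deliberately not implemented here, both because
the estimator is external to this package's scope and because the
bootstrap variants dominate it in finite samples.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` / `epsilon_rel` | — | absolute margin, or fraction of the fitted response range (exactly one) |
| `alpha` | 0.05 | one-sided level, must be in (0, 0.5) |
| `n_boot` | 500 | bootstrap replicates; 500 matches the precision of three-decimal rejection-rate summaries at feasible cost |
| `families` | emax + exponential | candidate set; may differ per group (list of two) |
| `weights` | `"bic"` | `"aic"`, `"equal"`, `"fixed"` also available |
| `n_grid` | 1001 | grid for the deviation maximum (see below) |
| `scal` | `1.2 * max(x)` | fixed beta-model scale, must exceed the largest design point |
| `seed` | — | master seed; all replicate randomness derives from it |

## Numerical choices

**Deviation maximum.** $\hat d$ is computed on a 1001-point equispaced
grid followed by staged local refinement: around each of the top three
(non-adjacent) grid points a 41-point window is zoomed three times,
localizing the maximum to about $10^{-7}$ of the range with a handful of
vectorized curve evaluations.  Ties break towards the smallest $x$,
which matters for shifted-curve configurations where the difference is
constant.  Against a $10^5$-point brute-force grid the result agrees to
well below $10^{-6}$ of the response range on all test curves.

**Fitting boxes.** Nonlinear coefficients are constrained to
design-scaled boxes: emax ED50 in $[0.001, 1.5] \cdot x_{max}$, sigmoid
emax additionally Hill exponent in $[0.5, 10]$, beta shape parameters in
$[0.05, 4]$, exponential rate scale in $[0.05, 3] \cdot x_{max}$.  The
exponential box is wider than the $[0.1, 2] \cdot x_{max}$ convention of
dose-finding software so that rate scales up to twice the design maximum
— including the benchmark value $8$ on the range $[0, 4]$ — sit strictly
inside the box rather than on its boundary.

**Information-criterion parameter count.** The penalty counts
$\dim(\theta) + 1$ parameters, including $\sigma^2$, the standard
likelihood convention.  Any fixed convention preserves the equal-count
AIC/BIC weight identity; this one keeps the criteria comparable across
families of different dimension.

**Degenerate fits.** A zero-residual fit has an undefined Gaussian
likelihood; the variance is floored at machine epsilon scaled by the
response variance and the fit is flagged `degenerate`.  With both group
variances degenerate the bootstrap collapses onto the fitted curves and
every $\hat d^*$ is essentially $\hat d$ — the correct limit.

**Convergence failures.** A candidate that fails inside a bootstrap
replicate is dropped for that replicate and the remaining weights are
renormalized (preserving the simplex); a replicate in which a group
loses *all* candidates is redrawn, at most ten times, and counted in
`n_redrawn`.

**Seeds and parallelism.** Every repetition (bootstrap replicate,
simulation run, screened gene) uses a substream seed derived
arithmetically from the master seed, so results are bit-identical for
any `threads` value and independent of execution order.  The bootstrap
is also made exactly symmetric in the two groups by assigning the two
noise substreams by a data fingerprint rather than by input order, so
swapping the group labels cannot change $u$.

## The simulation frame

`scenario_config()` / `estimate_rejection_rate()` /
`run_scenario_sweep()` reproduce a standard three-scenario benchmark on
the dose range $[0, 4]$ with levels $x = 0, \dots, 4$ and equal
per-level counts $n_l/5$:

1. emax $\theta_1 = (1, 2, 1)$ vs exponential
   $\theta_2 = (\beta_{20}, 2.2, 8)$, $\beta_{20} \in \{0.25, 0.5, 0.75,
   1, 1.5\}$ giving $d \in \{1.5, 1.25, 1, 0.75, 0.5\}$, margin
   $\varepsilon = 1$;
2. two shifted emax curves ($d$ equal to the shift everywhere),
   $\varepsilon = 0.5$;
3. two shifted exponential curves, likewise $\varepsilon = 0.5$.

Variance pairs $(0.25, 0.25), (0.25, 0.5), (0.5, 0.5)$ and sample sizes
$10/20/50$ per group complete the grid; $\alpha = 0.05$ throughout.  The
`specification` argument selects what is fitted: the true families, one
family forced on both groups (`emax_emax`, `exp_exp`), the truth with
groups swapped (`swapped`), or model averaging over
$\{$emax, exponential$\}$ with BIC (`ma_bic`) or equal weights
(`ma_equal`) — the candidate pair that makes one specification correct
and three misspecified in scenario 1.

Problem sizes: the package defaults are 1000 simulation repetitions and
500 bootstrap replicates per test.  The shipped acceptance script runs
300 repetitions with 300 bootstrap replicates per cell, and the test
suite 100–150 repetitions with 200 bootstrap replicates — desk-scale
settings whose binomial Monte-Carlo error
($2\sqrt{p(1-p)/n_{sim}} \approx 0.04$ at $p = 0.05$, $n_{sim} = 150$)
is accounted for in every assertion band.  All bands were fixed from
these error formulas before the corresponding checks were run.

## Gene screening and relative margins

For time-course expression screening the response scale differs per
gene, so a single absolute margin is meaningless.  `equiv_screen()`
resolves, per gene $g$,

$$\varepsilon_g = \tilde\varepsilon \cdot \big(\max_{l,i} \hat y_{gli} -
\min_{l,i} \hat y_{gli}\big),$$

the margin as a fraction $\tilde\varepsilon$ of the range of the fitted
(averaged) response values of both groups at their design points —
$\tilde\varepsilon = 0.2$ or $0.25$ are typical.  Equivalently the
scaled bound $\tilde u_g = u_g / \mathrm{range}$ is compared with
$\tilde\varepsilon$ directly; both decision rules coincide and both
quantities are reported.  Genes are screened marginally, without
multiplicity adjustment: the scientific question is per-gene, not a
global null, so each gene's decision stands alone.  Since the decision
is a strict threshold on a fixed bound, the set of equivalent genes can
only grow as $\tilde\varepsilon$ increases — a property the suite checks
exactly.

## What the synthetic generators emulate — and what they do not

`simulate_curve_data()` draws Gaussian responses around chosen candidate
curves at a fixed, few-level design: exactly the data-generating process
the test assumes.  `simulate_gene_data()` emulates log2-scale normalized
expression for many genes on two unbalanced time designs (nine time
points with counts 5,5,5,5,5,5,5,4,8 for one group; six with counts
7,5,5,7,3,5 for the other; $t = 0$ labels the first sampled week).
Per-gene curves are drawn from the candidate families with gene-varying
baselines (uniform on 6–12 log2 units), signed amplitudes of 1–4 log2
units, and residual standard deviations of 0.2–0.6 — magnitudes chosen
once to resemble moderately expressed, clearly regulated genes in a bulk
time-course experiment.  A configurable fraction of genes is planted as
exactly equivalent and the rest differ by a known vertical shift, so
screening performance can be judged against planted truth.

The generators do *not* emulate: count noise (expression is generated
directly on the continuous log2 scale, mirroring how high-count data are
analyzed after normalization), normalization artifacts, correlation
between genes, heteroscedasticity along the curve, or non-Gaussian
errors.  Passing tests therefore demonstrate correctness of the
machinery under its own assumptions, not robustness to those real-data
features.

## Known limitations

* Gaussian errors only; the bootstrap generation and likelihood would
  both need changes for other outcome distributions.
* The asymptotic theory behind the hybrid bound holds for smooth BIC and
  fixed weights, not for smooth AIC weights; AIC weighting is provided
  for comparison, not as a recommended default.
* Equal-weight averaging is implemented and simulation shows why it
  should not be used for testing: it inherits the inflation of its
  misspecified members.
* The deviation grid is one-dimensional; multivariate covariates are out
  of scope.
* Bootstrap redraws after total convergence failure cap at ten attempts
  per replicate and then abort, to avoid silent bias.

## A worked example

```{r example, eval = FALSE}
library(equivcurve)

dat <- simulate_curve_data(
  curve_params("emax", c(1, 2, 1)),
  curve_params("exponential", c(1, 2.2, 8)),   # true d = 0.75
  sigma2 = c(0.25, 0.25), n = c(50, 50), seed = 1
)

tst <- equiv_test(dat, families = c("emax", "exponential"),
                  epsilon = 1, n_boot = 500, seed = 2)
tst
glance(tst)
tidy(tst)       # per-candidate weights per group
autoplot(tst)
```
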