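---
title: "Designing and analyzing multi-reader concordance trials with concord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analyzing multi-reader concordance trials with concord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concord)
```

## The setting

An AI-based device that assigns BI-RADS-style lexicon categories (e.g.
Shape: oval / round / irregular) to breast images cannot be validated
against a gold standard, because the lexicon has none. Instead, a trial
enrolls $n$ subjects whose images are read by the device and by a panel
of radiologists, and asks whether the device *agrees* with radiologists
the way radiologists agree with each other. Two readings concur when
they carry the same category label — `concord` treats this as exact
label equality after whitespace and case normalization, with no partial
credit for adjacent categories, because that is the only agreement
notion the design supports. Each lexicon classification is analyzed
separately; no multiplicity adjustment is built in, since trials
typically power only the clinically most important classification and
report the others descriptively. Adjustment across classifications, if
wanted, is left to the user.

## Objective 1: non-inferiority to radiologist agreement

For subject $i$, radiologists $j < j'$, let $r_{ijj'} = 1$ if
radiologists $j$ and $j'$ concur and $s_{ij} = 1$ if radiologist $j$
concurs with the device, with rates $p_r = E(r_{ijj'})$ and
$p_s = E(s_{ij})$. The per-subject scores are

$$r_i = \binom{m}{2}^{-1}\sum_{j<j'} r_{ijj'}, \qquad
  s_i = m^{-1}\sum_j s_{ij},$$

and $\hat p_r$, $\hat p_s$ are their means over subjects — unbiased GEE
estimators under working independence. Because $p_s \le p_r$ by
construction, the trial specifies a similarity margin $\delta_1 > 0$ and
tests $H_1\colon p_s \le p_r - \delta_1$ with

$$Z_1 = \frac{\sqrt{n}\,(\hat p_s - \hat p_r + \delta_1)}{\hat\sigma_1},
\qquad
\hat\sigma_1^2 = n^{-1}\sum_i (s_i - r_i + \delta_1)^2,$$

rejecting when $Z_1 > z_{1-\alpha}$ (one-sided, to avoid the very large
samples a two-sided test of a small margin would need). The variance is
*null-anchored*: under the boundary $p_s = p_r - \delta_1$ the summands
$s_i - r_i + \delta_1$ have mean zero, so $\hat\sigma_1^2$ is consistent
for the asymptotic variance there. The GEE sandwich alternative
(`variance_flavor = "gee_robust"`) centers at the estimate instead,
$n^{-1}\sum_i\{(s_i - r_i) - (\hat p_s - \hat p_r)\}^2$; the two are
asymptotically identical under $H_1$ and the package asserts their
ratio tends to one in its test suite. The null-anchored form is the
default because it is the statistic whose operating characteristics the
package's simulations target. A degenerate $\hat\sigma_1 = 0$ (every
$s_i - r_i$ exactly $-\delta_1$) raises an error rather than returning
an infinite statistic; this finite-sample corner has no principled
resolution and the caller should see it.

## Objective 2: senior versus junior radiologists

With $m$ senior and $m$ junior radiologists, $x_{ij}$ and $y_{ij}$
indicate agreement of the device with senior (junior) radiologist $j$,
$p_x = E(x_{ij})$, $p_y = E(y_{ij})$, and $H_2\colon p_x = p_y$ is
tested two-sided with
$Z_2 = \sqrt{n}(\hat p_x - \hat p_y)/\hat\sigma_2$,
$\hat\sigma_2^2 = n^{-1}\sum_i (x_i - y_i)^2$. Here there is no
small-margin issue, so the conventional two-sided test is used.

Both variance estimators divide by $n$, not $n-1$ — the estimators are
method-of-moments forms and the divide-by-$n$ convention is what the
sample-size formulas invert, so the package keeps it exactly.

## Compound correlation algebra

Power depends on $\rho_1 = \mathrm{corr}(r_i, s_i)$ (resp.
$\rho_2 = \mathrm{corr}(x_i, y_i)$), which is determined by the
correlations between individual indicators, classified by shared
readers:

* $\rho_{r1} = \mathrm{corr}(r_{i12}, r_{i13})$ (pairs sharing a
  reader), $\rho_{r2} = \mathrm{corr}(r_{i12}, r_{i34})$ (disjoint),
  $\rho_{s1} = \mathrm{corr}(r_{i12}, s_{i1})$,
  $\rho_{s2} = \mathrm{corr}(r_{i12}, s_{i3})$,
  $\rho_{ss} = \mathrm{corr}(s_{i1}, s_{i2})$;
* $\rho_{xx}, \rho_{yy}, \rho_{xy}$ for Objective 2.

`rho1_from_components()` implements the closed form

$$\rho_1 = \frac{\tfrac2m\rho_{s1} + \tfrac{m-2}{m}\rho_{s2}}
{\sqrt{\Big[\tfrac{2}{m(m-1)} + \tfrac{4(m-2)}{m(m-1)}\rho_{r1}
 + \tfrac{(m-2)(m-3)}{m(m-1)}\rho_{r2}\Big]
 \Big[\tfrac1m + \tfrac{m-1}{m}\rho_{ss}\Big]}}.$$

For Objective 2 the package derives the analogous form itself by
covariance algebra: all $m^2$ cross-covariances
$\mathrm{cov}(x_{ij}, y_{ij'})$ share the correlation $\rho_{xy}$ and
the marginal Bernoulli factors cancel, giving

$$\rho_2 = \frac{\rho_{xy}}
{\sqrt{\big[\tfrac1m + \tfrac{m-1}{m}\rho_{xx}\big]
       \big[\tfrac1m + \tfrac{m-1}{m}\rho_{yy}\big]}}.$$

This derived formula is gated on two independent checks in the test
suite: a Monte-Carlo oracle (empirical $\mathrm{corr}(x_i, y_i)$ over
$10^5$ simulated subjects agrees within 0.01) and exact reproduction of
all four reference component tuples at $m = 5$.

Because a single $\rho$ target under-determines the components, the
inverse solvers adopt the standard offset constraints
($\rho_{s1} = \rho_{s2} + 0.1$, $\rho_{r1} = \rho_{r2} + 0.1$,
$\rho_{ss} = \rho_{r1} = \rho_{s1} + 0.1$; for Objective 2
$\rho_{xx} = \rho_{yy} = \rho_{xy} + 0.1$) and solve the one free
parameter: a bracketed root-find to $10^{-12}$ for Objective 1, a
closed form for Objective 2. The general identification problem is
deliberately out of scope; with pilot data,
`estimate_components_from_pilot()` pools empirical Pearson correlations
over all indicator pairs in each structural class instead, and a
two-stage trial can recompute the sample size from first-stage
estimates.

```{r solvers}
solve_components_obj1(0.1, m = 10)
solve_components_obj2(0.3, m = 5)
```

## Power and sample size

With $\bar\Phi$ the standard normal survivor function and
$\sigma_1^2 = \mathrm{var}(s_i) + \mathrm{var}(r_i)
 - 2\rho_1\sqrt{\mathrm{var}(s_i)\mathrm{var}(r_i)}$ evaluated at the
alternative $p_s = p_r$,

$$1-\beta = \bar\Phi\!\left(\frac{z_{1-\alpha}\sqrt{\sigma_1^2+\delta_1^2}
 - \sqrt{n}\,\delta_1}{\sigma_1}\right),
\qquad
n = \frac{\big(z_{1-\alpha}\sqrt{\sigma_1^2+\delta_1^2}
 + z_{1-\beta}\sigma_1\big)^2}{\delta_1^2},$$

and analogously for Objective 2 with $z_{1-\alpha/2}$, $\delta_2$ and
$\sigma_2^2$ evaluated at $p_y = p_x - \delta_2$ (the far-tail rejection
probability of the two-sided test is neglected, as is conventional).
Sample sizes are rounded up; ceiling is adopted because it is the
conservative convention and reproduces every reference table value
(e.g. 209.44 → 210). The $\sqrt{\sigma^2 + \delta^2}$ factor appears
because the null-anchored variance estimator converges to
$\sigma^2 + \delta^2$ under the alternative. Normal quantiles are
computed to machine precision — table lookups would break the exact
reproduction of the published grids. Two identities are asserted across
the full design grid: the unrounded $n$ inverts the power function to
$10^{-10}$, and Objective-1 sample sizes are symmetric in
$p_r \leftrightarrow 1 - p_r$ since $\sigma_1^2$ depends on $p_r$ only
through $p_r(1-p_r)$.

```{r design}
spec <- design1_spec(m = 10, pr = 0.3, delta1 = 0.05, power = 0.8, rho1 = 0.1)
samplesize_objective1(spec)
power_objective1(210, spec)
```

## Simulating correlated concordance indicators

The simulator draws a latent multivariate normal vector per subject and
sets indicator $k$ to 1 when the latent coordinate exceeds the
upper-tail threshold $\bar\Phi^{-1}(p_k)$ of its marginal (the
upper-tail convention is fixed so thresholds are reproducible). The
latent correlation for each pair is *solved* (Emrich–Piedmonte style)
so that the induced **binary** correlation hits the target exactly:
$\Phi_2(\tau_j, \tau_k; \rho^*) = \rho_b\sqrt{p_jq_jp_kq_k} + p_jp_k$,
with the bivariate orthant probability evaluated by adaptive
one-dimensional quadrature and the root found by bracketed bisection.
Copying binary correlations directly onto the latent scale would bias
every pairwise correlation downward in magnitude, and the asymptotic
variances the tests rely on are functions of the binary correlations —
so exact matching is the only defensible choice. Feasibility of every
target against the Fréchet bounds for its marginal pair is checked at
layout assembly.

Pairwise-solved latent matrices need not be positive semidefinite; the
model repairs them by eigenvalue clipping at $10^{-10}$ with
re-normalization to unit diagonal, recording the largest entry
perturbation and warning if it exceeds 0.01 (for the reference designs
the matrices are PSD and the repair is a no-op). Two features of real
reading data are deliberately *not* reproduced: logical transitivity of
exact-match agreement ($r_{12} = r_{13} = 1 \Rightarrow r_{23} = 1$) is
not enforced, since indicators are generated directly, and only
pairwise binary correlations are controlled — higher-order joint
structure follows from the latent Gaussian family. Passing operating-
characteristic tests therefore validates the asymptotic theory under a
plausible dependence structure, not under every dependence structure a
real trial could produce.

## Monte-Carlo operating characteristics

`run_scenario()` solves components, computes $n$, simulates under the
null ($p_s = p_r - \delta_1$, or $p_x = p_y$) and the design alternative
($p_s = p_r$, or $p_y = p_x - \delta_2$), and reports rejection
fractions with binomial Monte-Carlo standard errors. The null keeps the
same component correlations as the alternative — the design tuples are
defined per $\rho$ target, not per rate, so holding them fixed is the
faithful reading. `reproduce_table()` runs the full 48-cell grid of
either reference table (replicates default to 10,000; 2,000 is
recommended for desk-scale runs and is what the package's own
acceptance tests use for a twelve-cell subset, with $10^5$-subject
fidelity checks for the simulator itself). Per-cell seeds are drawn
from the master seed as a fixed `sample.int` stream indexed by cell, so
any subset of cells reproduces independently. Degenerate-variance
replicates are counted and the run errors if they exceed 0.1%.

```{r scenario, eval = FALSE}
run_scenario(scenario(1, m = 10, rate = 0.3, delta = 0.05, rho = 0.1,
                      reps = 2000, seed = 42))
#> n = 210; empirical type-I error ~ 0.05; empirical power ~ 0.81
```

## Known limitations

* Complete single-replicate blocks are required: a missing reading is a
  hard error, never imputed, and repeated readings by the same
  radiologist are not modeled.
* No ordinal or weighted agreement, and no Cohen's kappa — with two
  panels there is no accepted way to judge how close two kappas must be.
* No finite-sample ($t$-based) corrections, no unequal Objective-2
  group sizes, and no two-stage stopping machinery beyond pilot-based
  component estimation.
* Generating raw categorical readings with a prescribed indicator
  correlation structure is under-determined; `simulate_readings()`
  produces i.i.d. categorical fixtures for input/output testing only.
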