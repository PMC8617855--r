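# concord

Design and analysis of multi-reader concordance trials for AI-based
diagnostic imaging devices.

## The problem

Descriptive imaging lexicons such as BI-RADS for breast ultrasound have
no gold standard: there is no "true" value against which an AI-based
reading can be scored. A clinical trial of such a device therefore
evaluates **agreement** — does the device read images the way human
radiologists do? `concord` implements the statistical machinery for two
such study objectives, for trials in which each of *n* subjects' images
is read by one device and a panel of radiologists:

* **Objective 1 (non-inferiority).** Let *p<sub>r</sub>* be the
  concordance rate among *m* radiologists and *p<sub>s</sub>* the rate
  between the device and the radiologists. Since *p<sub>s</sub>* cannot
  exceed *p<sub>r</sub>*, a similarity margin δ₁ > 0 is specified and
  H₁: *p<sub>s</sub>* ≤ *p<sub>r</sub>* − δ₁ is tested against
  *p<sub>s</sub>* > *p<sub>r</sub>* − δ₁ with the one-sided statistic

  Z₁ = √n (p̂ₛ − p̂ᵣ + δ₁) / σ̂₁,  σ̂₁² = n⁻¹ Σᵢ (sᵢ − rᵢ + δ₁)²,

  where rᵢ and sᵢ are per-subject mean agreement indicators. The
  estimators are GEE working-independence estimators and a centered
  robust (sandwich) variance is available as an alternative.

* **Objective 2 (experience comparison).** With *m* senior and *m*
  junior radiologists, the device–senior rate *p<sub>x</sub>* is
  compared with the device–junior rate *p<sub>y</sub>* by the two-sided
  statistic Z₂ = √n (p̂ₓ − p̂ᵧ) / σ̂₂, σ̂₂² = n⁻¹ Σᵢ (xᵢ − yᵢ)².

Because every reading of the same image is correlated, power and sample
size depend on the correlation ρ₁ = corr(rᵢ, sᵢ) (resp. ρ₂ =
corr(xᵢ, yᵢ)), which the package expresses in closed form from the
pairwise *component* correlations of the binary indicators
(ρ<sub>r1</sub>, ρ<sub>r2</sub>, ρ<sub>s1</sub>, ρ<sub>s2</sub>,
ρ<sub>ss</sub> | ρ<sub>xx</sub>, ρ<sub>yy</sub>, ρ<sub>xy</sub>), with
inverse solvers, pilot-data estimators, a correlated-binary simulator
(dichotomized latent Gaussian vectors with exactly matched pairwise
binary correlations), and a Monte-Carlo driver that reproduces the
operating-characteristic tables of the underlying methodology. See the
methods vignette (`vignettes/concordance-trial-design.Rmd`) for the full
model.

## Worked example

Design an Objective-1 trial with m = 10 radiologists, expected
radiologist concordance 0.3, margin δ₁ = 0.05, ρ₁ = 0.1, one-sided
α = 0.05, power 0.8 — then simulate a trial of that size under the
alternative *p<sub>s</sub>* = *p<sub>r</sub>* and test it:

```r
library(concord)

spec <- design1_spec(m = 10, pr = 0.3, delta1 = 0.05,
                     alpha = 0.05, power = 0.8, rho1 = 0.1)
spec$components
#> Objective-1 component correlations (m = 10):
#>   rho_r1 = 0.200966, rho_r2 = 0.100966, rho_s1 = 0.100966, rho_s2 = 0.000966, rho_ss = 0.200966
#>   implied rho1 = corr(r_i, s_i) = 0.100000

(n <- samplesize_objective1(spec))
#> [1] 210                       # unrounded value 209.4441
power_objective1(210, spec)
#> [1] 0.800931

lay <- assemble_layout(1, m = 10, marginals = c(0.3, 0.3),
                       components = spec$components)
trial <- simulate_dataset(lay, n = 210, seed = 1)
test_objective1(trial, delta1 = 0.05)
#> Concordance test, Objective 1: Z1 (one-sided non-inferiority)
#>   n = 210, statistic = 2.78007, critical value = 1.64485 (alpha = 0.05)
#>   estimates: ps = 0.3000, pr = 0.2964, delta1 = 0.0500
#>   variance (null_anchored) = 0.078056, p-value = 0.00272
#>   decision: reject null
```

The solved component tuple rounds to (0.101, 0.001, 0.201, 0.201,
0.101); the required sample size of 210 subjects and the simulated power
near 0.81 match the published design table for this cell. Analysis of
real data starts from a long-format readings CSV
(`subject_id,reader_id,reader_role,classification,value`; see
`inst/extdata/example_readings.csv`) via `indicators_from_readings()`
or, from the shell, the `inst/cli/concord` script:

```sh
inst/cli/concord samplesize --objective 1 --m 10 --rate 0.3 --delta 0.05 --rho 0.1 --power 0.8
inst/cli/concord test --data inst/extdata/example_readings.csv --objective 1 --delta 0.1
```

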