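---
title: "Methods: Bayesian small-area mapping of chronic disease prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian small-area mapping of chronic disease prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(areaprev)
```

This vignette is the package's account of its statistical methods: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices
made where the design was genuinely open, and known limitations. It
states no empirical result that the test suite does not itself compute.

## 1. The problem

Chronic-disease surveillance from administrative health records asks:
after removing the effects of age and sex, which small areas carry
excess disease prevalence, is prevalence trending over time, and do those
trends differ between areas? The raw ingredients are person-level record
streams (insurance registry spells, hospital abstracts, physician claims,
drug prescriptions), small-area census covariates, and an areal map. The
outputs are standardized risk ratios per region(-year), posterior
probabilities of excess risk, and model-comparison evidence for
spatially varying time trends.

## 2. Cohort and case definition

A person is a prevalent case from the earliest date at which they satisfy
one of three evidence patterns: at least one hospital abstract; at least
two physician claims within a rolling window (default five years); or at
least one claim plus two drug prescriptions within the window. Windows
are intervals of `round(365.25 * window_years)` days ending at an event;
the onset date is the date of the event that completes the first
satisfied criterion. Two readings of the published wording exist for the
hospital route; the default treats a single hospital abstract as
qualifying unconditionally (a one-event "combination" is vacuously inside
any window, so the two readings coincide; the flag `hospital_windowed`
exists for auditability). Cases are counted in the prevalence numerator
until censoring by death, emigration, or the 85th birthday (the age
window is `[40, 85)`, matching strata 40–44 … 80–84).

Annual prevalence is point prevalence at a fixed reference date, by
default April 1 (the fiscal-year start), which makes `Y ≤ n` provable
cell by cell: a person counted in the numerator on a date is necessarily
in the denominator on that date. The engine is validated against an
independent combinatorial oracle that enumerates claim pairs and
claim–drug–drug triples directly.

## 3. Standardization

Expected counts use indirect age-sex standardization against the
whole-study-area reference:

\[ E_i = \sum_j \frac{Y_j^{(s)}}{n_j^{(s)}} n_{ij}, \qquad
   E_{it} = \sum_j \frac{Y_{jt}^{(s)}}{n_{jt}^{(s)}} n_{ijt}, \]

with reference totals obtained by summing the cube over regions. Because
the reference is internal, \(\sum_i E_i = \sum_i Y_i\) exactly (and
per-year for \(E_{it}\)); the population-weighted mean standardized ratio
is 1, i.e. the relative-risk baseline is the overall prevalence. For the
spatial model the default pools the final five calendar years, summing
both numerators and denominators (the ratio is invariant to
summing-versus-averaging when the reference is internal). Zero-case
strata contribute rate 0 with no continuity correction, keeping E an
expectation.

One consequence worth knowing: the internal reference couples `E` to the
realized counts (stratum-year totals are conserved exactly). Residuals
`Y/E` are therefore slightly less dispersed than independent Poisson
residuals. This is invisible in estimation but visible to exact
calibration diagnostics — see §7.

## 4. Covariates

The deprivation index is the score vector of a one-factor
maximum-likelihood factor analysis (regression/Thomson scores) of four
standardized census variables; the sign is oriented so the score
correlates positively with the unemployment rate, making larger = more
deprived and the income loading negative. When the correlation matrix is
numerically rank-1 the ML model is degenerate and the first principal
component (its limit) is used. Scores are invariant to affine rescaling
of the inputs and have mean 0 across regions. The Indigenous population
proportion enters the design per 0.1-proportion step, so exponentiated
coefficients read as the RR of a 0.1 increase; the assembly records the
scaling as metadata and cross-checks `exp(0.1 · β_per_unit)` algebra in
the tests. Census covariates are treated as stationary over the study
period. Because a published abstract can mislabel log-scale coefficients
as RRs, `covariate_effects()` always reports both scales explicitly.

## 5. Models and priors

All models are hierarchical Poisson regressions with offset
\(\log E\):

- **spatial**: \(\log\lambda_i = \log E_i + \beta_0 + X_i\beta + v_i + u_i\)
- **st_main**: \(\log\lambda_{it} = \log E_{it} + \beta_0 + v_i + u_i + \gamma_t + \phi_t\)
- **st_interaction**: st_main \(+\ \delta_{it}\)

with \(v_i \sim N(0, \sigma_v^2)\) iid; \(u\) intrinsic CAR with
conditionals \(u_i \mid u_{-i} \sim N(\sum_j a_{ij}u_j/N_i,\,
\sigma_u^2/N_i)\); \(\gamma_t \sim N(0, \sigma_\gamma^2)\) iid;
\(\phi\) first-order random walk; and \(\delta\) Gaussian with precision
\(\tau_\delta\, (K_{space} \otimes K_{time})\). The interaction type is
IV (ICAR × RW1) by default — the fully structured reading of a
Kronecker-product interaction — with types I–III available
(`interaction_type`), since published analyses often leave the type
unnamed. Covariates enter the spatial form only, as in the source
analysis design.

Priors: precisions of all random effects get Gamma(shape 1, rate 0.0005)
(the "logGamma(1, 0.0005)" convention of the INLA-style software family);
a sensitivity option puts Uniform(0, `uniform_upper`) on standard
deviations (default upper bound 10, on the log-RR scale effectively
unbounded). The intercept and regression coefficients get diffuse
Normal(0, 1000). Intrinsic effects are improper, so \(u\), \(\phi\), and
both margins of \(\delta\) are constrained to sum to zero; the sampler
enforces this by recentring each iteration with compensating shifts into
the intercept (and, for \(\delta\), into \(u\) and \(\phi\)), so the
linear predictor is unchanged and the constrained posterior is targeted.

### Inference

Inference is adaptive Metropolis-within-Gibbs MCMC implemented in C++
(single-site random-walk updates for latent terms with their Gaussian
full-conditional priors; conjugate Gamma draws, or truncated-Gamma
inverse-CDF draws under the uniform prior, for variances). Defaults: 4
chains × 5,000 iterations, 2,500 burn-in, thin 1; step sizes adapt
toward ~40% acceptance during burn-in only. Convergence is summarized by
split-\(\hat R\) and a bulk effective sample size for the intercept,
coefficients, and log variances; fits with any \(\hat R > 1.05\) are
flagged with a warning, never silently accepted. All randomness flows
from R's RNG, so a seed fixes every draw bit-for-bit.

Two structural moves matter beyond textbook single-site sampling:

- **Deconfounding move.** A regression coefficient and the ICAR field
  are nearly unidentified along the direction where \(u\) absorbs
  \(\beta(x - \bar x)\). A joint proposal shifts \(\beta\) and
  compensates \(u\) and \(\beta_0\) exactly, leaving the likelihood
  invariant and accepting on the prior ratio. Without it, mixing along
  that ridge is prohibitively slow on smooth covariates.
- **Prior-only mode.** With the likelihood switched off the sampler
  draws the constrained intrinsic fields by exact Gibbs; the sample
  covariance of \(u\) must match \(\sigma_u^2 K^+\) (Moore–Penrose
  pseudo-inverse), which the acceptance suite checks to 10% Frobenius
  error at 50,000 draws.

### A known limitation: spatial confounding

When a covariate is itself spatially smooth (as a deprivation score
tied to a geographic gradient is), the BYM posterior genuinely
attenuates its coefficient: part of \(\beta x\) is absorbed by \(u\),
and credible intervals do not cover the generative value at the nominal
rate. This is the well-documented spatial-confounding behaviour of CAR
models, not a sampler defect — with a spatially unstructured covariate
the same machinery recovers the truth with nominal coverage (the
parameter-recovery acceptance test uses such a covariate; the module
tests pin the GLM limit and prior-only covariance independently).
Substantive coefficients for smooth covariates should be read as
"association conditional on the spatial field".

## 6. Diagnostics

- **DIC** \(= \bar D + p_D\), \(p_D = \bar D - D(\hat\eta)\), deviance
  \(-2\log p(y \mid \lambda)\) evaluated at the posterior mean of the
  linear predictor.
- **CPO** via the harmonic-mean identity
  \(CPO_i = [S^{-1}\sum_s 1/p(y_i\mid\theta_s)]^{-1}\), summarized as
  \(\sum_i \log CPO_i\) (the convention matching published single-number
  "CPO" columns); validated on a conjugate toy against closed-form
  leave-one-out predictives. Draws with vanishing likelihood flag the
  observation as unstable rather than failing silently.
- **PIT** is the *leave-one-out* predictive CDF, estimated by weighting
  each draw with \(1/p(y_i \mid \theta_s)\) (the same identity as CPO),
  randomized for discrete counts:
  \(U_i \sim \text{Unif}(F_i(y_i-1), F_i(y_i))\); the midpoint version is
  available. The plain posterior-predictive CDF conditions on \(y_i\)
  and is center-biased even for a perfectly specified model — measurably
  so at ~400 observations — which is why the cross-validated form is the
  field's convention for this check.
- **Variance partitioning**: empirical variance, across its own index,
  of each posterior-mean effect vector, normalized to percentages
  (intrinsic effects have no proper marginal variance, so hyperparameter
  variances are not comparable across terms; empirical shares are, and
  they sum to exactly 100).
- **Exceedance** Pr(RR > 1) is the fraction of posterior RR draws above
  the threshold; under an RR ≡ 1 world its mean across regions is ~0.5.
- **Moran's I** uses binary contiguity weights (matching the binary
  \(a_{ij}\) in the CAR prior) and a two-sided permutation p-value
  \((1 + \#\{|I_{perm} - E_0| \ge |I_{obs} - E_0|\})/(B+1)\) with
  \(E_0 = -1/(N-1)\); the pipeline applies it to
  \(\log((Y_i + 0.5)/E_i)\), but the operation is generic (the published
  account does not say whether raw ratios or residuals were tested, so
  the choice lives in the pipeline, not the test).

## 7. The synthetic world

The generator produces every input with known truth, at the scale of the
motivating study: a 12 × 8 irregular lattice (96 regions; a fraction of
rook edges removed and diagonal links added, connectivity enforced), 9
five-year age groups × 2 sexes, 18 years, stratum populations log-normal
around a declining age profile (~300 persons per region-stratum by
default), and baseline prevalence rising from ~1% at ages 40–44 to ~25%
(men) / ~15% (women) at 80–84 — a realistic chronic-disease profile
chosen once, not tuned. The Indigenous proportion follows a north–south
logit gradient; four census inputs come from a one-factor model
(loadings 0.8) whose factor correlates with that proportion at a
configurable target (default 0.92, matching the strong collinearity such
covariates show in practice). Counts are drawn from the models
themselves, with constrained intrinsic fields sampled exactly via
eigendecomposition (covariance \(\sigma^2 K^+\)). Person-level records
with qualifying and sub-threshold event patterns exercise the cohort
module; their induced cube matches the intended case statuses exactly
when patterns are unambiguous.

What a green test does **not** establish: real administrative data have
linkage error, coding drift, boundary changes, shadow billing, and
non-stationary covariates — none of which the generator emulates. Counts
are capped at stratum populations (a prevalence cube must satisfy
Y ≤ n); at realistic rates the cap essentially never binds, but extreme
configurations would truncate the Poisson tail.

Two deliberate offset choices in the calibration tests: the PIT and
exceedance checks fix the offset at the generator's true expected counts
(`true_expected_counts()`), because the internally re-standardized E is
coupled to the counts (§3) and mildly center-biases even an oracle's
PIT. Estimation tests use the internal E, as the real pipeline does.

## 8. Numerical choices

- Window arithmetic in days (`round(365.25 · years)`), avoiding
  calendar-month edge cases; birthday arithmetic falls back to March 1
  for February 29 births.
- Eigendecomposition null spaces use a relative tolerance of 1e-9;
  structure-matrix row sums are asserted to 1e-10.
- The truncated-Gamma draw for the uniform-on-sd prior uses inverse-CDF
  sampling with a guard at rank ≤ 1.
- Tie-breaks: onset at the *completing* event (earliest window end), the
  alternative first-event convention being a documented flag decision;
  RR classes use strict interval exclusion of 1.
- Degenerate inputs error early and loudly: islands are rejected by
  every CAR-based operation (the ICAR conditional is undefined at
  \(N_i = 0\)), constant vectors by Moran's I, constant covariate
  columns by the factor analysis, zero-reference strata by
  standardization.
- Pipeline seeds derive from the master seed by small fixed offsets, so
  one integer reproduces every artifact hash; stage manifests are
  append-only with md5 content hashes.

## 9. Scaling of the shipped tests

The acceptance criteria run at reduced sampler settings (1–2 chains,
3,000–8,000 iterations, and a 48-region × 6-year world for the
interaction comparison) so the whole suite completes in a few minutes on
one CPU; thresholds, tolerances, replicate counts, and seeds are as
specified, not adjusted. At these settings the weakly identified
log-variances can show \(\hat R\) above 1.05 — the criteria monitor the
quantities they test (coefficients, DIC, shares, calibration), which mix
well.
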