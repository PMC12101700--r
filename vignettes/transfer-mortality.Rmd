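---
title: "Transferring mortality models to countries without portfolio data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferring mortality models to countries without portfolio data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmort)
```

## The estimation problem

An insurer entering country *M* must price mortality risk with no claims
experience of its own there. What it does have is (a) aggregated portfolio
experience — deaths $D$ and exposure $E$ in life-years per cell of feature
combinations — from $K$ other countries, (b) national population mortality
schedules for all countries including *M*, and (c) public country-level
indicators of insurance-market development and healthcare. `transmort` turns
these into an age–gender (and beyond) mortality schedule for *M*'s insured
population, together with diagnostics for how far the transfer can be
trusted.

The core modelling assumption is multiplicative structure: insured mortality
in any country is the product of a shared global surface over comparable
features (age, gender, national mortality level, …) and a country-specific
adjustment driven by local features and residual idiosyncrasy. The transfer
is then a matter of (i) estimating the global surface on pooled data,
(ii) estimating each source's adjustment, and (iii) deciding how much each
source should speak for the target.

## Country similarity

Similarity is computed entirely from external data, never from the
portfolios. All $K + 1$ indicator vectors (sources plus target) are centred
and scaled jointly — including the target, since the target's position
relative to the source spread is exactly what the index must measure — and
each source gets

$$d_j = \lVert z_j - z_M \rVert_1, \qquad s_j = e^{-d_j} \in (0, 1].$$

The exponential map makes scores comparable and, importantly, provides the
noise scale for synthesis. Resampling weights are $w_j = s_j / \sum_k s_k$.
Two conventions the indicator data force on us: a full age×sex mortality
schedule enters as one scalar item, computed by `age_standardized_rate()` as
the equal-weight mean over (age, sex) cells at the latest common year (a
uniform standard age structure — any fixed structure works, uniformity is
declared); and missing indicator values are a hard validation error rather
than imputed, because an L1 sum silently shifts when a component is invented.
A constant indicator column carries no distance information and is zeroed
with a warning.

## Synthetic portfolio

`synthesize_portfolio()` draws rows from source $j$ with replacement,
probability proportional to row exposure — preserving the marginal
feature–exposure distribution — until the block reaches its quota
$E_{Mj} = w_j \cdot E_M$ of the total $E_M$ (100 million life-years by
default; the last source's quota absorbs the floating-point remainder, and
the last drawn row of each block is trimmed, deaths pro rata, so the quota is
hit exactly). Each block is then perturbed with noise inversely tied to
similarity, $\sigma_j = 1 - s_j + 10^{-6}$:

* metric features: Gaussian noise of sd $\sigma_j$ on the feature's
  standardized (per-source mean/sd) scale, mapped back — $\sigma$ lives on
  the unitless similarity scale, so noise must too; age is clamped to the
  observed age range;
* categorical features: a draw $z \sim N(0, \sigma_j^2)$ keeps the level if
  $|z| \le 1$ (the retention half-width, configurable), otherwise the level
  is redrawn uniformly from the feature's observed levels. At $s = 0$ the
  redraw event has probability $2(1 - \Phi(1)) \approx 0.32$; at $s = 1$ it
  vanishes.

Deaths and exposure are never perturbed — rows are resampled *with* their
claims experience. Finally the population-mortality feature is replaced by
the target's schedule matched on (rounded age, gender), normally the
Lee–Carter one-year-ahead projection (`lee_carter()` + `project_rates()`;
SVD of the age-centred log-rate matrix, first triplet, $\sum_x b_x = 1$,
$\sum_t k_t = 0$ imposed exactly, drift = mean first difference of $k_t$,
fitting window 2008–2018 by default). Zero rates in the window abort with an
instruction to floor them at half the smallest positive rate
(`floor_zeros = TRUE`), since silent flooring would hide data problems.

## Two-stage boosting and the transfer composition

Both model stages minimize Poisson deviance with an offset, via gradient
boosted trees (xgboost). The global model uses
$\log(E \cdot \bar\mu)$ as offset, $\bar\mu$ the pooled deaths/exposure
ratio, so with zero boosting rounds the model *is* the pooled base rate. The
specialized stage re-uses the fitted global model as its offset,
$\log(q(x) \cdot E)$: boosting then learns the multiplicative correction
$h_j(x)$ directly, which makes the composition
$\hat\mu_M = q(x) \cdot h_{j(x)}(x)$ exact by construction rather than an
approximation to a warm start. This offset reading of "initialised from the
pretrained model" is a deliberate design decision: it is the only reading
under which the prediction formula's product form holds identically.

Tuning parameters (`boost_spec()`): 500 rounds, learning rate 0.05, depth 3,
and a 20% holdout (stratified by country) for early stopping, after which
the selected round count is refitted on all rows. Leaf granularity is
governed by exposure, not row counts: `min_child_exposure` (default 1000
life-years) is mapped to the boosting library's hessian floor as
`min_child_exposure × base rate`, because the Poisson hessian in a leaf is
the sum of predicted deaths — a leaf must represent at least the expected
deaths of 1000 life-years at the base rate. Poisson leaf updates use the
library's standard damping (`max_delta_step` 0.7), so a single-leaf,
learning-rate-1 round equals the Newton step
$\sum(D - \mu) / (\sum \mu \cdot e^{0.7})$ — the closed form the test suite
checks. Categorical features are encoded as frozen integer level codes;
an unseen level at prediction time becomes a missing value, which the trees
route by their learned default direction. All randomness (holdout split,
any subsampling) is controlled by the spec's seed; training deviance traces
are stored and must be non-increasing.

## Agreement, uncertainty, drift

Agreement with a reference table is evaluated on (age, gender) cells present
in both tables: Spearman correlation of mid-ranks, uncentred cosine
similarity, and $R^2$ after centring both vectors by their own means. All
three are invariant to a uniform level shift or rescaling — deliberately:
the framework transfers the *shape* of mortality across features, while the
overall level is expected to be calibrated locally from population data.

Uncertainty bands come from a percentile bootstrap that resamples synthetic
rows with replacement within each origin block (preserving the similarity
quotas) and re-aggregates cell rates. Because row-level predictions are
deterministic given the fitted models, re-aggregating resampled rows is
mathematically identical to re-predicting the resampled portfolio — the
implementation exploits this and never refits or re-predicts inside the
loop. Quantiles use the order-statistic definition (R's type 6), the
convention of classical percentile intervals; the interpolating default
(type 7) systematically narrows intervals at bootstrap sample sizes and
measurably under-covers. Default $B = 200$ replicates, percentile method
only — bias-corrected variants are left out for desk-scale runtime.

The drift model reads the remaining discrepancy as a multiplicative ratio
$\delta$ between transferred and reference deaths and decomposes it:

$$\log \delta = \beta_0 + \beta_{\text{age}} x_1 + \dots + \log D_{\text{ref}},$$

a log-link Poisson-deviance GLM with $D_{\text{ref}}$ as offset, fitted by
IRLS to a relative deviance change of $10^{-12}$. The mathematically
equivalent ratio form (response $\hat D_M / D_{\text{ref}}$, prior weights
$D_{\text{ref}}$) is provided and tested to agree to $10^{-8}$. Categorical
features use deviation (sum-to-zero) coding so that $\exp(\beta_0)$ is the
average ratio and each exponentiated effect a deviation from it; with
treatment coding the intercept would be a reference-cell ratio, which is not
how the effects are meant to be read. The implied last level's coefficient
and standard error are reconstructed from the constraint and the coefficient
covariance. Non-integer responses are handled as quasi-likelihood (identical
IRLS estimates); standard errors are reported from the expected information
with dispersion fixed at 1 and flagged as nominal. Age enters banded
(`band_age()`, default decadal) for effect tables — banding is reporting
only; a numeric age column gives a metric slope instead. Main effects only;
no interactions.

## The synthetic world

`generate_world()` produces the fully known ground truth the tests run on:
insured rates $\mu = \text{selection} \times \text{frailty}_j \times
\alpha e^{\beta \cdot \text{age}} \times \text{gender mult.}^{[M]}
\times \text{local effect}$, population rates the same without selection and
local effects, deaths Poisson given exposure, annual improvement
$e^{-0.01 t}$, and indicators built as affine transforms of log frailty plus
noise (7 informative items) together with pure-noise items (6, emulating the
mixed relevance of real indicator sets; 13 items in total). Defaults: 8
source countries, ages 30–69, frailties spread geometrically over
$e^{\pm 0.35}$, selection factor 0.7, gender ratio 1.5, Gompertz
$\alpha = 3\times10^{-5}$, $\beta = 0.09$ — adult insured-mortality
magnitudes a practitioner would recognize; the target's true rates are a
configurable mixture of the sources'. What the generator does *not* emulate:
cohort effects, non-Gompertz age structure (accident humps), reporting lags,
feature measurement error, and correlated indicator noise. Passing tests
therefore demonstrate correctness of the machinery and recoverability under
the stated generative assumptions, not performance on any real market.
`table1_fixture()` is separate: a deterministic eight-country portfolio
whose per-country totals match a published pooled-portfolio overview
(9,412 deaths over 9,116,634 life-years), disaggregated by a fixed
allocation so the totals are bit-stable.

## Experiment sizes and numerical conventions

The test-suite experiments are sized for a desk run: end-to-end recovery
uses a 4-country world with the target copying source 1 and a synthetic
exposure of $10^7$ life-years; the bootstrap-coverage experiment uses a
3-country world with fully informative indicators, source cells of
$1.2\times10^7$ life-years (so that model error is small next to the
synthetic-sampling noise the bands quantify), 50 outer replications of an
$8\times10^9$ life-year synthetic portfolio (≈15–20 rows per age–gender
cell) and $B = 100$; measured coverage of the nominal 95% bands is ~92%.
Remaining conventions: quotas use largest-remainder correction on the last
source; the trimmed row scales deaths pro rata so cell rates are unchanged;
CSV output is comma-separated UTF-8 with `.` decimal and 15 significant
digits, making `load_table(write_table(t))` an identity up to float
representation; ages are modelled on the metric scale throughout and only
banded for reporting; gender is carried as `"F"`/`"M"` strings end to end.

## Limitations

The similarity index is only as good as the indicator set; with mostly
uninformative indicators the scores degenerate towards uniform weights and
the noise scale $\sigma_j \to 1$, heavily corrupting the synthetic rows.
Bootstrap bands quantify synthesis-resampling uncertainty only — model error
from the boosting stages is outside them, which is visible in the coverage
experiment at fine age granularity. The drift model attributes, but cannot
causally explain, residual discrepancy. Level calibration of the transferred
table is explicitly out of scope and must come from local population data or
a reference table.
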