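---
title: "Hyperelastic characterization of skin surrogates: models, protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperelastic characterization of skin surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwskin)
```

## The problem

Human skin is a nonlinear, strain-stiffening material: nearly compliant in a
low-stretch "toe" regime, then rapidly stiffening as collagen engages.
Elastomeric surrogates engineered to mimic skin at specific body sites are
characterized by uniaxial tension tests on clamped coupons (nominally
35 × 10 × 3 mm after clamping). `vwskin` turns the raw machine output of
such tests into constitutive parameters and linear-regime descriptors, and
provides a synthetic generator so the whole chain is verifiable in code.

## Constitutive model

The package uses the Veronda–Westmann strain-energy function, a two-parameter
exponential model widely used for skin:

$$\psi = c_1\left(e^{c_2 (I_1 - 3)} - 1\right) - \frac{c_1 c_2}{2}(I_2 - 3),$$

with $I_1 = \sum_i \lambda_i^2$, $I_2 = \sum_{i<j}\lambda_i^2\lambda_j^2$,
$I_3 = \prod_i \lambda_i^2$. $c_1$ carries stress units (MPa, consistent
with all reported stresses); $c_2$ is dimensionless because it sits in an
exponent. Under incompressible uniaxial extension
($\lambda_2 = \lambda_3 = \lambda^{-1/2}$, so $I_3 = 1$ and
$I_1 = \lambda^2 + 2/\lambda$) the principal Cauchy stress reduces to the
closed form

$$\sigma(\lambda) = 2\left(\lambda^2 - \tfrac1\lambda\right) c_1 c_2
  \left(e^{c_2 (I_1 - 3)} - \tfrac{1}{2\lambda}\right).$$

Two conventions deserve comment, since index notation for the second
invariant is ambiguous ($i<j$, $i\neq j$, or unrestricted) and
incompressibility is an assumption rather than a given:

* **$I_2$ is the unordered-pair sum** (three terms), the standard second
  invariant. With this convention, and only with it, the closed form above
  is *exactly* $\lambda\, d\hat\psi/d\lambda$ of the energy restricted to
  the incompressible path.
* **Incompressibility is assumed**, as is conventional for elastomers and
  soft tissue. Both choices are certified rather than asserted: the package
  ships a model-agnostic finite-difference oracle
  (`uniaxial_stress_numeric()`, central differences with relative step
  $10^{-6}$ — a balance of truncation against round-off in double
  precision) and the tests require agreement with the closed form to a
  relative $10^{-6}$ over the whole catalog and stretch grid. At exactly
  $\lambda = 1$ the closed form is zero by construction while the finite
  difference carries only round-off ($\sim 10^{-9}$ MPa), so the identity
  point is compared absolutely.

## The seven-step preprocessing protocol

`preprocess_pipeline()` applies, in order: slack trimming, yield
truncation, origin shifting, engineering→true conversion, polynomial
trendline fitting, grid standardization, and stretch conversion. The spots
where the protocol needed sharper definitions than "trim", "yield", or
"standardize" are:

* **Slack boundary.** The slack region ends at the last *strictly negative*
  load preceding the first sustained run (≥ 5 samples) of positive loads;
  everything up to and including that sample is removed, including positive
  noise blips inside the slack region. A genuinely zero load at the tension
  onset is kept — it is the origin sample. Negative loads *after* sustained
  tension indicate grip failure and raise a data-quality error instead of
  being trimmed silently.
* **Yield point** is the global load maximum, tie broken to the earliest
  index. This is parameter-free and correct for elastomer rupture records,
  which rise monotonically and then fail.
* **Origin shift** subtracts the first remaining sample from both axes; the
  small machine preload (< 0.1 N) used to take up slack is thereby removed
  implicitly, with no separate preload parameter.
* **Trendline abscissa.** The degree-5 trendline regresses true stress on
  *engineering strain* $\lambda - 1$ (recovered exactly from log strain via
  $\varepsilon_{eng} = e^{\varepsilon_{true}} - 1$), i.e. on the same
  standardized stretch axis the trend is later resampled on. Regressing on
  log strain instead degrades the polynomial approximation at low stretch
  by an order of magnitude (measured 1.3–3.5% vs ≤ 0.2% across the catalog
  pairs), which would swamp the toe-region stresses. `fit_poly_trend()`
  retains an `x` argument for the log-strain variant.
* **Standardized grid.** Resampling targets the stretch grid
  $\lambda \in [1.00, 2.00]$, step 0.01 (101 points, bit-reproducible from
  its `(start, stop, step)` settings), equivalently
  $\varepsilon_{eng} \in [0, 1]$. A literal true-strain range of 1–2 would
  correspond to $\lambda \approx 2.7$–$7.4$, beyond any tested stretch, so
  the stretch reading is the coherent one. Grid points outside the fitted
  strain domain are clipped with a warning, never extrapolated.
* **Stretch conversion.** The default mode uses the exact identity
  $\lambda = 1 + \varepsilon_{eng} = e^{\varepsilon_{true}}$; a
  `paper_literal` mode applies $\lambda = 1 + \varepsilon$ to whichever
  strain array is present, for reproducing legacy arithmetic where
  $1 + \varepsilon_{true}$ was used.
* **$R^2$ conventions.** Trendline $R^2$ below 0.95 warns (the protocol's
  quality band is 0.95–1) but does not error; constant observations define
  $R^2 = 0$ with a warning, since they admit no explained variance.

## Fitting

`fit_veronda_westmann()` minimizes unweighted squared residuals in
true-stress–stretch space (the space the protocol produces) with bounded
Levenberg–Marquardt. Defaults: start $(c_1, c_2) = (10, 0.25)$ — near the
centre of the catalog coefficient cloud — and bounds
$c_1 \in (10^{-6}, 10^3)$ MPa, $c_2 \in (10^{-6}, 10)$. Because the stress
law is linear in $c_1$, a failed or non-converged start triggers a
deterministic multi-start over five log-spaced $c_2$ values with the
closed-form profiled $c_1$; the best residual sum of squares wins, and a
still-unconverged result is returned flagged with a warning. Linearity in
$c_1$ also yields an exact scale equivariance (scaling all stresses by $k$
scales $c_1$ by $k$ and leaves $c_2$ fixed), which the tests assert to
$10^{-6}$.

## Tissue metrics

`tissue_metrics()` reports the slope of true stress vs $\lambda - 1$ over
the toe window $\lambda \in [1.0, 1.1]$ (`e_low`), over the terminal 10% of
the stretch range ending at the maximum-stress point (`e_high`), and the
maximum true stress (`uts`). The windows are conventions — no standard
exists — so they are fully configurable and every output row carries the
windows used. The terminal window is anchored at the *last* stretch
attaining the maximum so plateaued curves keep a non-degenerate window.
Modulus columns are in MPa by consistency with the stress units.

## The synthetic generator

`synth_raw_record()` emulates the raw records the protocol was designed
for: a slack segment (default 20 samples over 0.5 mm) whose loads are
negative half-normal readings with 0.02 N scale — a slack coupon carries no
tension and the load cell reads slightly below zero — followed by a loading
branch mapping $\lambda \in [1, 2]$ (300 samples, the $\lambda = 1$ sample
carrying exactly zero load at the tension origin) through the inverse of
the preprocessing conversions, with multiplicative Gaussian load noise
(default CV 3%, chosen multiplicative because load spans orders of
magnitude over a test), and a rupture tail (10 samples decaying
geometrically by 15% per sample — enough to exercise the yield trimmer; it
is not meant to be physical). Ground-truth constants default to
$(13.1, 0.21)$, the catalog's control-composition pair. Optional geometry
jitter draws width and thickness uniformly within the printed manufacturing
tolerances (9–11 mm, 2.8–3.1 mm). Spec + seed determine the record
bit-for-bit.

The generator requires a positive slack-noise scale whenever slack is
enabled: an exactly-zero slack shelf would be indistinguishable from the
tension origin, and the trimmer would (correctly) keep it.

What the generator does *not* emulate: viscoelasticity and strain-rate
dependence, anisotropy (Langer lines), machine compliance, temperature or
humidity effects, and multi-layer tissue structure. Passing tests therefore
demonstrate correctness of the analysis chain under the stated noise model,
not robustness to every artifact of real testing-machine data.

## Numerical behaviour and known limitations

* **End-to-end identity.** For artifact-free synthetic records the full
  pipeline reproduces the generating model curve with max relative error
  $5 \times 10^{-4}$ on $\lambda \in [1.05, 1.95]$ (default constants);
  polynomial approximation error dominates at the edges. The error grows
  with $c_2$: across the catalog pairs it ranges from $4.6\times10^{-4}$ to
  $2.0\times10^{-3}$ ($c_2 = 0.33$). A degree-5 polynomial is simply a
  limited basis for strongly exponential curves; raise `poly_degree` if
  low-stretch fidelity matters more than protocol fidelity.
* **Noise-induced biases.** Under 5% load noise, Monte-Carlo over the full
  generate→preprocess→fit path (100 replicates per catalog pair) shows
  pooled parameter bias under 1% and RMSE under 5% for both constants. Two
  metrics inherit small noise-proportional systematic biases: UTS is biased
  low (≈ −4% at 5% noise) because yield truncation cuts at the *noisy* load
  peak, which typically occurs slightly before the true terminal stretch;
  the toe modulus is biased high (≈ +3%) by trend smoothing of the toe.
  Repeatability tests therefore centre noisy batch means within
  max(2 SE, noise CV × truth) of the reference rather than 2 SE alone.
* **Problem sizes.** The test suite and the acceptance script use 100
  replicates per catalog pair for Monte-Carlo checks, 36-specimen
  repeatability batches, and 300-sample records — sizes at which the
  stochastic summaries are stable to well within their asserted margins
  while the whole suite runs in well under a minute.
* **Scope.** Only the Veronda–Westmann model is fitted; the neo-Hookean
  model exists solely as a closed-form fixture for the stress oracle.
  Compositions absent from the catalog are not interpolated — no
  composition–property model is claimed. Fracture/toughness metrics are out
  of scope (the surrogates do not fracture like natural skin).

## Catalog notes

The bundled tables (checksum-guarded CSVs under `inst/extdata/`) transcribe
the tested compositions: 23 four-part batches, and 11 site compositions
with their fitted constants. Ratio notation "3:7" is parsed as part A = 3,
part B = 7 wt %; the first two numeric columns are the soft (Shore 00-10)
elastomer parts and the last two the stiff (Shore 30A) parts, the reading
consistent with the in-bounds compositions (46–57 wt % of 30A part A).
Every quadruple sums to 100 wt %. Site locations are stored as integers
1–11; the source assigns them to back regions and Langer-line orientations
only in prose, so no name mapping is bundled.

## Worked pipeline

```{r example, eval = FALSE}
rec <- synth_raw_record(synthetic_spec(seed = 42))
curve <- preprocess_pipeline(rec)
fit <- fit_veronda_westmann(curve)
glance(fit)
tissue_metrics(curve)
autoplot(fit)
```
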