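---
title: "Models and methods behind nanorad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanorad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanorad)
```

## The scientific question

Titanium dioxide nanomaterials (NMs) are photocatalytic: incident photons
above the band gap generate reactive oxygen species. If cells of healthy
tissue are contaminated with such particles and then exposed to
therapeutic ionizing radiation, the particles might amplify the
radiation's cytotoxicity. `nanorad` packages the statistical machinery
needed to ask that question quantitatively from three standard assays —
flow cytometry (particle uptake and cell death), automated fluorescence
microscopy (growth), and qPCR (oxidative-stress markers) — and, at its
core, a formal test of whether the combined NM + radiation kill exceeds
what two *independently acting* agents would produce.

## The synergy model

### Independent action as the null

Let `p_NM(d)` be the mortality caused by the nanomaterial alone at
surface dose `d`, and let `q` be the *conditional* kill of irradiation
alone — the probability that a cell which would have survived untreated
dies because of the radiation. From the untreated controls,

```
q = (p_IR_ctrl − p_NI_ctrl) / (1 − p_NI_ctrl)          ir_impulse()
```

If the two agents kill independently (Bliss independence), combined
survival is the product of single-agent survivals:

```
p_sim(d) = 1 − (1 − p_NM(d)) (1 − q)                   transfer_impulse()
```

Mapping every non-irradiated response through this formula yields a
*simulated* irradiated dose–response curve (`simulate_ir_curve()`): the
expected outcome in the absence of any interaction. Treating the
radiation kill as a single dose-0-derived impulse transferred onto each
NM condition is an interpretive choice — it is the only reading of
"adding the radiation response to each NM condition" that requires no
extra parameters — and it is deliberately exposed as its own function
rather than buried in the pipeline.

### The LL4 backbone

Both the simulated and the observed irradiated curves are summarised by
a four-parameter log-logistic model

```
f(d) = lower + (upper − lower) / (1 + (ed50/d)^shape),   f(0) = lower
```

with `lower` the baseline mortality, `upper` the plateau at saturating
dose, `ed50` the half-effect dose and `shape > 0` the steepness. This
parameterization is algebraically the classical 4PL but with the slope
sign fixed for increasing mortality curves, which removes a fitting
ambiguity. Dose 0 enters through the analytic limit `f(0) = lower`, so
control wells are ordinary data points.

Fitting (`fit_ll4()`) is bounded least squares: Levenberg–Marquardt on
`(lower, upper, log ed50, log shape)` with asymptotes boxed to `[0, 1]`,
from a heuristic start (extreme responses as asymptotes, interpolated
half-response dose as `ed50`, shape 1) plus four seeded random restarts.
Unweighted least squares on fractions is used because per-well event
counts are typically equal by design; a flat response is returned but
flagged `degenerate`. Replicated noise-free recovery and a noisy-recovery
suite (Gaussian noise, sd 0.02 on the mortality fraction) are part of
the test battery; the noisy criterion is a median `ed50` error under 15%
across 100 seeded replicates.

### The coefficient-distance score

Synergy is scored as the Euclidean distance between the two fitted
coefficient vectors, by default `(lower, upper, log ed50, shape)`
(`coefficient_distance()`). The log on `ed50` stops the half-effect
dose's units from dominating the norm; raw coefficients
(`log_ed50 = FALSE`) and user-supplied coordinate scalings (e.g.
bootstrap standard errors) are available because the choice of scale is
not canonical. The distance is unsigned, so `synergy_call()` attaches a
direction: the sign of the mean per-dose difference (observed −
simulated) over nonzero doses — positive when the observed combined kill
exceeds the independent-action prediction (synergy), negative when it
falls short (antagonism, or simple saturation when the NM alone already
kills most cells).

No analytic null distribution exists for this statistic, so the package
calibrates it by simulation: `null_synergy_distribution()` generates a
world with interaction coefficient 0, re-runs the whole scoring path,
and returns the signed scores; the 95th percentile of their absolute
value is the recommended "indistinguishable from zero" tolerance.

## The synthetic world

The generator exists to validate the analysis: it produces data with the
same statistical structure the assays assume, with known ground truth.

* **True mortality.** `p = 1 − (1 − p_NM(d))(1 − q·IR)(1 − s·p_NM(d)·IR)`,
  with `s` the interaction coefficient (`synergy_coeff`). `s = 0` makes
  independent action hold *exactly*, which is what null calibration
  requires; `s > 0` adds a conditional kill that scales with the NM dose
  response, so interaction grows with dose, as a photocatalytic
  mechanism would.
* **Anchors.** The default NM-alone curves are anchored at the measured
  72 h and 7 d single-agent mortalities at the top dose (e.g. 27.95%
  for non-coated TiO2 at 64 µg/cm² and 72 h; 60% at 32 µg/cm² for the
  double-coated material, whose toxicity saturates within 24 h), and the
  4 Gy kill is 25.5% at 72 h and 63.4% at 7 d. Values the assays did not
  report — the non-irradiated baseline mortality (set to 5%), the
  24/48 h anchors, the curve plateaus (0.90–0.92) and shapes (1.8–2.5) —
  are this package's assumptions, chosen once for monotone-in-time
  realism, and are *not* measured values.
* **Cytometer channels.** Log-normal baselines with a multiplicative
  SSC shift (default 2.5×) for the particle-laden fraction, whose size
  follows the saturating uptake curve `u(d) = d/(d + 12 µg/cm²)`.
  DiOC6(3) and PI are drawn from well-separated log-normal high/low
  populations; the apoptotic fraction of non-live cells declines with
  time (0.7 − 0.0025·t, floored at 0.15) to mimic the apoptotic-to-dead
  progression of the double-negative state.
* **Growth fields.** Nuclei are Gaussian blobs (σ = 2 px) on a dark
  noisy background, placed by rejection sampling with a minimum
  separation of 6.5 σ so that, with zero overlap, segmentation can
  recover the count exactly. Expected counts follow exponential growth
  (0.69/day ≈ a 24 h doubling time) saturating at a per-field carrying
  capacity (default 120 nuclei — confluence, and also what a field can
  hold without overlap), attenuated by `(1 − mortality)`;
  `carrying_capacity = Inf` gives pure exponential growth. Per-field
  counts are Poisson draws of the expectation and the placed count is
  stored as ground truth.
* **qPCR.** HMOX1 Ct decreases with a stress score that ramps in over
  24 h and grows with relative dose, irradiation, and their product;
  NQO1 and TXNRD1 are flat by default, and the reference gene is stable.
  Technical noise is Gaussian in Ct space.
* **Seeds.** One master seed; each sample uses
  `(master + 99991·counter) mod (2³¹ − 1)` so stages are independently
  reproducible and two equal-seed runs are bit-identical.

What the generator does **not** emulate: spectral spillover and
compensation, debris and doublets, cytometer saturation, illumination
gradients and focus drift in microscopy, qPCR efficiency below 2, or
plate-position effects. Tests passing on this world therefore validate
the *statistical pipeline*, not robustness to those instrumental
artifacts.

## Gating and classification choices

* The SSC threshold is the type-1 empirical quantile of control SSC
  (smallest value with CDF ≥ target): deterministic and exactly
  invertible on continuous data. Targets default to 70% SSC-low for
  non-irradiated and 60% for irradiated controls, re-derived per
  timepoint, because irradiation itself alters granularity.
* PI takes precedence over DiOC: a PI+ event is dead no matter its DiOC
  signal.
* Mortality is `1 − live`, counting the apoptotic quadrant as death.
  The quantification the assay reports as "% of cell death" does not
  unambiguously state this; it is a documented convention here, and the
  `death_fractions` object keeps all three states so the alternative is
  one subtraction away.
* Dye thresholds are either explicit or placed at the density valley
  between the two modes of the log-intensity distribution; the valley
  rule refuses unimodal input (secondary mode below 5% of the primary,
  or valley above half the lower peak) rather than inventing a gate.

## Nucleus counting

`count_nuclei()` rescales the image to `[0, 1]` (making the count
invariant to positive intensity rescaling), smooths with a Gaussian
(σ = 2 px), thresholds (Otsu by default), labels 8-connected components
and discards those below 20 px. There is no watershed: two nuclei closer
than the smoothed resolution merge into one object, a limitation pinned
by a dedicated fixture test. Images are (row, col)-indexed from the
top-left.

## Statistics

Welch's unequal-variance t-test is used for all mortality contrasts, in
two families: each irradiated condition against its non-irradiated
counterpart (`*` stars), and each NM dose on irradiated cells against
the irradiated untreated control (`#` stars). No multiple-testing
correction is applied by default, matching the assay's convention of
reporting per-comparison significance; Benjamini–Hochberg within family
is available (`adjust = "BH"`) for users who want familywise control.
qPCR fold changes use 2^−ΔΔCt with efficiency fixed at 2 and
normalization to the untreated non-irradiated control of the same
timepoint; the reference gene must be named (the generator uses a
designated stable gene, GAPDH by label).

## Problem sizes and numerical choices

The validation suites run at sizes chosen to make sampling error
negligible relative to the tolerances they assert: event-level recovery
at 10⁵ events (binomial SD ≈ 0.15 percentage points), null calibration
with 200 seeded replicates at 10⁴ events/well, detection power with 100
replicates. Null calibration and power suites draw per-well mortality
directly as `Binomial(n, p_true)/n` — the exact sampling distribution of
classifying a simulated event table of that size — while one end-to-end
test exercises the full event path. The power scenario uses
`synergy_coeff = 0.8`, which puts the combined mortality 12 percentage
points above the null at the top dose; the design criterion is a `+1`
sign call in at least 95% of replicates whenever that excess reaches 10
points.

Degenerate inputs are handled explicitly rather than silently: flat
dose-responses are flagged, `ed50` of a flat curve errors, empty event
tables error, a constant SSC column warns, an all-background image
counts zero, and a protective irradiation contrast (IR control below NI
control) is rejected because the impulse model does not cover it.

## Worked example

```{r example, eval = FALSE}
ref <- reference_mortality()
q <- ir_impulse(ref$p_ir_alone / 100, 0)
pred <- 100 * transfer_impulse(ref$p_nm_alone / 100, q)
cbind(ref[c("nm_type", "timepoint_h", "p_observed")],
      predicted = round(pred, 2))
```

At 72 h the observed combined mortalities of the three single-coated
materials exceed their independent-action predictions — the synergy
signature — while at 7 days (and for the double-coated material, whose
own toxicity saturates the assay) the prediction meets or exceeds the
observation.

## Known limitations

* The impulse-transfer null needs trustworthy dose-0 controls; with
  noisy controls, uncertainty in `q` propagates into the whole simulated
  curve and is not currently accounted for in the distance.
* The coefficient distance mixes parameters with different geometric
  meaning; two fits can be close in curve space yet distant in
  coefficient space (and vice versa) when the design gives little
  information about a parameter. The per-dose deltas in
  `synergy_call()` are the model-free cross-check.
* Counting without watershed undercounts crowded fields; the generator's
  zero-overlap default makes the validation exact but real confluent
  images will need the declared `overlap_rate` stress tests and caution.
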