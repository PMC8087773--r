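---
title: "Models and methods: retinal sensitivity fitting and synaptic puncta quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: retinal sensitivity fitting and synaptic puncta quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinasens)
library(dplyr)
```

retinasens analyses two kinds of retinal data — flash-evoked electrical
responses (electroretinogram, ERG, and single-rod photocurrents) and
two-channel confocal images of synaptic staining in the outer plexiform
layer (OPL) — and ties them together with the paired-ratio statistics used
to compare wild-type (WT) and knockout (KO) littermates. Every stage is
driven by a synthetic-data generator with complete ground truth, so the
whole chain is verifiable at desk scale. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic data do and do not establish about real recordings.

## Response models

**B-wave saturation.** The B-wave (the corneal-positive ERG deflection
dominated by ON-bipolar cells) saturates hyperbolically with flash
intensity $I$:

$$ B/B_{max} = \frac{S_B I}{1 + S_B I} $$

where $S_B$ is the sensitivity — the inverse of the half-saturating
intensity — and $B_{max}$ the saturating amplitude. The experimental
protocol measures two flashes (a dim and a saturating one; scotopic
defaults 0.00022 and 0.011 cd·s/m²), and with two measurements the law
inverts algebraically: it is linear in reciprocal coordinates,
$1/B = 1/B_{max} + 1/(B_{max} S_B I)$. `fit_saturation()` uses the exact
two-point inversion when given two points and bounded nonlinear least
squares for more; the two routes agree to machine precision on consistent
data (a property test asserts the equivalence against a Newton-type
least-squares oracle).

**Rising phase of the photoreceptor response.** The activation phase of
the A-wave and of rod photocurrents follows a delayed
Gaussian-exponential:

$$ A(I, t)/A_{max} = 1 - \exp\!\left(-S_A I (t - t_d)^2\right) $$

with a fixed transduction/recording delay $t_d$. `fit_rising_phase()`
fits one $(S_A, A_{max}, t_d)$ triple jointly across all flash
intensities of an eye or rod. Windowing conventions differ by modality:

* **ERG A-wave** — from $t_d$ after the flash to the response maximum,
  or to 5 ms before the maximum when the rise lasts longer than 5 ms.
  That sentence admits two readings; we implement "end 5 ms before the
  maximum" as the default (`rule = "end_before_peak"`) and "cap the
  window at 5 ms length" as `rule = "cap_length"`. Default $t_d$ bounds
  3.4–4.4 ms.
* **Rod photocurrent** — a fixed 60 ms window; flashes are much dimmer,
  so the rise is slow. We start the window at $t_d$ (configurable to
  start at the flash); default $t_d$ bounds 14–17 ms.

ERG traces are stored corneal-positive and the A-wave segment is negated
before fitting (the A-wave is corneal-negative); photocurrents are stored
response-positive.

**Optimization.** The delay enters the model through a kink
(`pmax(t - t_d, 0)`), and flash intensities can span five decades; joint
gradient descent in all three parameters reliably stalls in a local
optimum with $t_d$ pinned at a bound. We therefore *profile* the delay:
for fixed $t_d$ the conditional $(S_A, A_{max})$ fit — log-parameterized
for conditioning and multistarted over deterministic decade factors — is
well behaved, and the profiled residual sum of squares is minimized over
the bounded 1-D delay by a 5-point grid plus golden-section refinement,
followed by a full joint polish. On noise-free synthetic families the
fit recovers parameters to ~1e-15 relative error; the package-wide
round-trip tests require 1e-6 and the headline acceptance checks 0.1%.

## Filtering and oscillatory potentials

The analysis conventions are 6th-order Butterworth filters: 22.5 Hz
low-pass for B-waves and rod photocurrents, 1 kHz low-pass for A-waves,
and a 75–300 Hz band-pass for oscillatory potentials (OPs). Because peak
*times* feed the windowing rules, filtering is zero-phase by default.
Numerically, running a 6th-order recursive transfer function forward and
backward is ill-conditioned at 22.5 Hz on 5 kHz sampling (relative cutoff
0.009; errors of order 1% appear even on constant input), so the
zero-phase path applies the exact Butterworth magnitude-squared response
$|H|^2 = 1/(1 + w^{2n})$ in the frequency domain — the ideal
forward-backward filter — with constant end-padding of two cutoff periods
against wrap-around transients. The causal single-pass mode
(`zero_phase = FALSE`) keeps the classical recursive digital design and
has exactly −3 dB gain at a low-pass cutoff; filter linearity holds to
machine precision in both modes.

The OP amplitude is measured on the band-passed saturating-flash
response, inside the B-wave rising phase (flash to B-wave peak of the
22.5 Hz trace): consecutive negative-then-positive peak pairs are
located, and the amplitude is the positive minus the negative peak value,
normalized by $B_{max}$. Which oscillation cycle represents "the"
OP is a reporting convention with no operational definition; we take the
largest swing by default (`pick = "largest"`), with the first complete
cycle as the alternative. This choice is explicit and configurable
because it is genuinely open.

## Image quantification

A section is a two-channel confocal z-stack: a punctum-marker reference
channel (mGluR6 proxy, marking ON-bipolar dendritic tips) and a target
protein channel (e.g. RGS7 or Gβ5). The pipeline
(`quantify_section()`):

1. **ONL normalization** — every channel is divided by the mean of its
   outer-nuclear-layer annotation, putting intensities in units of the
   non-specific background; all downstream quantities are then invariant
   to rescaling a slide.
2. **OPL mean** — the z-averaged ROI (default geometry 105 × 7.5 µm,
   0.3 µm/slice) is thresholded at the background level; by default the
   background is also subtracted (value − 1) and thresholded pixels count
   as zeros in the denominator, so the statistic is zero for a blank
   section and scales linearly with staining. Both choices are exposed
   because the published description fixes only the threshold.
3. **Detection** — strict 26-neighbour local maxima in the 3-D ROI
   volume of the reference channel. Plateaus yield no maximum: this is
   the literal reading and keeps detection deterministic.
4. **Tip mask** — pixels of the z-averaged reference image above the
   background threshold, with components smaller than 2 × 2 pixels
   removed. The published procedure does not specify the mask
   construction; this reconstruction is deliberately minimal and its
   threshold multiplier and minimum size are configurable.
5. **Classification** — by the horizontal extent of the mask component
   through the maximum: at most 0.5 µm on each side of the centre → rod
   tip; more than 1.1 µm in total → cone tip patch; anything between
   satisfies neither criterion and is excluded. Extent is measured along
   the OPL-parallel axis because cone patches are horizontally elongated.
6. **Window sums** — per channel, the sum of background-subtracted
   values over a 1.1 × 1.1 µm window (nearest odd pixel count) centred
   at the maximum, averaged per class.

## Paired-ratio statistics

Staining comparisons between littermates use a two-step normalization —
each slide's mean to 1, then each WT/KO pair's mean to 1 — followed by
the jackknife bias-corrected ratio: with pairs $(x_i, y_i)$,

$$ r = \frac{\sum y_i}{\sum x_i}, \quad
   r_i = \frac{\sum_{j \ne i} y_j}{\sum_{j \ne i} x_j}, \quad
   r_c = n r - \frac{n-1}{n} \sum_i r_i $$

with $s^2 = \frac1n \sum (r_i - r)^2$ and
$s_c^2 = \frac1{n-1} \sum (r_i - r_c)^2$. The correction removes the
$O(1/n)$ term of the ratio-estimator bias, leaving $O(n^{-2})$ or less.
Two empirical notes from our Monte-Carlo verification are worth
recording. First, the bias of $r$ comes entirely from denominator
randomness, so a simulation in which KO noise is purely multiplicative on
the same section intensities ($y_i = R\,x_i e_i$) produces an *unbiased*
$r$ — bias studies need independent noise on both members
(`sim_paired_samples(structure = "independent")`). Second, for
log-normal noise the $n^{-2}$ coefficient is nearly cancelled by the
distribution's third moment (it is $\propto \mathrm{cv}^6$), and the
corrected bias actually crosses zero near $n = 4$; the corrected
estimator is *better* than $n^{-2}$ there, and slope measurements of the
decay are meaningful only on the asymptotic range ($n \ge 8$). The test
suite measures the decay with a Rao-Blackwellized, antithetic,
control-variate Monte-Carlo for that reason.

Hypothesis tests: paired Student's t for littermate designs; Welch's t
from summary statistics (mean, SEM, size) with Satterthwaite degrees of
freedom and the two-sided p evaluated through the regularized incomplete
beta function $I_{v/(v+t^2)}(v/2, 1/2)$; a double-difference Welch test
on four log-scale summaries for ratio-of-ratios comparisons (unknown
multiplicative factors cancel; the log base does not affect p);
Pearson and Spearman correlations with the t-transform p-value on
$n - 2$ degrees of freedom (average ranks for ties). All p-values are
two-sided; no multiple-testing correction is applied, matching the
source analyses — callers see raw p-values and the count of tests.
Degenerate inputs (zero SEMs, zero-variance differences) are rejected or
flagged explicitly rather than regularized.

## The synthetic-data generator

The generator emulates the *structure* of the study, with effect sizes
in the regime the analyses were built for:

* **ERG cohorts** (`sim_erg_cohort()`): 7 littermate pairs by default,
  two eyes per mouse, one dim and one saturating flash per eye at 0.2 ms
  sampling; KO sensitivity scaled by a configurable factor (default 1.5)
  with identical amplitude distributions; an oscillation (75–300 Hz,
  default 120 Hz) rides the saturating-flash rising phase, optionally
  coupled to sensitivity. Mouse- and eye-level parameters are log-normal
  with unit mean (cv 0.15 and 0.07), so the KO/WT expectation ratio
  equals the configured factor exactly.
* **B-wave kinetics**: the saturation law constrains only the peak, so
  the waveform is a gamma-function rise
  $(t/t_{pk})^k e^{k(1-t/t_{pk})}$ scaled to the law's amplitude — only
  the peak and rising phase matter downstream.
* **Rising-phase traces** follow the activation model exactly, zero
  before $t_d$, with optional plateau capping for the unmodelled
  recovery.
* **Confocal stacks** (`sim_confocal_stack()`): 0.1 µm pixels, 0.3 µm
  slices; an OPL band with truncated-Gaussian puncta (rod σ 0.12 µm,
  footprint ≈ 0.29 µm/side; cone σx 0.55 µm, ≈ 1.35 µm/side — both
  sides of the classification cutoffs with ≥ 2-pixel margins) and an ONL
  band of pure background. Centres are placed with guaranteed separation
  larger than the quantification window, so ground truth is unambiguous;
  infeasible requests fail rather than degrade. The OPL background
  equals the ONL background, so strict thresholding removes it exactly
  and noise-free pipelines are exact. Matched pairs
  (`sim_stack_pair()`) share placements and amplitudes, with the KO
  target channel scaled by the effect ratio (default 1.4, the regime of
  the staining comparisons this emulates).
* **Seeding**: one root seed; per-object streams derived
  deterministically; a fixed configuration reproduces outputs
  bit-identically, and generators restore the caller's RNG state.

What passing tests show — and do not. On synthetic data the pipelines
are *exact*: detection equals ground truth, classification is 100%
correct, noise-free KO/WT ratios equal the configured effect exactly.
Real recordings add eye blinks and drift, scattering and
depth-dependent attenuation, chromatic offsets between channels,
overlapping and irregular puncta — none of which the generator models
(registration, deconvolution and artifact rejection are out of scope).
The synthetic closure therefore validates the *computations*, not the
robustness of the conventions to real-world artifacts.

## Problem sizes and numerical defaults

The test suite runs cohorts of 2–7 pairs, stacks of 25–105 µm ROI width
with 3–24 puncta, Monte-Carlo blocks of 10⁴–10⁵ replicates, and the
acceptance round trips use three flash intensities per modality
(2/8/32 R*/rod; 0.05/1/1000 cd·s/m²) — sizes chosen so the whole suite
exercises every stage in about a minute and a half on one core while
keeping Monte-Carlo error far below every asserted margin. Convergence
tolerances are 1e-15 (relative) on least-squares cost, 1e-12 on the
profiled delay; ties in maxima detection are broken by coordinates;
rectangle annotations are half-open in pixel space so abutting regions
never share pixels.

## Known limitations

* The tip-mask construction and the OP cycle choice are reconstructions
  of under-specified procedures; both are flagged and configurable.
* TIFF round trips are exact only to 32-bit float precision.
* The Welch implementation takes summary statistics, not raw samples, by
  design (matching how such results are reported); it cannot check
  normality.
* The supplementary non-parametric test mentioned alongside the original
  comparisons is not described in the available text and is not
  implemented.
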