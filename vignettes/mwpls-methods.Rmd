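---
title: "Moving-window PLS wavelength selection: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving-window PLS wavelength selection: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mwpls)
```

`mwpls` implements interval selection and calibration for quantitative
NIR monitoring of fermentations: PLS-1 regression, moving-window PLS
residue lines (MWPLSR), the searching-combination interval optimizer
(SCMWPLS), Savitzky–Golay second-derivative pretreatment, and ISO
12099-style validation, together with a synthetic spectra generator that
reproduces the multi-batch study design the methods are meant for. This
vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic data can and cannot tell
you about real spectra.

## The calibration model and its assumptions

The spectroscopic premise is Beer–Lambert linearity: absorbance at each
channel is (approximately) a linear mixture of constituent contributions
plus baseline and noise, so a linear calibration

$$ y = \mathbf{X} b + e $$

relating mean-centered spectra to an analyte concentration is
appropriate. PLS-1 fits this by extracting successive latent variables
maximizing covariance with $y$. For a single response the NIPALS weight
per factor has the closed form $w \propto \mathbf{X}'y$; the
implementation deflates $\mathbf{X}$ only, so the fit is fully
deterministic and reproducible bit for bit. No variance scaling is
applied anywhere — NIR channels share units, and autoscaling would
inflate noise channels.

Centering is recomputed inside every fit: every moving window, every
sub-interval candidate, and every cross-validation fold. (For column
subsets of one sample set this equals subsetting a once-centered matrix,
which the hot paths exploit; for cross-validation folds it genuinely
changes the numbers, and the leave-one-out engine recenters per fold.)

Latent-variable counts are selected in two different situations with two
different rules:

* **Published models** use leave-one-out cross-validation
  (`loo_rmsecv()`): the chosen count is the smallest $k$ whose RMSECV is
  below that at $k+1$ — the first local minimum. If the curve never
  rises the global minimizer is taken, with a warning, since the curve
  gives no better guidance.
* **Inside the interval search** (`max_lv_for_region()`), where a
  cross-validation per candidate would be prohibitive and the published
  rule is qualitative ("stops improving appreciably"), the cap is the
  smallest $k$ at which the relative RMSEC improvement falls below
  `rel_improvement` (default 0.02, exposed in the configuration). Every
  candidate in a search step is then compared at
  $k = \min(\text{cap}, \text{channels}, n-1)$, which prevents the
  degenerate "more latent variables always win" behaviour that raw RMSEC
  comparison would invite.

## The two-stage interval search

**Stage 1 — MWPLSR.** A window of `H = 20` channels (window size must
exceed the latent-variable ceiling of 10, and 20 points at 8 cm⁻¹ spans a
typical NIR band) slides across each contiguous segment; per position the
log₁₀ of the sum of squared calibration residues is recorded for
$k = 1 \dots 10$, giving ten residue lines. Log base 10 is used so the
magnitudes quoted for residue plateaus (≈ 2.3 for SSR ≈ 200) read
naturally. Windows never bridge the gap left by an excluded region.

**Detection.** Informative regions are contiguous runs of window
positions whose residue at `lv_ref` latent variables falls below the
`quantile_threshold` quantile of that line, expanded to the union of the
contributing windows. Defaults: `lv_ref = 3` (the typical dimensionality
of a small-molecule fermentation matrix) and `quantile_threshold = 0.25`.
The quartile was chosen because residue-line distributions on realistic
data are bimodal — informative valleys against a signal-free plateau —
and a median cut admits plateau windows that merely fluctuate low. Note
that a quantile threshold *always* selects about that fraction of
positions; on pure noise the result is scattered, not empty, which is why
detection output should be inspected (or supplied manually via
`informative_regions(..., regions = )`, the reproduction path for
hand-picked regions).

**Stage 2 — SCMWPLS.** Within the first region every sub-interval (all
widths, all positions — `w_min`, `w_max`, `stride` default to the
exhaustive search; anything else is an approximation) is fitted, and the
smallest-RMSEC interval becomes the base. Each further region is scanned
in combination with the base, *including the empty interval* so that a
region can be discarded outright, and the winning combination becomes the
new base.

Open points the implementation had to settle:

* **Processing order.** The default (`order_policy = "wavenumber"`)
  visits regions high-to-low, matching how region lists are written. The
  alternative `"rmsec"` visits them by ascending own-region RMSEC, i.e.
  best first. The greedy procedure can never drop the *first* region (the
  base stage has no empty candidate), so an outcome in which only a
  mid-spectrum region survives is only reachable under quality ordering —
  worth remembering when a single-interval result is expected.
* **Tie-breaking.** RMSEC ties within 1e-12 prefer fewer channels, then
  the higher starting wavenumber: parsimony first, and a deterministic
  result regardless of enumeration order.
* **Cap monotonicity.** The per-step latent-variable cap never decreases
  across combination steps. The empty candidate is therefore always
  assessed with at least as many factors as the previous accepted step,
  which guarantees the accepted-step RMSEC trace is non-increasing.
* **Retention behaviour.** Because the objective is in-sample RMSEC,
  adding a sub-interval almost always helps a little once the cap allows
  it, so the optimizer tends to *keep* a (possibly narrow) piece of most
  regions offered to it rather than discarding them. With strongly
  co-varying constituents — ethanol rising as sugars fall — intervals
  belonging to a correlated constituent are genuinely informative and are
  legitimately retained. Users wanting minimal interval sets should
  present fewer, tighter detected regions rather than expect the
  combination stage to prune aggressively.

The search kernels are compiled (RcppArmadillo). Sub-interval candidates
are evaluated in sample space through the kernel matrix
$\mathbf{M} = \mathbf{X}_S\mathbf{X}_S'$, grown by rank-one updates as a
window widens; the $k$-factor fitted values are the projection of $y$
onto the Krylov space $\mathcal{K}_k(\mathbf{M}, \mathbf{M}y)$, computed
with a re-orthogonalized basis. This is algebraically identical to NIPALS
PLS-1 but costs $O(k n^2)$ per candidate independent of interval width,
which is what makes the exhaustive enumeration practical. The test suite
cross-checks it against brute-force enumeration built on the plain NIPALS
fitter, and the final model of every search is refit from scratch and
must reproduce the trace RMSEC to 1e-10.

## Preprocessing

The second-derivative pretreatment is a Savitzky–Golay filter (local
polynomial order 2, window 7 points — the window length is the "number of
smoothing points") applied per contiguous segment, after the saturated
detector band is excluded, so that no derivative window mixes values
across the physical gap. The derivative is taken with respect to channel
index; the $1/\Delta\tilde\nu^2$ factor is omitted deliberately because
centred PLS calibration is invariant to a global positive scaling of
$\mathbf{X}$, and channel-index scaling matches common chemometrics
software. The edge policy is trim: $(w-1)/2 = 3$ channels are dropped at
each segment end rather than extrapolated. On the standard 949-point
acquisition grid, excluding 5248–4984 cm⁻¹ leaves segments of 786 + 129
channels, and trimming leaves 780 + 123 = 903; this 903-point contract is
asserted in the tests. (Published whole-region tabulations sometimes
quote 901 points for derivative-treated spectra; the two-point difference
is not reproducible from any stated trimming convention, and the package
documents its own arithmetic instead of chasing it.)

## Validation statistics

`evaluate_model()` reports R², RMSEC/RMSEP, SEP (the bias-corrected
standard error, denominator $n-1$), bias, RPD = SD/RMSEP, and the
ISO 12099 confidence limits

$$ T_b = t_{1-\alpha/2,\,n_e-1} \cdot \mathrm{SEP}/\sqrt{n_e}, \qquad
   T_{UE} = \mathrm{SEC} \cdot \sqrt{F_{1-\alpha}(\nu, M)} $$

with $\nu = n_e - 1$ and $M = n_{cal} - k - 1$. Two points deserve
flagging. First, $T_{UE}$ uses the square root of the $F$ quantile (the
ISO 12099 form); tabulations that drop the radical are not reproducible
from their own inputs, and this package does not attempt to match them.
Second, $n_e$ (`n_effective`) is caller-supplied, defaulting to the
number of test predictions: when replicate subsamples of one sampling
event share a single reference value, the number of *events* (33 in the
default design: 99 spectra / 3 subsamples) is the defensible count of
independent observations, and published limits consistent with 33 rather
than 99 confirm that practice. The verdicts use strict inequalities
(SEP < T_UE, |bias| < T_b), so a degenerate all-zero-error comparison is
rejected rather than accepted by convention.

## The synthetic fermentation generator

The generator exists so that every stage — preprocessing, residue lines,
interval search, validation — runs against data with known ground truth
under the study design the methods target: three independent fermentation
batches, each sampled on 11 days × 3 events × 3 subsamples = 99 spectra,
two batches (198 spectra) for calibration and one (99) for testing.

* **Kinetics.** Daily mean concentrations over the 11 days (ethanol 0.06
  → 10.76 %, TSS 23.70 → 10.25 °Brix, TA 0.29 → 0.46 %, TVA 1.30 → 1.80
  × 10⁻³ %) are linearly interpolated at the sampling times; a logistic
  parametric mode is available. Within-day events sit at +0, +3 and +6 h
  (three samplings, then an 18 h gap); day-10 events past 240 h hold the
  final value — fermentation has plateaued — and times further out are
  errors.
* **Spectra.** Absorbance is a Gaussian-band mixture: water (constant
  concentration) with its strong ~6900 cm⁻¹ band and the ~5100 cm⁻¹
  combination feature that drives detector saturation; ethanol bands in
  the C–H first-overtone (5976–5500 cm⁻¹) and combination (4504–4250
  cm⁻¹) windows plus weaker 8400/6800 cm⁻¹ features; sugar bands at
  7056, 6400, 5610 and 4400 cm⁻¹; citric and acetic acid bands
  overlapping the majors with amplitudes small enough that the acids sit
  near the noise floor — the low-SNR regime that makes acid calibration
  hard in practice. Band amplitudes are absorbance per unit
  concentration for a ~2 mm transflection path.
* **Instrumental effects.** Per spectrum: multiplicative scatter (sd
  0.01), baseline offset (sd 5 × 10⁻³ AU) and slope (sd 10⁻⁵
  AU/channel), additive channel noise (sd 10⁻³ AU), and hard clipping at
  2.5 AU inside 5248–4984 cm⁻¹ only. Subsamples share their event's
  concentrations but draw independent instrumental effects.
* **Batch effects.** Each batch draws one log-normal multiplicative
  factor per analyte (sd 0.02), so the test batch is genuinely out of
  calibration — prediction errors include a bias component, as they do
  across real fermentation runs. A consequence worth stating: the
  *ranges* of an i.i.d. test batch are not guaranteed to nest strictly
  inside the calibration ranges (that event has probability ~1/3 per
  analyte end under exchangeable batches); nesting holds, and is tested,
  up to a 3-sigma batch-effect margin.
* **Seeds.** All randomness flows from one integer seed; batch seeds are
  derived from it, and identical seeds reproduce spectra bit for bit.

**What passing tests on this generator do and do not show.** They show
the machinery is correct: residue lines equal direct per-window fits, the
search equals brute-force enumeration, planted single-region signals are
localized, noiseless mixtures are recovered exactly, and selected-interval
models predict an independent batch no worse than whole-region models.
They do not show that selected regions isolate one constituent's bands on
real data: the tabulated kinetics make ethanol and sugars almost
perfectly (anti)correlated within a batch, so sugar intervals carry real
ethanol information and the optimizer retains them — selected ethanol
regions overlap the planted ethanol bands but also cover co-varying sugar
bands, holding the Jaccard overlap with the ethanol-only ground truth
near 0.5. Real studies show the same signature (published ethanol
selections span sugar and water regions); breaking the confound would
require experimental designs that decorrelate the analytes, not a better
optimizer. The generator also omits temperature effects, CO₂ bubble
artefacts, wavelength-dependent scatter curvature and reference-method
error.

## Degenerate inputs and numerical conventions

* Regions are closed intervals on an exact 8-divisible grid; no snapping
  is performed, and misaligned endpoints are errors naming the offender.
* Index spans are 1-based and inclusive at both ends, mirroring the
  closed wavenumber intervals.
* A segment narrower than the derivative window, a window size not
  exceeding the latent-variable ceiling, zero-variance responses, and
  empty region sets for the combiner are all errors; segments narrower
  than the moving window are skipped with a warning.
* NIPALS stops early when the residual covariance norm falls below
  1e-13 of its initial scale; RMSEC paths are padded with their last
  value so they remain monotone and well-defined.
* Problem sizes in the test suite (and the simulation counts behind the
  stochastic properties: 20 seeds for recovery rates, 10 for noise
  monotonicity) were chosen so the whole suite runs in about a minute on
  one core; they are stated in the tests themselves.

## Known limitations

* The greedy combination stage optimizes in-sample RMSEC; it is not a
  sparsity method and will keep marginally helpful intervals
  (see *Retention behaviour* above).
* `T_UE` depends on a calibration-error estimate; with very small RMSEC
  the limit is tight and a test batch with its own batch effect can
  legitimately fail the SEP criterion while predicting well in RMSEP
  terms. This is a property of the acceptance statistic, not a defect.
* The JCAMP-DX support is the fixed-abscissa `(X++(Y..Y))` subset, one
  spectrum per file; compressed ordinate encodings and multi-block files
  are out of scope.
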