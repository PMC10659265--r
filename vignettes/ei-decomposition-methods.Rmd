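---
title: "Compartmental decomposition of electrical images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental decomposition of electrical images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eidecomp)
```

## The model

The electrical image (EI) of a neuron recorded on a dense multielectrode
array (MEA) is the mean spatiotemporal voltage footprint of its spikes: a
`T x N` matrix `X` of mean spike-triggered voltages over a window around
the spike time (by default 3 ms before to 6 ms after at 20 kHz, so
`T = 180` with the spike at sample 60) on `N` electrodes. Every electrode
sees a superposition of stereotyped contributions from the cell's
compartments: a fast biphasic somatic spike (strong early negative peak),
a slower biphasic dendritic return current (strong early positive peak),
and a narrow triphasic axonal spike that propagates away from the soma.

`eidecomp` models each electrode's trace as a nonnegatively weighted,
integer-circularly-shifted superposition of `C = 3` learned basis
waveforms shared across electrodes:

$$
\min_{B,\,A \ge 0,\,\tau}\;
\frac12 \sum_{n=1}^{N} \Big\| \textstyle\sum_{c} A_{cn}\,
S_{\tau_{cn}} B_{c} - X_{:,n} \Big\|_2^2
\;+\; \lambda_L \sum_{n} \big( \|A_{\{s,d\},n}\|_2 + |A_{a,n}| \big)
\;+\; \frac{\lambda_P}{2} \sum_{c} (B_c - \mu_c)^\top K_c\, (B_c - \mu_c)
$$

where `S_tau` is the circular shift by `tau` samples, the `L2,1` group
penalty uses groups {soma, dendrite} and {axon} so whole compartment
groups vanish on electrodes without signal, and the Gaussian shape prior
pulls each learned waveform toward a stereotyped mean `mu_c`. The
precision matrices `K_c` are radial basis function kernels over the sample
times with length scale 250 microseconds (5 samples at 20 kHz) plus a
1e-6 diagonal jitter, which keeps the waveform update full rank even when
a compartment is never observed.

Assumptions worth stating explicitly: each compartment contributes at most
once per electrode (cells with self-crossing axons or several distinct
spike shapes violate this); shifts are integer samples with circular
(mod T) convention, which is harmless because the window's leading and
trailing samples are near zero; and amplitudes are nonnegative because
they represent physical contributions of cellular compartments.

The factorization has a per-compartment scale ambiguity
(`B_c -> s B_c, A_c -> A_c / s`); [canonicalize_decomposition()] fixes the
convention (unit peak waveforms) before cross-cell comparisons.

## Fitting

The objective is non-convex and is minimized by alternating two descent
steps ([fit_decomposition()]):

1. **Amplitudes and shifts, basis fixed** ([fit_amplitudes_shifts()]).
   Electrodes are independent. For a candidate shift combination the
   amplitude subproblem is convex and is solved by FISTA with constant
   step `1 / ||D'D||_2` and proximal operator equal to projection onto the
   nonnegative orthant followed by groupwise soft-thresholding; the
   composition is *verified against independent oracles in the test
   suite* (a smoothed box-constrained quasi-Newton solver and a literal
   projected-subgradient run) rather than assumed. The exported solver
   iterates to a fixed-point tolerance of 1e-10 (cap 10000 iterations; the
   per-iteration change understates the distance to the optimum, so the
   tolerance sits below the accuracy required of the solution); a looser
   1e-8/300 setting scores shift candidates, and the winning combination
   gets a tight 1e-12/5000 polish.

2. **Basis waveforms, amplitudes and shifts fixed** ([fit_waveforms()]).
   Circular shifts are diagonal in the Fourier domain, so the data term
   couples compartments within each frequency while the shape prior
   couples samples within each compartment; the normal-equation blocks of
   the data term are circulant (block `(c, d)` is a weighted sum of shift
   matrices with offsets `tau_d - tau_c`), which the implementation
   exploits when assembling the single `(C T) x (C T)` linear system. The
   update is exact; it is checked against an explicit time-domain
   normal-equations oracle built from dense shift matrices.

Both steps are descent steps — the previous shifts are always among the
candidates and the previous per-electrode solution is retained whenever
the new one is not an improvement — so the recorded objective trace is
non-increasing; this is asserted (relative tolerance 1e-9) in the tests.
Convergence is declared when the relative objective decrease falls below
1e-6 (default cap 50 alternations). The fit is deterministic given its
inputs; no randomness enters the optimization.

### The shift search

The per-electrode search over shift combinations deserves its own note,
because the obvious schedule fails. A blind coarse grid (stride 8 per
compartment) ranks candidates by an objective that is *flat* between the
narrow correlation peaks of spike waveforms, so its survivors are
arbitrary and refinement around them cannot recover. The implemented
schedule ([shift_search()]) therefore:

* augments the (sparse) grid with the best `n_corr = 12` shifts per
  compartment by matched-filter correlation between the compartment
  waveform and the electrode trace;
* adds matching-pursuit multi-starts: compartments are introduced one at a
  time (all 6 orders), each at the shift maximizing its correlation with
  the *residual* of the already-selected compartments — this rescues weak
  compartments masked by strong superimposed ones;
* evaluates all candidate combinations, keeps the best `n_keep = 10`,
  refines by stride halving (4, 2, 1) around survivors, then polishes each
  survivor with coordinate-exhaustive sweeps (each compartment swept over
  its whole range holding the others fixed);
* finally runs a bounded-budget pairwise lattice sweep on the winner,
  which escapes "label swap" optima in which one compartment impersonates
  another's peak — a failure mode that no sequence of single-compartment
  moves can cross.

An exhaustive mode scores every combination and is used as the oracle in
tests: on 100 random three-compartment toy problems (`T = 32`) the
schedule attains the exhaustive objective to within a 1e-9 relative
tolerance on every instance. Per-compartment shift windows can be
narrowed (e.g. small perisomatic lags for soma/dendrite, forward
propagation delays for the axon) purely as a speed optimization.

### Hyperparameters

No reference values for the regularization weights are published, so the
defaults are heuristic and exposed: `lambda_l` defaults to 0.05 times the
median per-electrode peak voltage ([default_lambda_l()]) and
`lambda_p = 1` in units where the prior means have unit peak.
[sweep_hyperparams()] refits over a (log-spaced) grid of both weights, the
standard sensitivity analysis. The kernel length (250 us) and the EI
window are fixed by convention, and all are configurable.

## Downstream inference

**Somatic and dendritic centers.** The somatic center is the
amplitude-weighted centroid of the largest-amplitude somatic electrode and
its six nearest neighbors (all available neighbors near edges); the
dendritic-field center is the amplitude-weighted centroid of electrodes
above a threshold fraction (default 0.1; the published procedure states
only "a threshold") of the maximum dendritic amplitude.

**Receptive fields.** [sta_rf_center()] reduces a spike-triggered average
to a center and diameter: pixels are significant when their peak |z|
exceeds 4 (noise SD estimated from frames preceding the STA peak; the
published significance rule is unstated), the time course is the mean over
significant pixels, the intensity map is the per-pixel regression onto
that time course, and the center is the intensity-weighted centroid. The
diameter is the equivalent-circle diameter of the half-maximum significant
region — parameter-free, at the cost of mild bias for non-Gaussian
profiles. [rf_prediction_fit()] compares affine maps from somatic centers
alone versus somatic plus dendritic centers to measured RF centers; errors
are in-sample ("fit quality") and normalized by the mean RF diameter. The
two models are nested, so the richer one never fits worse; the quantity of
interest is the size of the improvement, which grows with the true
soma-to-dendrite offsets. Electrode-to-stimulus registration uses RANSAC
([ransac_affine()]) for robustness to boundary outliers, refit by least
squares on the consensus set.

**Dendritic mosaics.** Per-cell dendritic amplitude profiles (elementwise
maxima over spike-sorting oversplits, [merge_oversplits()]) are deposited
on a raster (default 6 um), blurred with a 54-um Gaussian, and
max-normalized. A single shared threshold maximizing the uniformity index
(UI; the fraction of the recording area covered by exactly one contour) is
selected from 99 uniform levels, ties toward the lower level.
Significance of mosaic coordination uses a rotation null (default
N = 250): each field is rotated about its amplitude centroid by an
independent uniform angle and the mosaic re-contoured; `p` is the fraction
of null UIs strictly exceeding the observed UI. With N draws the smallest
resolvable nonzero p is 1/N, so a reported 0 means p < 1/N; the report
includes the conservative upper bound `(k + 1)/(N + 1)`. One
implementation subtlety is load-bearing: rotating the *blurred surface* by
interpolation smooths the null draws but not the observed surface, which
measurably biases p downward. The null draws therefore rotate the
underlying electrode amplitude deposits (exact, since the Gaussian blur is
isotropic and commutes with rotation) and re-run the identical
deposit-snap-blur pipeline; deposits leaving the raster are discarded.
Calibration holds only when fields' sampled support lies inside the array
— fields truncated by the array edge are not exchangeable with their
rotations, a property of the data rather than of the test.

**Cell-type classification.** Features per cell are the three aligned
basis waveforms (principal zero-crossing for soma/dendrite, absolute
minimum for axon, landmark at `T %/% 2`; no temporal rescaling)
concatenated with the three compartment amplitude L2 norms z-scored within
each preparation — 543 features at `T = 180`. The classifier is a small
feed-forward network: three hidden layers of 25 ReLU units with batch
normalization and a 4-way softmax ("four layers" read as hidden plus
output — the conventional count; the width and depth are configurable),
trained with cross-entropy for 30 epochs, batch size 32, Adam at the
standard 1e-3 learning rate (unstated in the source procedure), batch-norm
statistics frozen at evaluation. Training is reproducible given a seed.
Evaluation is leave-one-preparation-out ([leave_one_out_eval()]):
four-way accuracy, class-weighted one-vs-rest AUROC, parasol-vs-midget
coarse accuracy/AUROC, and ON/OFF accuracy/AUROC within parasols and
within midgets using the conditional ON probability given the coarse
class. For separability analyses, [logistic_separability_auroc()] reports
*training-set* AUROC of a linear logistic classifier on single-compartment
waveforms, and [amplitude_norm_auroc()] scores fixed anatomy-derived
decision rules (parasol norms exceed midget norms; ON norms exceed OFF
norms) without refitting, so values below 0.5 are reported as-is.

**Sensitivity to EI signal-to-noise.** [snr_accuracy_trend()] refits
decompositions to EIs emulating 100 / 1000 / 10000 recorded spikes (EI
noise scales as `1/sqrt(n_spikes)`) and scores each held-out preparation
with the leave-one-out network trained once on the other preparations'
full-spike-count decompositions — the classifier is not retrained per
noise level, so the trend isolates feature degradation.

## The synthetic-data generator

No recordings are distributed with the package; every analysis is
validated on synthetic data with known ground truth, generated by the
`synthesize_*` family. What it emulates, and what it does not:

* **Templates** ([stereotyped_templates()]): difference-of-Gaussians
  parameterizations of the three compartment waveform classes, normalized
  to unit peak. The lobe widths keep the three shapes well separated
  (worst-case residual after optimally scaling and shifting one template
  onto another is ~0.6-0.9 of its norm): with nearly anti-collinear
  somatic/dendritic shapes the factorization itself becomes
  unidentifiable, which would test nothing about the fitting machinery.
  Real waveform classes are clearly distinct in the same sense.
* **Cells** ([synthesize_cell()]): phenomenological spatial amplitude
  kernels (Gaussian around the soma, sigma 35 um; anisotropic Gaussian
  disk around the dendritic center; exponential lateral decay, 45 um, from
  a straight axon path starting 120 um from the soma — the proximal
  initial segment contributes little extracellular signal, and the gate
  keeps somatic and axonal contributions temporally distinct), axonal
  delays equal to arc length over a 1 m/s conduction velocity rounded to
  samples, and a hard support floor (amplitudes below 5% of the
  compartment maximum are absent) so the ground truth is well-posed.
  These are not cable-equation or volume-conductor simulations: passing
  recovery tests shows the inverse solver works when the signal model
  holds, not that the signal model describes tissue.
* **Cohorts** ([synthesize_preparation_set()], default 29 preparations):
  per-type waveform morphs (lobe width/ratio changes) and amplitude scales
  (parasol ~2x midget somatic/dendritic norms, ON ~1.3x OFF), chosen to
  emulate the separability regime reported for real recordings (strong
  parasol/midget norm separation, moderate ON/OFF overlap); lognormal
  per-preparation time scale (6%) and gain (20%); per-cell waveform noise
  (8% of peak) and lognormal norm variability (30%); type-dependent
  dendritic offsets (midgets ~45 um, parasols ~15 um from the soma,
  mirroring the anatomical observation that midget dendritic fields are
  more displaced). [typed_records()] emulates decomposition output
  directly from this ground truth for cohort-scale classification tests;
  [decompose_preparation()] runs the real EI -> decomposition -> feature
  path and is used for the SNR analyses, so both routes are exercised.
* **Recovery benchmark** ([synthesize_recovery_ei()]): every compartment
  substantially observable on every electrode (amplitudes uniform in
  50-200 uV, shifts uniform, noise 5% of the somatic peak). Parameter
  recovery is a property of the solver; a spatially realistic cell leaves
  many electrodes at the noise floor where amplitude attribution is
  inherently ambiguous, so solver correctness is benchmarked where it is
  identifiable.
* **STAs** ([synthesize_sta()]): separable space-time Gaussian-by-biphasic
  profiles, sign-flipped for OFF types.

All generators are deterministic given a seed; changing the seed changes
noise draws, not the study conditions.

## Numerical choices and degenerate inputs

* Spikes whose windows overrun the recording are dropped, never
  zero-padded (padding biases the mean).
* Electrode coordinates are centered at the array centroid; no community
  standard fixes an origin, and centering conditions the affine fits.
* An all-zero basis row forces its amplitude to zero with a warning; an
  unobserved compartment with `lambda_p = 0` raises a rank error, and
  during alternation its waveform is reset to the prior mean.
* Shift-combination ties break toward the lexicographically earlier
  candidate; threshold ties in mosaic contouring break toward the lower
  level; "greater UI" in the rotation p-value is strict, so ties count
  against significance.
* EIs and fits serialize to a JSON text container with full floating-point
  precision; round-trips are bit-exact.

## Problem sizes in the shipped tests

The test-suite experiments run at desk scale, chosen so each check
measures what it claims with comfortable margins: the recovery benchmark
uses 64 electrodes at `T = 180`; search-vs-exhaustive comparisons use
`T = 32` toys where exhaustive enumeration is exact; mosaic calibration
uses 200 independent mosaics of 5 cells with 250 null rotations each; the
classification cohort uses 29 preparations of 24 cells; and the SNR trend
uses 5 preparations of 8 cells at `T = 120` on a 37-electrode array.

## Known limitations

* One shift and one amplitude per compartment per electrode: cells with
  crossing axons or multiple spike shapes need a richer model.
* Fractional (sub-sample) shifts are not fitted.
* In-sample RF prediction errors measure fit quality, not generalization;
  a cross-validated variant is a straightforward extension.
* The rotation null is calibrated for fields away from array boundaries;
  edge-truncated fields are intrinsically non-exchangeable with their
  rotations.
* Classification numbers on synthetic cohorts are properties of the
  pipeline under the generator's effect sizes, not predictions of
  real-data performance.
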