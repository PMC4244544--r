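---
title: "Quantitative rest/acetazolamide CBF SPECT: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative rest/acetazolamide CBF SPECT: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cbfspect simulates and analyses a complete multicentre quantitative
brain-perfusion SPECT study: dual administration of an
I-123-iodoamphetamine-like tracer in a single session (rest scan, then a
vasodilator challenge with acetazolamide, then a second injection),
quantitative reconstruction to absolute Bq/mL, autoradiographic table look-up
to cerebral blood flow (CBF), cross-scanner resolution equalization, and
nonparametric inter-institution statistics. Everything runs on synthetic
data: the package contains the digital phantoms, the tracer-kinetic and
acquisition simulator, and the full estimation chain, so each analysis step
can be validated against a known ground truth.

## The kinetic model

Tissue tracer concentration follows a one-tissue compartment model,

$$\frac{dC_t}{dt} = f\,C_a(t) - \frac{f}{V_d}\,C_t(t),$$

with `f` the flow per mL of tissue (mL/min/mL), `C_a` the arterial
whole-blood input (Bq/mL) and `V_d` the distribution volume, fixed at
35.0 mL/mL. Perfusion is reported as CBF in mL/min/100 g through the tissue
density 1.06 g/mL: `CBF = 100 f / 1.06`. `tissue_tac()` integrates this ODE
with an exact exponential integrator and trapezoidal quadrature of the
driving term on a 1-s internal grid; against closed-form solutions (constant
and exponential inputs) the error is below 0.1%.

The arterial input is a fixed population shape — a gamma-variate first pass
peaking at 1.2 min plus a biexponential whole-blood tail (time constants 12
and 90 min, weights 0.85/0.10/0.05, 180 Bq/mL per MBq administered) — scaled
linearly by dose. The shape's parameters are package constants chosen to
give realistic peak (~20 kBq/mL at 122 MBq) and 10-min (~2 kBq/mL) levels;
published population curves for this protocol are not available, so the
curve is a documented stand-in. Because the whole chain is linear in the
input, only its shape (not its absolute level) influences recovery accuracy,
and each simulated subject's curve is re-calibrated from a single 10-min
blood sample exactly as the estimator prescribes.

## Autoradiographic look-up and the dual-table procedure

For a calibrated input, `build_lookup_table()` tabulates the window-mean
tissue activity predicted by the model on a flow grid (0 to 1.2 mL/min/mL in
steps of 0.001, covering >110 mL/min/100 g); the table is strictly
increasing, so `invert_lookup()` maps activity back to flow by linear
interpolation with a unique answer. Window means rather than sums make
tables frame-duration invariant. Activities above the table maximum clamp to
the maximal flow and are counted; negative activities are an error.

The first-scan estimation (`compute_rest_cbf()`) anchors the global scale on
the 24–28 min frame — the timing least sensitive to input-shape variation —
by inverting the gray-matter mean activity with a 24–28 min table, then
rescales the 0–28 min table's activity axis (bisection on [0.2, 5],
tolerance 1e-4) until the gray-matter mean of the pixelwise inverted CBF
matches that global value. Note that the consistent axis scale *decreases*
as the target global CBF grows. Pixelwise look-up, a 7-mm Gaussian
smoothing filter, and extra-cranial masking (voxels outside the attenuation
mask are zeroed, so accumulation outside the head cannot bias the scaling)
complete the rest CBF image.

The second scan (30–58 min) contains the residue of the first injection.
`predict_background()` continues the model per voxel with the rest-phase
flow and subtracts that predicted background from the second-scan window
mean before a second table look-up (`compute_acz_cbf()`), using a table
built for the second injection's input and window and the same axis scale as
the rest table. Cerebrovascular reactivity is
`CVR = 100 (CBF_acz - CBF_rest) / CBF_rest`; it is invariant to any common
multiplicative calibration error of the two CBF images.

## Quantitative reconstruction

The reconstruction chain mirrors a quantitative SPECT package:

1. **Outline and attenuation map.** Filtered back-projection without
   corrections, thresholded at a fraction of the robust (99th percentile)
   maximum; the largest connected component is closed and hole-filled and
   receives the uniform coefficient 0.160 cm^-1, the conventional
   brain-plus-skull average for I-123. The threshold is object-dependent (in
   clinical practice it is tuned per study): the default 0.5 traces a
   blurred uniform edge at half maximum and is right for calibration
   cylinders; heads use 0.10 so the faint scalp rim — and with it skull and
   scalp — falls inside the mask. This choice matters: a mask that misses
   the skull under-corrects attenuation by tens of percent.
2. **Scatter and septal penetration.** Transmission-dependent convolution
   subtraction: the local scatter fraction is
   `SF = 1 - 1/(A - B t^beta)` with `t` the chord transmission factor
   forward-projected from the attenuation map (defaults A = 2, B = 1,
   beta = 0.5), and the scatter estimate is the offset-corrected projection
   convolved with a unit-area mono-exponential kernel (40 mm decay length).
   High-energy septal penetration is an essentially uniform background,
   modelled as 3% of the mean observed counts. The simulator adds scatter
   as the self-consistent fixed point of the same model, so on noiseless
   data the correction is exact up to the attenuation-map approximation;
   the parameters are per-profile configuration.
3. **Geometric-mean OS-MLEM.** Opposed views are combined bin-wise as
   geometric means. The product of opposed attenuation factors is the
   full-chord transmission, and the residual distributed-source factor is
   handled by correcting the measured geometric mean with the model ratio
   (unattenuated projection / geometric mean of attenuated projections)
   evaluated for a source model: for a uniform source in the mask this is
   exactly the classical conjugate-view factor `sqrt(T) sinh(x/2)/(x/2)`,
   and one self-consistency refinement (re-evaluating the ratio at the
   smoothed first-pass reconstruction) removes the bias that arises because
   the skull attenuates but does not emit. EM then runs with the
   unattenuated projector: 3 iterations over 5 angle-interleaved subsets,
   uniform positive initialisation inside the mask, neutral update for rays
   with zero estimated counts, and a 7-mm Gaussian post-filter. Output is
   non-negative by construction.
4. **Calibration.** The Becquerel calibration factor (BCF) is measured on a
   simulated syringe of known activity; because reconstruction conserves
   counts, the effective mean (image total over source volume) is used so
   that spill-out does not bias the factor. The well-counter
   cross-calibration factor (CCF) comes from the uniform 16-cm cylinder.
   Dividing by the acquisition duration and multiplying by BCF yields Bq/mL
   independent of frame length.

The projector is rotate-and-sum with bilinear interpolation; each view's
rotation is materialised once as a cached sparse matrix, so back-projection
(the transpose) is the exact adjoint — the inner-product identity holds to
machine precision, which makes the EM machinery safe by construction.

## The phantoms and what the simulator does (and does not) emulate

The brain phantom is a two-slice numerical head: a cerebral slice with
scalp (5 mm), skull (9 mm), a convoluted cortical gray-matter mantle, a
white-matter core and deep nuclei, and an infratentorial slice with pons,
vermis and cerebellum. True attenuation is heterogeneous — skull
0.230 cm^-1 over brain/scalp at 0.146 cm^-1 (water at 159 keV) — with the
geometry chosen so the head-averaged chord stays within ~2% of the uniform
0.160 cm^-1 the reconstruction assumes; the uniform-mu approximation is
therefore genuinely exercised, at about its clinical severity. Truth values
are CBF 35.7/51.7 mL/min/100 g (gray, rest/acetazolamide) and
25.8/34.3 (white), the group means of the multicentre normal cohort this
design reproduces; scalp receives a token 9 mL/min/100 g so the head
outline is detectable, as it is clinically.

Compartments are drawn generously large relative to clinical SPECT
resolution (the cortical mantle is 20–40 mm thick, not 3 mm). This is a
deliberate validation-phantom choice: the package's recovery claims concern
the kinetic estimator, and partial-volume dilution is a scanner property
that the resolution module measures separately. For the same reason the
canonical gray-matter region for global CBF is the *cortical core*
(`gm_core_mask()`, the gray mask eroded by 8 mm): boundary voxels diluted by
the point-spread function are excluded. Parameter-recovery validation runs
at the highest-resolution profile (institution C, 10.26 mm); at the
17.13-mm scanner the same code runs but partial volume, not kinetics,
dominates the full-mask numbers — visible in the regional tables, whose
full-territory means sit ~13% below truth at every institution, which is
precisely why the multicentre comparison equalizes resolution before
pooling.

Acquisition follows the dual-injection protocol: two 28-min dynamic scans of
7 × 4-min frames, injections at 0 and 30 min, acetazolamide at 20 min, one
blood sample at 10 min. The first injection's kinetics continue with
rest-phase flow for the whole hour (the background-prediction model assumes
exactly this); the acetazolamide response applies to the second injection
only, with the onset left at the second scan by default. Counts are Poisson
with the mean set by a per-profile sensitivity proportional to `1/BCF`
(scale constant 2.0), giving roughly 0.2–0.6 million counts per 4-min frame
for the two simulated slices — per slice, a typical clinical count level
(a full 3-D acquisition scales with slice coverage). Physical decay is omitted (activities are
decay-corrected, as routine). Frames are simulated per compartment — frame
sinograms are linear combinations of per-compartment attenuated projections
— which is exact for piecewise-constant compartments and makes cohorts
cheap.

Real data differ in ways the generator does not model: continuous
gray-matter flow heterogeneity, subject motion between frames, non-Gaussian
collimator response, fan-beam acquisition, dead time, and physiological CVR
variability. Inter-subject variation is a single multiplicative log-normal
factor on global CBF (CV 16%, the spread reported for healthy cohorts with
this technique) applied jointly to rest and challenge flows, so simulated
CVR varies much less between subjects than the ~18 percentage points seen
clinically. Passing tests therefore demonstrate correctness of the
estimation chain under its own model assumptions plus honest instrumental
approximations — not robustness to motion or to kinetic-model violations.

## Resolution measurement and equalization

Each scanner's resolution is measured as in the semi-automated
phantom procedure: the gray-matter-filled brain phantom is scanned and
reconstructed, both the measured and the digitally designed images are
Fourier transformed, and the magnitude ratio is fitted (weighted least
squares on the log, free intercept for intensity calibration) to a Gaussian
modulation transfer function over frequencies where the reference spectrum
exceeds 5% of its maximum — a noise floor that stabilises the ratio where
the reference has no power; the band is configurable. The simulator applies
the quadrature complement `sqrt(FWHM^2 - 7^2)` of each profile's nominal
resolution as collimator blur, so the reconstructed phantom measures close
to nominal at the 17-mm scanner, while the sharper scanners measure 2–3 mm
broader than nominal because the reconstruction itself (3 EM iterations,
bilinear interpolation, 30 effective views) contributes blur that matters
relatively more there. The equalization consequently uses *measured*, not
nominal, widths: images are brought to the worst scanner's resolution with
a Gaussian of `FWHM_additional = sqrt(FWHM_target^2 - FWHM_current^2)`;
a target sharper than the current resolution is an error (one cannot
sharpen), and equal widths give the identity. All Gaussian filtering is
done in the Fourier domain with the exact transfer function, so the
quadrature composition law holds to numerical precision and total counts
are conserved.

## Statistics

Regional values come from a deterministic ROI template that partitions the
phantom's gray matter into vascular territories (anterior/middle/posterior
cerebral artery sectors by azimuth, basal ganglia, thalamus, pons, vermis,
cerebellum) plus bilateral centrum-semiovale white matter; hemisphere values
aggregate ACA+MCA+PCA+basal ganglia+thalamus, and bilateral rows average the
left and right region means. Cohort summaries report mean ± sample SD per
institution × region × condition, with CVR summarised per subject and then
averaged (not derived from group means).

Inter-institution comparison uses the Steel–Dwass all-pairs procedure: each
pair's tie-corrected rank-sum statistic is referred to the studentized range
distribution (`sqrt(2)|t|` against `Q_k` with infinite degrees of freedom),
controlling the family-wise error over pairs within each region × condition.
Pairwise t and Mann–Whitney tests are available alongside; the Mann–Whitney
p is exact by complete enumeration (ties handled exactly) up to n = 8 per
group and a tie-corrected normal approximation without continuity
correction beyond. Degenerate inputs (zero variance) are flagged rather
than erroring. Significance is two-sided at alpha = 0.05 throughout.

## Problem sizes and numerical choices

Simulations run on a 64 × 64 grid (3.4375 mm pixels, 220 mm field) with two
slices and 60 views over 360 degrees — the scale at which the full
multicentre study (three institutions, their enrolments of 9/13/10 subjects,
calibration experiments, equalized re-analysis) completes in minutes on one
core. The validation suite uses: single subjects for noiseless recovery;
10 Poisson seeds for the noise envelope; 20 replicate three-institution
null studies (n = 10 each) for the family-wise null behaviour; and exact
enumeration oracles at small n (all 34,650 relabelings for the 4+4+4
Steel–Dwass permutation check). The bundled acceptance script reruns the
same computations with 10 null replicates.

Numerical details worth knowing: the EM update skips rays with zero
estimated counts (neutral factor, avoiding 0/0); reconstruction is clipped
at zero after the post-filter (FFT ringing is below 1e-12 of the maximum);
the simulator clamps mean counts at zero for the same reason; bisection
tolerances are 1e-4 on the consistency scale; the look-up inversion clamps
above-table activities to the maximal flow with a warning count; an empty
attenuation mask, a non-monotone look-up table, zero-variance t-test input,
and a consistency target outside the bracket all fail with explicit
messages. A study with no counts returns an all-zero CBF map rather than
failing. Every random draw flows from explicit integer seeds; identical
seeds give byte-identical cohort tables.

## Known limitations

- The population input shape is synthetic; absolute CBF accuracy against a
  *real* population curve is untested (and untestable without one).
- Recovery tolerances hold for the cortical-core region at the sharpest
  scanner; full-territory means remain resolution-biased by design, as in
  clinical data.
- The Steel–Dwass reference is the asymptotic studentized range; at n = 10
  per group it is mildly conservative (verified against the exact
  permutation null at n = 4 per group).
- 2-D multi-slice geometry: no axial scatter or axial partial volume; all
  algorithms are slice-separable by construction.
- Detection power for a deliberately biased institution at these cohort
  sizes is partial — a 20% CBF offset is only ~1.15 between-subject SDs —
  so the package's multicentre claims are about controlling false
  differences, not about guaranteed detection of small calibration errors.
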