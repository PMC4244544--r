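# cbfspect

Quantitative brain-perfusion SPECT, end to end, on synthetic data.

Multicentre SPECT studies of cerebral blood flow (CBF) face a basic
obstacle: different scanners and vendor reconstructions give different
numbers from the same brain. A quantitative reconstruction chain —
threshold-based attenuation maps with a uniform 0.160 cm⁻¹ coefficient,
transmission-dependent convolution-subtraction (TDCS) scatter correction
with a septal-penetration offset, geometric-mean OS-MLEM (3 iterations,
5 subsets, 7-mm post filter) and absolute Bq/mL calibration — combined with
dual-administration ¹²³I-IMP autoradiography makes rest and
post-acetazolamide CBF comparable across institutions, once the remaining
resolution differences are equalized with a quadrature-matched Gaussian
filter.

cbfspect re-implements that entire methodology as a tested R package and
supplies the synthetic ground truth to validate it: digital head and
calibration phantoms, a one-tissue-compartment tracer-kinetic simulator
(dC_t/dt = f·C_a − (f/V_d)·C_t, V_d = 35 mL/mL, CBF = 100·f/1.06 in
mL/min/100 g), an attenuated parallel-beam projector with an exact adjoint,
the quantitative reconstruction chain, the dual-table look-up estimation of
rest CBF, acetazolamide CBF and cerebrovascular reactivity
(CVR = 100·(CBF_acz − CBF_rest)/CBF_rest), Fourier-domain resolution
estimation and cross-scanner equalization
(FWHM_additional = √(FWHM_target² − FWHM_current²)), and the
inter-institution statistics (paired t, exact Mann–Whitney, Steel–Dwass
all-pairs comparison on the studentized range).

It is intended for researchers developing or teaching quantitative
emission-tomography pipelines who need a fully controlled testbed: every
stage can be run against a phantom whose flow, attenuation and resolution
are known exactly.

## Worked example

One simulated subject at the sharpest scanner profile (10.26 mm), with the
site's own simulated calibration experiments:

```r
library(cbfspect)

phantom  <- make_brain_phantom()       # CBF truth: GM 35.7 / 51.7 mL/min/100 g
profile  <- default_institutions()$C
schedule <- acquisition_schedule()     # 2 x 7 frames of 4 min, injections at 0/30 min

# one-time site preparation: BCF, CCF and resolution phantom experiments
site <- prepare_institution(profile, phantom, schedule, seed = 5)
#> BCF = 56178, CCF = 0.935, measured FWHM = 12.73 mm

cfg   <- study_config(n_subjects = 1, seed = 42, subject_cv = 0,
                      institutions = default_institutions()["C"])
study <- run_institution_study(profile, 1, seed = 42, config = cfg, precomp = site)
fit   <- study$subjects[[1]]$fit
gm    <- gm_core_mask(phantom)
c(rest = mask_mean(fit$rest, gm), acz = mask_mean(fit$acz, gm),
  cvr = mask_mean(fit$cvr, gm))
#> global CBF 37.0, GM rest 36.6, GM acz 53.2 mL/min/100g, CVR 45.6%
```

The cortical-core rest and challenge values land within a few percent of
the phantom truth (35.7 and 51.7 mL/min/100 g; CVR truth 44.8%) — the
residual is Poisson noise plus the honest instrumental approximations
(uniform-μ attenuation, estimated outline, measured calibration factors).
Regional territory means from `tidy(study)` sit lower (e.g. hemisphere
rest ≈ 32), because full-territory ROIs include partial-volume-diluted
boundary voxels; that resolution effect is exactly what the multicentre
comparison equalizes before pooling:

```r
report <- run_multicenter_comparison(study_config(seed = 1))   # A, B, C; n = 9/13/10
glance(report)          # measured FWHMs, significant pairs raw vs equalized
tidy(report)            # Steel-Dwass table per region x condition
autoplot(report)        # cohort box plots, raw vs equalized
write_report(report, "results/")
```

See the vignette (`vignettes/quantitative-cbf-spect.Rmd`) for the models,
parameter choices and limitations.

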