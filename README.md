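# fernet

Free-water elimination for single-shell diffusion MRI with an interpolated
initialization (FERNET), plus a bi-compartment phantom simulator and
evaluation tools.

## The problem

Diffusion tensor imaging in and around pathology — most prominently the
edematous peritumoral region of brain tumors — is confounded by freely
diffusing extracellular water. Mixed into a voxel, free water inflates mean
diffusivity (MD), depresses fractional anisotropy (FA), and interrupts
tractography. Multi-shell acquisitions can separate the compartments, but
clinical data are overwhelmingly single-shell, where the two-compartment fit
is mathematically ill-posed: the outcome is decided by how the fit is
initialized.

This package is for researchers who want to estimate a free-water (FW) map
and a free-water-corrected tissue tensor from routine single-shell DWI, and
for methodologists who want a tested simulation/evaluation harness for this
model class.

## The model

Each voxel's attenuation along gradient direction *qᵢ* at b-value *b* is

    Aᵢ(D, f) = f · exp(−b qᵢᵀ D qᵢ) + (1 − f) · exp(−b d)

with tissue volume fraction *f* (FW = 1 − f), tissue tensor *D*, and fixed
free-water diffusivity d = 3.0×10⁻³ mm²/s. The tissue fraction is
initialized by a logarithmic interpolation of two strategies,

    f_init = f_b0^(1−α) · f_MD^α ,
    f_b0   = 1 − log(S₀/S_t) / log(S_w/S_t) ,
    f_MD   = (e^(−b·MD) − e^(−b·d)) / (e^(−b·MD_tissue) − e^(−b·d)) ,

where S_t and S_w are the 5th/95th percentile unweighted signals of
white-matter and CSF reference regions, MD comes from the standard tensor
fit, MD_tissue = 0.60×10⁻³ mm²/s, and the weight α is f_b0 restricted to
[0, 1] — so normal-appearing white matter follows the MD-based estimate,
CSF-like voxels follow the S₀-based estimate, and edematous voxels blend
between them. Per-voxel bounds [f_min, f_max] derived from the extreme
attenuations (with tissue diffusivities assumed within
[0.1, 2.5]×10⁻³ mm²/s) clamp the estimate. Each voxel is then refined by
projected gradient descent with the tensor kept positive definite through
its matrix logarithm. The classic "b0 initialization" (f_b0 only,
out-of-range voxels replaced by the bound midpoint) is included as a
baseline, as is an optional spatial smoothness penalty on the fraction map.

## Worked example

Simulate scenario-A white matter (FA 0.5, MD 7.7×10⁻⁴ mm²/s) with added
free water at SNR 20, fit with the interpolated initialization, and
summarize the signed FW error:

```r
library(fernet)
scen <- build_scenario("A", vf_grid = c(0.2, 0.5, 0.8), snr_grid = 20,
                       n_realizations = 100, n_rotations = 1)
sim  <- run_simulation(scen, seed = 42)
fit  <- fwe_fit_signals(sim$signals, sim$scheme, scen$s0_wm, scen$s0_csf,
                        mode = "fernet")
fw_error_summary(fit$fw, 1 - sim$records$f_true,
                 groups = data.frame(vf = sim$records$vf))
#>    vf   n   mean     sd     q05   q95
#> 1 0.2 100 0.1127 0.0187 0.08034 0.138
#> 2 0.5 100 0.1003 0.0140 0.07636 0.120
#> 3 0.8 100 0.0253 0.0142 0.00128 0.047
```

The `mean` column is the signed FW error (estimate − truth): at high
free-water content the estimates are nearly unbiased, while at lower
fractions they carry the initialization's structural bias (≈ +0.1), tightly
concentrated — in contrast to the b0 baseline, whose errors are strongly
skewed and bimodal there (swap `mode = "b0"` to see).

On real data the entry point is `fit_volume()` (arrays) or the CLI
(`inst/cli/fernet`):

```sh
fernet fit --dwi dwi.nii.gz --bval d.bval --bvec d.bvec \
  --mask brain.nii.gz --wm-mask wm.nii.gz --csf-mask csf.nii.gz \
  --init fernet --bias-corrected --out out/
```

which writes FW, tissue-fraction, corrected FA/MD, tensor, residual and
initialization maps plus a JSON manifest. `fernet simulate`,
`fernet evaluate` and `fernet agree` expose the simulator and the
evaluation metrics (error summaries, voxelwise correlation/MSE,
implausible-fit percentages).

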