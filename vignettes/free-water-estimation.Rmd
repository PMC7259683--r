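---
title: "Free-water elimination from single-shell DWI: model, initialization, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-water elimination from single-shell DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fernet)
```

## The model and its assumptions

A diffusion-weighted voxel is modeled as two compartments in slow exchange:
anisotropic tissue, described by a symmetric positive-definite tensor $D$,
and isotropic free water with fixed diffusivity $d = 3.0\times10^{-3}$
mm²/s (the diffusivity of unrestricted water at body temperature). The
attenuation along direction $q_i$ at b-value $b$ is

$$A_i(D, f) = f\,e^{-b\,q_i^T D q_i} + (1-f)\,e^{-b d},$$

with $f$ the tissue volume fraction; the free-water fraction is $1-f$.
With a single nonzero shell this model is ill-posed: for essentially any
feasible $f$ there is a tensor that fits the measured attenuations almost
equally well, so the data alone cannot pick the solution. The package
treats this honestly: the *initialization* carries the anatomical
information, and the optimizer refines without pretending the data
determine a unique optimum.

Assumptions inherited from the model: Gaussian (tensor) diffusion in the
tissue compartment, a single fixed isotropic diffusivity for everything
"free" (edema, CSF partial volume), no exchange, and an unweighted image
free of multiplicative bias. The last one matters in practice: the
initialization reads tissue composition out of $S_0$, so a bias field
translates directly into a biased fraction map. Bias-field correction is an
input contract, not something this package performs; the CLI warns when the
`--bias-corrected` assertion is absent.

## The interpolated initialization

Two per-voxel fraction estimates are combined:

* **T2-based**: $f_{b0} = 1 - \log(S_0/S_t)/\log(S_w/S_t)$, where $S_t$ and
  $S_w$ are the 5th percentile of $S_0$ in a white-matter reference region
  and the 95th percentile in a CSF region. Percentiles (rather than means)
  make the references robust to residual partial voluming in the masks;
  quantiles use linear interpolation (R type 7).
* **MD-based**: $f_{MD} = (e^{-b\,MD} - e^{-bd})/(e^{-b\,MD_t} - e^{-bd})$
  with $MD_t = 0.60\times10^{-3}$ mm²/s, the expected MD of white matter
  unaffected by partial voluming.

The initialization is their geometric interpolation
$f_{init} = f_{b0}^{1-\alpha} f_{MD}^{\alpha}$, with $\alpha$ equal to the
unclamped $f_{b0}$ restricted to $[0,1]$. Voxels whose $S_0$ resembles the
white-matter reference are governed by $f_{MD}$; CSF-like voxels by
$f_{b0}$; intermediate (edematous) voxels blend toward the geometric mean.
Per-voxel bounds from the extreme attenuations,

$$f_{min} = \frac{\min(\hat A) - e^{-bd}}{e^{-b\lambda_{max}} - e^{-bd}},
\qquad
f_{max} = \frac{\max(\hat A) - e^{-bd}}{e^{-b\lambda_{min}} - e^{-bd}},$$

with $[\lambda_{min}, \lambda_{max}] = [0.1, 2.5]\times10^{-3}$ mm²/s,
clamp the estimates. Two details were genuinely open and decided here:

* $f_{init}$ itself is re-clamped to $[f_{min}, f_{max}]$ after the
  interpolation, because that interval is the optimizer's feasible region
  and the inputs to the interpolation obey it; leaving the interpolant
  outside the bounds would hand the optimizer an infeasible start.
* The raw bound formulas can leave $[0,1]$ or invert under noise (whenever
  the actual axial diffusivity falls short of $\lambda_{max}$, the
  $f_{min}$ formula exceeds 1). Both values are clamped to
  $[10^{-4}, 1]$ and ordered. The $10^{-4}$ floor also keeps the geometric
  interpolation and the $1/f$ attenuation correction finite; the model
  formulas are undefined at exactly 0.

The baseline "b0 initialization" (`mode = "b0"`) uses the raw $f_{b0}$ and
replaces out-of-range voxels with $(f_{min}+f_{max})/2$ — the behaviour of
the earlier generation of single-shell free-water methods, kept for
head-to-head comparisons. Its characteristic failure mode, a hard jump
between kept and replaced neighbours, is what the interpolated scheme was
designed to remove.

## Fitting

Each voxel minimizes the attenuation sum of squares
$\sum_i (\hat A_i - A_i(D,f))^2$ — the model is stated in attenuation
space, so the loss is too. The tensor is parameterized by its matrix
logarithm (log-Euclidean coordinates), which keeps it positive definite
without explicit constraints; $f$ is projected onto $[f_{min}, f_{max}]$
after every step. Steps follow the joint gradient normalized by its
max-norm, with an initial step of 0.1 in those normalized units,
backtracking halving (up to 20) enforcing a monotone non-increasing
objective, and the line search warm-starting from twice the last accepted
step. Convergence is declared when the relative objective decrease falls
below $10^{-8}$ or after `max_iters` (default 100) iterations; voxels with
non-finite objectives are flagged and returned at their initialization.
Before the logarithm, initial-tensor eigenvalues are floored at $10^{-7}$
mm²/s (noisy corrected attenuations can produce indefinite tensors).

A property of this first-order scheme worth stating plainly: on the
ill-posed single-shell objective the minimizing "valley" in $(f, D)$ is so
poorly conditioned that gradient descent barely travels along it — fits are
initialization-dominated, which is precisely the regime in which the choice
of initialization (the subject of this package) matters. A second-order or
profiled optimizer would travel the valley, but under noise the valley
bottom is essentially arbitrary, so such an optimizer would replace the
anatomically informed initialization with noise. Consequently, noise-free
recovery error equals the initialization's structural bias (about +0.1 in
free water at intermediate fractions under the simulator's conditions, see
below), and perturbing the start moves the answer. This is a property of
the method class, not an implementation accident.

The optional spatial regularizer is a quadratic 6-neighbourhood penalty
$\omega \sum_{(a,b)} (f_a - f_b)^2$, fitted by block-coordinate sweeps
(default 5) in which each voxel couples to its neighbours' current
fractions. The per-voxel iteration budget is split across sweeps so that
regularized and unregularized fits spend the same total number of descent
iterations — otherwise a sensitivity comparison would confound the penalty
with extra iterations. The penalty form is this package's choice; only the
qualitative behaviour (the interpolated initialization's insensitivity to
$\omega$, the b0 baseline's sensitivity) is asserted anywhere.

## The simulator

`run_simulation()` generates single voxels from the generative model the
fit assumes, plus magnitude noise:

* $S_0 = f S_0^{WM} + (1-f) S_0^{CSF}$ — the spin-echo proton-density and
  relaxation factors of each compartment are constant across the fraction
  grid, so they collapse into the two reference intensities (defaults 400
  and 1200 scanner units, a realistic CSF:WM b0 ratio of 3 at long TE).
* $S_i = S_0 (f A_{tissue,i} + (1-f) A_{water})$ for each direction.
* Rician noise: $\sqrt{(S+n_1)^2 + n_2^2}$, $n_{1,2} \sim N(0, \sigma^2)$,
  $\sigma = S_0^{WM}/\mathrm{SNR}$ (SNR defined against the tissue b0, the
  conventional DWI definition).

Three scenarios cover healthy and pathological tissue: **A** — prolate
tensor with FA 0.5, MD $7.7\times10^{-4}$ mm²/s (healthy white matter
averages); **B** — the scenario-A eigenvalues treated as already containing
free water at fraction 0.15 and extrapolated per eigenvalue to fraction 0,
giving FA 0.6, MD $6.0\times10^{-4}$; **C** — FA 0.1, MD
$5.5\times10^{-4}$ (restricted diffusion in tumor). Scenarios stated only
through FA/MD are realized as axially symmetric (prolate) tensors — the
disambiguation that reproduces scenario B's printed values. The default
grids are 10 volume fractions (0–0.9) × 10 SNR levels (10–100) × 100
realizations × 100 rotations = $10^6$ records per scenario. The simulated
acquisition is 3 b0 volumes plus 30 electrostatic-repulsion directions at
$b = 800$ s/mm²; $b = 800$ is the shell that reproduces the scenario-B
extrapolation ($b = 1000$ would give MD $\approx 6.2\times10^{-4}$). One
master seed spawns an independent child stream per grid record, so any
subset is reproducible in isolation.

What the simulator deliberately does not emulate: spatial noise
correlation, eddy/motion artifacts, bias fields, non-Gaussian tissue
diffusion, fiber crossings and exchange. Passing simulation tests therefore
demonstrates internal consistency of model, initialization and optimizer
under the model's own assumptions — not robustness to everything real data
do.

`smooth_phantom()` arranges the same generative model on a 3-D grid whose
free-water field ramps smoothly (with a small in-plane tilt so the FW
histogram is continuously distributed, as whole-brain histograms are)
between a pure-tissue slab and a pure-water slab; the slabs double as the
initialization's reference regions.

## Evaluation conventions

Signed free-water error is estimate − truth (positive = overestimated free
water); summaries use the sample (n−1) standard deviation and moment
skewness. Voxelwise agreement between co-registered map stacks is Pearson
correlation and mean squared difference across subjects, with zero-variance
voxels emitted as missing. A corrected-tensor fit is flagged implausible
when its MD drops below $0.40\times10^{-3}$ mm²/s, well under any healthy
tissue estimate. Regularization sensitivity is summarized as the
total-variation distance $\tfrac12\sum_k |p_k - q_k|$ between 50-bin FW
histograms on $[0,1]$ — near 0 when the penalty leaves the distribution
alone.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script use reduced designs chosen as
the smallest sizes at which the statistical contrasts are stable: 200
records per fraction level for the SNR-20 accuracy comparison, phantoms of
$10\times10\times12$ voxels for regularization sensitivity, $10^5$ draws
for the Rayleigh check. Attenuations are clipped to $(10^{-8}, 1]$ before
logarithms (magnitude noise can make normalized signals non-positive);
multiple b0 volumes are averaged into one $S_0$ before attenuation is
computed. The standard tensor fit is weighted linear least squares on
log-signals with one reweighting pass using squared predicted signals —
the standard variance-stabilizing weights for log-transformed Rician data.

## Known limitations

* Single tensor + isotropic water only: crossing fibers, high orientation
  dispersion, and non-Gaussian restriction are outside the model; a voxel
  of isotropic tissue and one of dispersed anisotropic tissue are
  indistinguishable.
* Estimates are initialization-dominated by design (see above); the FW map
  inherits the initialization's biases where the data cannot arbitrate,
  e.g. a structural offset where the linear $S_0$ mixing of real tissue
  meets the logarithmic $f_{b0}$ scale.
* The regularizer is a generic quadratic smoother, not a geometric flow;
  only qualitative sensitivity comparisons should be read from it.
* No preprocessing is performed or checked beyond grid/affine consistency:
  denoising, eddy/motion correction, skull stripping and bias-field
  correction are upstream obligations.
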