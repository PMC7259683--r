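#' Simulated unweighted signal of a two-compartment voxel
#'
#' The b0 intensity of a voxel mixing tissue and free water is the linear
#' combination of the two compartments' reference intensities,
#' \eqn{S_0 = f\,S_0^{WM} + (1-f)\,S_0^{CSF}} (the spin-echo proton-density
#' and relaxation factors of each compartment are constant across the
#' volume-fraction grid, so they collapse into the two references).
#'
#' @param f Tissue volume fraction in \[0, 1\] (vectorized).
#' @param s0_wm,s0_csf Reference b0 intensities of pure tissue and pure CSF.
#' @return Numeric vector of S0 values.
#' @export
simulate_s0 <- function(f, s0_wm, s0_csf) {
  stopifnot(all(f >= 0 & f <= 1), s0_wm > 0, s0_csf > 0)
  f * s0_wm + (1 - f) * s0_csf
}

#' Noise-free bi-compartment DWI signals
#'
#' \eqn{S_i = S_0 (f A_{tissue,i} + (1-f) A_{water})}: the simulated signal
#' for every volume of the scheme, b0 volumes included (their value is
#' `s0`). Weighted volumes agree with `s0 *` [signal_attenuation()] by
#' construction.
#'
#' @param D Tissue tensor (3x3 or length-6).
#' @param f Tissue volume fraction.
#' @param s0 Unweighted intensity (e.g. from [simulate_s0()]).
#' @param scheme A [gradient_scheme()].
#' @param params An [init_params()].
#' @return Numeric vector, one entry per volume of the scheme.
#' @export
simulate_dwi <- function(D, f, s0, scheme, params = init_params()) {
  out <- numeric(length(scheme$bvals))
  out[scheme$b0] <- s0
  out[!scheme$b0] <- s0 * signal_attenuation(D, f, scheme, params)
  out
}

#' Add Rician noise to magnitude signals
#'
#' Magnitude-MR noise: each signal is replaced by
#' \eqn{\sqrt{(S + n_1)^2 + n_2^2}} with independent zero-mean Gaussians
#' \eqn{n_1, n_2} of standard deviation \eqn{\sigma = S_{0,ref}/SNR}. Uses
#' the current R random-number stream (seed upstream for reproducibility).
#'
#' @param signals Numeric vector of noise-free signals.
#' @param snr Signal-to-noise ratio (> 0), defined against `s0_ref`.
#' @param s0_ref Reference intensity that defines the SNR (conventionally
#'   the tissue b0 intensity).
#' @return Noisy signals (non-negative).
#' @export
add_rician_noise <- function(signals, snr, s0_ref) {
  stopifnot(snr > 0, s0_ref > 0)
  sigma <- s0_ref / snr
  n <- length(signals)
  sqrt((signals + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Uniformly random 3-D rotation
#'
#' Drawn via a normalized Gaussian quaternion, which is uniform over SO(3).
#'
#' @return A 3x3 rotation matrix (orthogonal, determinant +1).
#' @export
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Extrapolate measured eigenvalues to a free-water fraction of zero
#'
#' Treats each measured eigenvalue as arising from a mixture of an unknown
#' tissue diffusivity and free water at an assumed volume fraction, and
#' inverts the single-direction bi-exponential in signal space:
#' \deqn{\lambda_{tissue} = -\ln\!\big[(e^{-b\lambda} - (1-f)e^{-bd})/f\big]/b,}
#' with tissue fraction `f = 1 - vf_assumed`. This turns eigenvalues
#' measured in tissue presumed to carry some extracellular water into the
#' eigenvalues of the water-free tissue.
#'
#' @param evals Measured eigenvalues (mm^2/s).
#' @param vf_assumed Assumed free-water volume fraction in (0, 1\];
#'   `vf_assumed = 0` returns the input unchanged.
#' @param b b-value (s/mm^2) at which the extrapolation is performed.
#' @param params An [init_params()].
#' @return Extrapolated eigenvalues; errors if a corrected attenuation is
#'   non-positive (mixture not invertible at this b).
#' @export
extrapolate_tissue_tensor <- function(evals, vf_assumed, b,
                                      params = init_params()) {
  stopifnot(vf_assumed >= 0, vf_assumed < 1, b > 0)
  f <- 1 - vf_assumed
  if (vf_assumed == 0) return(evals)
  att_t <- (exp(-b * evals) - (1 - f) * exp(-b * params$d)) / f
  if (any(att_t <= 0))
    stop("corrected attenuation non-positive; eigenvalues cannot be ",
         "extrapolated at this b-value / assumed fraction")
  -log(att_t) / b
}

#' Simulation scenario definition
#'
#' Bundles the ground-truth tissue eigenvalues, reference b0 intensities,
#' and the simulation grids. The default grids are 10 free-water volume
#' fractions (0 to 0.9), 10 SNR levels (10 to 100), 100 noise realizations
#' and 100 random tensor rotations — one million records per scenario.
#'
#' @param evals Ground-truth tissue eigenvalues (descending, mm^2/s).
#' @param name Scenario label.
#' @param s0_wm,s0_csf Reference b0 intensities (scanner units).
#' @param vf_grid True free-water volume fractions.
#' @param snr_grid SNR levels.
#' @param n_realizations Noise realizations per grid cell.
#' @param n_rotations Random tensor rotations per cell.
#' @param b,n_dirs,n_b0 Simulated acquisition (see [simulation_scheme()]).
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(evals, name = "custom", s0_wm = 400, s0_csf = 1200,
                         vf_grid = seq(0, 0.9, by = 0.1),
                         snr_grid = seq(10, 100, by = 10),
                         n_realizations = 100, n_rotations = 100,
                         b = 800, n_dirs = 30, n_b0 = 3) {
  stopifnot(length(evals) == 3, all(evals > 0), s0_wm > 0, s0_csf > 0,
            all(vf_grid >= 0 & vf_grid < 1), all(snr_grid > 0),
            n_realizations >= 1, n_rotations >= 1)
  fm <- fa_md(sort(evals, decreasing = TRUE))
  structure(list(name = name, evals = sort(evals, decreasing = TRUE),
                 fa = fm$fa, md = fm$md, s0_wm = s0_wm, s0_csf = s0_csf,
                 vf_grid = vf_grid, snr_grid = snr_grid,
                 n_realizations = as.integer(n_realizations),
                 n_rotations = as.integer(n_rotations),
                 b = b, n_dirs = as.integer(n_dirs),
                 n_b0 = as.integer(n_b0)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario %s: FA %.3f, MD %.3e mm^2/s\n",
              x$name, x$fa, x$md))
  cat(sprintf("  grids: %d VF x %d SNR x %d realizations x %d rotations = %s records\n",
              length(x$vf_grid), length(x$snr_grid), x$n_realizations,
              x$n_rotations, format(scenario_n_records(x), big.mark = ",")))
  invisible(x)
}

#' Build one of the three named simulation scenarios
#'
#' * `"A"` — healthy white matter: prolate tensor with FA 0.5 and MD
#'   7.7e-4 mm^2/s (average WM values of healthy controls).
#' * `"B"` — healthy WM assumed to already carry free water: the scenario-A
#'   eigenvalues are assigned a free-water fraction of 0.15 and extrapolated
#'   to fraction 0 ([extrapolate_tissue_tensor()]), giving FA 0.6 and MD
#'   6.0e-4.
#' * `"C"` — restricted diffusion in tumor: prolate tensor with FA 0.1 and
#'   MD 5.5e-4.
#'
#' @param name `"A"`, `"B"` or `"C"`.
#' @param ... Overrides passed to [sim_scenario()] (grids, references,
#'   acquisition).
#' @return A [sim_scenario()].
#' @examples
#' build_scenario("B")
#' @export
build_scenario <- function(name, ...) {
  name <- toupper(as.character(name))
  dots <- list(...)
  b <- if (!is.null(dots$b)) dots$b else 800
  evals <- switch(name,
    A = tensor_eigensystem(prolate_tensor(0.5, 7.7e-4))$values,
    B = extrapolate_tissue_tensor(
          tensor_eigensystem(prolate_tensor(0.5, 7.7e-4))$values,
          vf_assumed = 0.15, b = b),
    C = tensor_eigensystem(prolate_tensor(0.1, 5.5e-4))$values,
    stop("unknown scenario '", name, "' (expected A, B or C)"))
  do.call(sim_scenario, c(list(evals = evals, name = name), dots))
}

#' Number of records in a scenario's full grid
#'
#' @param scenario A [sim_scenario()].
#' @return Integer-valued count: VF levels x SNR levels x realizations x
#'   rotations.
#' @export
scenario_n_records <- function(scenario) {
  length(scenario$vf_grid) * length(scenario$snr_grid) *
    scenario$n_realizations * scenario$n_rotations
}

#' Enumerate a scenario's simulation grid
#'
#' @param scenario A [sim_scenario()].
#' @return A data frame with one row per record: `vf` (true free-water
#'   fraction), `snr`, `realization`, `rotation`.
#' @export
scenario_grid <- function(scenario) {
  expand.grid(rotation = seq_len(scenario$n_rotations),
              realization = seq_len(scenario$n_realizations),
              snr = scenario$snr_grid, vf = scenario$vf_grid,
              KEEP.OUT.ATTRS = FALSE)[, c("vf", "snr", "realization",
                                          "rotation")]
}

# Deterministic per-cell child seed derived from the master seed, so any
# subset of the grid is reproducible in isolation (kept below 2^31).
child_seed <- function(master, k) {
  x <- (as.double(master) %% 2147483647) + 1
  k <- as.double(k)
  as.integer((x * 48271 + k * 30269 + (k * k) %% 65537) %% 2147483647)
}

#' Run a simulation scenario
#'
#' Iterates the full (or reduced) VF x SNR x realization x rotation grid
#' deterministically under a master seed. Each record draws its own rotation
#' and noise from an independent child stream, rotates the ground-truth
#' tensor, simulates the bi-compartment signals and adds Rician noise at
#' \eqn{\sigma = S_0^{WM}/SNR}.
#'
#' @param scenario A [sim_scenario()].
#' @param scheme Optional [gradient_scheme()]; default built from the
#'   scenario's acquisition fields.
#' @param seed Master seed (integer).
#' @return List with `records` (the grid plus `f_true`, `s0_true`),
#'   `signals` (volumes x records matrix of noisy signals), `scheme`,
#'   `scenario`, `seed`.
#' @export
run_simulation <- function(scenario, scheme = NULL, seed = 1) {
  if (is.null(scheme))
    scheme <- simulation_scheme(scenario$b, scenario$n_dirs, scenario$n_b0)
  grid <- scenario_grid(scenario)
  n <- nrow(grid)
  D0 <- diag(scenario$evals)
  signals <- matrix(NA_real_, length(scheme$bvals), n)
  f_true <- 1 - grid$vf
  s0_true <- simulate_s0(f_true, scenario$s0_wm, scenario$s0_csf)
  for (k in seq_len(n)) {
    set.seed(child_seed(seed, k))
    R <- random_rotation()
    D <- R %*% D0 %*% t(R)
    clean <- simulate_dwi(D, f_true[k], s0_true[k], scheme)
    signals[, k] <- add_rician_noise(clean, grid$snr[k], scenario$s0_wm)
  }
  grid$f_true <- f_true
  grid$s0_true <- s0_true
  list(records = grid, signals = signals, scheme = scheme,
       scenario = scenario, seed = seed)
}

#' Pack simulated records into a 4-D phantom volume
#'
#' Arranges a set of simulated records on a 3-D grid (filling x fastest) so
#' that volume-based tools ([fit_volume()], NIfTI writers) can consume the
#' simulation output.
#'
#' @param sim Output of [run_simulation()].
#' @param dim3 Grid dimensions; must hold at least `ncol(sim$signals)`
#'   records (extra voxels are zero and excluded from the returned mask).
#' @return List with `dwi` (4-D array), `mask` (records), `fw_true`,
#'   `f_true` (3-D ground-truth maps, NA off-mask).
#' @export
pack_phantom <- function(sim, dim3) {
  n <- ncol(sim$signals)
  stopifnot(prod(dim3) >= n)
  nvol <- nrow(sim$signals)
  dwi <- array(0, c(dim3, nvol))
  flat <- matrix(0, prod(dim3), nvol)
  flat[seq_len(n), ] <- t(sim$signals)
  dwi <- array(flat, c(dim3, nvol))
  mask <- array(FALSE, dim3); mask[seq_len(n)] <- TRUE
  f_true <- array(NA_real_, dim3); f_true[seq_len(n)] <- sim$records$f_true
  list(dwi = dwi, mask = mask, f_true = f_true, fw_true = 1 - f_true)
}

#' Smooth two-compartment test phantom
#'
#' Builds a small 4-D acquisition whose free-water fraction varies smoothly
#' along the last axis between two homogeneous reference slabs: a pure
#' tissue slab (first slice, used as the white-matter reference region) and
#' a pure free-water slab (last slice, the CSF reference region). Intended
#' for volume-level validation: the smooth interior exercises the spatial
#' regularizer, and the slabs give the initialization its reference
#' regions.
#'
#' @param scenario A [sim_scenario()] providing the tissue tensor, b0
#'   references and acquisition.
#' @param dim3 Grid dimensions, default `c(6, 6, 10)`.
#' @param snr Rician SNR (`Inf` for noise-free).
#' @param vf_range Free-water fraction range spanned between the slabs
#'   (default 0 to 0.9).
#' @param seed Seed for rotation/noise reproducibility.
#' @return List with `dwi` (4-D array), `scheme`, `mask`, `wm_mask`,
#'   `csf_mask`, `f_true`, `fw_true`.
#' @export
smooth_phantom <- function(scenario, dim3 = c(6, 6, 10), snr = 20,
                           vf_range = c(0, 0.9), seed = 1) {
  stopifnot(length(dim3) == 3, dim3[3] >= 4)
  scheme <- simulation_scheme(scenario$b, scenario$n_dirs, scenario$n_b0)
  nz <- dim3[3]
  # slice 1: pure tissue; slice nz: pure free water; in between the
  # free-water fraction ramps along z with a gentle in-plane tilt, so the
  # field is spatially smooth but continuously distributed (as whole-brain
  # FW histograms are), rather than piling up on a few discrete values
  vf_z <- c(0, seq(vf_range[1], vf_range[2], length.out = nz - 2), 1)
  f_true <- array(NA_real_, dim3)
  dwi <- array(0, c(dim3, length(scheme$bvals)))
  D0 <- diag(scenario$evals)
  set.seed(child_seed(seed, 0))
  R <- random_rotation()
  D <- R %*% D0 %*% t(R)
  tilt <- 0.5 * min(abs(diff(vf_z[2:(nz - 1)])), 0.05)
  for (z in seq_len(nz)) for (x in seq_len(dim3[1])) for (y in seq_len(dim3[2])) {
    vf <- vf_z[z]
    if (z > 1 && z < nz)
      vf <- min(max(vf + tilt * ((x - 1) / max(dim3[1] - 1, 1) - 0.5) +
                         tilt * ((y - 1) / max(dim3[2] - 1, 1) - 0.5), 0), 1)
    f <- 1 - vf
    f_true[x, y, z] <- f
    s0 <- simulate_s0(f, scenario$s0_wm, scenario$s0_csf)
    clean <- simulate_dwi(D, f, s0, scheme)
    set.seed(child_seed(seed, ((z * dim3[1] + x) * dim3[2] + y)))
    dwi[x, y, z, ] <- if (is.finite(snr))
      add_rician_noise(clean, snr, scenario$s0_wm) else clean
  }
  mask <- array(TRUE, dim3)
  wm_mask <- array(FALSE, dim3); wm_mask[, , 1] <- TRUE
  csf_mask <- array(FALSE, dim3); csf_mask[, , nz] <- TRUE
  list(dwi = dwi, scheme = scheme, mask = mask, wm_mask = wm_mask,
       csf_mask = csf_mask, f_true = f_true, fw_true = 1 - f_true)
}
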