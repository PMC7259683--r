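#' Reference unweighted signals from white-matter and CSF regions
#'
#' `S_t` is the 5th percentile of the unweighted signal over the
#' white-matter reference region and `S_w` the 95th percentile over the CSF
#' region (percentiles are robust to residual partial voluming inside the
#' masks). Quantiles use linear interpolation (R type 7).
#'
#' @param s0_map Numeric array/vector of unweighted (b0) intensities.
#' @param wm_mask,csf_mask Logical (or 0/1) masks of the same length/shape.
#' @return List with `s_t` and `s_w`; errors if either mask is empty, if
#'   masked values are non-positive, or if `s_t >= s_w` (mask quality).
#' @export
reference_signals <- function(s0_map, wm_mask, csf_mask) {
  wm_mask <- as.logical(wm_mask); csf_mask <- as.logical(csf_mask)
  if (!any(wm_mask, na.rm = TRUE)) stop("white-matter reference mask is empty")
  if (!any(csf_mask, na.rm = TRUE)) stop("CSF reference mask is empty")
  wm <- s0_map[which(wm_mask)]; csf <- s0_map[which(csf_mask)]
  if (any(!is.finite(wm)) || any(!is.finite(csf)) ||
      any(wm <= 0) || any(csf <= 0))
    stop("unweighted signal must be positive and finite inside the masks")
  s_t <- unname(quantile(wm, 0.05, type = 7))
  s_w <- unname(quantile(csf, 0.95, type = 7))
  if (s_t >= s_w)
    stop(sprintf(paste0("S_t (%.4g) >= S_w (%.4g): white-matter and CSF ",
                        "reference regions are not separable; check mask ",
                        "placement and bias-field correction"), s_t, s_w))
  list(s_t = s_t, s_w = s_w)
}

# Unclamped log-scaled b0 fraction (Eq. of the T2-based strategy):
# f = 1 - log(S0/S_t) / log(S_w/S_t)
f_b0_raw <- function(s0, s_t, s_w) {
  stopifnot(s_t > 0, s_w > s_t)
  1 - log(s0 / s_t) / log(s_w / s_t)
}

#' Tissue fraction from b0 scaling
#'
#' The T2-based initialization strategy: the mean unweighted signal is
#' log-scaled between the white-matter and CSF references,
#' \eqn{f = 1 - \log(S_0/S_t)/\log(S_w/S_t)}, so a voxel at `S_t` maps to 1
#' and a voxel at `S_w` maps to 0. Values outside the per-voxel
#' `[f_min, f_max]` interval are set to the nearest of the two bounds.
#'
#' @param s0_map Positive unweighted intensities (vector or array).
#' @param s_t,s_w Reference signals from [reference_signals()].
#' @param f_min,f_max Per-voxel bounds (recycled if scalar); `NULL` leaves
#'   the map unclamped.
#' @return Numeric map of the same shape as `s0_map`.
#' @export
f_b0_map <- function(s0_map, s_t, s_w, f_min = NULL, f_max = NULL) {
  stopifnot(all(s0_map > 0))
  f <- f_b0_raw(s0_map, s_t, s_w)
  if (!is.null(f_min)) f <- pmax(f, f_min)
  if (!is.null(f_max)) f <- pmin(f, f_max)
  f
}

#' Per-voxel bounds on the tissue fraction from extreme attenuations
#'
#' Minimum and maximum plausible tissue fraction implied by the most and
#' least attenuated directions, assuming tissue diffusivities within
#' \eqn{[\lambda_{min}, \lambda_{max}]}:
#' \deqn{f_{min} = \frac{\min(\hat A) - e^{-bd}}{e^{-b\lambda_{max}} - e^{-bd}},
#'  \quad
#'  f_{max} = \frac{\max(\hat A) - e^{-bd}}{e^{-b\lambda_{min}} - e^{-bd}}.}
#' Both are clamped to `[1e-4, 1]` and then ordered so `f_min <= f_max`
#' (noise can invert the raw values).
#'
#' @param att Attenuation vector (one voxel) or `n_dwi` x nvox matrix,
#'   already clipped to `(1e-8, 1]`.
#' @param b Shell b-value (s/mm^2).
#' @param params An [init_params()].
#' @return List with `f_min`, `f_max` (scalars or per-voxel vectors).
#' @export
f_bounds <- function(att, b, params = init_params()) {
  ew <- exp(-b * params$d)
  emax <- exp(-b * params$lambda_max)
  emin <- exp(-b * params$lambda_min)
  if (is.matrix(att)) {
    amin <- apply(att, 2, min); amax <- apply(att, 2, max)
  } else {
    amin <- min(att); amax <- max(att)
  }
  fmin <- (amin - ew) / (emax - ew)
  fmax <- (amax - ew) / (emin - ew)
  fmin <- pmin(pmax(fmin, EPS_F), 1)
  fmax <- pmin(pmax(fmax, EPS_F), 1)
  swap <- fmin > fmax
  if (any(swap)) {
    tmp <- fmin[swap]; fmin[swap] <- fmax[swap]; fmax[swap] <- tmp
  }
  list(f_min = fmin, f_max = fmax)
}

#' Tissue fraction from mean diffusivity
#'
#' The diffusivity-based initialization strategy: the observed MD from the
#' standard single-tensor fit is mapped to a tissue fraction by treating the
#' voxel as a mixture of tissue at `md_tissue` and free water at `d`:
#' \deqn{f_{MD} = \frac{e^{-b\,MD} - e^{-b d}}{e^{-b\,MD_{tissue}} - e^{-b d}},}
#' clamped to `[1e-4, 1]`.
#'
#' @param md_map MD values (mm^2/s) from [fit_standard_tensor()].
#' @param b Shell b-value (s/mm^2).
#' @param params An [init_params()].
#' @return Numeric map in `[1e-4, 1]`.
#' @export
f_md_map <- function(md_map, b, params = init_params()) {
  ew <- exp(-b * params$d)
  f <- (exp(-b * md_map) - ew) / (exp(-b * params$md_tissue) - ew)
  pmin(pmax(f, EPS_F), 1)
}

#' Interpolated initialization of the tissue fraction
#'
#' Geometric (logarithmic) interpolation between the two strategies,
#' \eqn{f_{init} = f_{b0}^{1-\alpha} f_{MD}^{\alpha}}, optionally clamped to
#' per-voxel bounds. The weight `alpha` is the unclamped b0 fraction
#' restricted to \[0,1\]: voxels whose S0 resembles white matter
#' (`alpha` near 1) follow the MD-based estimate, CSF-like voxels
#' (`alpha` near 0) follow the b0-based estimate, and intermediate voxels
#' (edema, partial volume) blend toward the geometric mean.
#'
#' @param f_b0 Clamped b0-based fraction map (in `[f_min, f_max]`).
#' @param f_md MD-based fraction map (in `(0, 1]`).
#' @param alpha Interpolation weight map in \[0, 1\].
#' @param f_min,f_max Optional per-voxel bounds for the final clamp.
#' @return The interpolated map.
#' @export
interpolated_init <- function(f_b0, f_md, alpha, f_min = NULL, f_max = NULL) {
  stopifnot(all(alpha >= 0 & alpha <= 1), all(f_b0 > 0), all(f_md > 0))
  f <- f_b0^(1 - alpha) * f_md^alpha
  if (!is.null(f_min)) f <- pmax(f, f_min)
  if (!is.null(f_max)) f <- pmin(f, f_max)
  f
}

#' Initial free-water-corrected tissue tensor
#'
#' Removes the free-water contribution implied by `f_init` from the observed
#' attenuations,
#' \eqn{\hat A_t = (\hat A - (1-f_{init})e^{-bd})/f_{init}} (clipped to
#' `(1e-8, 1]`), and fits a single tensor to the corrected attenuations.
#'
#' @param att Attenuation vector (one voxel) or matrix (`n_dwi` x nvox).
#' @param f_init Tissue-fraction initialization (scalar or per-voxel).
#' @param scheme A [gradient_scheme()].
#' @param params An [init_params()].
#' @return As [fit_standard_tensor()] (fit of the corrected attenuations,
#'   with `s0` close to 1 by construction).
#' @export
corrected_tensor_init <- function(att, f_init, scheme, params = init_params()) {
  ew <- exp(-scheme$shell_b * params$d)
  if (is.matrix(att)) {
    att_t <- sweep(sweep(att, 2, (1 - f_init) * ew, "-"), 2, f_init, "/")
    att_t <- pmin(pmax(att_t, EPS_ATT), 1)
    full <- rbind(matrix(1, sum(scheme$b0), ncol(att)), att_t)
  } else {
    att_t <- (att - (1 - f_init) * ew) / f_init
    att_t <- pmin(pmax(att_t, EPS_ATT), 1)
    full <- c(rep(1, sum(scheme$b0)), att_t)
  }
  # reassemble in scheme volume order: b0 rows first is only valid if the
  # scheme lists b0 volumes first; build explicitly instead
  reorder <- order(c(which(scheme$b0), which(!scheme$b0)))
  if (is.matrix(att)) full <- full[reorder, , drop = FALSE] else full <- full[reorder]
  fit_standard_tensor(full, scheme)
}

#' Full initialization of the bi-tensor fit
#'
#' Runs the complete per-voxel initialization on a signal matrix: attenuation
#' and S0 extraction, per-voxel fraction bounds, the two fraction strategies,
#' their interpolation (or the b0-only baseline), and the initial corrected
#' tissue tensor.
#'
#' In `mode = "fernet"` the initial fraction is the interpolated estimate
#' clamped to `[f_min, f_max]`; in `mode = "b0"` it is the raw b0-scaled
#' fraction with out-of-range voxels replaced by `(f_min + f_max)/2` (the
#' classic baseline behaviour).
#'
#' @param signals Signal matrix, rows = volumes, columns = voxels (a single
#'   voxel may be given as a vector).
#' @param scheme A [gradient_scheme()].
#' @param s_t,s_w Reference unweighted signals ([reference_signals()]).
#' @param mode `"fernet"` (interpolated) or `"b0"` (baseline).
#' @param params An [init_params()].
#' @return List with per-voxel vectors `f_init`, `f_b0`, `f_md`, `alpha`,
#'   `f_min`, `f_max`, `s0`, `md_standard`, the attenuation matrix `att`,
#'   the initial corrected tensor fit `tensor_init` (6 x nvox), its
#'   `md_init`/`fa_init`, and `mode`.
#' @export
fwe_initialize <- function(signals, scheme, s_t, s_w,
                           mode = c("fernet", "b0"),
                           params = init_params()) {
  mode <- match.arg(mode)
  if (!is.matrix(signals)) signals <- matrix(signals, ncol = 1)
  sa <- signal_to_attenuation(signals, scheme)
  b <- scheme$shell_b
  bounds <- f_bounds(sa$att, b, params)
  std <- fit_standard_tensor(signals, scheme)
  f_md <- f_md_map(std$md, b, params)
  raw <- f_b0_raw(pmax(sa$s0, EPS_ATT), s_t, s_w)
  alpha <- pmin(pmax(raw, 0), 1)
  f_b0 <- pmin(pmax(raw, bounds$f_min), bounds$f_max)
  if (mode == "fernet") {
    f_init <- interpolated_init(f_b0, f_md, alpha,
                                bounds$f_min, bounds$f_max)
  } else {
    mid <- (bounds$f_min + bounds$f_max) / 2
    out <- raw < bounds$f_min | raw > bounds$f_max
    f_init <- ifelse(out, mid, raw)
  }
  ct <- corrected_tensor_init(sa$att, f_init, scheme, params)
  list(f_init = f_init, f_b0 = f_b0, f_md = f_md, alpha = alpha,
       f_min = bounds$f_min, f_max = bounds$f_max, s0 = sa$s0,
       md_standard = std$md, att = sa$att,
       tensor_init = ct$tensor, md_init = ct$md, fa_init = ct$fa,
       mode = mode)
}
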