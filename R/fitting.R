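#' Options for the per-voxel bi-tensor fit
#'
#' @param max_iters Maximum gradient-descent iterations per voxel (default
#'   100).
#' @param tol Convergence tolerance: relative objective decrease below which
#'   the voxel is declared converged (default 1e-8).
#' @param step0 Initial trial step, in normalized parameter units: the
#'   gradient is scaled by its max-norm so the largest parameter change per
#'   trial step is `step0` (default 0.1).
#' @param max_halvings Backtracking halvings per iteration (default 20).
#' @param reg_weight Spatial regularization weight \eqn{\omega \ge 0} on the
#'   fraction map (default 0 = off); see [regularization_penalty()].
#' @param sweeps Outer block-coordinate sweeps when `reg_weight > 0`
#'   (default 5).
#' @param ev_floor Eigenvalue floor (mm^2/s) applied before the matrix
#'   logarithm of the initial tensor (default 1e-7).
#' @return An object of class `"fit_options"`.
#' @export
fit_options <- function(max_iters = 100, tol = 1e-8, step0 = 0.1,
                        max_halvings = 20, reg_weight = 0, sweeps = 5,
                        ev_floor = 1e-7) {
  stopifnot(max_iters >= 1, tol > 0, step0 > 0, max_halvings >= 0,
            reg_weight >= 0, sweeps >= 1, ev_floor > 0)
  structure(list(max_iters = as.integer(max_iters), tol = tol, step0 = step0,
                 max_halvings = as.integer(max_halvings),
                 reg_weight = reg_weight, sweeps = as.integer(sweeps),
                 ev_floor = ev_floor),
            class = "fit_options")
}

#' Fit the bi-tensor model at a single voxel
#'
#' Projected gradient descent on the attenuation sum-of-squares
#' ([voxel_objective()]) over the tissue fraction `f` (projected to
#' `[f_min, f_max]` each step) and the tissue tensor (parameterized by its
#' matrix logarithm, so it stays positive definite). Backtracking line
#' search enforces a monotone non-increasing objective. If the objective or
#' gradient turns non-finite the voxel is flagged and the initialization is
#' returned unchanged.
#'
#' @param att Observed attenuation vector (length `scheme$n_dwi`).
#' @param scheme A [gradient_scheme()].
#' @param f_init Initial tissue fraction (inside the bounds).
#' @param D_init Initial tensor (3x3 matrix or length-6 [dt6()] vector).
#' @param f_min,f_max Per-voxel feasible interval for `f`.
#' @param options A [fit_options()].
#' @param params An [init_params()].
#' @return List with `f`, `fw` (= 1 - f), `tensor` (length-6), `fa`, `md`,
#'   `objective` (the recorded objective sequence), `residual` (final
#'   objective), `iterations`, `converged`, `flagged`.
#' @export
fit_voxel <- function(att, scheme, f_init, D_init, f_min = EPS_F, f_max = 1,
                      options = fit_options(), params = init_params()) {
  stopifnot(length(att) == scheme$n_dwi, f_min <= f_max,
            f_init >= f_min - 1e-12, f_init <= f_max + 1e-12)
  D6 <- if (is.matrix(D_init)) dt6(D_init) else as.numeric(D_init)
  r <- cpp_fit_voxel(att, t(scheme$dirs), scheme$shell_b, params$d,
                     f_init, D6, f_min, f_max, options$max_iters,
                     options$tol, options$step0, options$max_halvings,
                     0, numeric(0), options$ev_floor)
  ev <- tensor_eigensystem(dt6_to_matrix(r$tensor))$values
  fm <- fa_md(ev)
  list(f = r$f, fw = 1 - r$f, tensor = r$tensor, fa = fm$fa, md = fm$md,
       objective = r$objective, residual = r$final_objective,
       iterations = r$iterations, converged = r$converged,
       flagged = r$flagged)
}

#' Pairwise smoothness penalty on the fraction map
#'
#' Discrete (6-neighbourhood) quadratic penalty
#' \eqn{\omega \sum_{(a,b)} (f_a - f_b)^2} over face-adjacent voxel pairs
#' inside the mask, with its per-voxel gradient
#' \eqn{2\omega \sum_{b \in N(a)} (f_a - f_b)}.
#'
#' @param f_map 3-D numeric array of tissue fractions.
#' @param mask Logical 3-D array (same shape); pairs with either voxel
#'   outside the mask are ignored. `NULL` = all voxels.
#' @param omega Non-negative weight.
#' @return List with `penalty` (scalar) and `gradient` (array like
#'   `f_map`, zero outside the mask).
#' @export
regularization_penalty <- function(f_map, mask = NULL, omega = 1) {
  stopifnot(omega >= 0, length(dim(f_map)) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim(f_map))
  mask <- array(as.logical(mask), dim(f_map))
  dm <- dim(f_map)
  pen <- 0
  grad <- array(0, dm)
  shift_pairs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (s in shift_pairs) {
    i1 <- list(seq_len(dm[1] - s[1]), seq_len(dm[2] - s[2]),
               seq_len(dm[3] - s[3]))
    i2 <- list(i1[[1]] + s[1], i1[[2]] + s[2], i1[[3]] + s[3])
    a <- f_map[i1[[1]], i1[[2]], i1[[3]], drop = FALSE]
    b <- f_map[i2[[1]], i2[[2]], i2[[3]], drop = FALSE]
    m <- mask[i1[[1]], i1[[2]], i1[[3]], drop = FALSE] &
         mask[i2[[1]], i2[[2]], i2[[3]], drop = FALSE]
    d <- (a - b) * m
    pen <- pen + sum(d^2)
    g1 <- grad[i1[[1]], i1[[2]], i1[[3]], drop = FALSE] + 2 * d
    grad[i1[[1]], i1[[2]], i1[[3]]] <- g1
    g2 <- grad[i2[[1]], i2[[2]], i2[[3]], drop = FALSE] - 2 * d
    grad[i2[[1]], i2[[2]], i2[[3]]] <- g2
  }
  list(penalty = omega * pen, gradient = omega * grad)
}

# 6-neighbourhood adjacency (linear indices) for masked voxels of a 3-D grid
neighbour_list <- function(dim3, mask_idx) {
  inside <- logical(prod(dim3))
  inside[mask_idx] <- TRUE
  coords <- arrayInd(mask_idx, dim3)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  lapply(seq_along(mask_idx), function(k) {
    nb <- sweep(offs, 2, coords[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
          nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
          nb[, 3] >= 1 & nb[, 3] <= dim3[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1) * dim3[1] +
           (nb[, 3] - 1) * dim3[1] * dim3[2]
    lin[inside[lin]]
  })
}

# Fit a matrix of independent voxels (no spatial coupling).
fit_signal_columns <- function(init, scheme, options, params) {
  nvox <- length(init$f_init)
  cpp_fit_voxels(init$att, t(scheme$dirs), scheme$shell_b, params$d,
                 init$f_init, init$tensor_init, init$f_min, init$f_max,
                 options$max_iters, options$tol, options$step0,
                 options$max_halvings, 0,
                 matrix(0, 0, nvox), matrix(0L, nvox, 1),
                 options$ev_floor)
}

#' Fit the free-water model to a signal matrix of independent voxels
#'
#' Initializes ([fwe_initialize()]) and fits each column of `signals` as an
#' independent voxel (no spatial regularization); this is the workhorse for
#' simulated records and the reduction used by [fit_volume()] when
#' `reg_weight = 0`.
#'
#' @inheritParams fwe_initialize
#' @param options A [fit_options()].
#' @return List with per-voxel vectors `f`, `fw`, `fa`, `md`, `tensor`
#'   (6 x nvox), `residual`, `initial_objective`, `iterations`, `converged`,
#'   `flagged`, plus the initialization under `init`.
#' @export
fwe_fit_signals <- function(signals, scheme, s_t, s_w,
                            mode = c("fernet", "b0"),
                            options = fit_options(),
                            params = init_params()) {
  mode <- match.arg(mode)
  init <- fwe_initialize(signals, scheme, s_t, s_w, mode, params)
  r <- fit_signal_columns(init, scheme, options, params)
  nvox <- length(r$f)
  fa <- md <- numeric(nvox)
  for (v in seq_len(nvox)) {
    fm <- fa_md(tensor_eigensystem(dt6_to_matrix(r$tensor[, v]))$values)
    fa[v] <- fm$fa; md[v] <- fm$md
  }
  list(f = r$f, fw = 1 - r$f, fa = fa, md = md, tensor = r$tensor,
       residual = r$final_objective, initial_objective = r$initial_objective,
       iterations = r$iterations, converged = r$converged,
       flagged = r$flagged, init = init)
}

#' Fit the free-water model over a masked volume
#'
#' Full pipeline on a 4-D acquisition: reference signals from the WM/CSF
#' masks, per-voxel initialization (interpolated or b0 baseline), then
#' per-voxel fits. With `reg_weight > 0` the fit alternates block-coordinate
#' sweeps: each sweep refits every voxel with a quadratic coupling
#' \eqn{\omega\sum_{b\in N(a)}(f_a - f_b)^2} to the neighbouring fractions
#' from the previous sweep.
#'
#' @param dwi 4-D numeric array (x, y, z, volume).
#' @param scheme A [gradient_scheme()]; volume count must match.
#' @param mask Logical 3-D array of voxels to fit.
#' @param wm_mask,csf_mask Reference-region masks for
#'   [reference_signals()].
#' @param init_mode `"fernet"` or `"b0"`.
#' @param options A [fit_options()].
#' @param params An [init_params()].
#' @return An object of class `"fwe_fit"`: 3-D maps `f`, `fw`, `fa`, `md`,
#'   `residual`, `converged`, `flagged` (NA outside the mask), the 4-D
#'   corrected `tensor` map (x, y, z, 6), the `init` maps, and metadata
#'   (`mode`, `options`, `params`, `s_t`, `s_w`).
#' @export
fit_volume <- function(dwi, scheme, mask, wm_mask, csf_mask,
                       init_mode = c("fernet", "b0"),
                       options = fit_options(), params = init_params()) {
  init_mode <- match.arg(init_mode)
  dm <- dim(dwi)
  stopifnot(length(dm) == 4, dm[4] == length(scheme$bvals))
  dim3 <- dm[1:3]
  mask <- array(as.logical(mask), dim3)
  if (!any(mask)) stop("fit mask is empty")
  s0_vol <- apply(dwi[, , , scheme$b0, drop = FALSE], 1:3, mean)
  refs <- reference_signals(s0_vol, wm_mask, csf_mask)
  idx <- which(mask)
  signals <- t(matrix(dwi, prod(dim3), dm[4])[idx, , drop = FALSE])
  init <- fwe_initialize(signals, scheme, refs$s_t, refs$s_w, init_mode,
                         params)
  nvox <- length(idx)
  if (options$reg_weight > 0) {
    nbl <- neighbour_list(dim3, idx)
    pos <- integer(prod(dim3)); pos[idx] <- seq_len(nvox)
    nb_count <- vapply(nbl, length, 1L)
    max_nb <- max(nb_count, 1L)
    nb_pos <- matrix(0L, max_nb, nvox)
    for (k in seq_len(nvox))
      if (nb_count[k] > 0) nb_pos[seq_len(nb_count[k]), k] <- pos[nbl[[k]]]
    f_cur <- init$f_init
    D_cur <- init$tensor_init
    res <- NULL
    # split the per-voxel iteration budget across sweeps so regularized and
    # unregularized fits see the same total number of descent iterations
    sweep_iters <- max(1L, as.integer(round(options$max_iters /
                                            options$sweeps)))
    for (s in seq_len(options$sweeps)) {
      f_nb <- matrix(0, max_nb, nvox)
      for (k in seq_len(nvox))
        if (nb_count[k] > 0)
          f_nb[seq_len(nb_count[k]), k] <- f_cur[nb_pos[seq_len(nb_count[k]), k]]
      res <- cpp_fit_voxels(init$att, t(scheme$dirs), scheme$shell_b,
                            params$d, f_cur, D_cur, init$f_min, init$f_max,
                            sweep_iters, options$tol, options$step0,
                            options$max_halvings, options$reg_weight,
                            f_nb, matrix(nb_count, ncol = 1),
                            options$ev_floor)
      f_cur <- res$f
      D_cur <- res$tensor
    }
  } else {
    res <- fit_signal_columns(init, scheme, options, params)
  }
  fa <- md <- numeric(nvox)
  for (v in seq_len(nvox)) {
    fm <- fa_md(tensor_eigensystem(dt6_to_matrix(res$tensor[, v]))$values)
    fa[v] <- fm$fa; md[v] <- fm$md
  }
  to_map <- function(vals, fill = NA_real_) {
    m <- array(fill, dim3); m[idx] <- vals; m
  }
  tensor4 <- array(NA_real_, c(dim3, 6))
  for (k in 1:6) {
    tk <- array(NA_real_, dim3); tk[idx] <- res$tensor[k, ]
    tensor4[, , , k] <- tk
  }
  structure(list(
    f = to_map(res$f), fw = to_map(1 - res$f), fa = to_map(fa),
    md = to_map(md), tensor = tensor4,
    residual = to_map(res$final_objective),
    initial_objective = to_map(res$initial_objective),
    iterations = to_map(res$iterations),
    converged = to_map(as.numeric(res$converged)) > 0,
    flagged = to_map(as.numeric(res$flagged)) > 0,
    init = list(f_init = to_map(init$f_init), f_b0 = to_map(init$f_b0),
                f_md = to_map(init$f_md), alpha = to_map(init$alpha),
                f_min = to_map(init$f_min), f_max = to_map(init$f_max),
                md_init = to_map(init$md_init)),
    mask = mask, mode = init_mode, options = options, params = params,
    s_t = refs$s_t, s_w = refs$s_w),
    class = "fwe_fit")
}

#' @export
print.fwe_fit <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("Free-water fit (%s initialization): %d voxels\n", x$mode, n))
  cat(sprintf("  converged: %d (%.1f%%); flagged: %d\n",
              sum(x$converged, na.rm = TRUE),
              100 * mean(x$converged[x$mask], na.rm = TRUE),
              sum(x$flagged, na.rm = TRUE)))
  cat(sprintf("  FW (median [IQR]): %.3f [%.3f, %.3f]\n",
              stats::median(x$fw[x$mask]),
              quantile(x$fw[x$mask], 0.25), quantile(x$fw[x$mask], 0.75)))
  invisible(x)
}
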