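#' Design matrix of the log-linear tensor model
#'
#' One row per volume: `[1, -b qx^2, -2b qx qy, -b qy^2, -2b qx qz,
#' -2b qy qz, -b qz^2]`, so that `X %*% c(log(S0), dt6(D))` equals the
#' log-signal of a mono-exponential tensor model. Column order after the
#' intercept matches the package's lower-triangular tensor packing ([dt6()]).
#'
#' @param scheme A [gradient_scheme()].
#' @return Numeric matrix, `length(bvals)` x 7.
#' @keywords internal
tensor_design <- function(scheme) {
  n <- length(scheme$bvals)
  X <- matrix(0, n, 7)
  X[, 1] <- 1
  w <- which(!scheme$b0)
  b <- scheme$bvals[w]
  q <- scheme$bvecs[, w, drop = FALSE]
  X[w, 2] <- -b * q[1, ]^2
  X[w, 3] <- -2 * b * q[1, ] * q[2, ]
  X[w, 4] <- -b * q[2, ]^2
  X[w, 5] <- -2 * b * q[1, ] * q[3, ]
  X[w, 6] <- -2 * b * q[2, ] * q[3, ]
  X[w, 7] <- -b * q[3, ]^2
  X
}

#' Weighted linear least-squares single-tensor fit
#'
#' Standard diffusion tensor fit on log-signals: an ordinary least-squares
#' fit is followed by one reweighted pass with weights equal to the squared
#' signals predicted by the initial fit (the usual WLLS scheme; the
#' log-transform makes noise variance proportional to 1/S^2). Signals are
#' clipped below at 1e-8 before the logarithm.
#'
#' @param signals Numeric vector (length = total volumes) for one voxel, or
#'   a matrix with one column per voxel.
#' @param scheme A [gradient_scheme()].
#' @param weighted Logical; `FALSE` stops after the ordinary LS pass.
#' @return For a vector input: list with `tensor` (length-6, [dt6()] order),
#'   `s0` (fitted unweighted signal), `md`, `fa`, `evals` (descending) and
#'   `flagged` (rank-deficient design). For a matrix input: list of
#'   per-voxel columns/vectors (`tensor` is 6 x nvox).
#' @examples
#' sch <- simulation_scheme()
#' D <- prolate_tensor(0.5, 7.7e-4)
#' s <- c(rep(100, 3), 100 * signal_attenuation(D, 1, sch))
#' fit_standard_tensor(s, sch)$md
#' @export
fit_standard_tensor <- function(signals, scheme, weighted = TRUE) {
  X <- tensor_design(scheme)
  one <- !is.matrix(signals)
  S <- if (one) matrix(signals, ncol = 1) else signals
  stopifnot(nrow(S) == nrow(X))
  nvox <- ncol(S)
  Y <- log(pmax(S, EPS_ATT))
  usable <- is.finite(Y)
  tensor <- matrix(NA_real_, 6, nvox)
  s0 <- md <- fa <- rep(NA_real_, nvox)
  evals <- matrix(NA_real_, 3, nvox)
  flagged <- rep(FALSE, nvox)
  # OLS solve shared across voxels with complete data
  XtX <- crossprod(X)
  ok_all <- colSums(usable) == nrow(X)
  beta0 <- matrix(NA_real_, 7, nvox)
  if (any(ok_all))
    beta0[, ok_all] <- solve(XtX, crossprod(X, Y[, ok_all, drop = FALSE]))
  for (v in seq_len(nvox)) {
    u <- usable[, v]
    if (sum(u) < 7) { flagged[v] <- TRUE; next }
    b0v <- beta0[, v]
    if (anyNA(b0v))
      b0v <- tryCatch(qr.solve(X[u, , drop = FALSE], Y[u, v]),
                      error = function(e) NULL)
    if (is.null(b0v)) { flagged[v] <- TRUE; next }
    beta <- b0v
    if (weighted) {
      w <- exp(2 * (X %*% b0v))[u]       # squared predicted signals
      Xw <- X[u, , drop = FALSE] * w
      beta <- tryCatch(solve(crossprod(Xw, X[u, , drop = FALSE]),
                             crossprod(Xw, Y[u, v])),
                       error = function(e) b0v)
      beta <- as.numeric(beta)
    }
    tensor[, v] <- beta[-1]
    s0[v] <- exp(beta[1])
    ev <- tensor_eigensystem(dt6_to_matrix(beta[-1]))$values
    evals[, v] <- ev
    fm <- fa_md(ev)
    md[v] <- fm$md
    fa[v] <- fm$fa
  }
  if (one)
    list(tensor = tensor[, 1], s0 = s0[1], md = md[1], fa = fa[1],
         evals = evals[, 1], flagged = flagged[1])
  else
    list(tensor = tensor, s0 = s0, md = md, fa = fa, evals = evals,
         flagged = flagged)
}
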