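#' Bi-compartment signal attenuation
#'
#' Evaluates the two-compartment model for each weighted direction
#' \eqn{q_i}:
#' \deqn{A_i = f\,e^{-b\,q_i^T D q_i} + (1-f)\,e^{-b d},}
#' the sum of an anisotropic tissue term (tensor `D`, tissue volume fraction
#' `f`) and an isotropic free-water term with fixed diffusivity `d`.
#'
#' @param D Tissue diffusion tensor: symmetric 3x3 matrix or length-6
#'   lower-triangular vector.
#' @param f Tissue volume fraction in \[0, 1\] (the free-water volume
#'   fraction is `1 - f`).
#' @param scheme A [gradient_scheme()].
#' @param params An [init_params()] (supplies `d`).
#' @return Numeric vector of attenuations, one per weighted volume, all in
#'   (0, 1\] for a positive-semidefinite `D`.
#' @examples
#' sch <- simulation_scheme()
#' signal_attenuation(diag(3) * 1e-3, 0.5, sch)
#' @export
signal_attenuation <- function(D, f, scheme, params = init_params()) {
  stopifnot(inherits(scheme, "gradient_scheme"), f >= 0, f <= 1)
  D <- as_tensor_matrix(D)
  b <- scheme$shell_b
  q <- scheme$dirs
  c_i <- colSums(q * (D %*% q))          # q_i^T D q_i
  f * exp(-b * c_i) + (1 - f) * exp(-b * params$d)
}

#' Sum-of-squares objective of the bi-tensor model at one voxel
#'
#' Reference (pure R) evaluation of the data term minimized by the per-voxel
#' fit: \eqn{\sum_i (\hat A_i - A_i(D, f))^2} with \eqn{A_i} from
#' [signal_attenuation()]. The compiled optimizer evaluates the same
#' quantity internally; this function is the independent check.
#'
#' @param att Observed attenuation vector (one entry per weighted volume).
#' @param scheme A [gradient_scheme()].
#' @param f Tissue volume fraction.
#' @param D Tissue tensor (3x3 or length-6).
#' @param params An [init_params()].
#' @return Non-negative scalar.
#' @export
voxel_objective <- function(att, scheme, f, D, params = init_params()) {
  stopifnot(length(att) == scheme$n_dwi)
  r <- att - signal_attenuation(D, f, scheme, params)
  sum(r^2)
}

#' Per-voxel attenuation from raw signals
#'
#' Divides each weighted volume by the mean unweighted signal and clips the
#' result to `(1e-8, 1]` before any logarithm is taken (Rician noise can
#' produce non-positive or super-unity normalized signals).
#'
#' @param signals Numeric vector (one voxel, length = total volumes) or a
#'   matrix with one column per voxel.
#' @param scheme A [gradient_scheme()].
#' @return For a vector input, a list with `att` (length `n_dwi`) and `s0`
#'   (mean b0 signal); for a matrix, `att` is `n_dwi` x nvox and `s0` a
#'   vector.
#' @export
signal_to_attenuation <- function(signals, scheme) {
  if (is.matrix(signals)) {
    stopifnot(nrow(signals) == length(scheme$bvals))
    s0 <- colMeans(signals[scheme$b0, , drop = FALSE])
    att <- sweep(signals[!scheme$b0, , drop = FALSE], 2, pmax(s0, EPS_ATT), "/")
    att <- pmin(pmax(att, EPS_ATT), 1)
    list(att = att, s0 = s0)
  } else {
    stopifnot(length(signals) == length(scheme$bvals))
    s0 <- mean(signals[scheme$b0])
    att <- signals[!scheme$b0] / max(s0, EPS_ATT)
    list(att = pmin(pmax(att, EPS_ATT), 1), s0 = s0)
  }
}
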