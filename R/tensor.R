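#' Tensor packing: lower-triangular six-vector
#'
#' Diffusion tensors are stored throughout the package (and written to file)
#' as six unique components in lower-triangular order
#' `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)`.
#'
#' @param D A symmetric 3x3 matrix.
#' @return `dt6()`: a length-6 numeric vector; `dt6_to_matrix()`: a 3x3
#'   symmetric matrix.
#' @examples
#' D <- diag(c(1, 2, 3)) * 1e-3
#' dt6(D)
#' dt6_to_matrix(dt6(D))
#' @export
dt6 <- function(D) {
  stopifnot(is.matrix(D), all(dim(D) == c(3, 3)))
  if (max(abs(D - t(D))) > 1e-10 * max(abs(D), 1e-300))
    stop("tensor matrix is not symmetric")
  c(D[1, 1], D[2, 1], D[2, 2], D[3, 1], D[3, 2], D[3, 3])
}

#' @rdname dt6
#' @param v A length-6 numeric vector in `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)`
#'   order.
#' @export
dt6_to_matrix <- function(v) {
  stopifnot(length(v) == 6)
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3, 3)
}

as_tensor_matrix <- function(D) {
  if (is.matrix(D)) {
    stopifnot(all(dim(D) == c(3, 3)))
    D
  } else {
    dt6_to_matrix(D)
  }
}

#' Eigensystem of a diffusion tensor
#'
#' @param D A symmetric 3x3 matrix or a length-6 lower-triangular vector
#'   (see [dt6()]).
#' @return A list with `values` (eigenvalues sorted descending,
#'   \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}) and `vectors` (columns are
#'   the matching unit eigenvectors).
#' @examples
#' tensor_eigensystem(diag(c(3, 2, 1)) * 1e-3)$values
#' @export
tensor_eigensystem <- function(D) {
  D <- as_tensor_matrix(D)
  e <- eigen(D, symmetric = TRUE)  # eigen() already sorts descending
  list(values = e$values, vectors = e$vectors)
}

#' Fractional anisotropy and mean diffusivity from eigenvalues
#'
#' Standard scalar invariants of the diffusion tensor:
#' \deqn{MD = (\lambda_1+\lambda_2+\lambda_3)/3, \quad
#'       FA = \sqrt{3/2}\,\|\lambda - MD\| / \|\lambda\|.}
#' An all-zero tensor has FA defined as 0.
#'
#' @param values Three real eigenvalues (any order).
#' @return A named list with `fa` (dimensionless, in \[0,1\] for non-negative
#'   eigenvalues) and `md` (mm^2/s).
#' @examples
#' fa_md(c(1.7, 0.3, 0.3) * 1e-3)
#' @export
fa_md <- function(values) {
  stopifnot(length(values) == 3, all(is.finite(values)))
  md <- mean(values)
  nrm <- sqrt(sum(values^2))
  if (nrm == 0) return(list(fa = 0, md = 0))
  fa <- sqrt(1.5) * sqrt(sum((values - md)^2)) / nrm
  list(fa = fa, md = md)
}

#' Construct an axially symmetric (prolate) tensor from FA and MD
#'
#' Builds the unique axially symmetric tensor with eigenvalues
#' \eqn{\lambda_1 = MD(1+2\delta)}, \eqn{\lambda_2=\lambda_3 = MD(1-\delta)}
#' whose fractional anisotropy equals `fa` and mean diffusivity equals `md`.
#' For this family \eqn{FA(\delta) = 3\delta/\sqrt{3+6\delta^2}}, which
#' inverts in closed form to \eqn{\delta = FA\sqrt{3}/\sqrt{9-6\,FA^2}}.
#'
#' @param fa Target fractional anisotropy in \[0, 1).
#' @param md Target mean diffusivity (mm^2/s), positive.
#' @param axis Unit 3-vector giving the principal eigenvector direction;
#'   default the x axis.
#' @return A symmetric 3x3 tensor matrix.
#' @examples
#' D <- prolate_tensor(0.5, 7.7e-4)
#' fa_md(tensor_eigensystem(D)$values)
#' @export
prolate_tensor <- function(fa, md, axis = c(1, 0, 0)) {
  stopifnot(fa >= 0, fa < 1, md > 0, length(axis) == 3)
  n <- sqrt(sum(axis^2))
  if (abs(n - 1) > 1e-6) stop("axis must be a unit vector")
  axis <- axis / n
  delta <- fa * sqrt(3) / sqrt(9 - 6 * fa^2)
  l1 <- md * (1 + 2 * delta)
  l23 <- md * (1 - delta)
  # D = l23 * I + (l1 - l23) * axis axis^T
  l23 * diag(3) + (l1 - l23) * tcrossprod(axis)
}
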