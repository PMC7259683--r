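#' Single-shell gradient scheme
#'
#' Validates and stores the acquisition scheme: per-volume b-values and unit
#' gradient directions, with the single nonzero shell `shell_b`. Volumes with
#' b below `b0_threshold` are treated as unweighted (b0).
#'
#' Invariants enforced: every weighted direction has unit Euclidean norm
#' (within 1e-6); at least one b0 volume and at least six distinct weighted
#' directions (the tensor fit is otherwise underdetermined); all weighted
#' b-values agree with `shell_b` within 1% (single-shell contract).
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x N matrix of gradient directions (columns), in the image
#'   coordinate frame. Directions for b0 volumes are ignored.
#' @param b0_threshold b-values strictly below this are treated as b = 0
#'   (default 50 s/mm^2).
#' @return An object of class `"gradient_scheme"`: a list with `bvals`,
#'   `bvecs`, `shell_b`, `b0` (logical per-volume index), `dirs` (3 x n
#'   weighted directions), `n_b0`, `n_dwi`.
#' @examples
#' sch <- gradient_scheme(c(0, 800, 800, 800, 800, 800, 800),
#'                        cbind(0, diag(3), -diag(3))[, 1:7])
#' sch$shell_b
#' @export
gradient_scheme <- function(bvals, bvecs, b0_threshold = 50) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3)
    stop("bvecs must be a 3 x N matrix (directions in columns)")
  if (length(bvals) != ncol(bvecs))
    stop("number of b-values (", length(bvals), ") does not match number of ",
         "gradient directions (", ncol(bvecs), ")")
  b0 <- bvals < b0_threshold
  if (!any(b0)) stop("scheme has no b0 (unweighted) volume")
  if (sum(!b0) < 6) stop("scheme has fewer than 6 weighted directions")
  dirs <- bvecs[, !b0, drop = FALSE]
  norms <- sqrt(colSums(dirs^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("weighted gradient directions must have unit norm (max deviation ",
         format(max(abs(norms - 1))), ")")
  shells <- bvals[!b0]
  shell_b <- stats::median(shells)
  if (any(abs(shells - shell_b) > 0.01 * shell_b)) {
    ub <- sort(unique(round(shells)))
    stop("multiple shells detected (b = ", paste(ub, collapse = ", "),
         "); this model requires single-shell data")
  }
  # distinct directions up to sign (antipodal directions sample the same
  # diffusion measurement)
  key <- apply(round(dirs, 4), 2, function(v) {
    s <- v[match(TRUE, abs(v) > 1e-8)]
    if (!is.na(s) && s < 0) v <- -v
    paste(v, collapse = ",")
  })
  if (length(unique(key)) < 6)
    stop("fewer than 6 distinct weighted directions; tensor fit is ",
         "underdetermined")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs,
                 shell_b = shell_b, b0 = b0, dirs = dirs,
                 n_b0 = sum(b0), n_dwi = sum(!b0)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("Single-shell gradient scheme: %d b0 + %d directions at b = %g s/mm^2\n",
              x$n_b0, x$n_dwi, x$shell_b))
  invisible(x)
}

#' Read an FSL-style gradient table
#'
#' Parses whitespace-separated `.bval`/`.bvec` files (bvecs as 3 rows by N
#' columns, in the image coordinate frame). Directions whose norm lies in
#' \[0.95, 1.05\] are renormalized to unit length; directions outside that
#' range are rejected. b-values below 50 s/mm^2 are treated as b0.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A [gradient_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- scan(bvec_path, quiet = TRUE)
  if (length(bv) != 3 * length(bvals))
    stop("bvec entry count (", length(bv), ") does not match 3 x ",
         length(bvals), " b-values")
  bvecs <- matrix(bv, nrow = 3, byrow = TRUE)
  b0 <- bvals < 50
  norms <- sqrt(colSums(bvecs^2))
  bad <- !b0 & (norms < 0.95 | norms > 1.05)
  if (any(bad))
    stop("gradient direction(s) ", paste(which(bad), collapse = ", "),
         " have norm outside [0.95, 1.05]")
  fix <- !b0 & abs(norms - 1) > 0
  bvecs[, fix] <- sweep(bvecs[, fix, drop = FALSE], 2, norms[fix], "/")
  gradient_scheme(bvals, bvecs)
}

#' Electrostatic-repulsion gradient directions
#'
#' Generates `n` approximately uniformly spread unit directions on the
#' hemisphere by minimizing the Coulomb energy of the `2n` antipodally
#' symmetric points, starting from a deterministic spherical Fibonacci
#' lattice. Used as the default simulated acquisition scheme.
#'
#' @param n Number of directions.
#' @param iters Repulsion iterations (default 200).
#' @return A 3 x `n` matrix of unit column vectors.
#' @export
gradient_directions <- function(n, iters = 200) {
  stopifnot(n >= 6)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n                      # hemisphere z in (0, 1)
  r <- sqrt(pmax(0, 1 - z^2))
  P <- rbind(r * cos(phi), r * sin(phi), z)
  step <- 0.05
  for (it in seq_len(iters)) {
    Fo <- matrix(0, 3, n)
    for (k in seq_len(n)) {
      d1 <- P - P[, k]            # repulsion from points and antipodes
      d2 <- -P - P[, k]
      w1 <- colSums(d1^2); w1[k] <- Inf
      w2 <- colSums(d2^2)
      Fo[, k] <- -(d1 %*% (w1^-1.5)) - (d2 %*% (w2^-1.5))
    }
    P <- P + step * Fo / max(sqrt(colSums(Fo^2)))
    P <- sweep(P, 2, sqrt(colSums(P^2)), "/")
  }
  P
}

#' Default simulated acquisition scheme
#'
#' Builds the scheme used by the phantom simulator: `n_b0` unweighted volumes
#' followed by `n_dirs` electrostatic-repulsion directions at a single shell.
#'
#' @param b Shell b-value (s/mm^2), default 800.
#' @param n_dirs Number of weighted directions, default 30.
#' @param n_b0 Number of b0 volumes, default 3.
#' @return A [gradient_scheme()].
#' @export
simulation_scheme <- function(b = 800, n_dirs = 30, n_b0 = 3) {
  dirs <- gradient_directions(n_dirs)
  gradient_scheme(c(rep(0, n_b0), rep(b, n_dirs)),
                  cbind(matrix(0, 3, n_b0), dirs))
}
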