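#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti that return plain numeric arrays carrying the
#' source image as an attribute, so outputs can be written back on the input
#' grid with the same affine.
#'
#' @param path Path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return `read_volume()`: a numeric array with attribute `"reference"`
#'   (the RNifti image).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "reference") <- img
  arr
}

#' @rdname read_volume
#' @param data Numeric array to write.
#' @param reference A volume previously returned by [read_volume()] (or an
#'   RNifti image) whose grid/affine the output inherits; `NULL` writes an
#'   identity affine.
#' @export
write_volume <- function(data, path, reference = NULL) {
  ref <- if (!is.null(attr(reference, "reference")))
    attr(reference, "reference") else reference
  img <- if (is.null(ref)) RNifti::asNifti(data)
         else RNifti::asNifti(data, reference = ref)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two volumes share a voxel grid and affine
#'
#' @param a,b Arrays from [read_volume()].
#' @param tol Maximum absolute affine difference (default 1e-4).
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_same_grid <- function(a, b, tol = 1e-4, what = "volume") {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  if (!identical(da, db))
    stop(what, " grid ", paste(db, collapse = "x"),
         " does not match DWI grid ", paste(da, collapse = "x"))
  ra <- attr(a, "reference"); rb <- attr(b, "reference")
  if (!is.null(ra) && !is.null(rb)) {
    xa <- RNifti::xform(ra); xb <- RNifti::xform(rb)
    if (max(abs(xa - xb)) > tol)
      stop(what, " affine differs from the DWI affine by ",
           format(max(abs(xa - xb))), " (tolerance ", tol, ")")
  }
  invisible(TRUE)
}

#' Write the maps of a volume fit to a directory
#'
#' Writes FW, tissue fraction, corrected FA/MD, the 6-component corrected
#' tensor (lower-triangular order), residual and convergence maps, plus the
#' initialization maps, all on the input grid.
#'
#' @param fit An `"fwe_fit"` from [fit_volume()].
#' @param dir Output directory (created if needed).
#' @param reference Volume carrying the target grid/affine.
#' @return Invisibly, the named vector of written paths.
#' @export
write_fwe_maps <- function(fit, dir, reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- list(fw = fit$fw, tissue_fraction = fit$f, corrected_fa = fit$fa,
               corrected_md = fit$md, tensor = fit$tensor,
               residual = fit$residual,
               converged = fit$converged * 1,
               f_init = fit$init$f_init, f_b0 = fit$init$f_b0,
               f_md = fit$init$f_md, alpha = fit$init$alpha,
               f_min = fit$init$f_min, f_max = fit$init$f_max)
  paths <- character(0)
  for (nm in names(maps)) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_volume(maps[[nm]], p, reference)
    paths[nm] <- p
  }
  invisible(paths)
}
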