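#' Grouped summary of signed free-water estimation errors
#'
#' The per-record signed error is `estimate - truth` (positive = free water
#' overestimated, matching the sign convention of the simulation figures).
#' Summaries use the sample (n-1) standard deviation and moment skewness
#' \eqn{m_3 / m_2^{3/2}}.
#'
#' @param estimates,truths Equal-length numeric vectors of free-water
#'   fractions.
#' @param groups Optional data frame (or vector) of grouping keys, one row
#'   per record (e.g. true VF and SNR).
#' @return A data frame with one row per group: the grouping keys, `n`,
#'   `mean`, `sd`, `skewness`, and the 5/25/50/75/95% quantiles of the
#'   signed error.
#' @export
fw_error_summary <- function(estimates, truths, groups = NULL) {
  if (length(estimates) != length(truths))
    stop("estimates and truths must have equal length")
  err <- estimates - truths
  if (is.null(groups)) groups <- data.frame(group = rep("all", length(err)))
  if (!is.data.frame(groups)) groups <- data.frame(group = groups)
  if (nrow(groups) != length(err))
    stop("groups must have one row per record")
  key <- interaction(groups, drop = TRUE, lex.order = TRUE)
  stats_one <- function(e) {
    m2 <- mean((e - mean(e))^2)
    m3 <- mean((e - mean(e))^3)
    c(n = length(e), mean = mean(e),
      sd = if (length(e) > 1) sd(e) else NA_real_,
      skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
      quantile(e, c(0.05, 0.25, 0.5, 0.75, 0.95)))
  }
  per <- t(vapply(split(err, key), stats_one, numeric(9)))
  keys <- unique(cbind(groups, .key = key))
  keys <- keys[match(rownames(per), keys$.key), , drop = FALSE]
  out <- cbind(keys[, setdiff(names(keys), ".key"), drop = FALSE],
               as.data.frame(per))
  names(out)[(ncol(out) - 4):ncol(out)] <- c("q05", "q25", "q50", "q75",
                                             "q95")
  rownames(out) <- NULL
  out
}

#' Voxelwise agreement between two map stacks
#'
#' For co-registered per-subject map stacks, computes at every voxel the
#' Pearson correlation across subjects and the mean squared difference.
#' Voxels where either stack has zero variance get `NA` correlation.
#'
#' @param stack_a,stack_b Arrays of identical shape whose last dimension
#'   indexes subjects (at least 3).
#' @return List with `correlation` and `mse` (arrays one dimension smaller).
#' @export
voxelwise_agreement <- function(stack_a, stack_b) {
  da <- dim(stack_a)
  if (!identical(da, dim(stack_b)))
    stop("map stacks must have identical dimensions")
  ns <- da[length(da)]
  if (ns < 3) stop("at least 3 co-registered subjects are required")
  vshape <- da[-length(da)]
  A <- matrix(stack_a, prod(vshape), ns)
  B <- matrix(stack_b, prod(vshape), ns)
  ma <- rowMeans(A); mb <- rowMeans(B)
  Ac <- A - ma; Bc <- B - mb
  va <- rowSums(Ac^2); vb <- rowSums(Bc^2)
  cov <- rowSums(Ac * Bc)
  corr <- ifelse(va > 0 & vb > 0, cov / sqrt(va * vb), NA_real_)
  mse <- rowMeans((A - B)^2)
  list(correlation = array(corr, vshape), mse = array(mse, vshape))
}

#' Fraction of implausible corrected-tensor fits
#'
#' A corrected-tensor fit is implausible when its MD falls below a
#' physiological floor (default 0.40e-3 mm^2/s, well under healthy brain
#' tissue). For a stack of subject MD maps (last dimension = subjects) the
#' result is the per-voxel percentage of subjects below threshold; for a
#' single map it is the percentage of in-mask voxels below threshold.
#'
#' @param md_maps Numeric array: a single MD map, or a stack with subjects
#'   in the last dimension (set `stack = TRUE`).
#' @param mask Logical mask over the voxel grid; must be nonempty.
#' @param threshold MD floor in mm^2/s (default 0.40e-3).
#' @param stack Treat the last dimension of `md_maps` as subjects.
#' @return Scalar percentage (single map) or a percentage map (stack).
#' @export
implausible_fraction <- function(md_maps, mask = NULL, threshold = 0.40e-3,
                                 stack = FALSE) {
  stopifnot(threshold >= 0)
  if (stack) {
    dm <- dim(md_maps)
    ns <- dm[length(dm)]
    vshape <- dm[-length(dm)]
    M <- matrix(md_maps, prod(vshape), ns)
    if (is.null(mask)) mask <- rep(TRUE, prod(vshape))
    mask <- as.logical(mask)
    if (!any(mask)) stop("mask is empty")
    pct <- 100 * rowMeans(M < threshold)
    pct[!mask] <- NA_real_
    array(pct, vshape)
  } else {
    if (is.null(mask)) mask <- rep(TRUE, length(md_maps))
    mask <- as.logical(mask)
    if (!any(mask)) stop("mask is empty")
    vals <- md_maps[which(mask)]
    100 * mean(vals < threshold)
  }
}

#' Total-variation distance between two free-water histograms
#'
#' Bins both samples on \[0, 1\] (50 bins by default), normalizes to
#' probabilities, and returns \eqn{\tfrac12\sum_k |p_k - q_k|} — the
#' regularization-sensitivity metric: near 0 when the regularized and
#' unregularized FW maps distribute alike.
#'
#' @param x,y Numeric samples (values outside \[0,1\] are clipped).
#' @param bins Number of equal-width bins on \[0, 1\].
#' @return A number in \[0, 1\].
#' @export
fw_histogram_tv <- function(x, y, bins = 50) {
  stopifnot(bins >= 2, length(x) > 0, length(y) > 0)
  br <- seq(0, 1, length.out = bins + 1)
  cx <- tabulate(findInterval(pmin(pmax(x, 0), 1), br, rightmost.closed = TRUE),
                 nbins = bins)
  cy <- tabulate(findInterval(pmin(pmax(y, 0), 1), br, rightmost.closed = TRUE),
                 nbins = bins)
  0.5 * sum(abs(cx / sum(cx) - cy / sum(cy)))
}
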