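# Agreement metrics between model-estimated and ground-truth tumours:
# spatial overlap (Dice), voxelwise concordance (Lin's CCC) and global
# cellularity error.

#' Binarize a tumour state
#'
#' A voxel belongs to the tumour mask iff its combined normalized density
#' \code{N_E + N_N} meets the threshold (default 0.16, the non-enhancing
#' seeding density; boundary voxels at exactly the threshold are included).
#'
#' @param state List with arrays \code{NE} and \code{NN}.
#' @param threshold Non-negative density threshold.
#' @return Logical array.
#' @export
tumour_mask <- function(state, threshold = 0.16) {
  stopifnot(threshold >= 0)
  (state$NE + state$NN) >= threshold
}

#' Dice similarity coefficient
#'
#' \code{2|A n B| / (|A| + |B|)}; 1 for identical non-empty masks, 0 for
#' disjoint masks. Two empty masks are defined to agree perfectly (1).
#'
#' @param mask_a,mask_b Logical arrays of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must share the same grid")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) return(1)  # identical emptiness
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Physical carrying capacity of a voxel in cells
#'
#' \code{packing * voxel_volume / (4/3 * pi * r^3)} with the defaults
#' 0.7405 packing density, 10 um cell radius and 0.5 mm^3 voxel volume
#' (about 8.84e4 cells).
#'
#' @param packing_density Sphere packing density.
#' @param cell_radius Cell radius in mm (default 0.01 = 10 um).
#' @param voxel_volume Voxel volume in mm^3.
#' @return Cells per voxel.
#' @export
theta_cells <- function(packing_density = 0.7405, cell_radius = 0.01,
                        voxel_volume = 0.5) {
  stopifnot(packing_density > 0, cell_radius > 0, voxel_volume > 0)
  packing_density * voxel_volume / (4 / 3 * pi * cell_radius^3)
}

#' Total tumour cellularity
#'
#' \code{theta_cells * sum(N_E + N_N)} over the computational domain.
#'
#' @param state List with arrays \code{NE} and \code{NN}.
#' @param theta_cells_value Cells per voxel at capacity (default
#'   [theta_cells()]).
#' @return Cell count.
#' @export
total_cellularity <- function(state, theta_cells_value = theta_cells()) {
  theta_cells_value * sum(state$NE + state$NN)
}

#' Lin's concordance correlation coefficient
#'
#' \code{2 s_ab / (s_a^2 + s_b^2 + (mean_a - mean_b)^2)} with population
#' (1/n) moments; 1 iff the vectors agree elementwise, bounded by [-1, 1].
#' Sample (1/(n-1)) moments are available via \code{sample_moments = TRUE}.
#'
#' @param a,b Numeric vectors of equal length (at least 2), not both
#'   constant.
#' @param sample_moments Use n-1 denominators instead of n.
#' @return CCC value.
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
ccc <- function(a, b, sample_moments = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (length(b) != n || n < 2) stop("a and b must have equal length >= 2")
  ma <- mean(a); mb <- mean(b)
  den <- if (sample_moments) n - 1 else n
  va <- sum((a - ma)^2) / den
  vb <- sum((b - mb)^2) / den
  cab <- sum((a - ma) * (b - mb)) / den
  denom <- va + vb + (ma - mb)^2
  if (denom == 0) stop("ccc undefined: both inputs are constant and equal")
  2 * cab / denom
}

#' Signed percentage error
#'
#' \code{100 * (estimate - truth) / truth}. Parameter-error summaries use
#' the absolute value; cellularity errors are reported signed.
#'
#' @param estimate,truth Numeric (truth nonzero).
#' @return Percentage error.
#' @export
percent_error <- function(estimate, truth) {
  if (any(truth == 0)) stop("truth must be nonzero")
  100 * (estimate - truth) / truth
}

#' Median and interquartile range
#'
#' Sample median and Q3 - Q1 with the linear-interpolation quantile
#' convention (type 7).
#'
#' @param values Non-empty numeric vector.
#' @return Named vector \code{c(median, iqr)}.
#' @export
summarize_metric <- function(values) {
  if (!length(values)) stop("empty input")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Agreement report between a model-estimated and a ground-truth state
#'
#' Computes the Dice coefficient of the thresholded masks, the voxelwise
#' concordance correlation of the combined density over the brain mask, and
#' the signed percentage error in total tumour cellularity.
#'
#' @param estimated,truth States (lists with arrays \code{NE}, \code{NN}).
#' @param brain_mask Logical array restricting the CCC to brain voxels.
#' @param threshold Binarization threshold for the Dice masks.
#' @param time_label \code{"calibration"} or \code{"prediction"}.
#' @return Object of class \code{metrics_report} (a one-row data frame
#'   with columns \code{dsc}, \code{ccc}, \code{pe_ttc},
#'   \code{time_label}).
#' @export
metrics_report <- function(estimated, truth, brain_mask,
                           threshold = 0.16,
                           time_label = c("calibration", "prediction")) {
  time_label <- match.arg(time_label)
  d <- dice(tumour_mask(estimated, threshold), tumour_mask(truth, threshold))
  a <- (truth$NE + truth$NN)[brain_mask]
  b <- (estimated$NE + estimated$NN)[brain_mask]
  # an annihilated tumour leaves both fields (numerically) constant zero,
  # where the CCC is undefined: identical emptiness counts as agreement
  cc <- if (var(a) + var(b) + (mean(a) - mean(b))^2 == 0) {
    if (max(abs(a - b)) < 1e-12) 1 else NA_real_
  } else ccc(a, b)
  tt <- total_cellularity(truth); te <- total_cellularity(estimated)
  pe <- if (tt == 0) {
    if (te == 0) 0 else NA_real_
  } else percent_error(te, tt)
  structure(data.frame(dsc = d, ccc = cc, pe_ttc = pe,
                       time_label = time_label),
            class = c("metrics_report", "data.frame"))
}
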