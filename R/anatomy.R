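# Synthetic anatomy: voxel grid, brain mask, tissue labels, tumour seed,
# enhancement-ratio map and fractionated dose maps. Emulates the role of
# treatment-planning MRI in a fully synthetic, seeded, reproducible way.

#' Voxel grid with brain mask and tissue labels
#'
#' @param dims Integer triple (nx, ny, nz).
#' @param spacing Voxel spacing in mm (default 0.5 x 0.5 x 2).
#' @param brain_mask Logical array of dimension \code{dims}.
#' @param tissue Integer array: 0 outside the brain, 1 white matter,
#'   2 grey matter. Every white/grey voxel must lie inside the mask.
#' @return An object of class \code{tumour_grid}.
#' @export
make_grid <- function(dims, spacing = c(0.5, 0.5, 2.0), brain_mask, tissue) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims > 0), length(spacing) == 3,
            all(spacing > 0))
  stopifnot(identical(dim(brain_mask), dims), identical(dim(tissue), dims))
  if (any((tissue > 0) != brain_mask))
    stop("tissue labels must partition the brain mask exactly")
  idx <- array(0L, dims)
  idx[brain_mask] <- seq_len(sum(brain_mask))
  g <- structure(
    list(dims = dims, spacing = as.numeric(spacing), brain_mask = brain_mask,
         tissue = tissue, idx = idx, n_inside = sum(brain_mask),
         cache = new.env(parent = emptyenv())),
    class = "tumour_grid")
  g
}

#' @export
print.tumour_grid <- function(x, ...) {
  cat(sprintf("<tumour_grid %dx%dx%d @ %.2gx%.2gx%.2g mm, %d brain voxels (%d white, %d grey)>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$n_inside, sum(x$tissue == 1L), sum(x$tissue == 2L)))
  invisible(x)
}

# 6-neighbour table over mask voxels (rows: -x,+x,-y,+y,-z,+z), 0 = no
# in-mask neighbour in that direction (zero-flux face).
.neighbour_table <- function(grid) {
  if (!is.null(grid$cache$nb)) return(grid$cache$nb)
  d <- grid$dims; idx <- grid$idx
  inside <- which(grid$brain_mask)
  coord <- arrayInd(inside, d)
  nb <- matrix(0L, nrow = 6, ncol = length(inside))
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  for (f in 1:6) {
    cc <- sweep(coord, 2, off[f, ], "+")
    ok <- cc[, 1] >= 1 & cc[, 1] <= d[1] & cc[, 2] >= 1 & cc[, 2] <= d[2] &
      cc[, 3] >= 1 & cc[, 3] <= d[3]
    lin <- rep(0L, length(inside))
    lin[ok] <- idx[cbind(cc[ok, 1], cc[ok, 2], cc[ok, 3])]
    nb[f, ] <- lin
  }
  grid$cache$nb <- nb
  nb
}

# Run expr with a private, seeded RNG stream; the caller's RNG state is
# untouched.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian smoothing of a 2D matrix (zero-padded, renormalized at edges).
.smooth2d <- function(m, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  w1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  ker <- outer(w1, w1)
  out <- matrix(0, nrow(m), ncol(m))
  wsum <- matrix(0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  for (di in -r:r) for (dj in -r:r) {
    wt <- ker[di + r + 1, dj + r + 1]
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    out[si, sj] <- out[si, sj] + wt * m[si + di, sj + dj]
    wsum[si, sj] <- wsum[si, sj] + wt
  }
  out / wsum
}

# In-plane erosion of a logical slice by one voxel (4-neighbourhood).
.erode2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[1, ] <- FALSE; out[nr, ] <- FALSE; out[, 1] <- FALSE; out[, nc] <- FALSE
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  out[i, j] <- m[i, j] & m[i - 1, j] & m[i + 1, j] & m[i, j - 1] & m[i, j + 1]
  out
}

#' Map apparent diffusion coefficient to normalized tumour density
#'
#' Inverse-linear conversion of diffusion-weighted-MRI ADC values to
#' normalized enhancing tumour density: low water mobility means densely
#' packed cells. The free-water ADC is fixed at 3e-3 mm^2/s.
#'
#' @param adc Numeric array/vector of ADC values (mm^2/s).
#' @param adc_min Minimum ADC observed within tumour (mm^2/s).
#' @param adc_w Free-water ADC (default 3e-3 mm^2/s).
#' @return Densities in [0, 1], same shape as \code{adc}.
#' @export
adc_to_density <- function(adc, adc_min, adc_w = 3e-3) {
  stopifnot(adc_min < adc_w)
  if (any(adc > adc_w + 1e-15) || any(adc < adc_min - 1e-15))
    stop("ADC values must lie within [adc_min, adc_w]")
  (adc_w - adc) / (adc_w - adc_min)
}

#' Generate a synthetic virtual-patient anatomy
#'
#' Builds, deterministically for a given seed, the fixed scaffold of one
#' virtual patient: an elliptical brain mask on a 3-slice voxel grid, a
#' smoothed random white/grey partition, an enhancing tumour core placed
#' interior to the mask (constructed through a pseudo-ADC map so the
#' ADC-to-density conversion round-trips), a non-enhancing rim at fixed
#' density 0.16, an enhancement-ratio (ER) map with background near 1 and an
#' elevated ring around the enhancing core, and gross/clinical target
#' volumes for dose planning.
#'
#' @param seed Integer seed; identical seeds give bit-identical anatomies.
#' @param dims Grid dimensions, at least (16, 16, 3).
#' @param spacing Voxel spacing in mm.
#' @param core_amplitude Peak normalized enhancing density (default 0.8).
#' @param sigma_core Gaussian radius of the enhancing core in mm.
#' @param rim_radius Outer radius of the non-enhancing rim in mm.
#' @param adc_min Minimum tumour ADC used for the pseudo-ADC construction.
#' @param constants \code{model_constants}.
#' @return An object of class \code{tumour_anatomy}: \code{grid},
#'   \code{er_map}, \code{gtv_mask}, \code{ctv_mask}, \code{initial}
#'   (list with fields \code{NE}, \code{NN} at day 0) and \code{seed}.
#' @export
make_anatomy <- function(seed, dims = c(24, 24, 3), spacing = c(0.5, 0.5, 2.0),
                         core_amplitude = 0.8, sigma_core = 1.2,
                         rim_radius = 3.0, adc_min = 0.5e-3,
                         constants = model_constants()) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < c(16L, 16L, 3L)))
    stop("dims must be at least (16, 16, 3)")
  .with_seed(seed, {
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    ii <- matrix(seq_len(nx), nx, ny)
    jj <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    a <- 0.44 * nx; b <- 0.46 * ny
    slice_mask <- ((ii - cx) / a)^2 + ((jj - cy) / b)^2 <= 1
    brain_mask <- array(rep(slice_mask, nz), dims)

    # white/grey: smoothed random field thresholded at its in-mask median
    f <- .smooth2d(matrix(rnorm(nx * ny), nx, ny), sigma = max(1.5, nx / 12))
    thr <- median(f[slice_mask])
    white2d <- slice_mask & (f >= thr)
    tissue <- array(0L, dims)
    for (k in seq_len(nz)) {
      tk <- matrix(0L, nx, ny)
      tk[white2d] <- 1L
      tk[slice_mask & !white2d] <- 2L
      tissue[, , k] <- tk
    }
    grid <- make_grid(dims, spacing, brain_mask, tissue)

    # tumour seed: in-plane interior margin of rim_radius from the mask edge
    margin_vox <- ceiling(rim_radius / spacing[1])
    eligible <- slice_mask
    for (m in seq_len(margin_vox)) eligible <- .erode2d(eligible)
    if (!any(eligible))
      stop("dims too small to place a tumour seed ", rim_radius,
           " mm inside the brain mask")
    pick <- sample(which(eligible), 1)
    sc <- arrayInd(pick, c(nx, ny))
    kz <- (nz + 1) %/% 2  # centre slice

    # physical distance from the seed
    xg <- (seq_len(nx) - sc[1]) * spacing[1]
    yg <- (seq_len(ny) - sc[2]) * spacing[2]
    zg <- (seq_len(nz) - kz) * spacing[3]
    d <- sqrt(outer(outer(xg^2, yg^2, "+"), zg^2, "+"))

    # enhancing core via a pseudo-ADC map (round-trips through Eq-style
    # inverse-linear ADC conversion)
    ne_target <- core_amplitude * exp(-d^2 / (2 * sigma_core^2))
    ne_target[ne_target < 0.05 | !brain_mask] <- 0
    adc_w <- 3e-3
    adc <- adc_w - ne_target * (adc_w - adc_min)
    NE <- adc_to_density(adc, adc_min = adc_min, adc_w = adc_w)
    NE[!brain_mask] <- 0

    NN <- array(0, dims)
    rim <- brain_mask & (NE == 0) & (d <= rim_radius)
    NN[rim] <- constants$theta_N

    # ER map: background ~1, elevated ring at the enhancing margin plus a
    # smooth non-negative random texture
    tex <- .smooth2d(matrix(rnorm(nx * ny), nx, ny), sigma = 2)
    tex <- (tex - min(tex)) / max(1e-12, diff(range(tex)))
    er <- array(1, dims)
    ring <- 0.9 * exp(-(d - 0.8 * rim_radius)^2 / (2 * 0.8^2))
    for (k in seq_len(nz)) er[, , k] <- 1 + ring[, , k] + 0.15 * tex
    er[!brain_mask] <- 1

    gtv <- NE > 0
    ctv <- .dilate_mm(gtv, brain_mask, spacing, 20)

    structure(
      list(grid = grid, er_map = er, gtv_mask = gtv, ctv_mask = ctv,
           initial = list(NE = NE, NN = NN, day = 0),
           seed_voxel = c(sc[1], sc[2], kz), seed = seed,
           constants = constants),
      class = "tumour_anatomy")
  })
}

# In-plane dilation of a mask by a physical margin (mm), clipped to brain.
.dilate_mm <- function(mask, brain_mask, spacing, margin_mm) {
  d <- dim(mask)
  rx <- floor(margin_mm / spacing[1]); ry <- floor(margin_mm / spacing[2])
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    ii <- matrix(seq_len(d[1]), d[1], d[2])
    jj <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    acc <- matrix(FALSE, d[1], d[2])
    for (r in seq_len(nrow(idx))) {
      acc <- acc | (((ii - idx[r, 1]) * spacing[1])^2 +
                      ((jj - idx[r, 2]) * spacing[2])^2 <= margin_mm^2)
    }
    out[, , k] <- acc
  }
  out & brain_mask
}

#' @export
print.tumour_anatomy <- function(x, ...) {
  cat(sprintf("<tumour_anatomy seed %s>\n", format(x$seed)))
  print(x$grid)
  cat(sprintf("  enhancing core: %d voxels (peak %.2f), non-enhancing rim: %d voxels @ %.2f\n",
              sum(x$initial$NE > 0), max(x$initial$NE),
              sum(x$initial$NN > 0), x$constants$theta_N))
  cat(sprintf("  GTV %d voxels, CTV %d voxels, ER in [%.2f, %.2f]\n",
              sum(x$gtv_mask), sum(x$ctv_mask),
              min(x$er_map[x$grid$brain_mask]), max(x$er_map[x$grid$brain_mask])))
  invisible(x)
}

#' Fractionated chemoradiation schedule
#'
#' Standard-of-care prescription: 60 Gy to the gross tumour volume (GTV) and
#' 50 Gy to the clinical target volume (GTV plus a 2 cm margin), delivered
#' in 30 weekday fractions over six weeks with concurrent chemotherapy on
#' every fraction day.
#'
#' @param anatomy A \code{tumour_anatomy}.
#' @param start_day Day of the first fraction (default 0).
#' @param n_fractions Number of fractions (default 30).
#' @param gtv_total_dose,ctv_total_dose Total doses in Gy (defaults 60, 50).
#' @return List of treatment events, each with \code{day}, \code{has_rt},
#'   \code{has_ct}, \code{dose_map} (Gy per fraction) and
#'   \code{fraction_index}.
#' @export
make_schedule <- function(anatomy, start_day = 0, n_fractions = 30,
                          gtv_total_dose = 60, ctv_total_dose = 50) {
  stopifnot(inherits(anatomy, "tumour_anatomy"))
  if (n_fractions <= 0) stop("n_fractions must be positive")
  dose <- array(0, anatomy$grid$dims)
  dose[anatomy$ctv_mask] <- ctv_total_dose / n_fractions
  dose[anatomy$gtv_mask] <- gtv_total_dose / n_fractions
  f <- seq_len(n_fractions) - 1L
  days <- start_day + 7 * (f %/% 5) + (f %% 5)  # Mon-Fri, weekend gaps
  lapply(seq_len(n_fractions), function(i) {
    list(day = days[i], has_rt = TRUE, has_ct = TRUE,
         dose_map = dose, fraction_index = i)
  })
}
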