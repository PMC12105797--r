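# Virtual-patient cohort: ground-truth parameter sampling, ground-truth
# trajectories, and noisy observations standing in for longitudinal MRI.

#' Sample ground-truth parameters for one variant
#'
#' Independent uniform draws within the bounds for the variant's calibrated
#' parameters; fixed parameters follow the variant rules (\code{alpha_CT =
#' 1} where it is not calibrated, all treatment terms inert for M11).
#'
#' @param variant A \code{model_variant}.
#' @param bounds A \code{parameter_bounds} object.
#' @param seed Optional integer; if given, draws use a private seeded RNG
#'   stream, otherwise the current RNG state.
#' @return Full named parameter vector (length 12) with attribute
#'   \code{"free"} naming the sampled entries.
#' @export
sample_parameters <- function(variant, bounds = default_parameter_bounds(),
                              seed = NULL) {
  draw <- function() {
    vals <- vapply(variant$free, function(nm) {
      p <- bounds[[nm]]
      if (is.null(p)) stop("no bounds for parameter ", nm)
      runif(1, p[1], p[2])
    }, numeric(1))
    out <- expand_parameters(variant, vals)
    attr(out, "free") <- variant$free
    out
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Add imaging noise to a simulated trajectory
#'
#' Voxelwise additive zero-mean Gaussian noise with standard deviation
#' \code{level * theta_j} per species. By default noise is restricted to
#' voxels where the species' true density exceeds a detectability floor,
#' mirroring a segmentation-based imaging pipeline in which densities exist
#' only inside delineated tumour regions; \code{where = "mask"} noises
#' every brain voxel instead. The baseline (day-0) fields are noised
#' identically to the later time points. Observations keep the raw noisy
#' values by default (zero-mean measurement error, so tumour-burden sums
#' stay unbiased); \code{truncate = TRUE} clamps them to the physical
#' range \code{[0, theta_j]} instead. The forward model itself always
#' clips its state to the physical range, whatever the observations do.
#'
#' @param sim A \code{tumour_sim} (or list of states).
#' @param level Noise level, e.g. 0.05 / 0.10 / 0.15; other non-negative
#'   values are allowed with a warning.
#' @param seed Integer seed for the private RNG stream.
#' @param where \code{"tumour"} (default) or \code{"mask"}.
#' @param floor Detectability floor as a fraction of each species' carrying
#'   capacity (default 0.05), used when \code{where = "tumour"}.
#' @param truncate Clamp noisy values to \code{[0, theta_j]} (default
#'   FALSE).
#' @param constants \code{model_constants}.
#' @param mask Logical array of brain voxels (required for
#'   \code{where = "mask"}; defaults to positive-capacity support).
#' @return Object of class \code{tumour_observations}: \code{days},
#'   \code{fields} (per day, arrays \code{NE}, \code{NN}),
#'   \code{noise_level}.
#' @export
add_noise <- function(sim, level, seed, where = c("tumour", "mask"),
                      floor = 0.05, truncate = FALSE,
                      constants = model_constants(), mask = NULL) {
  where <- match.arg(where)
  if (level < 0) stop("noise level must be non-negative")
  if (level > 0 && !isTRUE(all.equal(level, 0.05)) &&
      !isTRUE(all.equal(level, 0.10)) && !isTRUE(all.equal(level, 0.15)))
    warning("noise level ", level, " is outside the study's 5/10/15% levels")
  states <- if (inherits(sim, "tumour_sim")) sim$states else sim
  theta <- c(NE = constants$theta_E, NN = constants$theta_N)
  .with_seed(seed, {
    fields <- lapply(states, function(st) {
      out <- list(day = st$day)
      for (sp in c("NE", "NN")) {
        f <- st[[sp]]
        if (level > 0) {
          eligible <- if (where == "tumour") f > floor * theta[[sp]]
          else if (!is.null(mask)) mask else f >= 0
          idx <- which(eligible)
          if (length(idx)) {
            f[idx] <- f[idx] + rnorm(length(idx), 0, level * theta[[sp]])
            if (truncate) f[idx] <- pmin(pmax(f[idx], 0), theta[[sp]])
          }
        }
        out[[sp]] <- f
      }
      out
    })
    structure(list(days = vapply(states, function(s) s$day, numeric(1)),
                   fields = fields, noise_level = level, where = where,
                   floor = floor),
              class = "tumour_observations")
  })
}

#' @export
print.tumour_observations <- function(x, ...) {
  cat(sprintf("<tumour_observations at days %s, %.0f%% noise (%s)>\n",
              paste(x$days, collapse = ", "), 100 * x$noise_level, x$where))
  invisible(x)
}

#' Generate a virtual-patient cohort
#'
#' For each of \code{n_patients} synthetic anatomies and each model variant,
#' samples a unique ground-truth parameter set, grows the ground-truth
#' tumour trajectory at the observation days (pre-treatment, the first three
#' weeks of radiotherapy, and four weeks post-radiotherapy), and attaches
#' noisy observations at each requested noise level. Fully reproducible from
#' \code{master_seed}.
#'
#' @param n_patients Number of virtual patients (anatomies).
#' @param variants List of \code{model_variant}s (default all eleven).
#' @param bounds \code{parameter_bounds} for ground-truth sampling.
#' @param noise_levels Numeric vector of noise levels (default 5/10/15%).
#' @param master_seed Integer master seed.
#' @param dims Grid dimensions per patient.
#' @param observation_days Imaging days (default \code{c(0, 7, 14, 21, 67)}:
#'   treatment planning, weeks 1-3 of RT, and four weeks after the 30th
#'   fraction on day 39).
#' @param noise_where Passed to [add_noise()].
#' @param max_retries Resampling attempts if a sampled parameter set makes
#'   the simulation blow up.
#' @param control [sim_control()].
#' @return Object of class \code{virtual_cohort}: \code{tumours} (list of
#'   virtual patients, each with anatomy, schedule, generating variant,
#'   true parameters, ground truth and observations), \code{manifest}
#'   (data frame) and the generation settings.
#' @export
generate_cohort <- function(n_patients, variants = model_family(),
                            bounds = default_parameter_bounds(),
                            noise_levels = c(0.05, 0.10, 0.15),
                            master_seed = 1L, dims = c(24, 24, 3),
                            observation_days = c(0, 7, 14, 21, 67),
                            noise_where = "tumour", max_retries = 5,
                            control = sim_control()) {
  stopifnot(n_patients >= 1)
  ncols <- 2 + length(variants) *
    (max_retries + 2 + max(1, length(noise_levels)))
  seeds <- .with_seed(master_seed, {
    matrix(sample.int(2^31 - 2, n_patients * ncols), nrow = n_patients)
  })
  tumours <- list()
  manifest <- list()
  ti <- 0L
  for (pi in seq_len(n_patients)) {
    anatomy <- make_anatomy(seeds[pi, 1], dims = dims)
    schedule <- make_schedule(anatomy)
    sc <- 2L
    for (vi in seq_along(variants)) {
      variant <- variants[[vi]]
      truth <- NULL; params <- NULL
      for (try in 0:max_retries) {
        sc <- sc + 1L
        params <- sample_parameters(variant, bounds, seed = seeds[pi, sc])
        truth <- tryCatch(
          simulate_tumour(variant, params, anatomy, schedule,
                          observation_days, control = control),
          error = function(e) NULL)
        if (!is.null(truth)) break
        message("patient ", pi, " ", variant$id,
                ": simulation failed, resampling parameters (retry ",
                try + 1, ")")
      }
      if (is.null(truth))
        stop("could not grow a tumour for patient ", pi, " variant ",
             variant$id, " after ", max_retries, " retries")
      obs <- list()
      for (li in seq_along(noise_levels)) {
        sc <- sc + 1L
        obs[[as.character(noise_levels[li])]] <-
          add_noise(truth, noise_levels[li], seed = seeds[pi, sc],
                    where = noise_where, constants = anatomy$constants)
      }
      ti <- ti + 1L
      tumours[[ti]] <- list(patient = pi, anatomy = anatomy,
                            schedule = schedule, variant = variant,
                            true_params = params, truth = truth,
                            observations = obs)
      manifest[[ti]] <- data.frame(
        tumour = ti, patient = pi, variant = variant$id,
        anatomy_seed = seeds[pi, 1],
        as.list(setNames(as.numeric(params), names(params))))
    }
  }
  structure(list(tumours = tumours, manifest = do.call(rbind, manifest),
                 master_seed = master_seed, noise_levels = noise_levels,
                 dims = dims, observation_days = observation_days),
            class = "virtual_cohort")
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf("<virtual_cohort: %d tumours (%d patients x %d variants), noise %s, master seed %s>\n",
              length(x$tumours), length(unique(x$manifest$patient)),
              length(unique(x$manifest$variant)),
              paste0(100 * x$noise_levels, "%", collapse = "/"),
              format(x$master_seed)))
  invisible(x)
}
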