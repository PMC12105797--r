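# Forward simulation of one model variant on a virtual-patient anatomy.

#' Simulation control settings
#'
#' @param dt_max Upper limit on the explicit time step in days (default
#'   0.1); the actual step is
#'   \code{min(dt_max, cfl / (2 * D_max * sum(1/h^2)))}, rounded down to an
#'   integer number of substeps per day.
#' @param cfl Safety factor on the diffusion stability bound (default 0.9).
#' @param mech_cadence Days between refreshes of the quasi-static mechanics
#'   solve and the stress-damped diffusion field (default 1).
#' @return List of class \code{sim_control}.
#' @export
sim_control <- function(dt_max = 0.1, cfl = 0.9, mech_cadence = 1) {
  stopifnot(dt_max > 0, cfl > 0, cfl <= 1, mech_cadence >= 1)
  structure(list(dt_max = dt_max, cfl = cfl, mech_cadence = mech_cadence),
            class = "sim_control")
}

# Hard diffusion stability bound for the explicit scheme.
.stability_bound <- function(D_max, spacing) {
  if (D_max <= 0) return(Inf)
  1 / (2 * D_max * sum(1 / spacing^2))
}

#' One explicit growth step
#'
#' Performs a single forward-Euler update of both species with
#' central-difference diffusion (zero-flux at the brain boundary) and
#' logistic-competition reactions, then clips to the carrying capacities.
#' Mostly useful for testing; [simulate_tumour()] drives whole trajectories.
#'
#' @param state List with arrays \code{NE}, \code{NN}.
#' @param D_E_field,D_N_field Diffusion fields (arrays, mm^2/day).
#' @param kpE_eff,kpN_eff Effective proliferation-rate fields (arrays,
#'   1/day).
#' @param params Named parameter vector (uses \code{beta_NE},
#'   \code{beta_EN}).
#' @param grid A \code{tumour_grid}.
#' @param constants \code{model_constants}.
#' @param dt Time step in days; must satisfy the stability bound.
#' @return Updated state (with a \code{clipped} attribute counting clips).
#' @export
growth_step <- function(state, D_E_field, D_N_field, kpE_eff, kpN_eff,
                        params, grid, constants = model_constants(), dt) {
  m <- grid$brain_mask
  D_max <- max(D_E_field[m], D_N_field[m], 0)
  bound <- .stability_bound(D_max, grid$spacing)
  if (dt > bound)
    stop(sprintf("dt = %g violates the diffusion stability bound %g", dt, bound))
  nb <- .neighbour_table(grid)
  out <- cpp_growth(state$NE[m], state$NN[m], D_E_field[m], D_N_field[m],
                    kpE_eff[m], kpN_eff[m],
                    params[["beta_NE"]], params[["beta_EN"]],
                    constants$theta_E, constants$theta_N,
                    nb, 1 / grid$spacing^2, dt, 1L)
  state$NE[m] <- out$NE
  state$NN[m] <- out$NN
  attr(state, "clipped") <- out$clipped
  state
}

# Static inputs of the C++ simulation engine for one (variant, anatomy,
# schedule) combination. Built once per calibration and reused for every
# residual/Jacobian evaluation.
.engine_context <- function(variant, anatomy, schedule,
                            control = sim_control()) {
  grid <- anatomy$grid
  m <- grid$brain_mask
  constants <- anatomy$constants
  mode_code <- function(x) switch(x, off = 0L, uniform = 1L,
                                  vasculature = 2L, density = 3L)
  treated <- !(variant$rt_coupling == "off" && variant$ct_coupling == "off" &&
                 !variant$combined)
  events <- if (treated && length(schedule)) schedule else list()
  n <- grid$n_inside
  dose_maps <- if (length(events))
    vapply(events, function(e) e$dose_map[m], numeric(n))
  else matrix(0, n, 0)
  needs_oer <- treated && (variant$rt_coupling == "vasculature" ||
                             variant$ct_coupling == "vasculature")
  oer <- if (needs_oer) oer_map(anatomy$er_map, m)[m] else rep(1, n)
  mech <- build_mechanics(grid, constants)
  list(
    grid = grid, constants = constants, variant = variant,
    lab = as.integer(grid$tissue[m]), nb = .neighbour_table(grid),
    inv_h2 = 1 / grid$spacing^2,
    event_days = as.integer(vapply(events, function(e) e$day, numeric(1))),
    event_has_rt = vapply(events, function(e) isTRUE(e$has_rt), logical(1)),
    dose_maps = dose_maps, oer = oer,
    rt_mode = mode_code(variant$rt_coupling),
    ct_mode = mode_code(variant$ct_coupling),
    combined = variant$combined,
    mech_csc = mech$csc, control = control)
}

# Run the engine for a matrix of parameter columns (12 x P, canonical
# order) from a common initial state; returns the raw engine output.
.engine_run <- function(ctx, par_mat, init_ne, init_nn, obs_days, day0) {
  use_mech <- any(par_mat[8, ] > 0)
  cpp_sim_engine(init_ne, init_nn, par_mat, ctx$lab, ctx$nb, ctx$inv_h2,
                 ctx$constants$theta_E, ctx$constants$theta_N,
                 ctx$control$dt_max, ctx$control$cfl,
                 as.integer(ctx$control$mech_cadence),
                 ctx$mech_csc, use_mech,
                 ctx$event_days, ctx$event_has_rt, ctx$dose_maps, ctx$oer,
                 ctx$rt_mode, ctx$ct_mode, ctx$combined,
                 as.integer(obs_days), as.integer(day0))
}

#' Simulate tumour growth and treatment response
#'
#' Integrates the coupled two-species reaction-diffusion system with
#' mechanics-damped diffusion between treatment events, applies each
#' fraction of radiotherapy/chemotherapy as a discrete voxelwise reduction
#' according to the variant's coupling assumption, accumulates the
#' proliferation-reducing effect of delivered fractions, and returns the
#' state at the requested observation days. Observations on an event day
#' are recorded before the event (imaging precedes the fraction).
#'
#' @param variant A \code{model_variant}.
#' @param params Full named parameter vector (see [expand_parameters()]).
#' @param anatomy A \code{tumour_anatomy}.
#' @param schedule Treatment schedule from [make_schedule()] (may be
#'   \code{NULL} or empty for untreated growth).
#' @param observation_days Sorted integer days; the first must equal the
#'   initial day of \code{init_state}.
#' @param init_state Optional starting state (default the anatomy's day-0
#'   state); used by calibration to start from the measured noisy fields.
#' @param control A [sim_control()].
#' @return Object of class \code{tumour_sim}: \code{states} (one per
#'   observation day, each with arrays \code{NE}, \code{NN} and
#'   \code{day}), \code{er_map}, \code{auxiliary} (final diffusion/stress
#'   diagnostics), \code{clipped} (number of clipped voxel updates) and the
#'   call ingredients.
#' @examples
#' an <- make_anatomy(1, dims = c(16, 16, 3))
#' v <- model_variant("M11")
#' p <- expand_parameters(v, c(kpE = 0.05, kpN = 0.03, D_w = 0.2, D_g = 0.1,
#'   f_NE = 1, beta_NE = 0.5, beta_EN = 0.5, lambda1 = 0.2))
#' sim <- simulate_tumour(v, p, an, NULL, c(0, 7))
#' sapply(sim$states, function(s) sum(s$NE))
#' @export
simulate_tumour <- function(variant, params, anatomy, schedule,
                            observation_days, init_state = NULL,
                            control = sim_control()) {
  stopifnot(inherits(variant, "model_variant"),
            inherits(anatomy, "tumour_anatomy"))
  grid <- anatomy$grid
  constants <- anatomy$constants
  m <- grid$brain_mask
  obs_days <- as.numeric(observation_days)
  if (is.unsorted(obs_days, strictly = TRUE))
    stop("observation_days must be strictly increasing")
  state0 <- if (is.null(init_state)) anatomy$initial else init_state
  day0 <- if (is.null(state0$day)) obs_days[1] else state0$day
  if (obs_days[1] != day0)
    stop("first observation day must equal the initial state's day")

  p <- params[parameter_names()]
  ctx <- .engine_context(variant, anatomy, schedule, control)
  # measured initial conditions may carry unclipped noise; the model state
  # itself lives in the physical range
  ne0 <- pmin(pmax(state0$NE[m], 0), constants$theta_E)
  nn0 <- pmin(pmax(state0$NN[m], 0), constants$theta_N)
  out <- .engine_run(ctx, matrix(p, ncol = 1), ne0, nn0, obs_days, day0)
  states <- lapply(seq_along(obs_days), function(i) {
    NEf <- array(0, grid$dims); NNf <- array(0, grid$dims)
    NEf[m] <- out$NE[[i]][, 1]
    NNf[m] <- out$NN[[i]][, 1]
    list(NE = NEf, NN = NNf, day = obs_days[i])
  })
  structure(
    list(states = states, er_map = anatomy$er_map,
         auxiliary = list(D_E = out$DE, D_N = out$DN,
                          von_mises = if (p[["lambda1"]] > 0) out$vm else NULL),
         clipped = out$clipped[1], variant = variant, params = p,
         observation_days = obs_days, dt = out$dt[1]),
    class = "tumour_sim")
}

#' @export
print.tumour_sim <- function(x, ...) {
  tots <- vapply(x$states, function(s) sum(s$NE + s$NN), numeric(1))
  cat(sprintf("<tumour_sim %s, %d observation days (dt = %.3g d, %g clipped updates)>\n",
              x$variant$id, length(x$states), x$dt, x$clipped))
  print(data.frame(day = x$observation_days, total_density = tots),
        row.names = FALSE)
  invisible(x)
}
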