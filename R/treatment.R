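# Discrete treatment response: linear-quadratic cell survival with optional
# coupling of efficacy to vasculature (oxygen enhancement ratio) or to local
# cell density, and the prolonged proliferation-reducing effect of
# fractionated radiotherapy.

#' Oxygen enhancement ratio from an enhancement-ratio map
#'
#' The enhancement ratio (post-/pre-contrast T1 signal) is taken as a proxy
#' for vasculature and hence tissue oxygenation. The voxel with the highest
#' enhancement ratio inside the brain mask is assumed fully oxygenated
#' (OER = 1); poorer-perfused voxels get OER > 1, which scales down the
#' effective radiation dose.
#'
#' @param er_field Numeric array of enhancement ratios (finite, positive).
#' @param mask Logical array; the maximum is taken over these voxels.
#' @return OER field, \code{>= 1} on the mask (set to 1 outside).
#' @examples
#' oer_map(array(c(1, 1.2, 2), c(3, 1, 1)), array(TRUE, c(3, 1, 1)))
#' @export
oer_map <- function(er_field, mask) {
  if (!any(mask)) stop("empty mask")
  er <- er_field[mask]
  if (!all(is.finite(er)) || any(er <= 0))
    stop("enhancement ratios must be finite and positive")
  out <- array(1, dim(er_field))
  out[mask] <- max(er) - er + 1
  out
}

#' Linear-quadratic surviving fraction
#'
#' Classical LQ cell survival for one fraction:
#' \code{SF = exp(-alpha * Dose * (1 + Dose / (alpha/beta)))}. For the
#' chemotherapy term the quadratic part is dropped (\code{alpha_beta =
#' Inf}), giving \code{SF = exp(-alpha * Dose)}.
#'
#' @param alpha Sensitivity (1/Gy), non-negative.
#' @param dose Dose (Gy), non-negative scalar or field.
#' @param alpha_beta Alpha/beta ratio (Gy); \code{Inf} drops the quadratic
#'   term (the chemotherapy convention).
#' @return Surviving fraction in (0, 1], same shape as \code{dose}.
#' @export
surviving_fraction_lq <- function(alpha, dose, alpha_beta) {
  if (alpha < 0 || any(dose < 0)) stop("alpha and dose must be non-negative")
  if (!is.infinite(alpha_beta) && alpha_beta <= 0)
    stop("alpha_beta must be positive (or Inf for the linear CT form)")
  quad <- if (is.infinite(alpha_beta)) 0 else dose / alpha_beta
  exp(-alpha * dose * (1 + quad))
}

#' Vasculature-coupled (OER-modified) surviving fraction
#'
#' The local dose is divided by the oxygen enhancement ratio before entering
#' the LQ model, so poorly perfused voxels respond less to treatment.
#' Reduces to [surviving_fraction_lq()] where \code{oer = 1}.
#'
#' @inheritParams surviving_fraction_lq
#' @param oer OER field, \code{>= 1}.
#' @return Surviving fraction field in (0, 1].
#' @export
surviving_fraction_oer <- function(alpha, dose, alpha_beta, oer) {
  if (any(oer < 1)) stop("oer must be >= 1 everywhere")
  surviving_fraction_lq(alpha, dose / oer, alpha_beta)
}

#' Density-modulated surviving fraction
#'
#' Interpolates between the LQ surviving fraction (at carrying capacity) and
#' no effect (in empty voxels) linearly in the total normalized density:
#' \code{SF = SF_min + (1 - SF_min) * (1 - (N_E + N_N)/(theta_E + theta_N))}.
#'
#' @param sf_min LQ surviving fraction field or scalar (the "minimum"
#'   survival, attained at carrying capacity), in (0, 1].
#' @param N_E,N_N Normalized density fields.
#' @param constants \code{model_constants}.
#' @return Surviving fraction field in \code{[sf_min, 1]}.
#' @export
surviving_fraction_density <- function(sf_min, N_E, N_N,
                                       constants = model_constants()) {
  tot <- N_E + N_N
  cap <- constants$theta_E + constants$theta_N
  if (any(N_E > constants$theta_E + 1e-9) ||
      any(N_N > constants$theta_N + 1e-9))
    stop("densities exceed carrying capacities")
  sf_min + (1 - sf_min) * (1 - tot / cap)
}

#' Apply one discrete treatment event
#'
#' Multiplies both species by the radiotherapy and chemotherapy surviving
#' fractions voxelwise.
#'
#' @param state List with fields \code{NE}, \code{NN} (and \code{day}).
#' @param sf_rt_field,sf_ct_field Surviving-fraction fields or scalars in
#'   (0, 1].
#' @return The post-event state.
#' @export
apply_treatment_event <- function(state, sf_rt_field, sf_ct_field) {
  for (sf in list(sf_rt_field, sf_ct_field))
    if (any(sf <= 0) || any(sf > 1)) stop("surviving fractions must lie in (0, 1]")
  state$NE <- state$NE * sf_rt_field * sf_ct_field
  state$NN <- state$NN * sf_rt_field * sf_ct_field
  state
}

#' Radiation-reduced effective proliferation rate
#'
#' Each delivered fraction leaves a smaller pool of actively proliferating
#' cells: \code{kp = kp0 * SF_RT_prolif^n} after \code{n} fractions.
#'
#' @param kp0 Baseline proliferation rate (1/day).
#' @param sf_rt_prolif Per-fraction proliferation surviving fraction in
#'   (0, 1] (scalar or field).
#' @param n_fractions Number of fractions delivered (non-negative integer).
#' @return Effective proliferation rate, monotone non-increasing in
#'   \code{n_fractions}.
#' @export
effective_proliferation <- function(kp0, sf_rt_prolif, n_fractions) {
  if (n_fractions < 0) stop("n_fractions must be non-negative")
  if (any(sf_rt_prolif <= 0) || any(sf_rt_prolif > 1))
    stop("sf_rt_prolif must lie in (0, 1]")
  kp0 * sf_rt_prolif^n_fractions
}
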