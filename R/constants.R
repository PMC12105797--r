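#' Fixed model constants
#'
#' Literature-assigned constants shared by every variant: carrying
#' capacities of the enhancing and non-enhancing species (normalized,
#' unitless), shear moduli of white and grey matter (kPa), Poisson's ratio
#' and the density-to-force mechanics coupling constant (magnitude 1 in the
#' internal kPa/mm/day unit system).
#'
#' @param theta_E,theta_N Carrying capacities (defaults 1 and 0.16).
#' @param G_w,G_g Shear moduli in kPa (defaults 2.7 and 3.1).
#' @param nu Poisson's ratio (default 0.45).
#' @param lambda2 Mechanics coupling constant (default 1).
#' @return An object of class \code{model_constants}.
#' @export
model_constants <- function(theta_E = 1, theta_N = 0.16,
                            G_w = 2.7, G_g = 3.1, nu = 0.45, lambda2 = 1) {
  stopifnot(theta_E > 0, theta_N > 0, theta_N <= theta_E,
            G_w > 0, G_g > 0, nu > 0, nu < 0.5, lambda2 > 0)
  structure(list(theta_E = theta_E, theta_N = theta_N, G_w = G_w, G_g = G_g,
                 nu = nu, lambda2 = lambda2),
            class = "model_constants")
}

#' Default calibration bounds for the model parameters
#'
#' Box bounds used both to sample ground-truth parameters for the virtual
#' cohort and to constrain calibration. The published study sampled from
#' supplementary ranges that are not part of the main text; these defaults
#' are physiologically plausible stand-ins for high-grade glioma on the
#' package's internal unit system (1/day, mm^2/day, 1/kPa, 1/Gy, Gy) and
#' are fully overridable.
#'
#' @param ... Named length-2 numeric vectors \code{c(lower, upper)}
#'   overriding individual parameter ranges.
#' @return A named list of \code{c(lower, upper)} pairs, one per parameter,
#'   of class \code{parameter_bounds}.
#' @examples
#' b <- default_parameter_bounds(kpE = c(0.01, 0.05))
#' b$kpE
#' @export
default_parameter_bounds <- function(...) {
  b <- list(
    kpE = c(0.005, 0.10), kpN = c(0.005, 0.10),
    D_w = c(0.01, 0.5), D_g = c(0.005, 0.25),
    f_NE = c(0.1, 5), beta_NE = c(0, 2), beta_EN = c(0, 2),
    lambda1 = c(0, 1),
    alpha_RT = c(0.01, 0.06), alpha_RT_prolif = c(0.001, 0.02),
    alpha_CT = c(0.005, 0.04), alpha_beta = c(5, 15))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(b)) stop("unknown parameter in bounds: ", nm)
    b[[nm]] <- as.numeric(over[[nm]])
  }
  for (nm in names(b)) {
    p <- b[[nm]]
    if (length(p) != 2 || !all(is.finite(p)) || p[1] >= p[2] || p[1] < 0)
      stop("invalid bounds for ", nm, ": need 0 <= lower < upper")
  }
  class(b) <- "parameter_bounds"
  b
}

#' Midpoint of the bounds, the calibration starting point
#' @param bounds A \code{parameter_bounds} object.
#' @param free Character vector of parameter names to extract.
#' @return Named numeric vector of midpoints.
#' @export
bounds_midpoint <- function(bounds, free = names(bounds)) {
  vapply(bounds[free], function(p) mean(p), numeric(1))
}
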