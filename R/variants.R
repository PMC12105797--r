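#' Canonical parameter names of the model family
#'
#' The full parameter vector of the most general variant, in canonical order:
#' proliferation rates of the enhancing and non-enhancing species (1/day),
#' unrestricted enhancing diffusion in white and grey matter (mm^2/day), the
#' non-enhancing diffusion scaling \code{f_NE} (so that D_N = D_E * f_NE),
#' the two inter-species competition coefficients, the stress-diffusion
#' coupling (1/kPa), the radiotherapy and chemotherapy sensitivities (1/Gy),
#' the radiotherapy proliferation-effect sensitivity (1/Gy) and the
#' alpha/beta ratio (Gy).
#'
#' @return Character vector of the 12 parameter names.
#' @export
parameter_names <- function() {
  c("kpE", "kpN", "D_w", "D_g", "f_NE", "beta_NE", "beta_EN", "lambda1",
    "alpha_RT", "alpha_RT_prolif", "alpha_CT", "alpha_beta")
}

# Static description of the eleven treatment-assumption variants.
# rt/ct coupling: "uniform", "vasculature", "density" or "off".
# combined variants use a single RT-form survival term and force SF_CT = 1.
# alpha_CT is fixed at 1 (not calibrated) for M2/M4/M8 and, because the
# combined term leaves it inert, also for M6/M10; M6/M10 nevertheless count
# k = 12 parameters in AICc, matching the published parameter accounting.
.variant_table <- list(
  M1  = list(rt = "uniform",     ct = "uniform",     combined = FALSE, n_params = 12L),
  M2  = list(rt = "uniform",     ct = "off",         combined = TRUE,  n_params = 11L),
  M3  = list(rt = "vasculature", ct = "uniform",     combined = FALSE, n_params = 12L),
  M4  = list(rt = "uniform",     ct = "vasculature", combined = FALSE, n_params = 11L),
  M5  = list(rt = "vasculature", ct = "vasculature", combined = FALSE, n_params = 12L),
  M6  = list(rt = "vasculature", ct = "off",         combined = TRUE,  n_params = 12L),
  M7  = list(rt = "density",     ct = "uniform",     combined = FALSE, n_params = 12L),
  M8  = list(rt = "uniform",     ct = "density",     combined = FALSE, n_params = 11L),
  M9  = list(rt = "density",     ct = "density",     combined = FALSE, n_params = 12L),
  M10 = list(rt = "density",     ct = "off",         combined = TRUE,  n_params = 12L),
  M11 = list(rt = "off",         ct = "off",         combined = FALSE, n_params = 8L)
)

#' Model variants of the treatment-response family
#'
#' Construct the description of one of the eleven model variants M1..M11.
#' The variants share a two-species reaction-diffusion growth core and
#' differ in how radiotherapy (RT) and chemotherapy (CT) efficacy is
#' spatially coupled: uniform, coupled to vasculature through the oxygen
#' enhancement ratio, or coupled to local cell density. Combined variants
#' (M2, M6, M10) collapse RT and CT into a single survival term and force
#' the CT surviving fraction to one; M11 ignores treatment altogether.
#'
#' @param id Variant id, one of \code{"M1"}..\code{"M11"} (or 1..11).
#' @param k_override Optional integer overriding the parameter count used in
#'   AICc (the published accounting lists 12 for M6/M10 although their
#'   \code{alpha_CT} is inert and not calibrated).
#' @return An object of class \code{model_variant} with elements \code{id},
#'   \code{rt_coupling}, \code{ct_coupling}, \code{combined},
#'   \code{n_params} (the AICc parameter count \code{k}) and \code{free}
#'   (names of the calibrated parameters).
#' @examples
#' model_variant("M11")$free
#' @export
model_variant <- function(id, k_override = NULL) {
  if (is.numeric(id)) id <- paste0("M", as.integer(id))
  if (!id %in% names(.variant_table))
    stop("unknown model variant: ", id)
  v <- .variant_table[[id]]
  free <- parameter_names()
  if (v$rt == "off" && v$ct == "off" && !v$combined) {
    free <- setdiff(free, c("alpha_RT", "alpha_RT_prolif", "alpha_CT", "alpha_beta"))
  } else if (v$combined || v$ct %in% c("vasculature", "density")) {
    # alpha_CT fixed at 1 for M2/M4/M8 (and inert for combined M6/M10)
    if (v$combined || id %in% c("M4", "M8")) free <- setdiff(free, "alpha_CT")
  }
  k <- if (is.null(k_override)) v$n_params else as.integer(k_override)
  structure(
    list(id = id, rt_coupling = v$rt, ct_coupling = v$ct,
         combined = v$combined, n_params = k, free = free),
    class = "model_variant")
}

#' All eleven model variants
#' @param ids Character or integer vector of variant ids (default all).
#' @return Named list of \code{model_variant} objects.
#' @export
model_family <- function(ids = names(.variant_table)) {
  if (is.numeric(ids)) ids <- paste0("M", as.integer(ids))
  setNames(lapply(ids, model_variant), ids)
}

#' Treatment-coupling class of a variant
#'
#' Groups variants by their assumption on treatment efficacy: spatially
#' uniform (M1, M2), coupled to vasculature (M3-M6), coupled to cell
#' density (M7-M10) or no treatment (M11). Used to report how often
#' misselections stay within the same coupling class.
#' @param id Variant id.
#' @return One of \code{"uniform"}, \code{"vasculature"}, \code{"density"},
#'   \code{"none"}.
#' @export
coupling_class <- function(id) {
  if (is.numeric(id)) id <- paste0("M", as.integer(id))
  switch(id,
         M1 = , M2 = "uniform",
         M3 = , M4 = , M5 = , M6 = "vasculature",
         M7 = , M8 = , M9 = , M10 = "density",
         M11 = "none",
         stop("unknown model variant: ", id))
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("<model_variant %s>  RT: %s  CT: %s%s  k = %d (%d calibrated)\n",
              x$id, x$rt_coupling, x$ct_coupling,
              if (x$combined) "  [combined RT/CT term]" else "",
              x$n_params, length(x$free)))
  invisible(x)
}

#' Full parameter vector for a variant
#'
#' Expands a named vector of calibrated parameter values into the full
#' 12-parameter vector, filling fixed values per the variant's rules:
#' \code{alpha_CT = 1} where it is fixed rather than calibrated, and all
#' treatment sensitivities zero (with a nominal unused alpha/beta) for M11.
#'
#' @param variant A \code{model_variant}.
#' @param values Named numeric vector covering \code{variant$free}.
#' @return Named numeric vector of length 12 in canonical order.
#' @export
expand_parameters <- function(variant, values) {
  stopifnot(inherits(variant, "model_variant"))
  full <- setNames(numeric(12), parameter_names())
  full["alpha_beta"] <- 10  # nominal, inert unless an RT term is active
  if (variant$id != "M11" &&
      !("alpha_CT" %in% variant$free)) full["alpha_CT"] <- 1
  miss <- setdiff(variant$free, names(values))
  if (length(miss)) stop("missing parameter values: ", paste(miss, collapse = ", "))
  full[variant$free] <- values[variant$free]
  if (any(full < 0)) stop("parameters must be non-negative")
  full
}
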