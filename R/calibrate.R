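# Bounded Levenberg-Marquardt calibration of one model variant to one
# virtual patient's noisy longitudinal observations.

#' Calibration control settings
#'
#' @param max_iterations Cap on accepted-step cycles (default 250).
#' @param param_tol Relative parameter-change stopping tolerance between
#'   successive iterations (default 1e-4, i.e. 0.01\%).
#' @param jacobian_step Finite-difference step in normalized (unit-box)
#'   parameter space (default 5e-4).
#' @param central Use central instead of forward differences for the
#'   Jacobian (slower, more accurate; default FALSE).
#' @param lambda_init,lambda_up,lambda_down,lambda_max Damping schedule:
#'   initial value, factor on rejection, divisor on acceptance, and the
#'   overflow limit that terminates the search.
#' @param jacobian_refresh Number of accepted steps a finite-difference
#'   Jacobian is kept alive; between full recomputes it is maintained by
#'   Broyden rank-one secant updates, and any rejected step with a stale
#'   Jacobian forces a fresh recompute before the damping is inflated
#'   (default 6; set 1 for a fresh Jacobian every iteration).
#' @param fit_combined Fit the combined density \code{N_E + N_N} instead of
#'   stacking the two species separately (default FALSE).
#' @return List of class \code{calibration_control}.
#' @export
calibration_control <- function(max_iterations = 250, param_tol = 1e-4,
                                jacobian_step = 5e-4, central = FALSE,
                                lambda_init = 1e-3, lambda_up = 10,
                                lambda_down = 3, lambda_max = 1e12,
                                jacobian_refresh = 6, fit_combined = FALSE) {
  stopifnot(max_iterations >= 1, param_tol > 0, jacobian_step > 0,
            lambda_up > 1, lambda_down > 1, lambda_max > lambda_init,
            jacobian_refresh >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 param_tol = param_tol, jacobian_step = jacobian_step,
                 central = central, lambda_init = lambda_init,
                 lambda_up = lambda_up, lambda_down = lambda_down,
                 lambda_max = lambda_max,
                 jacobian_refresh = as.integer(jacobian_refresh),
                 fit_combined = fit_combined),
            class = "calibration_control")
}

# Default residual days: the interior observation days (weeks 1-3 of RT);
# the first day seeds the simulation, the last is held out for prediction.
.fit_days <- function(days) days[days > days[1] & days < days[length(days)]]

# Stacked observation vector over the fit days.
.obs_vector <- function(observations, mask, fit_days, combined = FALSE) {
  unlist(lapply(fit_days, function(d) {
    f <- observations$fields[[match(d, observations$days)]]
    if (combined) (f$NE + f$NN)[mask] else c(f$NE[mask], f$NN[mask])
  }), use.names = FALSE)
}

#' Residual vector of a variant against noisy observations
#'
#' Runs the forward model from the measured (noisy) day-0 state and stacks
#' \code{observation - model} over both species, all brain-mask voxels and
#' the interior observation days (weeks 1-3 of radiotherapy). The held-out
#' post-treatment day never enters the residual.
#'
#' @param variant A \code{model_variant}.
#' @param params Full named parameter vector.
#' @param observations A \code{tumour_observations}.
#' @param anatomy,schedule The patient's fixed scaffold and treatment plan.
#' @param control [calibration_control()] (for \code{fit_combined}).
#' @param sim_ctrl [sim_control()].
#' @return Numeric residual vector of length \code{2 * n_mask * n_days}
#'   (or \code{n_mask * n_days} for combined-density fitting).
#' @export
residual_tumour <- function(variant, params, observations, anatomy, schedule,
                            control = calibration_control(),
                            sim_ctrl = sim_control()) {
  ctx <- .engine_context(variant, anatomy, schedule, sim_ctrl)
  R <- tryCatch(
    .resid_mat(ctx, matrix(params[parameter_names()], ncol = 1),
               observations, control$fit_combined),
    error = function(e)
      stop("simulation failed during residual evaluation (params: ",
           paste(sprintf("%s=%.4g", names(params), params), collapse = ", "),
           "): ", conditionMessage(e)))
  R[, 1]
}

# Residual matrix for a batch of full parameter columns (12 x P) sharing
# one observation set; column ci holds y - f(params_ci).
.resid_mat <- function(ctx, par_mat, observations, combined) {
  m <- ctx$grid$brain_mask
  fit_days <- .fit_days(observations$days)
  day0 <- observations$days[1]
  init <- observations$fields[[1]]
  cst <- ctx$constants
  ne0 <- pmin(pmax(init$NE[m], 0), cst$theta_E)
  nn0 <- pmin(pmax(init$NN[m], 0), cst$theta_N)
  out <- .engine_run(ctx, par_mat, ne0, nn0, c(day0, fit_days), day0)
  y <- .obs_vector(observations, m, fit_days, combined)
  P <- ncol(par_mat)
  R <- matrix(0, length(y), P)
  for (ci in seq_len(P)) {
    mod <- unlist(lapply(seq_along(fit_days), function(i) {
      ne <- out$NE[[i + 1]][, ci]; nn <- out$NN[[i + 1]][, ci]
      if (combined) ne + nn else c(ne, nn)
    }), use.names = FALSE)
    R[, ci] <- y - mod
  }
  R
}

#' Calibrate a model variant to one virtual patient
#'
#' Bounded Levenberg-Marquardt nonlinear least squares: starting from the
#' midpoint of the parameter bounds, iteratively updates the variant's free
#' parameters to minimize the residual sum of squares between the noisy
#' observations and the forward model over the first three weeks of
#' radiotherapy. Parameters are optimized in the unit box defined by the
#' bounds (clamped projection), the Jacobian is computed by finite
#' differences, and the damping factor increases on rejected steps and
#' decreases on accepted ones. The search stops at the iteration cap, when
#' the relative parameter change drops below the tolerance, when the
#' residual vanishes, or when the damping overflows (all steps rejected).
#'
#' @param observations A \code{tumour_observations} (day-0 field included;
#'   the last day is held out for prediction).
#' @param variant A \code{model_variant} to fit.
#' @param anatomy The patient's \code{tumour_anatomy}.
#' @param schedule Treatment schedule.
#' @param bounds \code{parameter_bounds}.
#' @param control [calibration_control()].
#' @param sim_ctrl [sim_control()].
#' @return Object of class \code{tumour_fit} with elements
#'   \code{params_hat} (full parameter vector), \code{rss},
#'   \code{n_points}, \code{k} (AICc parameter count), \code{iterations},
#'   \code{converged}, \code{termination} and a per-iteration \code{trace}
#'   data frame. Supports \code{coef}, \code{print}, \code{summary},
#'   \code{residuals}, \code{predict} and \code{logLik}.
#' @export
calibrate_tumour <- function(observations, variant, anatomy, schedule,
                             bounds = default_parameter_bounds(),
                             control = calibration_control(),
                             sim_ctrl = sim_control()) {
  stopifnot(inherits(observations, "tumour_observations"),
            inherits(variant, "model_variant"))
  free <- variant$free
  lo <- vapply(bounds[free], `[`, numeric(1), 1)
  hi <- vapply(bounds[free], `[`, numeric(1), 2)
  width <- hi - lo
  to_p <- function(x) setNames(lo + x * width, free)
  ctx <- .engine_context(variant, anatomy, schedule, sim_ctrl)
  full_of <- function(x) unname(expand_parameters(variant, to_p(x)))
  n_calls <- 0L; n_cols <- 0L  # engine passes / simulated columns
  resid_cols <- function(xmat) {  # columns of normalized parameters
    pm <- apply(xmat, 2, full_of)
    n_calls <<- n_calls + 1L; n_cols <<- n_cols + ncol(pm)
    tryCatch(.resid_mat(ctx, pm, observations, control$fit_combined),
             error = function(e) NULL)
  }
  resid_x <- function(x) {
    R <- resid_cols(matrix(x, ncol = 1))
    if (is.null(R)) NULL else R[, 1]
  }

  k_free <- length(free)
  x <- rep(0.5, k_free)  # midpoint-of-bounds initialization
  r <- resid_x(x)
  if (is.null(r)) stop("simulation failed at the midpoint initialization")
  rss <- sum(r^2)
  n_points <- length(r)
  lambda <- control$lambda_init
  h <- control$jacobian_step
  termination <- "max_iterations"
  converged <- FALSE
  iter <- 0L
  trace <- vector("list", control$max_iterations)

  fresh_jacobian <- function() {
    J <- matrix(0, n_points, k_free)
    if (control$central) {
      hp <- pmin(h, 1 - x); hm <- pmin(h, x)
      if (any(hp + hm <= 0)) return(NULL)
      X <- matrix(x, k_free, 2 * k_free)
      for (j in seq_len(k_free)) {
        X[j, j] <- x[j] + hp[j]
        X[j, k_free + j] <- x[j] - hm[j]
      }
      R <- resid_cols(X)
      if (is.null(R)) return(NULL)
      for (j in seq_len(k_free))
        J[, j] <- (R[, j] - R[, k_free + j]) / (hp[j] + hm[j])
    } else {
      hs <- ifelse(x + h <= 1, h, -h)
      X <- matrix(x, k_free, k_free)
      diag(X) <- x + hs
      R <- resid_cols(X)
      if (is.null(R)) return(NULL)
      for (j in seq_len(k_free)) J[, j] <- (R[, j] - r) / hs[j]
    }
    J
  }

  J <- NULL
  stale <- .Machine$integer.max  # accepted steps since the last fresh J
  last_dx <- NULL; last_dr <- NULL

  while (iter < control$max_iterations) {
    iter <- iter + 1L
    if (rss == 0) { termination <- "zero_residual"; converged <- TRUE; iter <- iter - 1L; break }
    # Jacobian: full finite-difference recompute (one batched engine pass)
    # every jacobian_refresh accepted steps, Broyden secant update between
    if (is.null(J) || stale >= control$jacobian_refresh) {
      J <- fresh_jacobian()
      if (is.null(J)) { termination <- "jacobian_failure"; break }
      stale <- 0L
    } else if (!is.null(last_dx)) {
      denom <- sum(last_dx^2)
      if (denom > 0)
        J <- J + tcrossprod(last_dr - as.numeric(J %*% last_dx),
                            last_dx) / denom
    }
    g <- crossprod(J, r)          # J^T r (note residual = y - f)
    H <- crossprod(J)
    dH <- pmax(diag(H), 1e-12)
    accepted <- FALSE
    lambda_entry <- lambda
    while (lambda <= control$lambda_max) {
      step <- tryCatch(solve(H + diag(lambda * dH, k_free), g),
                       error = function(e) NULL)
      # active-set pass: parameters sitting on a bound that the step would
      # push further outward are frozen and the damped system re-solved in
      # the remaining coordinates, so the search can slide along a face of
      # the box instead of stalling against it
      if (!is.null(step)) {
        act <- (x <= 0 & step > 0) | (x >= 1 & step < 0)
        if (any(act) && !all(act)) {
          fr <- which(!act)
          sub <- tryCatch(
            solve(H[fr, fr, drop = FALSE] +
                    diag(lambda * dH[fr], length(fr)), g[fr]),
            error = function(e) NULL)
          if (!is.null(sub)) {
            step <- rep(0, k_free); step[fr] <- as.numeric(sub)
          }
        }
      }
      if (!is.null(step)) {
        # backtrack along the proposed direction before inflating the
        # damping: near-degenerate parameter combinations (e.g. the LQ
        # alpha/alpha-beta trade-off) form long curved valleys in which a
        # shortened Gauss-Newton step makes progress where the
        # gradient-like heavily damped step does not. All candidate scales
        # are simulated in one batched engine pass; the first improving
        # candidate (in order) is accepted, exactly as if tried one by one
        scales <- c(1, 0.5, 0.25, 0.1, 0.03, 0.01)
        X <- vapply(scales, function(s)
          pmin(pmax(x - s * as.numeric(step), 0), 1), numeric(k_free))
        keep <- !duplicated(t(X))
        R <- resid_cols(X[, keep, drop = FALSE])
        if (!is.null(R)) {
          rsses <- colSums(R^2)
          hit <- which(rsses <= rss)[1]
          if (!is.na(hit)) {
            x_new <- X[, keep, drop = FALSE][, hit]
            r_new <- R[, hit]
            p_old <- to_p(x); p_new <- to_p(x_new)
            rel <- max(abs(p_new - p_old) / pmax(abs(p_old), 1e-3 * width))
            last_dx <- x_new - x; last_dr <- r_new - r
            x <- x_new; r <- r_new; rss <- rsses[hit]
            lambda <- max(lambda / control$lambda_down, 1e-12)
            accepted <- TRUE
            stale <- stale + 1L
            trace[[iter]] <- data.frame(iteration = iter, rss = rss,
                                        lambda = lambda, max_rel_change = rel)
            if (rel < control$param_tol) {
              termination <- "param_tol"; converged <- TRUE
            }
          }
        }
        if (accepted) break
      }
      lambda <- lambda * control$lambda_up
    }
    if (!accepted) {
      if (stale > 0L) {
        # everything rejected under a stale Jacobian: recompute it fresh
        # before concluding the damping has overflowed
        J <- NULL; last_dx <- NULL; last_dr <- NULL
        lambda <- lambda_entry
        next
      }
      termination <- "damping_overflow"
      break
    }
    if (converged) break
  }
  if (iter >= control$max_iterations && termination == "max_iterations")
    converged <- FALSE

  params_hat <- expand_parameters(variant, to_p(x))
  structure(
    list(params_hat = params_hat, free = free, rss = rss,
         n_points = n_points, k = variant$n_params, iterations = iter,
         converged = converged, termination = termination,
         trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
         n_engine_calls = n_calls, n_sim_columns = n_cols,
         variant = variant, bounds = bounds, control = control,
         sim_ctrl = sim_ctrl, observations = observations,
         anatomy = anatomy, schedule = schedule),
    class = "tumour_fit")
}

#' Gaussian profile log-likelihood of a least-squares fit
#'
#' The maximized log-likelihood under the constant-variance Gaussian noise
#' model, with the variance profiled out at \code{sigma2 = RSS / n}:
#' \code{-(n/2) * log(2 * pi * sigma2) - n/2}. A zero residual sum of
#' squares returns \code{Inf} (the documented degenerate-fit sentinel).
#'
#' @param rss Residual sum of squares (non-negative).
#' @param n_points Number of residuals (positive).
#' @return Log-likelihood value.
#' @export
profile_log_likelihood <- function(rss, n_points) {
  stopifnot(rss >= 0, n_points > 0)
  if (rss == 0) return(Inf)
  n <- n_points
  -(n / 2) * log(2 * pi * rss / n) - n / 2
}

#' @export
coef.tumour_fit <- function(object, ...) object$params_hat[object$free]

#' @export
residuals.tumour_fit <- function(object, ...) {
  residual_tumour(object$variant, object$params_hat, object$observations,
                  object$anatomy, object$schedule, object$control,
                  object$sim_ctrl)
}

#' @export
logLik.tumour_fit <- function(object, ...) {
  structure(profile_log_likelihood(object$rss, object$n_points),
            df = object$k + 1, nobs = object$n_points, class = "logLik")
}

#' Forward prediction from a calibrated fit
#'
#' Re-simulates the fitted variant from the measured day-0 state through the
#' full treatment schedule to the requested days (by default up to the
#' held-out post-treatment observation day).
#'
#' @param object A \code{tumour_fit}.
#' @param days Observation days (default all of the patient's days).
#' @param ... Unused.
#' @return A \code{tumour_sim}.
#' @export
predict.tumour_fit <- function(object, days = NULL, ...) {
  obs <- object$observations
  if (is.null(days)) days <- obs$days
  init <- obs$fields[[1]]
  init <- list(NE = init$NE, NN = init$NN, day = obs$days[1])
  simulate_tumour(object$variant, object$params_hat, object$anatomy,
                  object$schedule, days, init_state = init,
                  control = object$sim_ctrl)
}

#' @export
print.tumour_fit <- function(x, ...) {
  cat(sprintf("<tumour_fit %s>  RSS = %.6g on %d points, k = %d\n",
              x$variant$id, x$rss, x$n_points, x$k))
  cat(sprintf("  %s after %d iterations (%s)\n",
              if (x$converged) "converged" else "not converged",
              x$iterations, x$termination))
  print(signif(coef(x), 4))
  invisible(x)
}

#' @export
summary.tumour_fit <- function(object, true_params = NULL, ...) {
  est <- coef(object)
  tab <- data.frame(estimate = est)
  if (!is.null(true_params)) {
    tr <- true_params[object$free]
    tab$truth <- as.numeric(tr)
    tab$pct_error <- 100 * (est - tab$truth) / tab$truth
  }
  out <- list(fit = object, table = tab,
              aicc = aicc(object$rss, object$n_points, object$k))
  class(out) <- "summary.tumour_fit"
  out
}

#' @export
print.summary.tumour_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  AICc = %.4g\n", x$aicc))
  print(signif(as.matrix(x$table), 4))
  invisible(x)
}
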