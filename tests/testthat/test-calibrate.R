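# Bounded Levenberg-Marquardt calibration against noisy longitudinal
# observations.

noiseless_obs <- function() {
  m11 <- fix_m11_truth()
  add_noise(m11$sim, 0, seed = 1)
}

test_that("residuals vanish at the generating parameters on clean data", {
  m11 <- fix_m11_truth()
  obs <- noiseless_obs()
  r <- residual_tumour(m11$variant, m11$params, obs, fix_anatomy(),
                       fix_schedule())
  expect_equal(max(abs(r)), 0)
  expect_length(r, 2 * fix_anatomy()$grid$n_inside * 3)
})

test_that("residual stacking matches a naive voxel-loop accumulation", {
  m11 <- fix_m11_truth()
  a <- fix_anatomy()
  obs <- add_noise(m11$sim, 0.05, seed = 3)
  p <- m11$params * 1.1  # deliberate misfit
  r <- residual_tumour(m11$variant, p, obs, a, fix_schedule())
  rss <- sum(r^2)

  sim <- simulate_tumour(m11$variant, p, a, fix_schedule(), c(0, 7, 14, 21),
                         init_state = c(obs$fields[[1]][c("NE", "NN")],
                                        day = 0))
  acc <- 0
  m <- a$grid$brain_mask
  for (ti in 2:4) {
    oy <- obs$fields[[ti]]
    st <- sim$states[[ti]]
    for (i in which(m)) {
      acc <- acc + (oy$NE[i] - st$NE[i])^2 + (oy$NN[i] - st$NN[i])^2
    }
  }
  expect_equal(rss, acc, tolerance = 1e-10)
})

test_that("initialization at the truth terminates immediately and cleanly", {
  m11 <- fix_m11_truth()
  tr <- m11$params[m11$variant$free]
  b <- default_parameter_bounds()
  for (nm in names(tr)) b[[nm]] <- c(0.5 * tr[[nm]], 1.5 * tr[[nm]] + 1e-9)
  fit <- calibrate_tumour(noiseless_obs(), m11$variant, fix_anatomy(),
                          fix_schedule(), bounds = b)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-12)
  expect_lt(fit$iterations, 5)
})

test_that("accepted-step RSS is monotone non-increasing and bounds hold", {
  m11 <- fix_m11_truth()
  obs <- add_noise(m11$sim, 0.10, seed = 8)
  fit <- calibrate_tumour(obs, m11$variant, fix_anatomy(), fix_schedule())
  expect_true(all(diff(fit$trace$rss) <= 0))
  b <- default_parameter_bounds()
  est <- coef(fit)
  for (nm in names(est)) {
    expect_gte(est[[nm]], b[[nm]][1])
    expect_lte(est[[nm]], b[[nm]][2])
  }
  expect_equal(fit$n_points, 2 * fix_anatomy()$grid$n_inside * 3)
  expect_equal(fit$k, 8)
})

test_that("calibration is deterministic", {
  m11 <- fix_m11_truth()
  obs <- add_noise(m11$sim, 0.05, seed = 4)
  f1 <- calibrate_tumour(obs, m11$variant, fix_anatomy(), fix_schedule())
  f2 <- calibrate_tumour(obs, m11$variant, fix_anatomy(), fix_schedule())
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$trace, f2$trace)
})

test_that("noiseless calibration recovers the generating parameters", {
  m11 <- fix_m11_truth()
  fit <- calibrate_tumour(noiseless_obs(), m11$variant, fix_anatomy(),
                          fix_schedule())
  err <- 100 * abs(coef(fit) - m11$params[fit$free]) / m11$params[fit$free]
  expect_lt(max(err), 1)
})

test_that("an independent Levenberg-Marquardt oracle lands on the same optimum", {
  m11 <- fix_m11_truth()
  a <- fix_anatomy()
  obs <- noiseless_obs()
  v <- m11$variant
  b <- default_parameter_bounds()
  lo <- vapply(b[v$free], `[`, numeric(1), 1)
  hi <- vapply(b[v$free], `[`, numeric(1), 2)
  fn <- function(par) {
    residual_tumour(v, expand_parameters(v, setNames(par, v$free)), obs, a,
                    fix_schedule())
  }
  fit <- calibrate_tumour(obs, v, a, fix_schedule())
  # polishing our optimum with the independent optimizer must neither move
  # the parameters nor find a meaningfully better residual
  ref <- minpack.lm::nls.lm(par = coef(fit), lower = lo, upper = hi,
                            fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 50, ptol = 1e-12, ftol = 1e-12))
  expect_lt(max(abs(ref$par - coef(fit)) / pmax(abs(coef(fit)), 1e-8)), 1e-2)
  expect_gte(fit$rss, ref$deviance - 1e-10)
  expect_lt(ref$deviance, 1e-10)  # both sit at the global (zero) optimum
  tru <- m11$params[v$free]
  expect_lt(max(abs(100 * (ref$par - tru) / tru)), 1)
})

test_that("fit methods expose prediction, residuals and likelihood", {
  m11 <- fix_m11_truth()
  obs <- add_noise(m11$sim, 0.05, seed = 12)
  fit <- calibrate_tumour(obs, m11$variant, fix_anatomy(), fix_schedule())
  pred <- predict(fit, days = c(0, 21, 67))
  expect_s3_class(pred, "tumour_sim")
  expect_equal(pred$observation_days, c(0, 21, 67))
  # prediction starts from the measured day-0 state (projected into the
  # physical range, since raw measurements carry unclipped noise)
  m <- fix_anatomy()$grid$brain_mask
  expect_equal(pred$states[[1]]$NE[m],
               pmin(pmax(obs$fields[[1]]$NE[m], 0), 1))
  expect_length(residuals(fit), fit$n_points)
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), profile_log_likelihood(fit$rss, fit$n_points))
  expect_equal(attr(ll, "df"), fit$k + 1)
  s <- summary(fit, true_params = m11$params)
  expect_true(all(c("estimate", "truth", "pct_error") %in% names(s$table)))
})
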