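# Forward model: explicit growth step, full trajectories, treatment
# coupling identities and numerical behaviour.

test_that("empty and saturated states are fixed points of the growth step", {
  a <- fix_anatomy()
  g <- a$grid
  dims <- g$dims
  params <- c(beta_NE = 0, beta_EN = 0)
  zeroD <- array(0, dims)
  kp <- array(0.1, dims)

  st0 <- state_of(array(0, dims), array(0, dims))
  out0 <- growth_step(st0, zeroD, zeroD, kp, kp, params, g, dt = 0.05)
  expect_equal(out0$NE, st0$NE)
  expect_equal(out0$NN, st0$NN)

  # single species at carrying capacity, no diffusion, no competition
  ne <- array(0, dims); ne[g$brain_mask] <- 1
  st1 <- state_of(ne, array(0, dims))
  out1 <- growth_step(st1, zeroD, zeroD, kp, kp, params, g, dt = 0.05)
  expect_equal(out1$NE, st1$NE)
})

test_that("growth step enforces the diffusion stability bound", {
  a <- fix_anatomy()
  D <- array(0.5, a$grid$dims)
  kp <- array(0, a$grid$dims)
  st <- state_of(array(0, a$grid$dims), array(0, a$grid$dims))
  expect_error(growth_step(st, D, D, kp, kp, c(beta_NE = 0, beta_EN = 0),
                           a$grid, dt = 0.5), "stability bound")
})

test_that("one explicit step matches a hand-computed stencil update", {
  a <- fix_anatomy()
  g <- a$grid
  m <- g$brain_mask
  set.seed(9)
  NE <- array(0, g$dims); NE[m] <- runif(g$n_inside, 0, 0.8)
  NN <- array(0, g$dims); NN[m] <- runif(g$n_inside, 0, 0.16)
  DE <- array(0, g$dims); DE[m] <- runif(g$n_inside, 0.05, 0.3)
  DN <- DE * 0.5
  kpE <- array(0, g$dims); kpE[m] <- 0.08
  kpN <- array(0, g$dims); kpN[m] <- 0.05
  pars <- c(beta_NE = 0.7, beta_EN = 1.2)
  dt <- 0.02
  out <- growth_step(state_of(NE, NN), DE, DN, kpE, kpN, pars, g, dt = dt)

  # naive voxel-loop update with central-difference fluxes and zero-flux
  # faces, clipped to the carrying capacities
  cst <- model_constants()
  h <- g$spacing
  ref_NE <- NE; ref_NN <- NN
  dims <- g$dims
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    if (!m[i, j, k]) next
    lapE <- 0; lapN <- 0
    for (d in 1:3) for (s in c(-1, 1)) {
      cc <- c(i, j, k); cc[d] <- cc[d] + s
      if (cc[d] < 1 || cc[d] > dims[d] || !m[cc[1], cc[2], cc[3]]) next
      wE <- (DE[i, j, k] + DE[cc[1], cc[2], cc[3]]) / 2
      wN <- (DN[i, j, k] + DN[cc[1], cc[2], cc[3]]) / 2
      lapE <- lapE + wE * (NE[cc[1], cc[2], cc[3]] - NE[i, j, k]) / h[d]^2
      lapN <- lapN + wN * (NN[cc[1], cc[2], cc[3]] - NN[i, j, k]) / h[d]^2
    }
    rE <- kpE[i, j, k] * NE[i, j, k] *
      (1 - (NE[i, j, k] + pars[["beta_NE"]] * NN[i, j, k]) / cst$theta_E)
    rN <- kpN[i, j, k] * NN[i, j, k] *
      (1 - (NN[i, j, k] + pars[["beta_EN"]] * NE[i, j, k]) / cst$theta_N)
    ref_NE[i, j, k] <- min(max(NE[i, j, k] + dt * (lapE + rE), 0), cst$theta_E)
    ref_NN[i, j, k] <- min(max(NN[i, j, k] + dt * (lapN + rN), 0), cst$theta_N)
  }
  expect_lt(max(abs(out$NE - ref_NE)), 1e-12)
  expect_lt(max(abs(out$NN - ref_NN)), 1e-12)
})

test_that("pure diffusion with zero-flux boundaries conserves mass", {
  a <- fix_anatomy()
  v <- model_variant("M11")
  p <- expand_parameters(v, c(kpE = 0, kpN = 0, D_w = 0.3, D_g = 0.15,
                              f_NE = 1.5, beta_NE = 0.5, beta_EN = 0.5,
                              lambda1 = 0.4))
  sim <- simulate_tumour(v, p, a, NULL, c(0, 7))
  m0 <- sum(sim$states[[1]]$NE + sim$states[[1]]$NN)
  m7 <- sum(sim$states[[2]]$NE + sim$states[[2]]$NN)
  expect_lt(abs(m7 - m0) / m0, 1e-10)
})

test_that("treatment-inert parameters reproduce the untreated model", {
  a <- fix_anatomy()
  sch <- fix_schedule()
  base <- c(kpE = 0.06, kpN = 0.04, D_w = 0.2, D_g = 0.1, f_NE = 1.2,
            beta_NE = 0.6, beta_EN = 0.8, lambda1 = 0.3)
  m11 <- fix_m11_truth()
  p11 <- expand_parameters(model_variant("M11"), base)
  p1 <- expand_parameters(model_variant("M1"),
                          c(base, alpha_RT = 0, alpha_RT_prolif = 0,
                            alpha_CT = 0, alpha_beta = 10))
  days <- c(0, 7, 21)
  s11 <- simulate_tumour(model_variant("M11"), p11, a, sch, days)
  s1 <- simulate_tumour(model_variant("M1"), p1, a, sch, days)
  for (i in seq_along(days)) {
    expect_equal(s1$states[[i]]$NE, s11$states[[i]]$NE, tolerance = 1e-14)
    expect_equal(s1$states[[i]]$NN, s11$states[[i]]$NN, tolerance = 1e-14)
  }
})

test_that("more radiation never increases any voxel's density", {
  a <- fix_anatomy()
  sch <- fix_schedule()
  v <- model_variant("M1")
  base <- c(kpE = 0.06, kpN = 0.04, D_w = 0.2, D_g = 0.1, f_NE = 1.2,
            beta_NE = 0.6, beta_EN = 0.8, lambda1 = 0.3,
            alpha_RT = 0.05, alpha_RT_prolif = 0.01, alpha_CT = 0.1,
            alpha_beta = 10)
  hi <- base; hi["alpha_RT"] <- 0.15
  s_lo <- simulate_tumour(v, expand_parameters(v, base), a, sch, c(0, 7, 21))
  s_hi <- simulate_tumour(v, expand_parameters(v, hi), a, sch, c(0, 7, 21))
  for (i in 2:3) {
    expect_true(all(s_hi$states[[i]]$NE <= s_lo$states[[i]]$NE + 1e-14))
    expect_true(all(s_hi$states[[i]]$NN <= s_lo$states[[i]]$NN + 1e-14))
  }
})

test_that("a flat enhancement-ratio map collapses vasculature coupling", {
  a <- make_anatomy(4, dims = c(16, 16, 3))
  a$er_map[] <- 1.5  # constant perfusion proxy: OER = 1 everywhere
  sch <- make_schedule(a)
  vals <- c(kpE = 0.06, kpN = 0.04, D_w = 0.2, D_g = 0.1, f_NE = 1.2,
            beta_NE = 0.6, beta_EN = 0.8, lambda1 = 0.3,
            alpha_RT = 0.08, alpha_RT_prolif = 0.01, alpha_CT = 0.2,
            alpha_beta = 9)
  days <- c(0, 7, 21)
  p1 <- expand_parameters(model_variant("M1"), vals)
  p3 <- expand_parameters(model_variant("M3"), vals)
  s1 <- simulate_tumour(model_variant("M1"), p1, a, sch, days)
  s3 <- simulate_tumour(model_variant("M3"), p3, a, sch, days)
  expect_equal(s3$states[[3]]$NE, s1$states[[3]]$NE, tolerance = 1e-14)

  vals2 <- vals[setdiff(names(vals), "alpha_CT")]
  p2 <- expand_parameters(model_variant("M2"), vals2)
  p6 <- expand_parameters(model_variant("M6"), vals2)
  s2 <- simulate_tumour(model_variant("M2"), p2, a, sch, days)
  s6 <- simulate_tumour(model_variant("M6"), p6, a, sch, days)
  expect_equal(s6$states[[3]]$NE, s2$states[[3]]$NE, tolerance = 1e-14)
})

test_that("observation days are returned exactly as requested", {
  s <- fix_m11_truth()$sim
  expect_equal(vapply(s$states, `[[`, numeric(1), "day"), c(0, 7, 14, 21, 67))
  a <- fix_anatomy()
  expect_error(simulate_tumour(fix_m11_truth()$variant, fix_m11_truth()$params,
                               a, NULL, c(0, 21, 7)), "increasing")
  expect_error(simulate_tumour(fix_m11_truth()$variant, fix_m11_truth()$params,
                               a, NULL, c(3, 7)), "initial state")
})

test_that("halving the time step changes the solution only at first order", {
  a <- fix_anatomy()
  sch <- fix_schedule()
  v <- model_variant("M1")
  p <- sample_parameters(v, seed = 31)
  s1 <- simulate_tumour(v, p, a, sch, c(0, 21), control = sim_control(dt_max = 0.1))
  s2 <- simulate_tumour(v, p, a, sch, c(0, 21), control = sim_control(dt_max = 0.05))
  d <- max(abs(s1$states[[2]]$NE - s2$states[[2]]$NE),
           abs(s1$states[[2]]$NN - s2$states[[2]]$NN))
  expect_lt(d, 5e-3)
})
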