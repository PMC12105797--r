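# Synthetic anatomy, ADC conversion, dose schedule and cohort generation.

test_that("anatomy generation is deterministic and seed-sensitive", {
  a1 <- make_anatomy(5, dims = c(16, 16, 3))
  a2 <- make_anatomy(5, dims = c(16, 16, 3))
  a3 <- make_anatomy(6, dims = c(16, 16, 3))
  expect_identical(a1$initial, a2$initial)
  expect_identical(a1$grid$tissue, a2$grid$tissue)
  expect_identical(a1$er_map, a2$er_map)
  # different seeds differ somewhere (tissue partition or tumour seat)
  expect_false(identical(a1$grid$tissue, a3$grid$tissue) &&
                 identical(a1$initial, a3$initial))
})

test_that("tissue labels partition the brain mask exactly", {
  a <- fix_anatomy()
  g <- a$grid
  expect_true(all((g$tissue > 0) == g$brain_mask))
  expect_true(all(g$tissue[!g$brain_mask] == 0))
  expect_setequal(unique(as.vector(g$tissue[g$brain_mask])), c(1L, 2L))
})

test_that("initial tumour state honours the imaging-derived construction", {
  a <- fix_anatomy()
  ne <- a$initial$NE; nn <- a$initial$NN
  expect_true(all(ne >= 0 & ne <= 1))
  expect_true(all(ne[!a$grid$brain_mask] == 0))
  rim <- nn > 0
  expect_true(all(nn[rim] == a$constants$theta_N))  # fixed 0.16 rim
  expect_false(any(rim & ne > 0))  # rim surrounds, not overlaps, the core
  expect_gt(sum(ne > 0), 0)
  expect_gt(sum(rim), 0)
  expect_true(all(a$gtv_mask == (ne > 0)))
  expect_true(all(a$gtv_mask[a$ctv_mask == FALSE] == FALSE))  # gtv in ctv
})

test_that("dims below the supported minimum are rejected", {
  expect_error(make_anatomy(1, dims = c(8, 8, 3)), "at least")
})

test_that("ADC to density conversion is the inverse-linear map", {
  expect_equal(adc_to_density(3e-3, 0.5e-3), 0)
  expect_equal(adc_to_density(0.5e-3, 0.5e-3), 1)
  expect_equal(adc_to_density(1.75e-3, 0.5e-3), 0.5)
  expect_error(adc_to_density(4e-3, 0.5e-3), "within")
  expect_error(adc_to_density(0.1e-3, 0.5e-3), "within")
})

test_that("schedule delivers the prescription in 30 weekday fractions", {
  a <- fix_anatomy()
  sch <- fix_schedule()
  expect_length(sch, 30)
  days <- vapply(sch, `[[`, numeric(1), "day")
  expect_equal(days[1], 0)
  expect_equal(days[30], 39)
  expect_true(all((days %% 7) %in% 0:4))     # Monday-Friday only
  expect_equal(vapply(sch, `[[`, numeric(1), "fraction_index"), 1:30)

  total <- Reduce(`+`, lapply(sch, `[[`, "dose_map"))
  expect_equal(unique(total[a$gtv_mask]), 60)
  ctv_only <- a$ctv_mask & !a$gtv_mask
  if (any(ctv_only)) expect_equal(unique(total[ctv_only]), 50)
  expect_true(all(total[!a$ctv_mask] == 0))
  expect_error(make_schedule(a, n_fractions = 0), "positive")
})

test_that("sampled parameters respect bounds and variant rules", {
  b <- default_parameter_bounds()
  for (vid in c("M1", "M2", "M4", "M11")) {
    v <- model_variant(vid)
    p <- sample_parameters(v, b, seed = 99)
    for (nm in v$free) {
      expect_gte(p[[nm]], b[[nm]][1])
      expect_lte(p[[nm]], b[[nm]][2])
    }
  }
  expect_length(attr(sample_parameters(model_variant("M11"), b, seed = 1),
                     "free"), 8)
  for (vid in c("M2", "M4", "M6", "M8", "M10"))
    expect_equal(sample_parameters(model_variant(vid), b, seed = 1)[["alpha_CT"]], 1)
  expect_false(identical(sample_parameters(model_variant("M1"), b, seed = 1),
                         sample_parameters(model_variant("M1"), b, seed = 2)))
})

test_that("noise injection is calibrated, truncated and deterministic", {
  dims <- c(40, 40, 3)
  truth <- list(state_of(array(0.5, dims), array(0.08, dims)))
  obs1 <- add_noise(truth, 0.05, seed = 7)
  obs2 <- add_noise(truth, 0.05, seed = 7)
  expect_identical(obs1$fields, obs2$fields)

  # empirical SD recovers the nominal level (species-scaled), +-5% relative
  dE <- obs1$fields[[1]]$NE - 0.5
  dN <- obs1$fields[[1]]$NN - 0.08
  expect_lt(abs(sd(dE) / 0.05 - 1), 0.05)
  expect_lt(abs(sd(dN) / (0.05 * 0.16) - 1), 0.05)

  # degenerate level leaves the truth untouched
  obs0 <- add_noise(truth, 0, seed = 1)
  expect_identical(obs0$fields[[1]]$NE, truth[[1]]$NE)

  # raw observations are unbiased; truncation mode clamps to the range
  obs15 <- add_noise(truth, 0.15, seed = 3)
  expect_lt(abs(mean(obs15$fields[[1]]$NE) - 0.5), 0.01)
  obs15t <- add_noise(truth, 0.15, seed = 3, truncate = TRUE)
  expect_true(all(obs15t$fields[[1]]$NE >= 0 & obs15t$fields[[1]]$NE <= 1))
  expect_true(all(obs15t$fields[[1]]$NN >= 0 & obs15t$fields[[1]]$NN <= 0.16))
  expect_error(add_noise(truth, -0.1, seed = 1), "non-negative")
  expect_warning(add_noise(truth, 0.3, seed = 1), "levels")
})

test_that("noise stays out of undetectable background by default", {
  dims <- c(10, 10, 3)
  ne <- array(0, dims); ne[1:50] <- 0.6
  truth <- list(state_of(ne, array(0, dims)))
  obs <- add_noise(truth, 0.15, seed = 2)
  expect_true(all(obs$fields[[1]]$NE[51:300] == 0))
  expect_false(all(obs$fields[[1]]$NE[1:50] == 0.6))
  # whole-mask mode does noise empty voxels
  obs_m <- add_noise(truth, 0.15, seed = 2, where = "mask",
                     mask = array(TRUE, dims))
  expect_gt(sum(obs_m$fields[[1]]$NE[51:300] > 0), 0)
})

test_that("cohort generation yields the full patient x variant grid", {
  fam <- model_family(c("M11", "M2"))
  ch <- generate_cohort(2, variants = fam, noise_levels = 0.05,
                        master_seed = 42, dims = c(16, 16, 3))
  expect_length(ch$tumours, 4)  # 2 patients x 2 variants
  expect_equal(nrow(ch$manifest), 4)
  for (tm in ch$tumours) {
    expect_length(tm$truth$states, 5)  # 1 pre + 3 during + 1 post
    expect_equal(tm$truth$observation_days, c(0, 7, 14, 21, 67))
    expect_named(tm$observations, "0.05")
  }
  # reproducibility: identical master seed, identical manifest
  ch2 <- generate_cohort(2, variants = fam, noise_levels = 0.05,
                         master_seed = 42, dims = c(16, 16, 3))
  expect_identical(ch$manifest, ch2$manifest)
  expect_identical(ch$tumours[[3]]$observations[["0.05"]]$fields,
                   ch2$tumours[[3]]$observations[["0.05"]]$fields)
})
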