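# Corrected-AIC scoring, argmin selection with parsimony tie-break, and
# cohort tallying.

fake_fit <- function(id, rss, n = 1000) {
  v <- model_variant(id)
  structure(list(rss = rss, n_points = n, k = v$n_params, variant = v),
            class = "tumour_fit")
}

test_that("aicc reproduces its closed form and shape properties", {
  expect_equal(aicc(100, 1000, 12),
               24 + 1000 * log(0.1) + 2 * 12 * 13 / 987, tolerance = 1e-12)
  expect_equal(aicc(100, 1000, 12), -2278.27, tolerance = 1e-2)
  # strictly increasing in k at fixed RSS and n
  expect_lt(aicc(50, 1000, 11), aicc(50, 1000, 12))
  # equal-k difference reduces to n * log(RSS ratio)
  expect_equal(aicc(80, 500, 8) - aicc(40, 500, 8), 500 * log(2),
               tolerance = 1e-10)
  expect_identical(aicc(0, 1000, 8), -Inf)
  expect_error(aicc(10, 10, 12), "exceed")
  expect_error(aicc(-1, 1000, 8), "non-negative")
})

test_that("selection takes the AICc argmin with parsimony tie-breaks", {
  # single candidate (degenerate argmin)
  s1 <- select_model(list(M3 = fake_fit("M3", 5)), generating = "M3")
  expect_equal(s1$selected, "M3")
  expect_true(s1$correct)

  # all RSS equal: fewest parameters wins (M11, k = 8)
  fits <- lapply(setNames(nm = paste0("M", 1:11)), fake_fit, rss = 5)
  expect_equal(select_model(fits)$selected, "M11")

  # equal AICc and equal k: lowest variant index
  two <- list(M5 = fake_fit("M5", 5), M3 = fake_fit("M3", 5))
  expect_equal(select_model(two)$selected, "M3")

  # mismatched n_points is a contract violation
  bad <- list(M1 = fake_fit("M1", 5, n = 1000), M2 = fake_fit("M2", 5, n = 900))
  expect_error(select_model(bad), "share")

  sel <- select_model(fits, generating = "M4")
  expect_false(sel$correct)
})

test_that("tally matches a hand-counted set of outcomes", {
  mk <- function(gen, sel) structure(
    list(selected = sel, generating = gen, correct = identical(gen, sel),
         aic_by_model = NULL), class = "model_selection")
  res <- list(mk("M1", "M1"), mk("M1", "M2"), mk("M3", "M3"),
              mk("M3", "M5"), mk("M7", "M11"), mk("M11", "M11"))
  tl <- tally_selections(res)
  expect_equal(sum(tl$counts), 6)
  expect_equal(tl$counts["M1", "M1"], 1L)
  expect_equal(tl$counts["M1", "M2"], 1L)
  expect_equal(tl$counts["M3", "M5"], 1L)
  expect_equal(unname(rowSums(tl$counts)[c("M1", "M3", "M7", "M11")]),
               c(2L, 2L, 1L, 1L))
  expect_equal(tl$overall_rate, 100 * 3 / 6)
  # wrong selections: M1->M2 (same class), M3->M5 (same class), M7->M11 (not)
  expect_equal(tl$within_class_fraction, 2 / 3)

  all_right <- list(mk("M2", "M2"), mk("M9", "M9"))
  tl2 <- tally_selections(all_right)
  expect_equal(tl2$overall_rate, 100)
  expect_true(all(tl2$counts[upper.tri(tl2$counts)] == 0L))
  expect_true(is.na(tl2$within_class_fraction))
})

test_that("profile log-likelihood matches the Gaussian formula", {
  expect_equal(profile_log_likelihood(100, 100), -50 * log(2 * pi) - 50,
               tolerance = 1e-12)
  expect_equal(profile_log_likelihood(100, 100), -141.89, tolerance = 1e-2)
  # independent oracle: dnorm at the profiled variance
  rss <- 3.7; n <- 40
  set.seed(5)
  r <- rnorm(n); r <- r * sqrt(rss / sum(r^2))  # residuals with exact RSS
  expect_equal(profile_log_likelihood(rss, n),
               sum(dnorm(r, 0, sqrt(rss / n), log = TRUE)), tolerance = 1e-10)
  # strictly decreasing in RSS at fixed n
  expect_gt(profile_log_likelihood(50, 100), profile_log_likelihood(100, 100))
  expect_identical(profile_log_likelihood(0, 100), Inf)
})
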