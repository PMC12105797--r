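# Evaluation metrics: Dice overlap, Lin's concordance, cellularity,
# percentage error, median/IQR summaries.

test_that("dice handles identity, disjointness and partial overlap", {
  a <- array(FALSE, c(4, 4, 2)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(4, 4, 2)); b[3:4, , ] <- TRUE
  expect_identical(dice(a, a), 1)
  expect_identical(dice(a, b), 0)

  # |A| = |B| = 100, overlap 80 -> 0.8
  a2 <- array(FALSE, c(20, 10, 1)); a2[1:100] <- TRUE
  b2 <- array(FALSE, c(20, 10, 1)); b2[21:120] <- TRUE
  expect_equal(dice(a2, b2), 0.8)
  expect_equal(dice(b2, a2), 0.8)  # symmetry

  expect_identical(dice(a & FALSE, b & FALSE), 1)  # identical emptiness
  expect_error(dice(a, array(TRUE, c(2, 2, 2))), "same grid")
})

test_that("ccc matches population-moment arithmetic and its identities", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4), sample_moments = TRUE), 2 / 3)
  set.seed(1)
  x <- runif(50); y <- runif(50)
  expect_equal(ccc(x, y), ccc(y, x))       # symmetric
  expect_lte(abs(ccc(x, y)), 1)            # bounded
  expect_equal(ccc(x, x), 1)               # metamorphic identity
  expect_error(ccc(rep(1, 5), rep(1, 5)), "constant")
  expect_error(ccc(1, 1), "length")
})

test_that("theta_cells follows packing/volume/radius scalings", {
  v <- theta_cells()
  expect_equal(v, 0.7405 * 0.5 / (4 / 3 * pi * 0.01^3), tolerance = 1e-12)
  expect_equal(v / 8.84e4, 1, tolerance = 1e-2)  # about 8.84e4 cells
  expect_equal(theta_cells(cell_radius = 0.02), v / 8)   # cubic in radius
  expect_equal(theta_cells(packing_density = 0.37025), v / 2)  # linear
})

test_that("total cellularity is linear and additive", {
  dims <- c(5, 2, 1)
  st <- state_of(array(0.3, dims), array(0.2, dims))
  expect_equal(total_cellularity(st, 1000), 1000 * 10 * 0.5)
  expect_equal(total_cellularity(state_of(array(0, dims), array(0, dims))), 0)
  # additive over disjoint regions
  a <- array(0, dims); a[1:5] <- 0.4
  b <- array(0, dims); b[6:10] <- 0.1
  expect_equal(total_cellularity(state_of(a + b, array(0, dims)), 10),
               total_cellularity(state_of(a, array(0, dims)), 10) +
                 total_cellularity(state_of(b, array(0, dims)), 10))
})

test_that("percent error is signed and guards zero truth", {
  expect_equal(percent_error(1, 1), 0)
  expect_equal(percent_error(0.9, 1), -10)
  expect_equal(percent_error(1.5, 1), 50)
  expect_error(percent_error(1, 0), "nonzero")
})

test_that("median/IQR summary uses the interpolation convention", {
  expect_equal(summarize_metric(1:5), c(median = 3, iqr = 2))
  expect_equal(summarize_metric(rep(7, 4)), c(median = 7, iqr = 0))
  set.seed(2); x <- rnorm(31)
  expect_equal(summarize_metric(x), summarize_metric(sample(x)))
  expect_error(summarize_metric(numeric(0)), "empty")
})

test_that("tumour mask binarizes the combined density at the threshold", {
  dims <- c(3, 1, 1)
  st <- state_of(array(c(0, 0.1, 0.2), dims), array(c(0, 0.06, 0), dims))
  m <- tumour_mask(st)  # default threshold 0.16, boundary included
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE))
  expect_false(any(tumour_mask(state_of(array(0, dims), array(0, dims)))))
  expect_true(all(tumour_mask(state_of(array(0.5, dims), array(0, dims)))))
})

test_that("vectorized metrics agree with naive reference loops", {
  set.seed(42)
  dims <- c(6, 5, 2)
  ne1 <- array(runif(prod(dims)), dims); nn1 <- array(runif(prod(dims), 0, 0.16), dims)
  ne2 <- array(runif(prod(dims)), dims); nn2 <- array(runif(prod(dims), 0, 0.16), dims)
  s1 <- state_of(ne1, nn1); s2 <- state_of(ne2, nn2)

  # naive dice
  m1 <- tumour_mask(s1); m2 <- tumour_mask(s2)
  inter <- 0; n1 <- 0; n2 <- 0
  for (i in seq_along(m1)) {
    if (m1[i] && m2[i]) inter <- inter + 1
    if (m1[i]) n1 <- n1 + 1
    if (m2[i]) n2 <- n2 + 1
  }
  expect_equal(dice(m1, m2), 2 * inter / (n1 + n2), tolerance = 1e-12)

  # naive ccc with population moments
  a <- as.vector(ne1 + nn1); b <- as.vector(ne2 + nn2)
  n <- length(a); ma <- sum(a) / n; mb <- sum(b) / n
  va <- 0; vb <- 0; cab <- 0
  for (i in seq_len(n)) {
    va <- va + (a[i] - ma)^2; vb <- vb + (b[i] - mb)^2
    cab <- cab + (a[i] - ma) * (b[i] - mb)
  }
  expect_equal(ccc(a, b), 2 * (cab / n) / (va / n + vb / n + (ma - mb)^2),
               tolerance = 1e-12)

  # naive cellularity
  tc <- 0
  for (i in seq_along(ne1)) tc <- tc + ne1[i] + nn1[i]
  expect_equal(total_cellularity(s1, 123.4), 123.4 * tc, tolerance = 1e-12)
})

test_that("metrics_report assembles the three agreement measures", {
  dims <- c(4, 4, 1)
  ne <- array(0.4, dims); nn <- array(0.1, dims)
  truth <- state_of(ne, nn)
  est <- state_of(ne * 0.9, nn)
  rep <- metrics_report(est, truth, array(TRUE, dims))
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$dsc, 1)
  expect_equal(rep$pe_ttc, percent_error(total_cellularity(est),
                                         total_cellularity(truth)))
  expect_equal(rep$time_label, "calibration")
})
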