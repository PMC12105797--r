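# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

# one small virtual patient scaffold reused across test files
fix_anatomy <- function() {
  if (is.null(.fix$anatomy)) .fix$anatomy <- make_anatomy(1, dims = c(16, 16, 3))
  .fix$anatomy
}

fix_schedule <- function() {
  if (is.null(.fix$schedule)) .fix$schedule <- make_schedule(fix_anatomy())
  .fix$schedule
}

# an untreated ground-truth trajectory (M11) with modest parameters
fix_m11_truth <- function() {
  if (is.null(.fix$m11)) {
    v <- model_variant("M11")
    p <- sample_parameters(v, seed = 11)
    .fix$m11 <- list(variant = v, params = p,
                     sim = simulate_tumour(v, p, fix_anatomy(), fix_schedule(),
                                           c(0, 7, 14, 21, 67)))
  }
  .fix$m11
}

# quantile-free helper: state list from arrays
state_of <- function(NE, NN, day = 0) list(NE = NE, NN = NN, day = day)

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), .Machine$double.eps), tol)
}
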