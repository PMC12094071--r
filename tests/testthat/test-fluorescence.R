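test_that("background correction subtracts the media control elementwise", {
  fi <- background_correct(c(1000, 200, 150), c(200, 200, 200))
  expect_equal(as.numeric(fi), c(800, 0, -50))
  expect_equal(attr(fi, "low_signal"), c(FALSE, FALSE, TRUE))
  expect_error(background_correct(1:3, 1:2), "length")
})

test_that("RFU is the mCherry/GFP ratio and is scale invariant", {
  expect_equal(compute_rfu(300, 600), 0.5)
  expect_equal(compute_rfu(c(5, 5), c(5, 5)), c(1, 1))
  set.seed(2)
  a <- runif(50, 10, 1000); b <- runif(50, 10, 1000)
  for (c_scale in c(0.01, 1, 7, 1e4)) {
    expect_equal(compute_rfu(c_scale * a, c_scale * b), compute_rfu(a, b))
  }
  # masking below the GFP floor
  r <- compute_rfu(c(10, 10), c(1e-12, 5))
  expect_true(is.na(r[1]) && r[2] == 2)
  expect_error(compute_rfu(c(1, 1), c(0, 0)), "no usable signal")
})

test_that("Savitzky-Golay smoothing reproduces low-degree polynomials exactly", {
  expect_equal(smooth_series(rep(3.5, 30)), rep(3.5, 30))
  t <- seq(0, 10, length.out = 41)
  ramp <- 2 + 0.7 * t
  expect_equal(smooth_series(ramp), ramp, tolerance = 1e-12)
  cubic <- 1 - t + 0.3 * t^2 - 0.01 * t^3
  expect_equal(smooth_series(cubic, window = 11, polyorder = 3), cubic,
               tolerance = 1e-10)
  expect_error(smooth_series(ramp, window = 10), "odd")
  expect_error(smooth_series(ramp, window = 3, polyorder = 3), "odd|polyorder")
  expect_error(smooth_series(1:5, window = 11), "length")
})

test_that("smoothing strictly reduces noise on a logistic curve", {
  set.seed(31)
  t <- seq(0, 36, 0.25)
  clean <- 1 / (1 + exp(-0.5 * (t - 10)))
  noisy <- clean + rnorm(length(t), 0, 0.02)
  sm <- smooth_series(noisy)
  expect_lt(var(sm - clean), var(noisy - clean))
})

test_that("growth-phase timepoints recover the logistic inflection", {
  t <- seq(0, 36, 0.25)
  for (r in c(0.1, 0.2, 0.5, 1.0)) {
    od <- 1 / (1 + exp(-r * (t - 10)))
    ph <- suppressWarnings(find_growth_phases(smooth_series(od), t))
    expect_lte(abs(ph$t_midexp - 10), 0.25)
  }
  # monotone curve: stationary timepoint is the final sample, with a warning
  od <- 1 / (1 + exp(-0.2 * (t - 30)))
  expect_warning(ph <- find_growth_phases(od, t), "final")
  expect_equal(ph$t_stat, 36)
  expect_error(find_growth_phases(rep(1, 20), seq_len(20)), "flat")
  expect_error(find_growth_phases(seq(5, 1, length.out = 20), 1:20),
               "never increases")
})

test_that("differential activity divides phase RFUs and is reciprocal", {
  t <- 0:20
  rfu <- c(rep(0.35, 11), rep(0.70, 10))
  expect_equal(differential_activity(rfu, t, t_midexp = 5, t_stat = 18), 0.5)
  expect_equal(differential_activity(rep(0.2, 21), t, 5, 18), 1.0)
  # swapping the two phase levels inverts the ratio
  swapped <- c(rep(0.70, 11), rep(0.35, 10))
  r1 <- differential_activity(rfu, t, 5, 18)
  r2 <- differential_activity(swapped, t, 5, 18)
  expect_equal(r1 * r2, 1)
  expect_error(differential_activity(rfu, t, 5, 50), "range")
  expect_error(differential_activity(c(rep(1, 11), rep(-1, 10)), t, 5, 18),
               "not positive")
})

test_that("phase-bias thresholds classify with boundaries as unbiased", {
  expect_equal(classify_phase_bias(0.5), "stationary_biased")
  expect_equal(classify_phase_bias(1.5), "exponential_biased")
  expect_equal(classify_phase_bias(c(0.7, 1.0, 1.3)),
               rep("unbiased", 3))
  expect_equal(classify_phase_bias(0.69999), "stationary_biased")
  expect_error(classify_phase_bias(-1), "positive")
})

test_that("detectability compares stationary RFU against background spread", {
  set.seed(12)
  bg <- rnorm(100, 0.001, 0.0005)
  expect_false(detect_active(mean(bg), bg))
  expect_true(detect_active(mean(bg) + 10 * sd(bg), bg))
  expect_error(detect_active(0.5, NULL), "background")
})

test_that("quadrant gating assigns events by closed AU intervals", {
  expect_equal(gate_quadrant(200000, 50000), "HH")
  expect_equal(gate_quadrant(30000, 3700), "LL")
  expect_equal(gate_quadrant(80000, 5000), "ungated")  # both in the gaps
  expect_equal(gate_quadrant(c(100000, 500000), c(8000, 90000)),
               c("HH", "HH"))                           # interval closure
  expect_equal(gate_quadrant(30000, 90000), "LH")
  expect_equal(gate_quadrant(150000, 3600), "HL")
  expect_error(gate_quadrant(-1, 10), "nonnegative")
})
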