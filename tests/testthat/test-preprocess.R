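grid_stream <- function(t, f) accel_stream(t, 0, f(t), 0)

test_that("kernel smoother reproduces constants and matches a direct sum", {
  t <- seq(0, 4, by = 1 / 80)
  s <- accel_stream(t, 1.5, 9.81, -2)
  q <- c(0, 0.33, 1.234, 4)
  out <- gaussian_smooth(s, 0.09, q)
  expect_equal(unname(out[, "ax"]), rep(1.5, 4), tolerance = 1e-12)
  expect_equal(unname(out[, "ay"]), rep(9.81, 4), tolerance = 1e-12)

  # unit impulse against the O(n*m) untruncated oracle
  y <- as.numeric(t == 1.0)
  imp <- grid_stream(t, function(tt) 0)
  imp$ay <- y
  got <- gaussian_smooth(imp, 0.09, t)[, "ay"]
  expect_equal(unname(got), nw_oracle(t, y, 0.09, t), tolerance = 1e-9)

  # linear ramp is preserved away from edges
  ramp <- grid_stream(t, identity)
  got <- gaussian_smooth(ramp, 0.09, 2.0)[, "ay"]
  expect_equal(unname(got), 2.0, tolerance = 1e-6)
})

test_that("smoothing is linear in the signal", {
  set.seed(7)
  t <- sort(runif(400, 0, 5))
  f <- rnorm(400)
  g <- rnorm(400)
  q <- seq(0.5, 4.5, length.out = 50)
  sm <- function(y) {
    s <- accel_stream(t, 0, y, 0)
    gaussian_smooth(s, 0.12, q)[, "ay"]
  }
  expect_equal(sm(2 * f - 3 * g), 2 * sm(f) - 3 * sm(g), tolerance = 1e-9)
})

test_that("smoother validates inputs", {
  s <- accel_stream(c(0, 1), 0, 0, 0)
  expect_error(gaussian_smooth(s, 0, 0.5), "sigma")
  expect_error(gaussian_smooth(s, 0.1, 1.5), "span")
  empty <- accel_stream(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_error(gaussian_smooth(empty, 0.1, numeric(0)), "empty")
})

test_that("sinusoid segmentation finds analytic minima", {
  t <- seq(0, 13.2, by = 1 / 80)
  s <- grid_stream(t, function(tt) 9.81 + 2 * sin(2 * pi * tt / 1.2))
  segs <- segment_cycles(s)
  expect_equal(nrow(segs), 10L)
  expect_true(all(abs(segs$duration - 1.2) < 0.05))
  bounds <- c(segs$start, segs$end[10])
  expect_true(max(abs(bounds - (0.9 + 1.2 * 0:10))) < 0.020)
})

test_that("sinusoid over k*T + T/2 yields k cycles (partials dropped)", {
  for (case in list(c(k = 8, T = 1.0), c(k = 12, T = 1.4))) {
    k <- case[["k"]]; Tc <- case[["T"]]
    t <- seq(0, k * Tc + Tc / 2, by = 1 / 80)
    s <- grid_stream(t, function(tt) 9.81 - 2 * sin(2 * pi * tt / Tc))
    expect_equal(nrow(segment_cycles(s)), k)
  }
})

test_that("constant and too-short streams are handled", {
  t <- seq(0, 10, by = 1 / 80)
  expect_equal(nrow(segment_cycles(grid_stream(t, function(tt) 9.81))), 0L)
  short <- grid_stream(seq(0, 0.9, by = 1 / 80), function(tt) 9.81)
  expect_error(segment_cycles(short), "too short")
})

test_that("segmentation is stable under irregular sampling", {
  f <- function(tt) 9.81 + 2 * sin(2 * pi * tt / 1.2)
  t1 <- seq(0, 13.2, by = 1 / 80)
  set.seed(11)
  t2 <- sort(t1 + runif(length(t1), -0.003, 0.003))
  t2 <- pmin(pmax(t2, 0), 13.2)
  t2 <- cummax(t2) + seq_along(t2) * 1e-9
  a <- segment_cycles(grid_stream(t1, f))
  b <- segment_cycles(grid_stream(t2, f))
  expect_equal(nrow(a), nrow(b))
  expect_true(max(abs(c(a$start, a$end[nrow(a)]) -
                        c(b$start, b$end[nrow(b)]))) < 0.020)
})

test_that("normalized cycles are 3 * n_steps long and exact on constants", {
  cfg <- preprocess_config()
  t <- seq(0, 4, by = 1 / 80)
  s <- accel_stream(t, 1, 9.81, -0.5)
  nc <- normalize_cycle(s, list(start = 1, end = 2.2), cfg)
  expect_equal(dim(unclass(nc)), c(100L, 3L))
  expect_equal(length(as.vector(unclass(nc))), 300L)
  expect_equal(unname(unclass(nc)[, 2]), rep(9.81, 100), tolerance = 1e-12)
  expect_error(normalize_cycle(s, list(start = 3.5, end = 4.7), cfg),
               "outside")
})

test_that("normalization is invariant to sampling rate and cycle speed", {
  tpl <- make_gear_template("G2L")
  mk <- function(Tc, rate) {
    tt <- seq(-1, 3 * Tc + 1, by = 1 / rate)
    v <- template_values(tpl, (tt %% Tc) / Tc)
    accel_stream(tt, v[, 1], v[, 2], v[, 3])
  }
  cfg <- preprocess_config()
  # 80 Hz vs 50 Hz, same duration
  a <- normalize_cycle(mk(1.2, 80), list(start = 1.2, end = 2.4), cfg)
  b <- normalize_cycle(mk(1.2, 50), list(start = 1.2, end = 2.4), cfg)
  expect_lt(max(abs(a - b)), 0.05)
  # same template played at 0.9 s vs 1.5 s per cycle
  c1 <- normalize_cycle(mk(0.9, 80), list(start = 0.9, end = 1.8), cfg)
  c2 <- normalize_cycle(mk(1.5, 80), list(start = 1.5, end = 3.0), cfg)
  expect_lt(max(abs(c1 - c2)), 0.05)
})

test_that("extract_cycles composes segmentation and normalization", {
  tr <- simulate_trial("G3", 10, sim_config(seed = 5, noise_sd = 0))
  cycles <- extract_cycles(tr$stream)
  segs <- attr(cycles, "segments")
  expect_equal(length(cycles), nrow(segs))
  expect_true(all(diff(segs$start) > 0))           # temporal order
  expect_true(all(vapply(cycles, function(cy)
    all(dim(unclass(cy)) == c(100L, 3L)), logical(1))))
  empty <- accel_stream(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_identical(length(extract_cycles(empty)), 0L)
})

test_that("config invariants are enforced", {
  expect_error(preprocess_config(sigma_segment = 0.05), "sigma")
  expect_error(preprocess_config(n_steps = 1), "n_steps")
  expect_error(preprocess_config(min_cycle_duration = 5), "cycle_duration")
})
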