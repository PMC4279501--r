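# small, well-separated trajectory templates for toy chains
toy_template <- function(n_steps, shift = 0) {
  phi <- seq(0, 1, length.out = n_steps)
  cbind(sin(2 * pi * phi) + shift, 9.81 + cos(2 * pi * phi), shift)
}

test_that("fitting two identical cycles gives ridge-only covariances", {
  V <- as_cycle(toy_template(10))
  m <- fit_markov_gaussian(list(V, V), "G3", ridge = 1e-3)
  expect_equal(m$S1, diag(1e-3, 3), tolerance = 1e-12)
  for (tt in 1:9)
    expect_equal(m$Q[, , tt], diag(1e-3, 3), tolerance = 1e-12)
  # the chain's implied mean trajectory reproduces the training cycle
  expect_equal(implied_means(m), unclass(V), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("degenerate training inputs are rejected", {
  V <- as_cycle(toy_template(10))
  expect_error(fit_markov_gaussian(list(V), "G3"), "insufficient")
  W <- as_cycle(toy_template(12))
  expect_error(fit_markov_gaussian(list(V, W), "G3"), "shape")
  expect_error(fit_markov_gaussian(list(V, V), "G7"), "unknown gear")
})

test_that("log-likelihood has the closed form on the mean trajectory", {
  tpl <- toy_template(100)
  A <- array(0, c(3, 3, 99))
  model <- structure(list(gear = "G3", n_steps = 100L, mu1 = tpl[1, ],
                          S1 = diag(3), A = A, b = t(tpl[-1, ]),
                          Q = array(diag(3), c(3, 3, 99)),
                          ridge = 0, n_train = 2L),
                     class = "gear_model")
  ll <- log_likelihood(model, as_cycle(tpl))
  expect_equal(ll, -150 * log(2 * pi), tolerance = 1e-9)

  # scaling the deviation from the mean strictly decreases log-likelihood
  dev <- matrix(0.1, 100, 3)
  lls <- vapply(c(1, 1.5, 2, 4), function(k)
    log_likelihood(model, as_cycle(tpl + k * dev)), numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("chain log-likelihood equals the joint-Gaussian density", {
  set.seed(21)
  train <- lapply(1:30, function(i)
    as_cycle(toy_template(3) + matrix(rnorm(9, 0, 0.3), 3, 3)))
  m <- fit_markov_gaussian(train, "G2L", ridge = 1e-4)
  for (i in 1:20) {
    cy <- as_cycle(toy_template(3) + matrix(rnorm(9, 0, 0.5), 3, 3))
    expect_equal(log_likelihood(m, cy), joint_gaussian_loglik(m, cy),
                 tolerance = 1e-8)
  }
})

test_that("non-positive-definite model covariance is a model error", {
  V1 <- as_cycle(toy_template(5))
  m <- fit_markov_gaussian(list(V1, as_cycle(toy_template(5, 1))), "G3")
  m$S1 <- matrix(c(1, 2, 2, 1, 1, 1, 1, 1, 1), 3, 3)  # not PD
  expect_error(log_likelihood(m, V1), "positive definite")
})

test_that("classifier training covers all gears and is deterministic", {
  set.seed(3)
  cyc <- lapply(gear_levels(), function(g)
    lapply(1:4, function(i)
      as_cycle(toy_template(8, shift = match(g, gear_levels())) +
                 matrix(rnorm(24, 0, 0.05), 8, 3))))
  names(cyc) <- gear_levels()
  clf <- train_classifier(cyc, ridge = 1e-3)
  expect_s3_class(clf, "gear_classifier")
  expect_named(clf$models, gear_levels())

  expect_error(train_classifier(cyc[c("G2L", "G2R", "G3", "G4L")]), "G4R")

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_model(train_classifier(cyc, ridge = 1e-3), f1)
  write_model(train_classifier(cyc, ridge = 1e-3), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("classification is argmax with canonical-order tie-breaking", {
  set.seed(9)
  mk_class <- function(shifts) {
    cyc <- lapply(shifts, function(s)
      lapply(1:4, function(i)
        as_cycle(toy_template(6, s) + matrix(rnorm(18, 0, 0.05), 6, 3))))
    names(cyc) <- gear_levels()
    train_classifier(cyc, ridge = 1e-3)
  }
  clf <- mk_class(shifts = c(0, 2, 4, 6, 8))
  probe <- as_cycle(toy_template(6, 4))            # on G3's template
  pred <- classify_cycle(clf, probe)
  expect_identical(pred$gear, "G3")
  expect_true(all(pred$loglik["G3"] >= pred$loglik))

  # argmax agrees with the brute-force joint-Gaussian oracle
  for (i in 1:10) {
    cy <- as_cycle(toy_template(6, runif(1, 0, 8)) +
                     matrix(rnorm(18, 0, 0.2), 6, 3))
    oracle <- vapply(clf$models, joint_gaussian_loglik, numeric(1),
                     cycle = cy)
    expect_identical(classify_cycle(clf, cy)$gear,
                     gear_levels()[which.max(oracle)])
  }

  # identical models tie towards the earlier gear
  clf$models$G4L <- clf$models$G2R
  clf$models$G4L$gear <- "G4L"
  probe2 <- as_cycle(toy_template(6, 2))
  pred2 <- classify_cycle(clf, probe2)
  expect_equal(pred2$loglik[["G2R"]], pred2$loglik[["G4L"]])
  expect_identical(pred2$gear, "G2R")
})

test_that("parameter recovery sharpens with more training cycles", {
  tpl <- toy_template(20)
  chain <- known_chain(tpl, q = 0.01)
  mse <- function(n, seed) {
    set.seed(seed)
    cyc <- simulate_chain_cycles(n, chain$mu1, chain$S1, chain$A, chain$b,
                                 chain$Q)
    mean((implied_means(fit_markov_gaussian(cyc, "G3", 1e-6)) - tpl)^2)
  }
  m50 <- vapply(1:8, function(s) mse(50, s), numeric(1))
  m500 <- vapply(1:8, function(s) mse(500, s + 100), numeric(1))
  expect_lt(mean(m500), mean(m50))
})

test_that("classifier output is invariant to a uniform time shift", {
  tr <- simulate_trial("G4L", 12, sim_config(seed = 31))
  clf <- train_classifier(training_cycles(n_cycles = 15, seeds = 41:45))
  p1 <- classify_stream(clf, tr$stream)
  shifted <- tr$stream
  shifted$time_s <- shifted$time_s + 1000
  p2 <- classify_stream(clf, shifted)
  expect_identical(p1$gear, p2$gear)
  expect_equal(p2$start_s - 1000, p1$start_s, tolerance = 1e-6)

  # constant stream: no cycles, no predictions
  t <- seq(0, 30, by = 1 / 80)
  expect_equal(nrow(classify_stream(clf, accel_stream(t, 0, 9.81, 0))), 0L)
})

test_that("own-gear held-out cycles outscore the mirror gear's model", {
  clf <- train_classifier(training_cycles(n_cycles = 25, seeds = 51:55))
  ev_l <- extract_cycles(simulate_trial("G2L", 15,
                                        sim_config(seed = 61))$stream)
  ev_r <- extract_cycles(simulate_trial("G2R", 15,
                                        sim_config(seed = 62))$stream)
  ll <- function(model, cycles)
    mean(vapply(cycles, log_likelihood, numeric(1), model = model))
  expect_gt(ll(clf$models$G2L, ev_l), ll(clf$models$G2L, ev_r))
  expect_gt(ll(clf$models$G2R, ev_r), ll(clf$models$G2R, ev_l))
})

test_that("models survive JSON round-trip", {
  clf <- train_classifier(training_cycles(n_cycles = 10, seeds = 71:75))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(clf, path)
  clf2 <- read_model(path)
  expect_identical(clf2$regime, clf$regime)
  expect_equal(clf2$preprocess, clf$preprocess)
  for (g in gear_levels()) {
    expect_equal(clf2$models[[g]]$mu1, clf$models[[g]]$mu1,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(clf2$models[[g]]$A, clf$models[[g]]$A, tolerance = 1e-12)
    expect_equal(clf2$models[[g]]$Q, clf$models[[g]]$Q, tolerance = 1e-12)
  }
  tr <- simulate_trial("G3", 8, sim_config(seed = 81))
  expect_identical(classify_stream(clf, tr$stream)$gear,
                   classify_stream(clf2, tr$stream)$gear)
})
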