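# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive (direct sums, explicit joint
# covariance construction) so it checks the package's faster code paths
# from a different direction.

# direct O(n*m) Gaussian weighted sum, no truncation, no blocking
nw_oracle <- function(t, y, sigma, q) {
  vapply(q, function(qi) {
    w <- exp(-(t - qi)^2 / (2 * sigma^2))
    sum(w * y) / sum(w)
  }, numeric(1))
}

# assemble the full joint Gaussian (3n x 3n) implied by a fitted
# Markov-Gaussian chain and evaluate its log-density directly
joint_gaussian_loglik <- function(model, cycle) {
  n <- model$n_steps
  d <- 3L * n
  mu <- numeric(d)
  Sigma <- matrix(0, d, d)
  blk <- function(i) ((i - 1L) * 3L + 1L):(i * 3L)
  mu[blk(1)] <- model$mu1
  Sigma[blk(1), blk(1)] <- model$S1
  for (tt in 2:n) {
    A <- model$A[, , tt - 1L]
    mu[blk(tt)] <- A %*% mu[blk(tt - 1L)] + model$b[, tt - 1L]
    for (ss in 1:(tt - 1L))
      Sigma[blk(tt), blk(ss)] <- A %*% Sigma[blk(tt - 1L), blk(ss)]
    Sigma[blk(tt), blk(tt)] <- A %*% Sigma[blk(tt - 1L), blk(tt - 1L)] %*%
      t(A) + model$Q[, , tt - 1L]
    for (ss in 1:(tt - 1L))
      Sigma[blk(ss), blk(tt)] <- t(Sigma[blk(tt), blk(ss)])
  }
  x <- as.vector(t(unclass(cycle)))   # step-major: (v1, v2, ..., vn)
  ch <- chol(Sigma)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + sum(z * z)) - sum(log(diag(ch)))
}

# sample cycles from a known linear-Gaussian chain
simulate_chain_cycles <- function(n_cycles, mu1, S1, A, b, Q) {
  n_steps <- ncol(b) + 1L
  lapply(seq_len(n_cycles), function(i) {
    V <- matrix(0, n_steps, 3)
    V[1, ] <- MASS::mvrnorm(1, mu1, S1)
    for (tt in 2:n_steps)
      V[tt, ] <- MASS::mvrnorm(1, A[, , tt - 1L] %*% V[tt - 1L, ] +
                                 b[, tt - 1L], Q[, , tt - 1L])
    structure(V, class = c("normalized_cycle", "matrix", "array"))
  })
}

# a chain with A_t = 0.5 I whose implied step means follow `template`
# (n_steps x 3), with isotropic noise
known_chain <- function(template, q = 0.01) {
  n <- nrow(template)
  A <- array(0, c(3, 3, n - 1L))
  b <- matrix(0, 3, n - 1L)
  Q <- array(0, c(3, 3, n - 1L))
  for (tt in 2:n) {
    A[, , tt - 1L] <- diag(0.5, 3)
    b[, tt - 1L] <- template[tt, ] - 0.5 * template[tt - 1L, ]
    Q[, , tt - 1L] <- diag(q, 3)
  }
  list(mu1 = template[1, ], S1 = diag(q, 3), A = A, b = b, Q = Q,
       template = template)
}

# implied mean trajectory of a fitted model, by forward recursion
implied_means <- function(model) {
  M <- matrix(0, model$n_steps, 3)
  M[1, ] <- model$mu1
  for (tt in 2:model$n_steps)
    M[tt, ] <- model$A[, , tt - 1L] %*% M[tt - 1L, ] + model$b[, tt - 1L]
  M
}

# wrap a plain matrix as a normalized cycle
as_cycle <- function(V) structure(V, class = c("normalized_cycle",
                                               "matrix", "array"))

# reference classifier under the default reference conditions (50 cycles per
# gear), fitted once per test run
.fixture_cache <- new.env(parent = emptyenv())
reference_classifier <- function() {
  if (is.null(.fixture_cache$clf))
    .fixture_cache$clf <- train_classifier(training_cycles(n_cycles = 50,
                                                           seeds = 1:5))
  .fixture_cache$clf
}

# quick synthetic training set: one fixed-gear trial per gear
training_cycles <- function(n_cycles = 50, seeds = 1:5, ...) {
  out <- lapply(seq_along(gear_levels()), function(i)
    extract_cycles(simulate_trial(gear_levels()[i], n_cycles,
                                  sim_config(seed = seeds[i], ...))$stream))
  names(out) <- gear_levels()
  out
}
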