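#' Fit a Markov chain of multivariate Gaussians to one gear's cycles
#'
#' The generative model for a normalized cycle `v_1, ..., v_n` (each `v_t`
#' a point in 3-D acceleration space) is a first-order linear-Gaussian
#' chain: `v_1 ~ N(mu1, S1)` and, for t = 2..n,
#' `v_t | v_{t-1} ~ N(A_t v_{t-1} + b_t, Q_t)`.  This keeps roughly 2.1k
#' parameters per gear -- far fewer than a full 300 x 300 covariance --
#' while still modelling the sequential correlation along the trajectory,
#' and it works on continuous accelerations without discretizing them.
#'
#' Estimation is step-wise least squares: `mu1`/`S1` are the sample mean
#' and covariance (MLE, i.e. 1/N) of the first-step vectors; each
#' `(A_t, b_t)` is the least-squares linear map from step t-1 to step t
#' across training cycles (minimum-norm solution via the pseudoinverse, so
#' degenerate training sets are handled); `Q_t` is the residual
#' covariance.  `ridge * I` is added to `S1` and every `Q_t`, guaranteeing
#' positive definiteness.
#'
#' @param cycles List of `normalized_cycle` matrices (all `n_steps` x 3),
#'   at least two.
#' @param gear Gear label from [gear_levels()].
#' @param ridge Non-negative ridge added to all covariance estimates.  The
#'   default (`NULL`) uses `1e-3` times the mean per-axis variance of the
#'   training values, floored at `1e-8`; with ~50 cycles per gear the raw
#'   3 x 3 residual covariances are occasionally near-singular.
#' @return An object of class `gear_model`.
#' @export
fit_markov_gaussian <- function(cycles, gear, ridge = NULL) {
  assert_gear(gear)
  if (length(cycles) < 2L)
    stop("insufficient data: need at least 2 cycles to fit a gear model, got ",
         length(cycles), call. = FALSE)
  dims <- vapply(cycles, function(cy) nrow(unclass(cy)), integer(1))
  n_steps <- dims[1]
  if (any(dims != n_steps) ||
      any(vapply(cycles, function(cy) ncol(unclass(cy)), integer(1)) != 3L))
    stop("shape error: all cycles must share n_steps x 3", call. = FALSE)
  arr <- vapply(cycles, function(cy) unclass(cy)[, , drop = FALSE],
                matrix(0, n_steps, 3))            # n_steps x 3 x N
  N <- length(cycles)
  if (is.null(ridge)) {
    axvar <- mean(apply(arr, 2, function(m) stats::var(as.vector(m))))
    ridge <- max(1e-3 * axvar, 1e-8)
  }
  if (!(ridge >= 0)) stop("ridge must be non-negative", call. = FALSE)

  dimnames(arr) <- NULL
  first <- t(arr[1, , ])                          # N x 3
  mu1 <- colMeans(first)
  c1 <- sweep(first, 2, mu1)
  S1 <- crossprod(c1) / N + diag(ridge, 3)

  A <- array(0, c(3, 3, n_steps - 1L))
  b <- matrix(0, 3, n_steps - 1L)
  Q <- array(0, c(3, 3, n_steps - 1L))
  for (tt in 2:n_steps) {
    X <- cbind(t(arr[tt - 1L, , ]), 1)            # N x 4
    Y <- t(arr[tt, , ])                           # N x 3
    beta <- MASS::ginv(X) %*% Y                   # 4 x 3, min-norm LS
    R <- Y - X %*% beta
    A[, , tt - 1L] <- t(beta[1:3, , drop = FALSE])
    b[, tt - 1L] <- beta[4, ]
    Q[, , tt - 1L] <- crossprod(R) / N + diag(ridge, 3)
  }
  structure(list(gear = gear, n_steps = as.integer(n_steps),
                 mu1 = mu1, S1 = S1, A = A, b = b, Q = Q,
                 ridge = ridge, n_train = N),
            class = "gear_model")
}

#' @export
print.gear_model <- function(x, ...) {
  cat(sprintf("<gear_model> %s: %d-step Markov-Gaussian chain, %d training cycles, ridge %.3g\n",
              x$gear, x$n_steps, x$n_train, x$ridge))
  invisible(x)
}

# log N(x; mu, Sigma) via Cholesky; errors on non-PD Sigma
ldmvn <- function(x, mu, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("model-integrity error: covariance not positive definite",
         call. = FALSE))
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + sum(z * z)) - sum(log(diag(ch)))
}

#' Log-likelihood of a normalized cycle under a gear model
#'
#' The chain factorization
#' `log N(v_1; mu1, S1) + sum_t log N(v_t; A_t v_{t-1} + b_t, Q_t)`,
#' computed in the log domain throughout (Cholesky factorizations of the
#' 3 x 3 covariances; no densities are ever exponentiated).
#'
#' @param model A [fit_markov_gaussian()] model.
#' @param cycle A `normalized_cycle` with the model's `n_steps`.
#' @return A single log-density.
#' @export
log_likelihood <- function(model, cycle) {
  V <- unclass(cycle)
  if (nrow(V) != model$n_steps || ncol(V) != 3L)
    stop("cycle shape ", nrow(V), " x ", ncol(V), " does not match model (",
         model$n_steps, " x 3)", call. = FALSE)
  ll <- ldmvn(V[1, ], model$mu1, model$S1)
  for (tt in 2:model$n_steps) {
    mu <- model$A[, , tt - 1L] %*% V[tt - 1L, ] + model$b[, tt - 1L]
    ll <- ll + ldmvn(V[tt, ], as.numeric(mu), model$Q[, , tt - 1L])
  }
  ll
}

#' Train the five-gear classifier
#'
#' Fits one Markov-Gaussian model per gear.  Training is deterministic:
#' identical input gives identical (bitwise, once serialized) models.
#'
#' @param labeled_cycles Named list mapping every gear in [gear_levels()]
#'   to a list of at least two `normalized_cycle` matrices.
#' @param ridge Passed to [fit_markov_gaussian()] (default `NULL`:
#'   data-scaled, chosen per gear).
#' @param preprocess The [preprocess_config()] used to produce the cycles;
#'   stored so classification uses the same settings.
#' @param regime `"collective"` (pooled multi-skier corpus) or
#'   `"individual"` (one skier's own calibration trial).
#' @return An object of class `gear_classifier`.
#' @export
train_classifier <- function(labeled_cycles, ridge = NULL,
                             preprocess = preprocess_config(),
                             regime = c("collective", "individual")) {
  regime <- match.arg(regime)
  missing <- setdiff(gear_levels(), names(labeled_cycles))
  if (length(missing))
    stop("coverage error: no training cycles for gear(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  models <- lapply(gear_levels(), function(g)
    fit_markov_gaussian(labeled_cycles[[g]], g, ridge))
  names(models) <- gear_levels()
  n_steps <- unique(vapply(models, `[[`, integer(1), "n_steps"))
  if (length(n_steps) != 1L)
    stop("gears were trained with differing n_steps", call. = FALSE)
  structure(list(models = models, preprocess = preprocess, regime = regime),
            class = "gear_classifier")
}

#' @export
print.gear_classifier <- function(x, ...) {
  n <- vapply(x$models, `[[`, integer(1), "n_train")
  cat(sprintf("<gear_classifier> regime=%s, n_steps=%d\n", x$regime,
              x$models[[1]]$n_steps))
  cat("  training cycles:",
      paste(sprintf("%s=%d", names(n), n), collapse = ", "), "\n")
  invisible(x)
}

#' Classify a single normalized cycle
#'
#' Evaluates the cycle's log-likelihood under all five gear models and
#' predicts the maximizer; exact ties go to the earlier gear in canonical
#' order.  Class priors are equal (pure likelihood argmax).
#'
#' @param classifier A [train_classifier()] result.
#' @param cycle A `normalized_cycle`.
#' @return A list with `gear` (predicted label), `loglik` (named vector
#'   over [gear_levels()]) and `segment` (the cycle's source segment, or
#'   NULL).
#' @export
classify_cycle <- function(classifier, cycle) {
  ll <- vapply(classifier$models, log_likelihood, numeric(1), cycle = cycle)
  list(segment = attr(cycle, "segment"),
       gear = gear_levels()[which.max(ll)],
       loglik = ll)
}

#' Classify every cycle of an accelerometer stream
#'
#' Runs [extract_cycles()] with the classifier's stored preprocessing
#' configuration (unless overridden) and classifies each cycle.
#'
#' @param classifier A [train_classifier()] result.
#' @param stream An [accel_stream()].
#' @param cfg Optional [preprocess_config()]; default: the configuration
#'   the classifier was trained with.
#' @return A data frame of class `gear_predictions` with columns
#'   `start_s`, `end_s`, `gear` and `loglik_<gear>` for each gear, one row
#'   per detected cycle in temporal order.  Zero rows if no cycles are
#'   found.
#' @export
classify_stream <- function(classifier, stream, cfg = NULL) {
  if (is.null(cfg)) cfg <- classifier$preprocess
  cycles <- extract_cycles(stream, cfg)
  preds <- lapply(cycles, classify_cycle, classifier = classifier)
  ll <- if (length(preds)) do.call(rbind, lapply(preds, `[[`, "loglik"))
        else matrix(0, 0, 5)
  gear_predictions(
    start_s = vapply(preds, function(p) p$segment$start, numeric(1)),
    end_s = vapply(preds, function(p) p$segment$end, numeric(1)),
    gear = vapply(preds, `[[`, character(1), "gear"),
    loglik = ll)
}

gear_predictions <- function(start_s, end_s, gear, loglik = NULL) {
  df <- data.frame(start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   gear = as.character(gear))
  if (nrow(df)) assert_gear(df$gear)
  if (is.null(loglik)) loglik <- matrix(NA_real_, nrow(df), 5)
  colnames(loglik) <- paste0("loglik_", gear_levels())
  out <- cbind(df, as.data.frame(loglik))
  structure(out, class = c("gear_predictions", "data.frame"))
}

#' Read / write per-cycle prediction tables
#'
#' CSV with header `start_s,end_s,gear,loglik_G2L,...,loglik_G4R`, the
#' `classify` output format of the command-line interface.
#'
#' @param path Path to a CSV file.
#' @return `read_predictions` returns a `gear_predictions` data frame.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE)
  need <- c("start_s", "end_s", "gear", paste0("loglik_", gear_levels()))
  if (!all(need %in% names(df)))
    stop("prediction file ", path, ": missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  gear_predictions(df$start_s, df$end_s, trimws(df$gear),
                   as.matrix(df[paste0("loglik_", gear_levels())]))
}

#' @param predictions A `gear_predictions` data frame.
#' @rdname read_predictions
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(as.data.frame(predictions), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize / deserialize a trained classifier as JSON
#'
#' The model file embeds the preprocessing configuration, the training
#' regime and, per gear, `mu1`, `S1`, the `A`/`b`/`Q` chain blocks, the
#' ridge and the training-cycle count, as nested JSON arrays at full
#' precision, so models are reproducible across platforms.
#'
#' @param classifier A [train_classifier()] result.
#' @param path Path of the JSON model file.
#' @return `read_model` returns a `gear_classifier`; `write_model`
#'   invisibly returns `path`.
#' @export
write_model <- function(classifier, path) {
  ms <- lapply(classifier$models, function(m) {
    nb <- m$n_steps - 1L
    list(mu1 = m$mu1, S1 = m$S1,
         A = lapply(seq_len(nb), function(i) m$A[, , i]),
         b = lapply(seq_len(nb), function(i) m$b[, i]),
         Q = lapply(seq_len(nb), function(i) m$Q[, , i]),
         ridge = m$ridge, n_train = m$n_train)
  })
  obj <- list(preprocess = unclass(classifier$preprocess),
              regime = classifier$regime, models = ms)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- obj$preprocess
  cfg <- preprocess_config(sigma_segment = pp$sigma_segment,
                           sigma_feature = pp$sigma_feature,
                           n_steps = pp$n_steps,
                           segmentation_channel = pp$segmentation_channel,
                           min_cycle_duration = pp$min_cycle_duration,
                           max_cycle_duration = pp$max_cycle_duration,
                           min_prominence_frac = pp$min_prominence_frac,
                           cycle_duration_ref = pp$cycle_duration_ref)
  missing <- setdiff(gear_levels(), names(obj$models))
  if (length(missing))
    stop("model file ", path, " lacks gear(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  models <- lapply(gear_levels(), function(g) {
    m <- obj$models[[g]]
    A <- aperm(m$A, c(2, 3, 1))
    Q <- aperm(m$Q, c(2, 3, 1))
    structure(list(gear = g, n_steps = as.integer(nrow(m$b) + 1L),
                   mu1 = as.numeric(m$mu1), S1 = as.matrix(m$S1),
                   A = A, b = t(m$b), Q = Q,
                   ridge = m$ridge, n_train = m$n_train),
              class = "gear_model")
  })
  names(models) <- gear_levels()
  structure(list(models = models, preprocess = cfg,
                 regime = match.arg(obj$regime,
                                    c("collective", "individual"))),
            class = "gear_classifier")
}
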