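#' Simulation configuration
#'
#' Conditions of the synthetic sessions the generator produces, emulating
#' chest-accelerometer recordings of treadmill roller-ski skating: a
#' nominal 80 Hz sampling rate with small timestamp jitter (phone clocks
#' are not metronomes), cycle durations around 1.4 s with cycle-to-cycle
#' jitter, mild per-cycle amplitude variation and additive white sensor
#' noise.
#'
#' @param cycle_duration_mean,cycle_duration_sd Per-cycle duration draw, in
#'   seconds (defaults 1.4 and 0.1).
#' @param noise_sd Additive Gaussian noise per axis and sample, m/s^2
#'   (default 0.3).
#' @param sample_rate Nominal sampling rate in Hz (default 80).
#' @param timestamp_jitter_sd Jitter added to each nominal sample time, in
#'   seconds (default 0.001); makes the sampling irregular.
#' @param amplitude_mean,amplitude_sd Per-cycle multiplicative scale of the
#'   oscillatory part of the template (defaults 1.0 and 0.05).
#' @param seed Mandatory integer seed; every stochastic draw of a
#'   simulation flows from this single source, so outputs are
#'   bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(cycle_duration_mean = 1.4,
                       cycle_duration_sd = 0.1,
                       noise_sd = 0.3,
                       sample_rate = 80,
                       timestamp_jitter_sd = 0.001,
                       amplitude_mean = 1.0,
                       amplitude_sd = 0.05,
                       seed) {
  if (missing(seed) || is.null(seed))
    stop("sim_config requires an explicit `seed` for reproducibility",
         call. = FALSE)
  cfg <- list(cycle_duration_mean = cycle_duration_mean,
              cycle_duration_sd = cycle_duration_sd,
              noise_sd = noise_sd,
              sample_rate = sample_rate,
              timestamp_jitter_sd = timestamp_jitter_sd,
              amplitude_mean = amplitude_mean,
              amplitude_sd = amplitude_sd,
              seed = as.integer(seed))
  pos <- c("cycle_duration_mean", "sample_rate", "amplitude_mean")
  for (f in pos) if (!(cfg[[f]] > 0))
    stop(f, " must be positive", call. = FALSE)
  nonneg <- c("cycle_duration_sd", "noise_sd", "timestamp_jitter_sd",
              "amplitude_sd")
  for (f in nonneg) if (!(cfg[[f]] >= 0))
    stop(f, " must be non-negative", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Fourier-series templates over cycle phase, m/s^2.  a0 + sum_k a_k
# cos(2 pi k phi) + b_k sin(2 pi k phi), order <= 4 per axis.  Shapes are
# hand-designed caricatures of the per-gear patterns seen in filtered
# chest-acceleration data (lateral "half-moon" coupling in G2, an almost
# symmetric "butterfly" in G3), not fits to any recording.  Every gear
# keeps a substantial fundamental on the vertical axis whose minimum sits
# at phase 0.5, mid-way through the constructed cycle: segmentation then
# lands on a consistent phase for all gears, and the detected boundaries
# fall in the interior of the stream (a recording starts mid-movement
# relative to the vertical minimum).  G3's lateral axis uses odd
# harmonics only, giving the half-cycle antisymmetry
# ax(phi) = -ax(phi + 1/2) of a symmetric technique.
template_coefs <- function() {
  z4 <- numeric(4)
  list(
    G2L = list(
      ax = list(a0 = 0.3, a = c(0, 0.6, 0, 0), b = c(2.5, 0, 0, 0)),
      ay = list(a0 = 9.81, a = c(2.5, 0, 0, 0), b = c(0, 1.0, 0, 0)),
      az = list(a0 = -1.2, a = c(1.8, 0, 0, 0), b = c(0, 1.0, 0, 0))),
    G3 = list(
      ax = list(a0 = 0, a = c(0.5, 0, 0, 0), b = c(2.2, 0, 0.7, 0)),
      ay = list(a0 = 9.81, a = c(2.3, 1.1, 0, 0), b = z4),
      az = list(a0 = -0.8, a = c(0, 1.6, 0, 0), b = c(0.9, 0, 0, 0))),
    G4L = list(
      ax = list(a0 = 0.4, a = z4, b = c(2.0, 0.9, 0, 0)),
      ay = list(a0 = 9.81, a = c(2.6, 0, 0.5, 0), b = c(0, -0.8, 0, 0)),
      az = list(a0 = -1.0, a = c(1.3, -0.9, 0, 0), b = c(0, 0, 0.5, 0))))
}

mirror_ax <- function(tpl) {
  tpl$ax$a0 <- -tpl$ax$a0
  tpl$ax$a <- -tpl$ax$a
  tpl$ax$b <- -tpl$ax$b
  tpl
}

#' Built-in gear acceleration templates
#'
#' Returns the periodic 3-axis template of a gear as coefficient lists of
#' a finite Fourier series in cycle phase.  The right-side variants G2R
#' and G4R are the exact lateral mirrors (ax negated) of G2L and G4L; G3's
#' lateral axis is half-cycle antisymmetric.  Templates are pairwise well
#' separated (RMS distance over a phase grid > 1 m/s^2 at default
#' amplitude), so the five classes are distinguishable by construction.
#'
#' @param gear A label from [gear_levels()].
#' @return A list of class `gear_template` with elements `gear` and
#'   per-axis coefficients `ax`, `ay`, `az` (`a0`, cosine `a`, sine `b`).
#' @export
#' @examples
#' tpl <- make_gear_template("G3")
#' template_values(tpl, c(0, 0.25, 0.5, 0.75))
make_gear_template <- function(gear) {
  assert_gear(gear)
  base <- template_coefs()
  tpl <- switch(gear,
                G2L = base$G2L, G3 = base$G3, G4L = base$G4L,
                G2R = mirror_ax(base$G2L), G4R = mirror_ax(base$G4L))
  structure(c(list(gear = gear), tpl), class = "gear_template")
}

#' Evaluate a gear template at given cycle phases
#'
#' @param template A [make_gear_template()] object.
#' @param phase Numeric vector of phases; used modulo 1.
#' @return Matrix `length(phase)` x 3 (columns ax, ay, az), m/s^2.
#' @export
template_values <- function(template, phase) {
  phi <- as.numeric(phase) %% 1
  eval_axis <- function(cf) {
    v <- rep(cf$a0, length(phi))
    for (k in 1:4)
      v <- v + cf$a[k] * cos(2 * pi * k * phi) +
        cf$b[k] * sin(2 * pi * k * phi)
    v
  }
  cbind(ax = eval_axis(template$ax), ay = eval_axis(template$ay),
        az = eval_axis(template$az))
}

template_offsets <- function(template)
  c(ax = template$ax$a0, ay = template$ay$a0, az = template$az$a0)

# Core synthesis: one stream from a per-cycle gear sequence.  Assumes the
# RNG state is already set by the caller (all draws flow from one seed).
synthesize_session <- function(cycle_gears, cfg) {
  n <- length(cycle_gears)
  dur <- rnorm(n, cfg$cycle_duration_mean, cfg$cycle_duration_sd)
  dur <- pmax(dur, 0.5 * cfg$cycle_duration_mean)
  amp <- rnorm(n, cfg$amplitude_mean, cfg$amplitude_sd)
  amp <- pmax(amp, 0.25 * cfg$amplitude_mean)
  bounds <- c(0, cumsum(dur))
  total <- bounds[n + 1L]

  t <- seq(0, total, by = 1 / cfg$sample_rate)
  if (cfg$timestamp_jitter_sd > 0) {
    t <- t + rnorm(length(t), 0, cfg$timestamp_jitter_sd)
    t <- sort(t)
    t <- pmin(pmax(t, 0), total)
    t <- cummax(t + seq_along(t) * 1e-9)   # enforce strict increase
    t <- t[t <= total]
  }
  m <- length(t)
  k <- findInterval(t, bounds, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), n)
  phi <- (t - bounds[k]) / dur[k]

  vals <- matrix(0, m, 3)
  tpls <- lapply(gear_levels(), make_gear_template)
  names(tpls) <- gear_levels()
  for (g in unique(cycle_gears)) {
    idx <- which(cycle_gears[k] == g)
    if (!length(idx)) next
    tpl <- tpls[[g]]
    off <- template_offsets(tpl)
    base <- template_values(tpl, phi[idx])
    dev <- sweep(base, 2, off)
    vals[idx, ] <- sweep(dev * amp[k[idx]], 2, off, "+")
  }
  if (cfg$noise_sd > 0)
    vals <- vals + matrix(rnorm(3 * m, 0, cfg$noise_sd), m, 3)

  stream <- accel_stream(t, vals[, 1], vals[, 2], vals[, 3],
                         meta = list(generator = "skigears-synthetic",
                                     nominal_rate_hz = cfg$sample_rate))
  attr(stream, "cycle_bounds") <- bounds
  attr(stream, "cycle_gears") <- cycle_gears
  # where the smoothed vertical minima -- the detectable cycle
  # boundaries -- are constructed to lie
  attr(stream, "expected_boundaries") <- bounds[seq_len(n)] + 0.5 * dur
  stream
}

#' Simulate a fixed-gear trial
#'
#' Concatenates `n_cycles` periods of one gear's template with per-cycle
#' duration and amplitude jitter, samples them on a jittered 80 Hz grid
#' and adds white noise -- the synthetic counterpart of a standardized
#' fixed-gear treadmill calibration trial of about 50 cycles.
#'
#' @param gear Gear label.
#' @param n_cycles Number of cycles, >= 1.
#' @param cfg A [sim_config()] (its `seed` determines all randomness).
#' @return List with `stream` (an [accel_stream()], generator bookkeeping
#'   attached as attributes `cycle_bounds` / `cycle_gears`) and `labels`
#'   (a single covering [gear_labels()] interval).
#' @export
#' @examples
#' trial <- simulate_trial("G3", 10, sim_config(seed = 1))
#' trial$labels
simulate_trial <- function(gear, n_cycles, cfg) {
  assert_gear(gear)
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  stream <- with_seed(cfg$seed,
                      synthesize_session(rep(gear, n_cycles), cfg))
  bounds <- attr(stream, "cycle_bounds")
  list(stream = stream,
       labels = gear_labels(0, bounds[length(bounds)], gear))
}

# block sequence whose expected totals mirror the reference variable
# protocol: ~140 cycles split ~30/27/30/26/26 over the gears with ~23
# transitions (mean block just under 6 cycles)
draw_gear_blocks <- function() {
  target <- c(G2L = 30, G2R = 27, G3 = 30, G4L = 26, G4R = 26)
  remaining <- target
  blocks <- list()
  prev <- ""
  while (sum(remaining) > 0) {
    open <- names(remaining)[remaining > 0]
    pick <- setdiff(open, prev)
    if (!length(pick)) pick <- open
    g <- if (length(pick) == 1L) pick
         else sample(pick, 1, prob = remaining[pick])
    len <- min(1L + rpois(1, 4.8), remaining[g])
    blocks[[length(blocks) + 1L]] <- list(gear = g, n = len)
    remaining[g] <- remaining[g] - len
    prev <- g
  }
  blocks
}

#' Simulate the variable-gear protocol
#'
#' Emulates a ~4-min free-choice treadmill trial: a block sequence over
#' the five gears with instantaneous gear changes at cycle boundaries.
#' When `gear_sequence` is not given, blocks are drawn so the totals match
#' the reference protocol (about 140 cycles split roughly
#' 30/27/30/26/26 across G2L/G2R/G3/G4L/G4R, with on the order of 23
#' transitions).  Label intervals exactly tile the stream's time span,
#' one per block.
#'
#' @param cfg A [sim_config()].
#' @param gear_sequence Optional explicit per-cycle gear vector overriding
#'   the block draw.
#' @return List with `stream` and `labels` (one interval per block), plus
#'   generator bookkeeping as in [simulate_trial()].
#' @export
simulate_variable_protocol <- function(cfg, gear_sequence = NULL) {
  with_seed(cfg$seed, {
    if (is.null(gear_sequence)) {
      blocks <- draw_gear_blocks()
      gear_sequence <- unlist(lapply(blocks, function(b) rep(b$gear, b$n)))
    } else {
      assert_gear(gear_sequence)
    }
    stream <- synthesize_session(gear_sequence, cfg)
    bounds <- attr(stream, "cycle_bounds")
    # collapse consecutive same-gear cycles into label intervals
    r <- rle(gear_sequence)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
    labels <- gear_labels(bounds[starts_idx], bounds[ends_idx + 1L],
                          r$values)
    list(stream = stream, labels = labels)
  })
}
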