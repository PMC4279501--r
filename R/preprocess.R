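#' Preprocessing configuration
#'
#' Parameters of the smoothing/segmentation/normalization pipeline.
#'
#' @param sigma_segment Standard deviation, in seconds, of the Gaussian
#'   kernel used to isolate the very-low-frequency component on which cycle
#'   boundaries are detected.  Default 0.370 s.
#' @param sigma_feature Standard deviation, in seconds, of the per-cycle
#'   feature smoother at the reference cycle duration
#'   (`cycle_duration_ref`).  Default 0.090 s.  Within [normalize_cycle()]
#'   the bandwidth is scaled proportionally to the cycle's duration so that
#'   smoothing is fixed in cycle phase, which makes the normalized
#'   representation independent of how fast the gear is executed.
#' @param n_steps Number of resampling steps per cycle; the normalized
#'   representation has `3 * n_steps` values.  Default 100 (300 dims).
#' @param segmentation_channel One of `"x"`, `"y"`, `"z"`, `"magnitude"`;
#'   the signal whose smoothed local minima define cycle boundaries.
#'   Default `"y"` (vertical), since chest vertical oscillation is periodic
#'   in every skating gear.
#' @param min_cycle_duration,max_cycle_duration Admissible cycle durations
#'   in seconds (defaults 0.5 and 3.0), bracketing reported skating cycle
#'   rates.
#' @param min_prominence_frac Minimum topographic prominence of a candidate
#'   boundary minimum, as a fraction of the interquartile range of the
#'   smoothed segmentation signal.  Default 0.1; rejects noise minima.
#' @param cycle_duration_ref Reference cycle duration in seconds at which
#'   `sigma_feature` applies exactly.  Default 1.4 s.
#' @return A list of class `preprocess_config`.
#' @export
#' @examples
#' preprocess_config()
preprocess_config <- function(sigma_segment = 0.370,
                              sigma_feature = 0.090,
                              n_steps = 100L,
                              segmentation_channel = c("y", "x", "z",
                                                       "magnitude"),
                              min_cycle_duration = 0.5,
                              max_cycle_duration = 3.0,
                              min_prominence_frac = 0.1,
                              cycle_duration_ref = 1.4) {
  segmentation_channel <- match.arg(segmentation_channel)
  cfg <- list(sigma_segment = sigma_segment,
              sigma_feature = sigma_feature,
              n_steps = as.integer(n_steps),
              segmentation_channel = segmentation_channel,
              min_cycle_duration = min_cycle_duration,
              max_cycle_duration = max_cycle_duration,
              min_prominence_frac = min_prominence_frac,
              cycle_duration_ref = cycle_duration_ref)
  if (!(cfg$sigma_segment > cfg$sigma_feature && cfg$sigma_feature > 0))
    stop("need sigma_segment > sigma_feature > 0", call. = FALSE)
  if (cfg$n_steps < 2L) stop("n_steps must be >= 2", call. = FALSE)
  if (!(cfg$min_cycle_duration > 0 &&
        cfg$min_cycle_duration < cfg$max_cycle_duration))
    stop("need 0 < min_cycle_duration < max_cycle_duration", call. = FALSE)
  if (cfg$cycle_duration_ref <= 0)
    stop("cycle_duration_ref must be positive", call. = FALSE)
  structure(cfg, class = "preprocess_config")
}

#' Gaussian kernel smoothing of an irregularly sampled stream
#'
#' Nadaraya-Watson estimator with a Gaussian kernel over sample *times*:
#' the value at query time q is `sum_i w_i s_i / sum_i w_i` with
#' `w_i = exp(-(t_i - q)^2 / (2 sigma^2))`.  Because weights are computed
#' from actual timestamps and renormalized per query, irregular sampling,
#' arbitrary query points and stream edges (truncated kernels) are all
#' handled by the same formula; constants are reproduced exactly.  The
#' kernel is truncated at +/- 4 sigma (discarding < 1e-4 of weight mass).
#'
#' @param stream An [accel_stream()].
#' @param sigma Kernel standard deviation in seconds, > 0.
#' @param query_times Times at which to evaluate; must lie within the
#'   stream's time span.
#' @param channels Character vector of stream columns to smooth.
#' @return Numeric matrix, `length(query_times)` rows, one column per
#'   requested channel.
#' @export
gaussian_smooth <- function(stream, sigma, query_times,
                            channels = c("ax", "ay", "az")) {
  validate_stream(stream)
  if (!is.numeric(sigma) || length(sigma) != 1L || !(sigma > 0))
    stop("sigma must be a single positive number", call. = FALSE)
  if (nrow(stream) == 0L) stop("cannot smooth an empty stream", call. = FALSE)
  t <- stream$time_s
  q <- as.numeric(query_times)
  if (any(q < t[1] - 1e-9 | q > t[length(t)] + 1e-9))
    stop("query time outside the stream's time span [", t[1], ", ",
         t[length(t)], "]", call. = FALSE)
  S <- as.matrix(as.data.frame(stream)[channels])
  out <- kernel_smooth(t, S, sigma, q)
  colnames(out) <- channels
  out
}

# blocked Nadaraya-Watson core: weights from actual sample times, built
# per block of sorted queries so the kernel matrix products use BLAS
kernel_smooth <- function(t, S, sigma, q) {
  out <- matrix(NA_real_, length(q), ncol(S))
  if (!length(q)) return(out)
  half <- 4 * sigma
  ord <- order(q)
  qs <- q[ord]
  block <- 256L
  for (b in seq.int(1L, length(qs), by = block)) {
    idx <- b:min(b + block - 1L, length(qs))
    qb <- qs[idx]
    i1 <- findInterval(qb[1] - half, t) + 1L
    i2 <- findInterval(qb[length(qb)] + half, t)
    i1 <- max(1L, min(i1, length(t)))
    i2 <- max(i1, i2)
    tw <- t[i1:i2]
    W <- exp(-(outer(qb, tw, "-"))^2 / (2 * sigma^2))
    W[W < 1e-12] <- 0
    out[ord[idx], ] <- (W %*% S[i1:i2, , drop = FALSE]) / rowSums(W)
  }
  out
}

# extend a sampled signal beyond both ends by point (odd) reflection
# through the endpoints, so the trend is continued rather than flattened:
# the pivot value at each edge comes from a short least-squares line fit,
# which keeps a noisy edge sample from biasing the whole extension.
extend_odd <- function(t, y, pad, fitwin = 0.15) {
  T0 <- t[1]
  T1 <- t[length(t)]
  pivot <- function(edge_t, idx) {
    if (length(idx) < 2L) return(y[which.min(abs(t - edge_t))])
    stats::lm.fit(cbind(1, t[idx] - edge_t), y[idx])$coefficients[1]
  }
  p0 <- pivot(T0, which(t <= T0 + fitwin))
  p1 <- pivot(T1, which(t >= T1 - fitwin))
  li <- which(t > T0 & t <= T0 + pad)
  ri <- which(t >= T1 - pad & t < T1)
  list(t = c(2 * T0 - rev(t[li]), t, 2 * T1 - rev(t[ri])),
       y = c(2 * p0 - rev(y[li]), y, 2 * p1 - rev(y[ri])))
}

# extend a sampled signal beyond both ends by copying whole periods of
# length P from the data -- exact for a periodic signal whatever phase the
# recording starts or ends on
extend_periodic <- function(t, y, pad, P) {
  T0 <- t[1]
  T1 <- t[length(t)]
  M <- ceiling(pad / P)
  lb <- which(t >= T0 & t < T0 + P)    # leading base period
  rb <- which(t > T1 - P & t <= T1)    # trailing base period
  lt <- ly <- rt <- ry <- list()
  for (m in seq_len(M)) {
    sel <- t[lb] - m * P >= T0 - pad
    lt[[m]] <- t[lb][sel] - m * P
    ly[[m]] <- y[lb][sel]
    sel <- t[rb] + m * P <= T1 + pad
    rt[[m]] <- t[rb][sel] + m * P
    ry[[m]] <- y[rb][sel]
  }
  tt <- c(unlist(lt), t, unlist(rt))
  yy <- c(unlist(ly), y, unlist(ry))
  ord <- order(tt)
  list(t = tt[ord], y = yy[ord])
}

segmentation_signal <- function(stream, channel) {
  switch(channel,
         x = stream$ax, y = stream$ay, z = stream$az,
         magnitude = sqrt(stream$ax^2 + stream$ay^2 + stream$az^2))
}

# topographic prominence of local minima of s at index positions `mins`:
# invert the signal and, on each side, take the lowest value reached before
# terrain higher than the peak (or the signal edge); prominence is peak
# minus the larger of the two bases.
min_prominence <- function(s, mins) {
  x <- -s
  n <- length(x)
  vapply(mins, function(i) {
    lo_l <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) {
      if (x[j] < lo_l) lo_l <- x[j]
      j <- j - 1L
    }
    lo_r <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) {
      if (x[j] < lo_r) lo_r <- x[j]
      j <- j + 1L
    }
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
}

# refine a discrete minimum by the vertex of the parabola through its
# three supporting (t, s) points; falls back to the sample time
refine_minimum <- function(t, s, i) {
  if (i <= 1L || i >= length(t)) return(t[i])
  t0 <- t[i - 1L]; t1 <- t[i]; t2 <- t[i + 1L]
  y0 <- s[i - 1L]; y1 <- s[i]; y2 <- s[i + 1L]
  d1 <- (y1 - y0) / (t1 - t0)
  d2 <- (y2 - y1) / (t2 - t1)
  a <- (d2 - d1) / (t2 - t0)
  if (!is.finite(a) || a <= 0) return(t[i])
  tv <- (t0 + t1) / 2 - d1 / (2 * a)
  min(max(tv, t0), t2)
}

#' Segment a stream into movement cycles
#'
#' Smooths the configured segmentation channel with `sigma_segment` (370 ms
#' by default), which leaves essentially only the per-cycle fundamental,
#' then places cycle boundaries at local minima of that very-low-frequency
#' signal.  Before smoothing, the channel is extended past both stream
#' ends by odd (point) reflection through the endpoints, which continues
#' the local trend and keeps boundary minima near the start/end of the
#' recording detectable.  Candidate minima must have topographic
#' prominence of at least
#' `min_prominence_frac` times the IQR of the smoothed signal; minima
#' closer together than `min_cycle_duration` are merged (the deeper one is
#' kept).  Every consecutive pair of retained minima whose spacing lies
#' within the duration bounds becomes one cycle; the partial cycles before
#' the first and after the last minimum are discarded.
#'
#' @param stream An [accel_stream()] spanning more than
#'   `2 * min_cycle_duration` seconds.
#' @param cfg A [preprocess_config()].
#' @return A data frame of class `cycle_segments` with columns `start`,
#'   `end`, `duration` (seconds), possibly with zero rows.
#' @export
segment_cycles <- function(stream, cfg = preprocess_config()) {
  validate_stream(stream)
  t <- stream$time_s
  if (length(t) < 3L || t[length(t)] - t[1] <= 2 * cfg$min_cycle_duration)
    stop("stream too short to segment (need > ",
         2 * cfg$min_cycle_duration, " s)", call. = FALSE)
  raw <- segmentation_signal(stream, cfg$segmentation_channel)
  pad <- 4 * cfg$sigma_segment

  smooth_detect <- function(ext) {
    s <- kernel_smooth(ext$t, matrix(ext$y, ncol = 1), cfg$sigma_segment,
                       t)[, 1]
    detect_boundaries(t, s, cfg)
  }
  # pass 1: odd-reflection padding continues the signal's trend past the
  # stream edges, so boundary minima close to the start/end are not
  # flattened away by the wide segmentation kernel
  bt <- smooth_detect(extend_odd(t, raw, pad))
  # pass 2: the movement is cyclic, so once the period is known from the
  # first-pass minima, periodic padding reconstructs the signal beyond the
  # edges essentially exactly; re-detect with that padding
  if (length(bt) >= 3L) {
    P <- stats::median(diff(bt))
    bt2 <- smooth_detect(extend_periodic(t, raw, pad, P))
    if (length(bt2) >= 2L) bt <- bt2
  }
  if (length(bt) < 2L) return(empty_segments())
  start <- bt[-length(bt)]
  end <- bt[-1]
  dur <- end - start
  ok <- dur >= cfg$min_cycle_duration & dur <= cfg$max_cycle_duration
  out <- data.frame(start = start[ok], end = end[ok], duration = dur[ok])
  rownames(out) <- NULL
  structure(out, class = c("cycle_segments", "data.frame"))
}

# local minima of the smoothed segmentation signal that pass the
# prominence gate and minimum-separation rule, refined by parabolic
# interpolation; returns boundary times
detect_boundaries <- function(t, s, cfg) {
  n <- length(s)
  if (n < 3L) return(numeric(0))
  cand <- which(s[2:(n - 1)] < s[1:(n - 2)] & s[2:(n - 1)] <= s[3:n]) + 1L
  if (!length(cand)) return(numeric(0))
  prom <- min_prominence(s, cand)
  # absolute floor (1e-6 m/s^2) keeps floating-point wiggle on flat
  # signals from masquerading as movement cycles
  gate <- max(cfg$min_prominence_frac * stats::IQR(s), 1e-6)
  keep <- cand[prom >= gate]
  if (!length(keep)) return(numeric(0))
  # enforce minimum separation, keeping the deeper minimum of a close pair
  sel <- keep[1]
  for (i in keep[-1]) {
    last <- sel[length(sel)]
    if (t[i] - t[last] < cfg$min_cycle_duration) {
      if (s[i] < s[last]) sel[length(sel)] <- i
    } else sel <- c(sel, i)
  }
  vapply(sel, function(i) refine_minimum(t, s, i), numeric(1))
}

empty_segments <- function() {
  structure(data.frame(start = numeric(0), end = numeric(0),
                       duration = numeric(0)),
            class = c("cycle_segments", "data.frame"))
}

#' Normalize one cycle to a fixed-length trajectory
#'
#' Evaluates the Gaussian kernel smoother at `n_steps` times uniformly
#' spaced over the segment, for all three axes, so smoothing and
#' resampling happen in a single kernel-regression pass.  The bandwidth is
#' `sigma_feature * duration / cycle_duration_ref`, i.e. fixed in cycle
#' phase (90 ms at the 1.4-s reference duration by default), which makes
#' the representation independent of both the sampling rate and how fast
#' the cycle was executed.  With the default 100 steps the result is a
#' trajectory of 100 points in 3-D acceleration space: a 300-dimensional
#' vector when flattened.
#'
#' @param stream An [accel_stream()] whose time span covers `segment`.
#' @param segment One row of a [segment_cycles()] result (or any list with
#'   `start` and `end`).
#' @param cfg A [preprocess_config()].
#' @return A `normalized_cycle`: an `n_steps` x 3 numeric matrix (columns
#'   ax, ay, az) with the source segment attached as attribute `segment`.
#' @export
normalize_cycle <- function(stream, segment, cfg = preprocess_config()) {
  start <- as.numeric(segment$start)
  end <- as.numeric(segment$end)
  t <- stream$time_s
  if (!length(t) || start < t[1] - 1e-9 || end > t[length(t)] + 1e-9)
    stop("segment [", start, ", ", end, "] outside stream time span",
         call. = FALSE)
  qs <- seq(start, end, length.out = cfg$n_steps)
  sig <- cfg$sigma_feature * (end - start) / cfg$cycle_duration_ref
  vals <- gaussian_smooth(stream, sig, qs)
  structure(vals, segment = list(start = start, end = end,
                                 duration = end - start),
            class = c("normalized_cycle", class(vals)))
}

#' Extract all normalized cycles from a stream
#'
#' Composition of [segment_cycles()] and [normalize_cycle()]: one
#' normalized trajectory per detected complete cycle, in temporal order.
#'
#' @inheritParams segment_cycles
#' @return A list of `normalized_cycle` objects with the segment table
#'   attached as attribute `segments`.  Empty (zero segments) is valid;
#'   streams too short to contain a complete cycle yield an empty list.
#' @export
extract_cycles <- function(stream, cfg = preprocess_config()) {
  t <- stream$time_s
  if (length(t) < 3L || t[length(t)] - t[1] <= 2 * cfg$min_cycle_duration)
    return(structure(list(), segments = empty_segments()))
  segs <- segment_cycles(stream, cfg)
  cycles <- lapply(seq_len(nrow(segs)), function(i)
    normalize_cycle(stream, segs[i, ], cfg))
  structure(cycles, segments = segs)
}

#' @export
print.cycle_segments <- function(x, ...) {
  cat(sprintf("<cycle_segments> %d cycle(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
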