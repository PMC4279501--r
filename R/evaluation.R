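#' Assign reference gear labels to detected cycles
#'
#' Each cycle segment receives the gear of the label interval that
#' overlaps it for the longest duration; exact ties go to the earlier
#' interval.  Cycles with no overlap at all get `NA` ("unlabeled") and are
#' excluded from scoring downstream -- a video gold standard labels every
#' cycle it sees, so unlabeled cycles only arise from gaps in
#' user-supplied annotations.
#'
#' @param intervals A [gear_labels()] table (sorted, non-overlapping).
#' @param segments A [segment_cycles()] table (or any data frame with
#'   `start`/`end` columns).
#' @return Character vector, one reference gear (or `NA`) per segment.
#' @export
align_labels <- function(intervals, segments) {
  validate_labels(intervals)
  vapply(seq_len(nrow(segments)), function(i) {
    s <- segments$start[i]
    e <- segments$end[i]
    ov <- pmin(intervals$end_s, e) - pmax(intervals$start_s, s)
    ov[ov <= 0] <- 0
    if (!any(ov > 0)) return(NA_character_)
    intervals$gear[which.max(ov)]          # first max = earlier interval
  }, character(1))
}

#' Confusion matrix of reference vs predicted gears
#'
#' Rows are the reference (video) gear, columns the predicted gear, both
#' in canonical order.  Pairs where the reference is `NA` (unlabeled
#' cycles) are dropped before counting.  Row percentages -- percent of the
#' total use of the gear in question -- are `NA` for gears that never
#' occur in the reference.
#'
#' @param predictions,references Character vectors of equal length with
#'   labels from [gear_levels()] (references may contain `NA`).
#' @return An object of class `gear_confusion`: list with `counts` (5 x 5
#'   integer matrix), `percent` (row-normalized, in 0-100) and `total`.
#' @export
confusion_matrix <- function(predictions, references) {
  if (length(predictions) != length(references))
    stop("predictions and references differ in length (",
         length(predictions), " vs ", length(references), ")", call. = FALSE)
  keep <- !is.na(references)
  p <- factor(predictions[keep], levels = gear_levels())
  r <- factor(references[keep], levels = gear_levels())
  assert_gear(predictions[keep])
  assert_gear(references[keep])
  counts <- table(reference = r, predicted = p)
  counts <- matrix(as.integer(counts), 5, 5,
                   dimnames = list(reference = gear_levels(),
                                   predicted = gear_levels()))
  rs <- rowSums(counts)
  percent <- counts / ifelse(rs > 0, rs, NA) * 100
  structure(list(counts = counts, percent = percent, total = sum(counts)),
            class = "gear_confusion")
}

#' @export
print.gear_confusion <- function(x, digits = 0, ...) {
  cat("<gear_confusion> reference (rows) vs predicted (columns), n (%)\n")
  cells <- matrix(sprintf("%d (%s%%)", x$counts,
                          ifelse(is.na(x$percent), "-",
                                 formatC(x$percent, format = "f",
                                         digits = digits))),
                  5, 5, dimnames = dimnames(x$counts))
  print(cells, quote = FALSE)
  cat("total scored cycles:", x$total, "\n")
  invisible(x)
}

#' Overall and per-gear accuracy from a confusion matrix
#'
#' Overall accuracy is the trace over the total; per-gear accuracy the
#' diagonal over the row sum (percent of that gear's cycles identified
#' correctly).  Gears absent from the reference are reported as `NA`.
#'
#' @param cm A [confusion_matrix()] result with at least one scored cycle.
#' @return List with `overall` (percent) and `per_gear` (named percent
#'   vector).
#' @export
accuracy_summary <- function(cm) {
  if (cm$total == 0L)
    stop("empty confusion matrix: no scored cycles", call. = FALSE)
  rs <- rowSums(cm$counts)
  list(overall = 100 * sum(diag(cm$counts)) / cm$total,
       per_gear = ifelse(rs > 0, 100 * diag(cm$counts) / rs, NA))
}

#' Break classification errors into startup / transition / other
#'
#' Mirrors the characteristic failure mode of per-cycle gear
#' classification: misclassifications concentrate
#' immediately after the start of measurement and around gear changes.  A
#' misclassified cycle is a *startup* error if it is among the first `k`
#' cycles; otherwise a *transition* error if it lies within `w` cycles of
#' a reference gear change (for a change whose first new-gear cycle has
#' index j, the window covers indices j - w .. j + w - 1); otherwise
#' *other*.  Categories are assigned with precedence startup > transition,
#' so the three counts always sum to the total number of errors.
#'
#' @param predictions,references Equal-length label vectors (aligned;
#'   reference `NA`s are dropped pairwise).
#' @param k Startup window: number of initial cycles (default 3).
#' @param w Transition window in cycles (default 1).
#' @return List of class `error_breakdown` with counts `n_startup`,
#'   `n_transition`, `n_other`, `n_errors`, `n_cycles` and the
#'   corresponding `fractions` (of total errors; `NaN`-free only when
#'   errors exist).
#' @export
error_breakdown <- function(predictions, references, k = 3L, w = 1L) {
  if (length(predictions) != length(references))
    stop("predictions and references differ in length", call. = FALSE)
  keep <- !is.na(references)
  p <- predictions[keep]
  r <- references[keep]
  n <- length(r)
  err <- which(p != r)
  change <- which(r[-1] != r[-n]) + 1L        # index of first new-gear cycle
  in_transition <- function(i)
    any(i >= change - w & i <= change + w - 1L)
  startup <- sum(err <= k)
  transition <- sum(vapply(err[err > k], in_transition, logical(1)))
  other <- length(err) - startup - transition
  fr <- if (length(err)) c(startup, transition, other) / length(err)
        else c(NA_real_, NA_real_, NA_real_)
  structure(list(n_startup = startup, n_transition = transition,
                 n_other = other, n_errors = length(err), n_cycles = n,
                 fractions = c(startup = fr[1], transition = fr[2],
                               other = fr[3]),
                 k = k, w = w),
            class = "error_breakdown")
}

#' @export
print.error_breakdown <- function(x, ...) {
  cat(sprintf(
    "<error_breakdown> %d errors / %d cycles: startup %d, transition %d, other %d (k=%d, w=%d)\n",
    x$n_errors, x$n_cycles, x$n_startup, x$n_transition, x$n_other,
    x$k, x$w))
  invisible(x)
}

#' Paired-sample t-test on per-subject accuracies
#'
#' Classical paired t on the differences `a - b` with `n - 1` degrees of
#' freedom (delegates to [stats::t.test()]).  The degenerate cases the
#' generic test refuses are resolved explicitly: identical vectors give
#' `t = 0, p = 1`; any other zero-variance difference vector is an error,
#' since the t statistic is then unbounded.
#'
#' @param a,b Equal-length numeric vectors, `n >= 2`.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need two equal-length vectors of length >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1L, p = 1))
    stop("degenerate input: differences have zero variance (all equal to ",
         mean(d), ")", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with the validation its intended use needs
#' (per-subject accuracy vs number of gear transitions): at least three pairs and
#' nonzero variance in both variables.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors of length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Score a prediction table against reference label intervals
#'
#' Convenience wrapper used by the `evaluate` command: aligns the
#' reference intervals to the predicted cycles, then computes the
#' confusion matrix, accuracy summary and error breakdown.
#'
#' @param predictions A `gear_predictions` table ([classify_stream()]).
#' @param intervals A [gear_labels()] table.
#' @param k,w Passed to [error_breakdown()].
#' @return List with elements `confusion`, `accuracy`, `breakdown`,
#'   `per_cycle` (data frame of start, end, predicted, reference).
#' @export
evaluate_predictions <- function(predictions, intervals, k = 3L, w = 1L) {
  segs <- data.frame(start = predictions$start_s, end = predictions$end_s)
  ref <- align_labels(intervals, segs)
  cm <- confusion_matrix(predictions$gear, ref)
  list(confusion = cm,
       accuracy = accuracy_summary(cm),
       breakdown = error_breakdown(predictions$gear, ref, k = k, w = w),
       per_cycle = data.frame(start_s = predictions$start_s,
                              end_s = predictions$end_s,
                              predicted = predictions$gear,
                              reference = ref))
}
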