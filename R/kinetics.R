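#' Background-subtracted intensity trace of one adhesion
#'
#' @param track_id integer identifier.
#' @param times sample times in seconds, strictly increasing.
#' @param intensities background-subtracted intensities, finite.
#' @param channel `"paxillin"` or `"gfp"`.
#' @return An `intensity_trace` object; `peak_index` is the argmax.
#' @export
intensity_trace <- function(track_id, times, intensities,
                            channel = "paxillin") {
  stopifnot(length(times) == length(intensities),
            all(is.finite(times)), all(diff(times) > 0),
            all(is.finite(intensities)))
  structure(list(track_id = track_id, times = times,
                 intensities = intensities, channel = channel,
                 peak_index = which.max(intensities)),
            class = "intensity_trace")
}

# adjusted R^2 of a simple (p = 1) linear regression of y on t
ols_adjusted_r2 <- function(t, y) {
  n <- length(t)
  fit <- stats::lm.fit(cbind(1, t), y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  list(slope = fit$coefficients[2],
       adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# shared adaptive-window scan; windows is a list of index vectors in the
# order of increasing preference under ties (later windows win ties only if
# strictly better, so enumerate preferred windows first)
best_window_fit <- function(times_min, y_fun, windows) {
  best <- NULL
  for (w in windows) {
    y <- y_fun(w)
    if (is.null(y)) next                 # window invalidated (I <= 0)
    f <- ols_adjusted_r2(times_min[w], y)
    if (is.null(best) || f$adjusted_r2 > best$adjusted_r2)
      best <- c(f, list(window = c(w[1], w[length(w)])))
  }
  best
}

#' Adhesion assembly rate constant by adaptive-window log-linear regression
#'
#' The assembly rate is the slope of \eqn{\ln(I/I_0)} against time, with
#' \eqn{I_0} the intensity at the first time point. Candidate windows start
#' at the trace start and end at sample \eqn{j} for \eqn{j} from the minimum
#' window length up to the intensity peak; ordinary least squares is fitted
#' on each and the window with the largest adjusted \eqn{R^2} is selected
#' (ties go to the longer window). Windows containing non-positive
#' intensities are skipped, not fatal. Natural logarithm; rate reported per
#' minute.
#'
#' @param trace an [intensity_trace()].
#' @param min_points minimum window length in samples (default 7, i.e.
#'   2 min of data at 20 s sampling; shorter windows let the adjusted-R^2
#'   window scan overfit pure noise).
#' @param r2_threshold adjusted-R^2 noise filter threshold (default 0.3).
#' @return A `kinetics_fit` list: `rate_constant` (per minute), `window`
#'   (start and end sample index), `adjusted_r2`, `i0`, `phase`,
#'   `passed_filter`, `failed`.
#' @export
assembly_rate <- function(trace, min_points = 7, r2_threshold = 0.3) {
  stopifnot(inherits(trace, "intensity_trace"))
  pk <- trace$peak_index
  failed <- function(msg) structure(
    list(rate_constant = NA_real_, window = c(NA, NA),
         adjusted_r2 = NA_real_, i0 = NA_real_, phase = "assembly",
         passed_filter = FALSE, failed = TRUE, reason = msg),
    class = "kinetics_fit")
  if (pk < min_points) return(failed("fewer than min_points samples before peak"))
  tmin <- trace$times / 60
  I <- trace$intensities
  i0 <- I[1]
  y_fun <- function(w) {
    v <- I[w]
    if (i0 <= 0 || any(v <= 0)) return(NULL)
    log(v / i0)
  }
  windows <- lapply(seq(pk, min_points), function(j) 1:j)  # longest first
  best <- best_window_fit(tmin, y_fun, windows)
  if (is.null(best)) return(failed("no valid window (non-positive intensities)"))
  structure(list(rate_constant = unname(best$slope), window = best$window,
                 adjusted_r2 = best$adjusted_r2, i0 = i0,
                 phase = "assembly",
                 passed_filter = best$adjusted_r2 >= r2_threshold,
                 failed = FALSE),
            class = "kinetics_fit")
}

#' Adhesion disassembly rate constant
#'
#' The disassembly rate is the slope of \eqn{\ln(I_0/I)} against time.
#' Candidate windows end at the last time point and start at sample \eqn{i}
#' for \eqn{i} from the intensity peak to `min_points` before the end;
#' \eqn{I_0} is the intensity at the earliest time point of each candidate
#' window (and hence of the selected one). Selection and filtering as in
#' [assembly_rate()]; a positive rate constant means decay.
#'
#' @inheritParams assembly_rate
#' @return A `kinetics_fit`, `phase = "disassembly"`.
#' @export
disassembly_rate <- function(trace, min_points = 7, r2_threshold = 0.3) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$times)
  pk <- trace$peak_index
  failed <- function(msg) structure(
    list(rate_constant = NA_real_, window = c(NA, NA),
         adjusted_r2 = NA_real_, i0 = NA_real_, phase = "disassembly",
         passed_filter = FALSE, failed = TRUE, reason = msg),
    class = "kinetics_fit")
  if (n < min_points)
    return(failed("fewer than min_points samples"))
  tmin <- trace$times / 60
  I <- trace$intensities
  y_fun <- function(w) {
    v <- I[w]
    if (any(v <= 0)) return(NULL)
    log(v[1] / v)
  }
  # when the peak sits within min_points of the end (e.g. a monotonically
  # increasing trace) the minimal trailing window is still scanned, so a
  # negative slope is reported rather than an error
  windows <- lapply(seq(min(pk, n - min_points + 1), n - min_points + 1),
                    function(i) i:n)
  best <- best_window_fit(tmin, y_fun, windows)
  if (is.null(best)) return(failed("no valid window (non-positive intensities)"))
  structure(list(rate_constant = unname(best$slope), window = best$window,
                 adjusted_r2 = best$adjusted_r2, i0 = I[best$window[1]],
                 phase = "disassembly",
                 passed_filter = best$adjusted_r2 >= r2_threshold,
                 failed = FALSE),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("kinetics_fit (%s): failed — %s\n", x$phase, x$reason))
  } else {
    cat(sprintf(
      "kinetics_fit (%s): k = %.4g /min, window [%d, %d], adj R2 = %.3f%s\n",
      x$phase, x$rate_constant, x$window[1], x$window[2], x$adjusted_r2,
      if (x$passed_filter) "" else " (filtered out)"))
  }
  invisible(x)
}

#' Filter kinetics fits by their best adjusted R-squared
#'
#' Noise-like trajectories are removed by requiring the best adjusted
#' \eqn{R^2} of the selected window to reach `threshold` (default 0.3).
#'
#' @param fits list of `kinetics_fit` objects.
#' @param threshold adjusted-R^2 floor.
#' @return List with `retained` (the surviving fits), `retention_rate`, and
#'   `n_failed` (fits that produced no valid window at all).
#' @export
filter_by_adjusted_r2 <- function(fits, threshold = 0.3) {
  ok <- vapply(fits, function(f) !f$failed, logical(1))
  keep <- vapply(fits, function(f)
    !f$failed && f$adjusted_r2 >= threshold, logical(1))
  list(retained = fits[keep],
       retention_rate = if (length(fits)) sum(keep) / length(fits) else NA_real_,
       n_failed = sum(!ok))
}

#' Kinetics of every sufficiently long track in a movie
#'
#' Builds per-track background-subtracted intensity traces from the fitted
#' amplitudes and runs both [assembly_rate()] and [disassembly_rate()].
#'
#' @param tracks data frame from [link_detections()] (with `amplitude`).
#' @param frame_interval seconds between frames.
#' @param min_length shortest track (in samples) analyzed.
#' @param channel channel label stored on the traces.
#' @return Data frame: one row per track and phase, with rate constant,
#'   window, adjusted R^2 and filter flag.
#' @export
track_kinetics <- function(tracks, frame_interval, min_length = 8,
                           channel = "paxillin") {
  sp <- split(tracks[!is.na(tracks$amplitude), ], tracks$track_id[!is.na(tracks$amplitude)])
  rows <- lapply(sp, function(tr) {
    if (nrow(tr) < min_length) return(NULL)
    trace <- intensity_trace(tr$track_id[1], tr$frame * frame_interval,
                             tr$amplitude, channel)
    do.call(rbind, lapply(list(assembly_rate(trace),
                               disassembly_rate(trace)), function(f)
      data.frame(track_id = tr$track_id[1], channel = channel,
                 phase = f$phase, rate_constant = f$rate_constant,
                 window_start = f$window[1], window_end = f$window[2],
                 adjusted_r2 = f$adjusted_r2,
                 passed_filter = f$passed_filter, failed = f$failed)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    track_id = integer(0), channel = character(0), phase = character(0),
    rate_constant = numeric(0), window_start = integer(0),
    window_end = integer(0), adjusted_r2 = numeric(0),
    passed_filter = logical(0), failed = logical(0))
  rownames(out) <- NULL
  out
}
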