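#' Construct a dual-channel photometry trace
#'
#' Container for a timestamped scheduled-acquisition recording with a
#' calcium-dependent channel (`f465`) and an isosbestic reference channel
#' (`f405`).
#'
#' @param time sample times, seconds, strictly increasing (off-duty gaps
#'   allowed).
#' @param f465,f405 channel fluorescence, arbitrary units, same length as
#'   `time`.
#' @param mask on-duty indicator (1 for every emitted sample).
#' @param meta list with at least `animal_id`; optionally `treatment`,
#'   `injection_time`, `recording_length`, `sample_rate`.
#' @return an object of class `dual_channel_trace`.
#' @export
new_dual_channel_trace <- function(time, f465, f405, mask = rep(1L, length(time)),
                                   meta = list()) {
  time <- as.numeric(time)
  if (length(time) < 2L) stop_input("trace needs at least 2 samples")
  if (any(diff(time) <= 0)) stop_input("time must be strictly increasing")
  if (length(f465) != length(time) || length(f405) != length(time))
    stop_input("f465/f405 must have the same length as time")
  if (anyNA(f465) || anyNA(f405)) stop_input("channels must not contain NA")
  structure(list(time = time, f465 = as.numeric(f465),
                 f405 = as.numeric(f405), mask = as.integer(mask),
                 meta = meta),
            class = "dual_channel_trace")
}

#' @export
print.dual_channel_trace <- function(x, ...) {
  cat(sprintf("dual_channel_trace: %d samples over %.1f s (animal %s)\n",
              length(x$time), diff(range(x$time)),
              x$meta$animal_id %||% "?"))
  invisible(x)
}

nominal_dt <- function(time) stats::median(diff(time))

#' Subtract the isosbestic channel from the calcium channel
#'
#' Removes calcium-independent background/motion components using the 405-nm
#' reference.  By default the reference is subtracted as-is; with
#' `fit_isosbestic = TRUE` the least-squares affine map of `f405` onto `f465`
#' is subtracted instead (useful when channel gains are not matched).
#'
#' @param trace a [new_dual_channel_trace()].
#' @param fit_isosbestic logical; fit `f405` to `f465` before subtracting.
#' @return class `corrected_trace`: list with `time`, `signal`,
#'   `processing_log`.
#' @export
subtract_background <- function(trace, fit_isosbestic = FALSE) {
  stopifnot(inherits(trace, "dual_channel_trace"))
  if (fit_isosbestic) {
    fit <- stats::lm.fit(cbind(1, trace$f405), trace$f465)
    ref <- fit$coefficients[1] + fit$coefficients[2] * trace$f405
    log_entry <- sprintf("subtract_background: affine fit (a=%.4g, b=%.4g)",
                         fit$coefficients[1], fit$coefficients[2])
  } else {
    ref <- trace$f405
    log_entry <- "subtract_background: plain 405-nm subtraction"
  }
  structure(list(time = trace$time, signal = trace$f465 - ref,
                 processing_log = log_entry, meta = trace$meta),
            class = "corrected_trace")
}

as_corrected <- function(x, time = NULL) {
  if (inherits(x, "corrected_trace")) return(x)
  if (is.numeric(x)) {
    if (is.null(time)) time <- seq_along(x) - 1
    return(structure(list(time = as.numeric(time), signal = as.numeric(x),
                          processing_log = character(), meta = list()),
                     class = "corrected_trace"))
  }
  stop_input("expected a corrected_trace or a numeric signal")
}

#' Moving-window baseline correction
#'
#' Estimates the slow baseline of a fluorescence signal as the per-window
#' 10th percentile in sliding windows of `window` seconds (stride
#' `window / 2`), interpolates between window centers with a natural cubic
#' spline, and subtracts it.  Transients much shorter than the window are
#' preserved in amplitude; drift and bleaching on the window scale are
#' removed.  Recordings shorter than two windows fall back to subtracting the
#' global 10th percentile (with a warning).
#'
#' @param x a `corrected_trace` (or numeric signal; see `time`).
#' @param window window size in seconds (default 900).
#' @param time sample times when `x` is a bare numeric vector.
#' @return a `corrected_trace` with the baseline removed.
#' @export
correct_baseline <- function(x, window = 900, time = NULL) {
  x <- as_corrected(x, time)
  window <- check_number(window, "window", min = 1e-9)
  tt <- x$time
  span <- diff(range(tt))
  if (span < 2 * window) {
    warning("recording shorter than two baseline windows; ",
            "subtracting global 10th percentile", call. = FALSE)
    base <- quantile(x$signal, 0.10, names = FALSE)
    x$signal <- x$signal - base
    x$processing_log <- c(x$processing_log,
      sprintf("correct_baseline: global q10 fallback (%.4g)", base))
    return(x)
  }
  stride <- window / 2
  centers <- seq(tt[1] + window / 2, tt[length(tt)] - window / 2, by = stride)
  q10 <- vapply(centers, function(cc) {
    quantile(x$signal[tt >= cc - window / 2 & tt <= cc + window / 2],
             0.10, names = FALSE)
  }, 0)
  base <- spline(centers, q10, xout = tt, method = "natural")$y
  x$signal <- x$signal - base
  x$processing_log <- c(x$processing_log,
    sprintf("correct_baseline: window=%gs stride=%gs q10, %d knots",
            window, stride, length(centers)))
  x
}

#' z-score a corrected signal
#'
#' `(x - mean(x)) / sd(x)` over the full recording.
#'
#' @param x a `corrected_trace` or numeric signal.
#' @param time sample times when `x` is numeric.
#' @return class `processed_trace`: list with `time`, `z`, `processing_log`.
#' @export
zscore <- function(x, time = NULL) {
  x <- as_corrected(x, time)
  s <- sd(x$signal)
  if (!is.finite(s) || s == 0)
    stop_input("degenerate signal: standard deviation is zero")
  structure(list(time = x$time, z = (x$signal - mean(x$signal)) / s,
                 processing_log = c(x$processing_log,
                   sprintf("zscore: mean=%.6g sd=%.6g", mean(x$signal), s)),
                 meta = x$meta),
            class = "processed_trace")
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("processed_trace: %d samples, z range [%.2f, %.2f]\n",
              length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' Detect peaks in a processed trace
#'
#' All strict local maxima with topographic prominence at least
#' `min_prominence`, in time order.  Plateau maxima resolve to the plateau
#' midpoint.
#'
#' @param trace a [zscore()] `processed_trace`.
#' @param min_prominence minimum topographic prominence, z units.
#' @return a `data.frame` (class `peak_table`) with columns `time`, `height`,
#'   `prominence`.
#' @export
detect_peaks <- function(trace, min_prominence = 1.0) {
  stopifnot(inherits(trace, "processed_trace"))
  res <- cpp_find_peaks(trace$z)
  idx <- res$index + 1L
  keep <- res$prominence >= min_prominence
  out <- data.frame(time = trace$time[idx[keep]],
                    height = trace$z[idx[keep]],
                    prominence = res$prominence[keep])
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Classify peaks into synchronization events
#'
#' Applies the two SE rules to detected peaks: (i) a peak must exceed 1/3 of
#' the highest peak of the recording, and (ii) accepted SEs must be more than
#' `min_spacing` seconds from each other peak-to-peak.  Spacing conflicts are
#' resolved greedily highest-amplitude-first (ties broken by earlier time),
#' which guarantees the accepted set satisfies both rules.  Onset, amplitude
#' and width at half maximum are then measured for each SE with [se_shape()].
#'
#' @param peaks a `peak_table` from [detect_peaks()] on the same trace.
#' @param trace the `processed_trace` the peaks came from.
#' @param min_spacing minimum peak-to-peak separation, seconds (default 160).
#' @param height_fraction fraction of the recording's highest peak required
#'   (default 1/3).
#' @return class `se_set`: data.frame with `peak_time`, `amplitude`,
#'   `onset_time`, `fwhm`, plus attributes `threshold`, `min_spacing`,
#'   `time_range`.
#' @export
classify_ses <- function(peaks, trace, min_spacing = 160,
                         height_fraction = 1 / 3) {
  stopifnot(inherits(trace, "processed_trace"))
  empty <- data.frame(peak_time = numeric(0), amplitude = numeric(0),
                      onset_time = numeric(0), fwhm = numeric(0),
                      fwhm_defined = logical(0))
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(structure(empty, class = c("se_set", "data.frame"),
                     threshold = NA_real_, min_spacing = min_spacing,
                     time_range = range(trace$time)))
  }
  threshold <- max(peaks$height) * height_fraction
  cand <- peaks[peaks$height >= threshold, , drop = FALSE]
  ord <- order(-cand$height, cand$time)
  kept_t <- numeric(0)
  for (i in ord) {
    if (!length(kept_t) || all(abs(cand$time[i] - kept_t) > min_spacing))
      kept_t <- c(kept_t, cand$time[i])
  }
  kept_t <- sort(kept_t)
  shapes <- lapply(kept_t, function(tp) se_shape(trace, tp))
  out <- data.frame(
    peak_time = kept_t,
    amplitude = vapply(shapes, `[[`, 0, "amplitude"),
    onset_time = vapply(shapes, `[[`, 0, "onset_time"),
    fwhm = vapply(shapes, `[[`, 0, "fwhm"),
    fwhm_defined = vapply(shapes, `[[`, TRUE, "fwhm_defined"))
  structure(out, class = c("se_set", "data.frame"), threshold = threshold,
            min_spacing = min_spacing, time_range = range(trace$time))
}

# crossing time of `level` between samples i and i+1, interpolating linearly
# only within nominally contiguous acquisition (not across off-duty gaps)
.crossing_time <- function(tt, zz, i, level, dt) {
  if (tt[i + 1] - tt[i] <= 2 * dt && zz[i + 1] != zz[i]) {
    tt[i] + (level - zz[i]) / (zz[i + 1] - zz[i]) * (tt[i + 1] - tt[i])
  } else {
    # gap: attribute the crossing to the supra-level side's sample time
    if (zz[i + 1] >= level) tt[i + 1] else tt[i]
  }
}

#' Measure amplitude, onset and width at half maximum of one SE
#'
#' Amplitude is the z value at the peak minus a local pre-peak baseline (the
#' median of the preceding `search_window` seconds, an unbiased level
#' estimate when transients occupy a small fraction of the window).  The width is the
#' time between the half-amplitude crossings bracketing the peak (linear
#' interpolation between samples); if a crossing is not found within
#' `search_window` seconds of the peak the width is flagged undefined.  The
#' onset is the last upward crossing of 20 % of the SE amplitude before the
#' peak.
#'
#' @param trace a `processed_trace`.
#' @param peak_time the SE peak time, seconds (must lie inside the trace).
#' @param search_window half-window for crossing searches, seconds.
#' @return list with `amplitude`, `fwhm`, `fwhm_defined`, `onset_time`.
#' @export
se_shape <- function(trace, peak_time, search_window = 300) {
  stopifnot(inherits(trace, "processed_trace"))
  tt <- trace$time; zz <- trace$z
  if (peak_time < tt[1] || peak_time > tt[length(tt)])
    stop_input("SE peak time lies outside the trace")
  dt <- nominal_dt(tt)
  pk <- which.min(abs(tt - peak_time))
  pre <- zz[tt >= tt[pk] - search_window & tt < tt[pk]]
  base <- if (length(pre)) median(pre) else min(zz)
  amp <- zz[pk] - base
  half <- base + amp / 2
  w <- which(tt >= tt[pk] - search_window & tt <= tt[pk] + search_window)
  lo <- w[1]; hi <- w[length(w)]

  t_left <- NA_real_
  if (pk > lo) for (i in seq(pk - 1L, lo)) {
    if (zz[i] < half) { t_left <- .crossing_time(tt, zz, i, half, dt); break }
  }
  t_right <- NA_real_
  if (pk < hi) for (i in seq(pk, hi - 1L)) {
    if (zz[i + 1] < half) { t_right <- .crossing_time(tt, zz, i, half, dt); break }
  }
  fwhm_defined <- is.finite(t_left) && is.finite(t_right)
  fwhm <- if (fwhm_defined) t_right - t_left else NA_real_

  onset_level <- base + 0.2 * amp
  onset <- NA_real_
  if (pk > lo) for (i in seq(pk - 1L, lo)) {
    if (zz[i] < onset_level && zz[i + 1] >= onset_level) {
      onset <- .crossing_time(tt, zz, i, onset_level, dt); break
    }
  }
  if (!is.finite(onset)) {
    below <- which(tt >= tt[pk] - search_window & tt < tt[pk])
    onset <- if (length(below)) tt[below[which.min(zz[below])]] else tt[pk]
  }
  list(amplitude = amp, fwhm = fwhm, fwhm_defined = fwhm_defined,
       onset_time = min(onset, tt[pk]))
}

#' SE counts, latency and inter-SE intervals around an injection
#'
#' Counts SEs (by peak time) in `n_bins` consecutive bins of `bin` seconds
#' after the injection and in one `baseline_bin`-second bin before it, and
#' measures the latency from the injection to the onset of the next SE plus
#' the intervals between the subsequent SE onsets.
#'
#' @param ses an [classify_ses()] `se_set` (time-sorted).
#' @param injection_time injection time, seconds; must lie inside the
#'   recording covered by `ses`.
#' @param bin post-injection bin width, seconds (default 4 h).
#' @param n_bins number of post-injection bins.
#' @param baseline_bin width of the pre-injection baseline bin, seconds.
#' @return class `se_timeline`: list with `baseline_count`, `bin_counts`,
#'   `latency_to_first` (NA-flagged when no SE follows the injection) and
#'   `inter_se_intervals`.
#' @export
se_timeline <- function(ses, injection_time, bin = 14400, n_bins = 2,
                        baseline_bin = 14400) {
  injection_time <- check_number(injection_time, "injection_time")
  rng <- attr(ses, "time_range")
  if (!is.null(rng) && (injection_time < rng[1] || injection_time > rng[2]))
    stop_input("injection_time lies outside the recording")
  pt <- ses$peak_time
  baseline_count <- sum(pt >= injection_time - baseline_bin & pt < injection_time)
  bin_counts <- vapply(seq_len(n_bins) - 1L, function(k) {
    sum(pt >= injection_time + k * bin & pt < injection_time + (k + 1) * bin)
  }, 0L)
  names(bin_counts) <- sprintf("bin%d", seq_len(n_bins))
  post <- ses[ses$onset_time >= injection_time, , drop = FALSE]
  post <- post[order(post$onset_time), , drop = FALSE]
  latency <- if (nrow(post)) post$onset_time[1] - injection_time else NA_real_
  intervals <- if (nrow(post) >= 2) diff(post$onset_time) else numeric(0)
  structure(list(baseline_count = baseline_count, bin_counts = bin_counts,
                 latency_to_first = latency,
                 latency_defined = nrow(post) > 0,
                 inter_se_intervals = intervals,
                 injection_time = injection_time, bin = bin),
            class = "se_timeline")
}

#' @export
print.se_timeline <- function(x, ...) {
  cat("SE timeline relative to injection at", x$injection_time, "s\n")
  cat("  baseline count:", x$baseline_count, "\n")
  cat("  post-injection bins:", paste(x$bin_counts, collapse = ", "), "\n")
  cat("  latency to first SE:",
      if (x$latency_defined) sprintf("%.1f s", x$latency_to_first) else
        "undefined (no SE after injection)", "\n")
  if (length(x$inter_se_intervals))
    cat("  inter-SE intervals:",
        paste(sprintf("%.1f", x$inter_se_intervals), collapse = ", "), "s\n")
  invisible(x)
}

#' Run the full SE detection pipeline on a dual-channel trace
#'
#' Convenience wrapper: isosbestic subtraction, moving-window baseline
#' correction, z-scoring, peak detection and SE classification.
#'
#' @inheritParams subtract_background
#' @inheritParams correct_baseline
#' @inheritParams detect_peaks
#' @inheritParams classify_ses
#' @return an `se_set` (see [classify_ses()]) whose
#'   `attr(, "processing_log")` records every step.
#' @examples
#' sim <- simulate_photometry(photometry_sim_config(duration = 14400, seed = 3))
#' ses <- detect_ses(sim$trace)
#' nrow(ses)
#' @export
detect_ses <- function(trace, window = 900, min_prominence = 1.0,
                       fit_isosbestic = FALSE, min_spacing = 160,
                       height_fraction = 1 / 3) {
  corr <- subtract_background(trace, fit_isosbestic = fit_isosbestic)
  corr <- correct_baseline(corr, window = window)
  proc <- zscore(corr)
  peaks <- detect_peaks(proc, min_prominence = min_prominence)
  ses <- classify_ses(peaks, proc, min_spacing = min_spacing,
                      height_fraction = height_fraction)
  attr(ses, "processing_log") <- c(proc$processing_log,
    sprintf("detect_peaks: min_prominence=%g -> %d peaks", min_prominence,
            nrow(peaks)),
    sprintf("classify_ses: threshold=%.3g spacing>%gs -> %d SEs",
            attr(ses, "threshold"), min_spacing, nrow(ses)))
  ses
}

#' @export
print.se_set <- function(x, ...) {
  cat(sprintf("se_set: %d synchronization events (threshold %.3g z, spacing > %g s)\n",
              nrow(x), attr(x, "threshold"), attr(x, "min_spacing")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' @export
summary.se_set <- function(object, ...) {
  cat(sprintf("%d SEs over %.2f h\n", nrow(object),
              diff(attr(object, "time_range")) / 3600))
  if (nrow(object)) {
    cat(sprintf("  amplitude (z): mean %.2f, range [%.2f, %.2f]\n",
                mean(object$amplitude), min(object$amplitude),
                max(object$amplitude)))
    ok <- object$fwhm_defined
    if (any(ok))
      cat(sprintf("  FWHM (s): mean %.1f, range [%.1f, %.1f] (%d defined)\n",
                  mean(object$fwhm[ok]), min(object$fwhm[ok]),
                  max(object$fwhm[ok]), sum(ok)))
    if (nrow(object) > 1)
      cat(sprintf("  inter-SE interval (s): median %.0f\n",
                  median(diff(object$peak_time))))
  }
  invisible(object)
}

#' @export
plot.se_set <- function(x, trace = NULL, ...) {
  if (!is.null(trace) && inherits(trace, "processed_trace")) {
    plot(trace$time / 3600, trace$z, type = "l", col = "grey40",
         xlab = "time (h)", ylab = "z", ...)
    graphics::points(x$peak_time / 3600,
                     trace$z[vapply(x$peak_time, function(tp)
                       which.min(abs(trace$time - tp)), 1L)],
                     col = "red", pch = 19)
  } else {
    plot(x$peak_time / 3600, x$amplitude, xlab = "peak time (h)",
         ylab = "amplitude (z)", pch = 19, ...)
  }
  invisible(x)
}

#' F1 score for event-time recovery
#'
#' Greedy one-to-one matching of detected event times to ground-truth times
#' within `tol` seconds, and the resulting precision/recall/F1.
#'
#' @param detected,truth numeric vectors of event times, seconds.
#' @param tol matching tolerance, seconds.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
event_recovery <- function(detected, truth, tol = 20) {
  detected <- sort(detected); truth <- sort(truth)
  used <- logical(length(detected))
  tp <- 0L
  for (t0 in truth) {
    d <- abs(detected - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- sum(!used); fn <- length(truth) - tp
  precision <- if (tp + fp) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn) tp / (tp + fn) else NA_real_
  f1 <- if (is.finite(precision) && is.finite(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}
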