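#' Construct a membrane-voltage trace
#'
#' @param time sample times, seconds, increasing.
#' @param vmem membrane voltage, mV.
#' @param drug_windows named list of `c(start, end)` application windows,
#'   seconds, all inside the recording.
#' @param meta list with `neuron_id`, `animal_id`, `antagonist`.
#' @return an object of class `vm_trace`.
#' @export
new_vm_trace <- function(time, vmem, drug_windows = list(), meta = list()) {
  time <- as.numeric(time)
  if (any(diff(time) <= 0)) stop_input("time must be strictly increasing")
  if (length(vmem) != length(time))
    stop_input("vmem must have the same length as time")
  for (w in drug_windows) {
    if (length(w) != 2L || w[1] >= w[2])
      stop_input("drug windows must be c(start, end), start < end")
    if (w[1] < time[1] || w[2] > time[length(time)])
      stop_input("drug window lies outside the recording")
  }
  structure(list(time = time, vmem = as.numeric(vmem),
                 drug_windows = drug_windows, meta = meta),
            class = "vm_trace")
}

# 1-s running-median smoothing (resists brief artifacts)
smooth_vm <- function(trace, span = 1) {
  dt <- nominal_dt(trace$time)
  k <- max(3L, round(span / dt))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, length(trace$vmem) - (1 - length(trace$vmem) %% 2))
  runmed(trace$vmem, k)
}

#' Quantify the membrane-voltage response to a drug application
#'
#' The pre-drug voltage is the mean of the 1-s-median-smoothed trace over the
#' `pre_window` seconds before the application; the drug voltage is the
#' minimum of the smoothed trace from application start to `post_extension`
#' seconds past its end (responses can outlast a 1-min application).
#' Washout recovery is declared if the smoothed trace returns to within
#' `recovery_tol` mV of the pre-drug voltage at any point 7-17 min after the
#' application ends.
#'
#' @param trace a [new_vm_trace()].
#' @param window `c(start, end)` of the application, seconds; defaults to the
#'   trace's first drug window.
#' @param pre_window pre-application averaging window, seconds (default 60).
#' @param post_extension search extension past application end, seconds
#'   (default 120).
#' @param recovery_tol recovery tolerance, mV.
#' @param washout_range washout search range after application end, seconds.
#' @return class `voltage_response`: list with `v_pre`, `v_drug`,
#'   `delta_vmem`, `responder`, `washout_recovered`, `neuron_id`,
#'   `antagonist`.
#' @export
quantify_vmem_response <- function(trace, window = NULL, pre_window = 60,
                                   post_extension = 120, recovery_tol = 2,
                                   washout_range = c(420, 1020)) {
  stopifnot(inherits(trace, "vm_trace"))
  window <- window %||% trace$drug_windows[[1]]
  if (is.null(window)) stop_input("no drug window supplied")
  if (window[1] - pre_window < trace$time[1])
    stop_input("recording does not cover the pre-application window")
  sm <- smooth_vm(trace)
  tt <- trace$time
  pre_idx <- tt >= window[1] - pre_window & tt < window[1]
  if (!any(pre_idx)) stop_input("no samples in the pre-application window")
  v_pre <- mean(sm[pre_idx])
  drug_idx <- tt >= window[1] & tt <= window[2] + post_extension
  v_drug <- min(sm[drug_idx])
  delta <- v_drug - v_pre
  wash_idx <- tt >= window[2] + washout_range[1] &
    tt <= window[2] + washout_range[2]
  recovered <- any(abs(sm[wash_idx] - v_pre) < recovery_tol)
  structure(list(v_pre = v_pre, v_drug = v_drug, delta_vmem = delta,
                 responder = classify_responder(delta),
                 washout_recovered = recovered,
                 neuron_id = trace$meta$neuron_id %||% NA_character_,
                 antagonist = trace$meta$antagonist %||% "none"),
            class = "voltage_response")
}

#' @export
print.voltage_response <- function(x, ...) {
  cat(sprintf("voltage_response: v_pre %.1f mV, v_drug %.1f mV, delta %.2f mV -> %s\n",
              x$v_pre, x$v_drug, x$delta_vmem,
              if (x$responder) "responder" else "non-responder"))
  invisible(x)
}

#' Classify a membrane-voltage change as a response
#'
#' A neuron is a responder when its drug-evoked voltage change is a
#' hyperpolarization of at least 5 mV (threshold inclusive: exactly -5 mV
#' counts), the cut separating the two clusters of the bimodal response
#' distribution.
#'
#' @param delta_vmem voltage change(s), mV (drug minus pre).
#' @return logical, `TRUE` for responders.
#' @examples
#' classify_responder(c(-9.9, -0.17, -5))
#' @export
classify_responder <- function(delta_vmem) {
  if (!is.numeric(delta_vmem) || anyNA(delta_vmem) || any(!is.finite(delta_vmem)))
    stop_input("delta_vmem must be finite")
  delta_vmem <= -5.0
}

#' Summarize paired NA1/NA2 applications by antagonist group
#'
#' The second-application (NA2) mean amplitude of each antagonist group is
#' compared against the pooled first-application (NA1) amplitudes from all
#' groups; percent reduction is
#' `100 * (|mean NA1| - |mean NA2|) / |mean NA1|`.
#'
#' @param na2_by_group named list: per antagonist group, the NA2 `delta_vmem`
#'   values (mV).
#' @param pooled_na1 pooled NA1 `delta_vmem` values (mV) from all groups.
#' @return class `paired_summary`: data.frame with `group`, `n`,
#'   `mean_na2`, `percent_reduction`; attribute `mean_na1`.
#' @examples
#' paired_application_summary(list(alpha = c(-3.5)), pooled_na1 = c(-9.2))
#' @export
paired_application_summary <- function(na2_by_group, pooled_na1) {
  if (!length(pooled_na1)) stop_input("pooled NA1 group is empty")
  if (!is.list(na2_by_group) || is.null(names(na2_by_group)))
    stop_input("na2_by_group must be a named list")
  m1 <- mean(pooled_na1)
  rows <- lapply(names(na2_by_group), function(g) {
    v <- na2_by_group[[g]]
    if (!length(v)) stop_input("empty NA2 group '", g, "'")
    m2 <- mean(v)
    data.frame(group = g, n = length(v), mean_na2 = m2,
               percent_reduction = 100 * (abs(m1) - abs(m2)) / abs(m1))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "mean_na1") <- m1
  class(res) <- c("paired_summary", "data.frame")
  res
}

#' Firing-rate change across a drug application
#'
#' The pre-application rate is the spike count in the `pre_window` seconds
#' before the application divided by the window length; the post rate uses
#' the window `post_offset` seconds after application start (default 0.5-1.5
#' min, per the cell-attached protocol).
#'
#' @param train a `spike_train` (list with `spike_times`,
#'   `application_windows`, `duration`) or numeric spike times (then
#'   `application_start` is required).
#' @param application_start application onset, seconds; defaults to the
#'   train's first window.
#' @param pre_window pre-application window length, seconds (default 60).
#' @param post_offset `c(start, end)` offsets of the post window from
#'   application start, seconds (default `c(30, 90)`).
#' @return class `firing_rate_response`: list with `rate_pre`, `rate_post`,
#'   `percent_reduction` (NA-flagged when `rate_pre` is 0, with
#'   `reduction_defined = FALSE`).
#' @examples
#' tr <- list(spike_times = c(seq(0.5, 59.5, 2), 95, 110),
#'            application_windows = list(c(60, 120)), duration = 180)
#' firing_rate_change(tr)
#' @export
firing_rate_change <- function(train, application_start = NULL,
                               pre_window = 60, post_offset = c(30, 90)) {
  if (is.numeric(train)) train <- list(spike_times = train,
                                       application_windows = list())
  st <- train$spike_times
  application_start <- application_start %||%
    (if (length(train$application_windows)) train$application_windows[[1]][1]
     else stop_input("application_start required"))
  if (application_start - pre_window < 0)
    stop_input("pre-application window extends before the recording")
  n_pre <- sum(st >= application_start - pre_window & st < application_start)
  rate_pre <- n_pre / pre_window
  p0 <- application_start + post_offset[1]
  p1 <- application_start + post_offset[2]
  n_post <- sum(st >= p0 & st < p1)
  rate_post <- n_post / (p1 - p0)
  defined <- rate_pre > 0
  structure(list(rate_pre = rate_pre, rate_post = rate_post,
                 percent_reduction = if (defined)
                   percent_reduction(rate_pre, rate_post) else NA_real_,
                 reduction_defined = defined),
            class = "firing_rate_response")
}

#' @export
print.firing_rate_response <- function(x, ...) {
  cat(sprintf("firing_rate_response: %.2f Hz -> %.2f Hz", x$rate_pre,
              x$rate_post))
  if (x$reduction_defined)
    cat(sprintf(" (%.0f%% reduction)", x$percent_reduction))
  cat("\n")
  invisible(x)
}
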