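#' Configuration for the whole-cell patch simulator
#'
#' Emulates membrane-voltage recordings of arcuate kisspeptin neurons during
#' 1-min bath applications of noradrenaline: a bimodal population in which a
#' `responder_fraction` subset shows a smooth transient hyperpolarization
#' (amplitude drawn from `response_amplitude`, scaled by the antagonist
#' condition) with recovery after a variable washout lag, while the rest show
#' noise only.
#'
#' @param n_neurons number of simulated neurons.
#' @param responder_fraction probability a neuron is a responder (default
#'   0.40).
#' @param response_amplitude [dist_spec] of hyperpolarization amplitudes, mV
#'   (negative; default mean -9.9).
#' @param response_threshold_margin responders are truncated to amplitudes at
#'   least this far beyond the -5 mV classification threshold (default 1 mV).
#' @param antagonist one of `"none"`, `"alpha"`, `"beta"`, `"both"`; selects
#'   the amplitude scale from `antagonist_scale`.
#' @param antagonist_scale named multipliers of the response amplitude under
#'   each antagonist (defaults: none 1, alpha 0.38, beta 0.33, both 0.02).
#' @param membrane_noise_sd membrane noise SD, mV.
#' @param baseline_vmem resting membrane voltage, mV (about -50).
#' @param washout_lag_range post-washout recovery lag range, seconds
#'   (default 7-17 min).
#' @param drug_window `c(start, end)` of the application, seconds.
#' @param duration,sample_rate recording length (s) and rate (Hz).
#' @param seed integer master seed.
#' @return an object of class `patch_sim_config`.
#' @export
patch_sim_config <- function(n_neurons = 20, responder_fraction = 0.40,
                             response_amplitude = dist_spec("normal",
                               mean = -9.9, sd = 2.5, max = -6),
                             response_threshold_margin = 1,
                             antagonist = c("none", "alpha", "beta", "both"),
                             antagonist_scale = c(none = 1, alpha = 0.38,
                                                  beta = 0.33, both = 0.02),
                             membrane_noise_sd = 0.5,
                             baseline_vmem = -50,
                             washout_lag_range = c(420, 1020),
                             drug_window = c(300, 360),
                             duration = 1800, sample_rate = 20,
                             seed = 1L) {
  antagonist <- match.arg(antagonist)
  if (any(antagonist_scale < 0) || any(antagonist_scale > 1))
    stop_input("antagonist_scale values must lie in [0, 1]")
  cfg <- list(
    n_neurons = as.integer(check_number(n_neurons, "n_neurons", min = 1)),
    responder_fraction = check_number(responder_fraction,
                                      "responder_fraction", min = 0, max = 1),
    response_amplitude = as_dist_spec(response_amplitude,
                                      "response_amplitude"),
    response_threshold_margin = check_number(response_threshold_margin,
                                             "response_threshold_margin",
                                             min = 0),
    antagonist = antagonist,
    antagonist_scale = antagonist_scale,
    membrane_noise_sd = check_number(membrane_noise_sd, "membrane_noise_sd",
                                     min = 0),
    baseline_vmem = check_number(baseline_vmem, "baseline_vmem"),
    washout_lag_range = washout_lag_range,
    drug_window = drug_window,
    duration = check_number(duration, "duration", min = 1),
    sample_rate = check_number(sample_rate, "sample_rate", min = 1e-9),
    seed = as.integer(seed))
  if (length(cfg$drug_window) != 2L || cfg$drug_window[1] >= cfg$drug_window[2] ||
      cfg$drug_window[2] > cfg$duration)
    stop_input("drug_window must be c(start, end) inside the recording")
  class(cfg) <- "patch_sim_config"
  cfg
}

# smooth 0->1->0 response envelope: smoothstep onset over `rise` seconds
# after drug onset, exact unit plateau, smoothstep recovery over `recover`
# seconds starting washout_lag after the application ends
response_envelope <- function(time, window, washout_lag,
                              rise = 30, recover = 60) {
  smoothstep <- function(s) { s <- pmin(pmax(s, 0), 1); s * s * (3 - 2 * s) }
  on <- smoothstep((time - window[1]) / rise)
  off <- smoothstep((time - (window[2] + washout_lag)) / recover)
  pmax(on - off, 0)
}

#' Simulate a cohort of whole-cell recordings
#'
#' @param config a [patch_sim_config()].
#' @return list with `traces` (list of class-`vm_trace` objects) and `truth`
#'   (`ground_truth` with `responder_flags`, `true_delta_vmem`,
#'   `washout_lags`).
#' @examples
#' sim <- simulate_patch(patch_sim_config(n_neurons = 5, seed = 7))
#' sim$truth$responder_flags
#' @export
simulate_patch <- function(config) {
  if (!inherits(config, "patch_sim_config"))
    config <- do.call(patch_sim_config, config)
  cfg <- config
  dt <- 1 / cfg$sample_rate
  time <- seq(0, cfg$duration - dt / 2, by = dt)
  scale <- cfg$antagonist_scale[[cfg$antagonist]]

  flags <- with_component_seed(cfg$seed, "responders",
    rbinom(cfg$n_neurons, 1, cfg$responder_fraction) == 1)
  amp_spec <- cfg$response_amplitude
  if (amp_spec$dist != "constant")  # constant amplitudes are taken literally
    amp_spec$max <- min(amp_spec$max %||% Inf,
                        -(5 + cfg$response_threshold_margin))
  amps <- with_component_seed(cfg$seed, "amplitudes",
    draw_spec(amp_spec, cfg$n_neurons))
  amps[!flags] <- 0
  true_delta <- amps * scale
  lags <- with_component_seed(cfg$seed, "washout",
    runif(cfg$n_neurons, cfg$washout_lag_range[1], cfg$washout_lag_range[2]))

  traces <- vector("list", cfg$n_neurons)
  for (i in seq_len(cfg$n_neurons)) {
    env <- if (flags[i])
      response_envelope(time, cfg$drug_window, lags[i]) else 0
    noise <- with_component_seed(cfg$seed, paste0("vm_noise_", i),
                                 rnorm(length(time), 0, cfg$membrane_noise_sd))
    vm <- cfg$baseline_vmem + true_delta[i] * env + noise
    traces[[i]] <- new_vm_trace(time, vm,
      drug_windows = list(NA1 = cfg$drug_window),
      meta = list(neuron_id = sprintf("n%02d", i), animal_id = "sim",
                  antagonist = cfg$antagonist))
  }
  truth <- structure(list(responder_flags = flags,
                          true_delta_vmem = true_delta,
                          washout_lags = lags),
                     class = "ground_truth")
  list(traces = traces, truth = truth)
}

#' Configuration for the cell-attached spike-train simulator
#'
#' Poisson spiking at `baseline_rate` with the rate multiplied by
#' `cno_rate_factor` inside each CNO application window.
#'
#' @param baseline_rate tonic firing rate, Hz (default 1.48).
#' @param cno_rate_factor rate multiplier during CNO (default 0.142, i.e.
#'   1.48 Hz down to 0.21 Hz).
#' @param cno_application_windows list of `c(start, end)` seconds;
#'   non-overlapping.
#' @param duration recording length, seconds.
#' @param seed integer master seed.
#' @return an object of class `spike_sim_config`.
#' @export
spike_sim_config <- function(baseline_rate = 1.48, cno_rate_factor = 0.142,
                             cno_application_windows = list(c(300, 420)),
                             duration = 900, seed = 1L) {
  cfg <- list(
    baseline_rate = check_number(baseline_rate, "baseline_rate", min = 0),
    cno_rate_factor = check_number(cno_rate_factor, "cno_rate_factor", min = 0),
    cno_application_windows = cno_application_windows,
    duration = check_number(duration, "duration", min = 1),
    seed = as.integer(seed))
  win <- cfg$cno_application_windows
  if (length(win)) {
    m <- do.call(rbind, win)
    if (ncol(m) != 2L || any(m[, 1] >= m[, 2]))
      stop_input("each window must be c(start, end) with start < end")
    o <- order(m[, 1])
    if (any(m[o, 1][-1] < m[o, 2][-nrow(m)]))
      stop_input("CNO application windows overlap")
    if (any(m < 0) || any(m > cfg$duration))
      stop_input("windows lie outside the recording")
  }
  class(cfg) <- "spike_sim_config"
  cfg
}

#' Simulate a cell-attached spike train
#'
#' @param config a [spike_sim_config()].
#' @return list with `train` (class `spike_train`: `spike_times`,
#'   `application_windows`, `duration`) and `truth` (`ground_truth` with
#'   per-segment `true_rates`).
#' @export
simulate_spiketrain <- function(config) {
  if (!inherits(config, "spike_sim_config"))
    config <- do.call(spike_sim_config, config)
  cfg <- config
  wins <- cfg$cno_application_windows
  # segment [0, duration] by the application windows
  bounds <- sort(unique(c(0, unlist(wins), cfg$duration)))
  in_win <- function(t) any(vapply(wins, function(w) t >= w[1] && t < w[2],
                                   TRUE))
  spikes <- with_component_seed(cfg$seed, "spikes", {
    out <- numeric(0)
    for (i in seq_len(length(bounds) - 1L)) {
      s <- bounds[i]; e <- bounds[i + 1L]
      rate <- cfg$baseline_rate *
        (if (length(wins) && in_win((s + e) / 2)) cfg$cno_rate_factor else 1)
      k <- rpois(1, rate * (e - s))
      if (k > 0) out <- c(out, sort(runif(k, s, e)))
    }
    sort(out)
  })
  seg_rates <- vapply(seq_len(length(bounds) - 1L), function(i) {
    cfg$baseline_rate * (if (length(wins) && in_win((bounds[i] + bounds[i + 1]) / 2))
      cfg$cno_rate_factor else 1)
  }, 0)
  train <- structure(list(spike_times = spikes,
                          application_windows = wins,
                          duration = cfg$duration),
                     class = "spike_train")
  truth <- structure(list(segment_bounds = bounds, true_rates = seg_rates),
                     class = "ground_truth")
  list(train = train, truth = truth)
}
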