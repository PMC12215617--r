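#' Configuration for the in-vivo photometry simulator
#'
#' Describes a scheduled-mode dual-channel fiber-photometry recording of the
#' arcuate kisspeptin population: acquisition at `sample_rate` Hz in a
#' `duty_on`-s-on / `duty_off`-s-off duty cycle, population synchronization
#' events (SEs) drawn from a gamma renewal process and convolved with a
#' GCaMP6s-like difference-of-exponentials kernel, slow baseline drift
#' (bleaching exponential plus low-frequency wander), a shared motion artifact
#' coupled into both channels, and optional post-injection suppression of the
#' SE hazard.
#'
#' @param duration recording length, seconds (default 24 h).
#' @param sample_rate acquisition rate while on-duty, Hz.
#' @param duty_on,duty_off scheduled acquisition cycle, seconds.
#' @param se_interval_model [dist_spec] for inter-SE intervals (gamma renewal
#'   by default: mean 4320 s, shape 4, about 20 SEs/24 h).  `NULL` disables SE
#'   generation entirely.
#' @param se_amplitude [dist_spec] for SE amplitudes, in units of the channel
#'   noise SD.
#' @param kernel_rise,kernel_decay transient kernel time constants, seconds;
#'   `kernel_rise` must be smaller than `kernel_decay`.
#' @param drift_model list with `bleach_amp`, `bleach_tau` (seconds),
#'   `wander_amp` and `wander_periods` (seconds) for slow additive baseline.
#' @param noise_sd white measurement noise SD per channel, signal units.
#' @param isosbestic_artifact_gain coupling of the shared artifact into both
#'   channels (0 removes it).
#' @param injection_time time of a (simulated) injection, seconds, or `NULL`.
#' @param suppression_duration,suppression_factor for `suppression_duration`
#'   seconds after `injection_time` the SE hazard is multiplied by
#'   `suppression_factor` (0 = complete suppression, 1 = none).
#' @param ovx_mode logical; ovariectomized-like regime with clustered,
#'   high-frequency, high-amplitude SEs (two-state modulated renewal).
#' @param seed integer master seed; identical seed + config gives
#'   bit-identical output.
#' @return an object of class `photometry_sim_config`.
#' @seealso [simulate_photometry()]
#' @export
photometry_sim_config <- function(duration = 86400,
                                  sample_rate = 10,
                                  duty_on = 5,
                                  duty_off = 10,
                                  se_interval_model = dist_spec("gamma",
                                    mean = 4320, shape = 4),
                                  se_amplitude = dist_spec("normal",
                                    mean = 25, sd = 3, min = 15),
                                  kernel_rise = 1.5,
                                  kernel_decay = 25,
                                  drift_model = list(bleach_amp = 3,
                                    bleach_tau = 20000, wander_amp = 0.5,
                                    wander_periods = c(3600, 7200, 14400)),
                                  noise_sd = 1,
                                  isosbestic_artifact_gain = 1,
                                  injection_time = NULL,
                                  suppression_duration = 0,
                                  suppression_factor = 1,
                                  ovx_mode = FALSE,
                                  seed = 1L) {
  cfg <- list(
    duration = check_number(duration, "duration", min = 1e-9),
    sample_rate = check_number(sample_rate, "sample_rate", min = 1e-9),
    duty_on = check_number(duty_on, "duty_on", min = 1e-9),
    duty_off = check_number(duty_off, "duty_off", min = 0),
    se_interval_model = if (is.null(se_interval_model)) NULL else
      as_dist_spec(se_interval_model, "se_interval_model"),
    se_amplitude = as_dist_spec(se_amplitude, "se_amplitude"),
    kernel_rise = check_number(kernel_rise, "kernel_rise", min = 1e-9),
    kernel_decay = check_number(kernel_decay, "kernel_decay", min = 1e-9),
    drift_model = drift_model,
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    isosbestic_artifact_gain = check_number(isosbestic_artifact_gain,
                                            "isosbestic_artifact_gain"),
    injection_time = if (is.null(injection_time)) NULL else
      check_number(injection_time, "injection_time", min = 0),
    suppression_duration = check_number(suppression_duration,
                                        "suppression_duration", min = 0),
    suppression_factor = check_number(suppression_factor,
                                      "suppression_factor", min = 0, max = 1),
    ovx_mode = isTRUE(ovx_mode),
    seed = as.integer(seed))
  if (cfg$kernel_rise >= cfg$kernel_decay)
    stop_input("kernel_rise must be < kernel_decay")
  class(cfg) <- "photometry_sim_config"
  cfg
}

# piecewise-constant hazard multiplier as (breaks, rate-on-[break_i,break_{i+1}))
hazard_profile <- function(cfg) {
  breaks <- c(0, cfg$duration)
  if (cfg$ovx_mode) {
    # two-state modulated renewal: clustered high-hazard periods alternating
    # with near-quiescent ones
    segs <- with_component_seed(cfg$seed, "ovx_states", {
      t <- 0; out <- list(); state <- TRUE
      while (t < cfg$duration) {
        d <- if (state) rgamma(1, 2, scale = 900) else rgamma(1, 2, scale = 2700)
        out[[length(out) + 1L]] <- c(t, min(t + d, cfg$duration),
                                     if (state) 6 else 0.15)
        t <- t + d; state <- !state
      }
      out
    })
    breaks <- sort(unique(c(breaks, vapply(segs, `[`, 0, 1),
                            vapply(segs, `[`, 0, 2))))
    mult_of <- function(t) {
      for (s in segs) if (t >= s[1] && t < s[2]) return(s[3])
      1
    }
  } else {
    segs <- NULL
    mult_of <- function(t) 1
  }
  if (!is.null(cfg$injection_time) && cfg$suppression_duration > 0) {
    t0 <- cfg$injection_time
    t1 <- min(t0 + cfg$suppression_duration, cfg$duration)
    breaks <- sort(unique(c(breaks, t0, t1)))
    base_mult <- mult_of
    mult_of <- function(t) {
      m <- base_mult(t)
      if (t >= t0 && t < t1) m * cfg$suppression_factor else m
    }
  }
  breaks <- breaks[breaks <= cfg$duration]
  mids <- head(breaks, -1)
  rates <- vapply(mids, mult_of, 0)
  list(breaks = breaks, rates = rates)
}

# draw renewal event times under a piecewise-constant hazard multiplier by
# running the renewal process in operational time and warping back
draw_renewal_times <- function(spec, profile, duration) {
  breaks <- profile$breaks
  rates <- profile$rates
  seglen <- diff(breaks)
  cum_op <- c(0, cumsum(seglen * rates))
  total_op <- cum_op[length(cum_op)]
  op_to_wall <- function(s) {
    i <- findInterval(s, cum_op, rightmost.closed = TRUE)
    i <- min(i, length(rates))
    while (i <= length(rates) && rates[i] == 0) i <- i + 1L
    if (i > length(rates)) return(Inf)
    breaks[i] + (s - cum_op[i]) / rates[i]
  }
  times <- numeric(0)
  s <- 0
  repeat {
    s <- s + draw_spec(spec, 1L)
    if (s >= total_op) break
    t <- op_to_wall(s)
    if (t >= duration) break
    times <- c(times, t)
    if (length(times) > 1e6) stop_input("renewal simulation runaway")
  }
  times
}

#' Simulate a dual-channel photometry recording
#'
#' Generates the calcium-dependent (465-490 nm) and isosbestic (405 nm)
#' channels on the scheduled-acquisition grid.  SE transients appear only in
#' the calcium channel; bleaching/drift and the shared artifact appear in both
#' (the artifact scaled by `isosbestic_artifact_gain` in each), so isosbestic
#' subtraction can remove it.
#'
#' @param config a [photometry_sim_config()].
#' @return a list with elements `trace` (class `dual_channel_trace`: `time`,
#'   `f465`, `f405`, `mask`, `meta`) and `truth` (class `ground_truth`:
#'   `se_times` — planted kernel-peak times — and `se_amplitudes`).
#' @examples
#' sim <- simulate_photometry(photometry_sim_config(duration = 7200, seed = 2))
#' length(sim$truth$se_times)
#' @export
simulate_photometry <- function(config) {
  if (!inherits(config, "photometry_sim_config"))
    config <- do.call(photometry_sim_config, config)
  cfg <- config
  dt <- 1 / cfg$sample_rate
  cycle <- cfg$duty_on + cfg$duty_off
  n_on <- max(1L, round(cfg$duty_on * cfg$sample_rate))
  starts <- seq(0, cfg$duration, by = cycle)
  time <- as.vector(vapply(starts, function(s) s + (0:(n_on - 1L)) * dt,
                           numeric(n_on)))
  time <- time[time < cfg$duration]
  n <- length(time)

  # planted SEs
  if (is.null(cfg$se_interval_model)) {
    se_times <- numeric(0)
  } else {
    prof <- hazard_profile(cfg)
    se_times <- with_component_seed(cfg$seed, "se_times",
      draw_renewal_times(cfg$se_interval_model, prof, cfg$duration))
  }
  se_amps <- with_component_seed(cfg$seed, "se_amplitudes",
    draw_spec(cfg$se_amplitude, length(se_times)))
  if (cfg$ovx_mode && length(se_times))
    se_amps <- se_amps * 1.5   # clustered SEs are also high-amplitude

  # SE signal on a dense regular grid, then sampled at the duty-cycle times
  # (a transient can rise or peak during an off-duty gap)
  kernel <- calcium_kernel(dt, cfg$kernel_rise, cfg$kernel_decay)
  dense_n <- ceiling(cfg$duration / dt) + 1L
  dense_sig <- add_transients(dense_n, 0, dt, se_times,
                              se_amps * cfg$noise_sd, kernel)
  se_signal <- dense_sig[pmin(dense_n, round(time / dt) + 1L)]

  # drift: bleaching exponential + slow sinusoidal wander
  dm <- cfg$drift_model
  drift_bleach <- (dm$bleach_amp %||% 0) * exp(-time / (dm$bleach_tau %||% 1e4))
  wander <- numeric(n)
  periods <- dm$wander_periods %||% numeric(0)
  if (length(periods) && (dm$wander_amp %||% 0) > 0) {
    phases <- with_component_seed(cfg$seed, "drift_phases",
                                  runif(length(periods), 0, 2 * pi))
    for (j in seq_along(periods))
      wander <- wander + (dm$wander_amp / length(periods)) *
        sin(2 * pi * time / periods[j] + phases[j])
  }

  # shared motion artifact: smoothed unit-variance noise, coupled into both
  artifact <- with_component_seed(cfg$seed, "artifact", {
    raw <- rnorm(n)
    k <- min(n - (1 - n %% 2), max(3L, round(2 * cfg$sample_rate) * 2L + 1L))
    sm <- runmed(raw, k)
    s <- sd(sm)
    if (s > 0) sm / s else sm
  })

  noise465 <- with_component_seed(cfg$seed, "noise465", rnorm(n, 0, cfg$noise_sd))
  noise405 <- with_component_seed(cfg$seed, "noise405", rnorm(n, 0, cfg$noise_sd))

  g <- cfg$isosbestic_artifact_gain
  f465 <- 10 + drift_bleach + wander + se_signal + g * artifact + noise465
  f405 <- 4 + 0.5 * drift_bleach + g * artifact + noise405

  trace <- new_dual_channel_trace(time, f465, f405,
    mask = rep(1L, n),
    meta = list(animal_id = "sim", treatment = if (cfg$ovx_mode) "ovx" else
      "diestrus", injection_time = cfg$injection_time,
      recording_length = cfg$duration, sample_rate = cfg$sample_rate,
      artifact = artifact * g, config_seed = cfg$seed))
  truth <- structure(list(se_times = se_times, se_amplitudes = se_amps),
                     class = "ground_truth")
  list(trace = trace, truth = truth)
}
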