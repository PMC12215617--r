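#' Configuration for the brain-slice network simulator
#'
#' Emulates multi-ROI GCaMP6s recordings of a slice containing 8-23 arcuate
#' kisspeptin neurons imaged at 2 Hz: each cell fires independent Poisson
#' calcium events, a latent network process recruits each cell with
#' probability `sync_fraction` (producing miniature synchronization events),
#' and a drug epoch multiplies all rates by `drug_rate_factor`.
#'
#' @param n_cells number of neurons in the focal plane (default 11).
#' @param duration recording length, seconds.
#' @param sample_rate imaging rate, Hz (default 2).
#' @param cell_event_rate total per-cell event rate, events/cell/h (default
#'   22.9); includes both independent and network-recruited events.
#' @param network_event_rate latent network-event rate, events/h.
#' @param sync_fraction probability that a latent network event recruits each
#'   cell.
#' @param drug_epoch `c(start, end)` seconds, or `NULL`.
#' @param drug_rate_factor multiplier applied to all event rates inside
#'   `drug_epoch`.
#' @param dff_event_amplitude [dist_spec] of event peak amplitudes, dF/F
#'   units (default centred on 0.20).
#' @param noise_sd imaging noise SD, dF/F-equivalent units.
#' @param background_level background ROI fluorescence, arbitrary units.
#' @param f0 resting cell fluorescence above background, arbitrary units.
#' @param kernel_rise,kernel_decay event kernel time constants, seconds.
#' @param seed integer master seed.
#' @return an object of class `slice_sim_config`.
#' @export
slice_sim_config <- function(n_cells = 11, duration = 7200, sample_rate = 2,
                             cell_event_rate = 22.9, network_event_rate = 6,
                             sync_fraction = 0.5, drug_epoch = NULL,
                             drug_rate_factor = 1,
                             dff_event_amplitude = dist_spec("normal",
                               mean = 0.20, sd = 0.02, min = 0.1),
                             noise_sd = 0.003, background_level = 100,
                             f0 = 1000, kernel_rise = 0.5, kernel_decay = 4,
                             seed = 1L) {
  cfg <- list(
    n_cells = as.integer(check_number(n_cells, "n_cells", min = 2)),
    duration = check_number(duration, "duration", min = 1),
    sample_rate = check_number(sample_rate, "sample_rate", min = 1e-9),
    cell_event_rate = check_number(cell_event_rate, "cell_event_rate", min = 0),
    network_event_rate = check_number(network_event_rate,
                                      "network_event_rate", min = 0),
    sync_fraction = check_number(sync_fraction, "sync_fraction",
                                 min = 0, max = 1),
    drug_epoch = drug_epoch,
    drug_rate_factor = check_number(drug_rate_factor, "drug_rate_factor",
                                    min = 0),
    dff_event_amplitude = as_dist_spec(dff_event_amplitude,
                                       "dff_event_amplitude"),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    background_level = check_number(background_level, "background_level"),
    f0 = check_number(f0, "f0", min = 1e-9),
    kernel_rise = check_number(kernel_rise, "kernel_rise", min = 1e-9),
    kernel_decay = check_number(kernel_decay, "kernel_decay", min = 1e-9),
    seed = as.integer(seed))
  if (!is.null(cfg$drug_epoch)) {
    if (length(cfg$drug_epoch) != 2L || cfg$drug_epoch[1] >= cfg$drug_epoch[2])
      stop_input("drug_epoch must be c(start, end) with start < end")
    if (cfg$drug_epoch[1] < 0 || cfg$drug_epoch[2] > cfg$duration)
      stop_input("drug_epoch lies outside the recording")
  }
  indep <- cfg$cell_event_rate - cfg$network_event_rate * cfg$sync_fraction
  if (indep < 0)
    stop_input("network_event_rate * sync_fraction exceeds cell_event_rate")
  cfg$indep_rate <- indep
  class(cfg) <- "slice_sim_config"
  cfg
}

# piecewise-homogeneous Poisson times on [0, duration] with the rate
# multiplied by `factor` inside `epoch`
piecewise_poisson <- function(rate_per_s, duration, epoch, factor) {
  segs <- if (is.null(epoch)) list(c(0, duration, 1)) else list(
    c(0, epoch[1], 1), c(epoch[1], epoch[2], factor), c(epoch[2], duration, 1))
  out <- numeric(0)
  for (s in segs) {
    len <- s[2] - s[1]
    if (len <= 0) next
    k <- rpois(1, rate_per_s * s[3] * len)
    if (k > 0) out <- c(out, sort(runif(k, s[1], s[2])))
  }
  sort(out)
}

#' Simulate a slice network recording
#'
#' @param config a [slice_sim_config()].
#' @return list with `roi_set` (class `roi_trace_set`) and `truth` (class
#'   `ground_truth` with `per_cell_event_times`, `per_cell_amplitudes` and
#'   `mse_memberships`, the latent groups that recruited at least two cells).
#' @examples
#' sim <- simulate_slice_network(slice_sim_config(duration = 1800, seed = 4))
#' names(sim$truth$per_cell_event_times)
#' @export
simulate_slice_network <- function(config) {
  if (!inherits(config, "slice_sim_config"))
    config <- do.call(slice_sim_config, config)
  cfg <- config
  dt <- 1 / cfg$sample_rate
  time <- seq(0, cfg$duration - dt / 2, by = dt)
  n <- length(time)
  cell_ids <- sprintf("cell_%03d", seq_len(cfg$n_cells))

  per_s <- function(per_h) per_h / 3600

  net_times <- with_component_seed(cfg$seed, "network_events",
    piecewise_poisson(per_s(cfg$network_event_rate), cfg$duration,
                      cfg$drug_epoch, cfg$drug_rate_factor))
  recruit <- with_component_seed(cfg$seed, "recruitment", {
    if (length(net_times))
      matrix(runif(length(net_times) * cfg$n_cells) < cfg$sync_fraction,
             nrow = length(net_times))
    else matrix(FALSE, 0, cfg$n_cells)
  })
  # small per-cell jitter of recruited event peaks within the <10 s window
  jitter_sd <- 1.5
  event_times <- vector("list", cfg$n_cells)
  names(event_times) <- cell_ids
  for (ci in seq_len(cfg$n_cells)) {
    indep <- with_component_seed(cfg$seed, paste0("indep_", ci),
      piecewise_poisson(per_s(cfg$indep_rate), cfg$duration,
                        cfg$drug_epoch, cfg$drug_rate_factor))
    rec <- net_times[recruit[, ci]]
    if (length(rec)) {
      jit <- with_component_seed(cfg$seed, paste0("jitter_", ci),
                                 rnorm(length(rec), 0, jitter_sd))
      parent <- rec
      rec <- pmin(pmax(rec + jit, 0), cfg$duration - dt)
      if (!is.null(cfg$drug_epoch)) {
        # jitter must not move an event across an epoch boundary (the epoch
        # rate factor applies exactly to the planted times)
        ep <- cfg$drug_epoch
        rec <- ifelse(parent < ep[1], pmin(rec, ep[1] - 1e-9),
               ifelse(parent >= ep[2], pmax(rec, ep[2]),
                      pmin(pmax(rec, ep[1]), ep[2] - 1e-9)))
      }
    }
    event_times[[ci]] <- sort(c(indep, rec))
  }
  mse_memberships <- lapply(which(rowSums(recruit) >= 2), function(k) {
    list(time = net_times[k], cells = cell_ids[recruit[k, ]])
  })

  kernel <- calcium_kernel(dt, cfg$kernel_rise, cfg$kernel_decay)
  cells <- vector("list", cfg$n_cells)
  names(cells) <- cell_ids
  amps_all <- vector("list", cfg$n_cells)
  for (ci in seq_len(cfg$n_cells)) {
    amps <- with_component_seed(cfg$seed, paste0("amps_", ci),
      draw_spec(cfg$dff_event_amplitude, length(event_times[[ci]])))
    amps_all[[ci]] <- amps
    dff <- add_transients(n, 0, dt, event_times[[ci]], amps, kernel)
    noise <- with_component_seed(cfg$seed, paste0("noise_", ci),
                                 rnorm(n, 0, cfg$noise_sd))
    cells[[ci]] <- cfg$background_level + cfg$f0 * (1 + dff + noise)
  }
  bg_noise <- with_component_seed(cfg$seed, "bg_noise",
                                  rnorm(n, 0, cfg$noise_sd * cfg$f0 * 0.1))
  background <- cfg$background_level + bg_noise

  roi_set <- new_roi_trace_set(time, cells, background,
    meta = list(slice_id = "sim", animal_id = "sim",
                drug_epochs = if (is.null(cfg$drug_epoch)) list() else
                  list(drug = cfg$drug_epoch),
                config_seed = cfg$seed))
  names(amps_all) <- cell_ids
  truth <- structure(list(per_cell_event_times = event_times,
                          per_cell_amplitudes = amps_all,
                          network_event_times = net_times,
                          mse_memberships = mse_memberships),
                     class = "ground_truth")
  list(roi_set = roi_set, truth = truth)
}
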