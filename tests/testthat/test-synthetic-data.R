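test_that("all simulators are bit-identical under a fixed seed", {
  p1 <- simulate_photometry(photometry_sim_config(duration = 3600, seed = 11))
  p2 <- simulate_photometry(photometry_sim_config(duration = 3600, seed = 11))
  expect_identical(p1$trace$f465, p2$trace$f465)
  expect_identical(p1$truth$se_times, p2$truth$se_times)

  s1 <- simulate_slice_network(slice_sim_config(duration = 900, seed = 11))
  s2 <- simulate_slice_network(slice_sim_config(duration = 900, seed = 11))
  expect_identical(s1$roi_set$cells, s2$roi_set$cells)

  v1 <- simulate_patch(patch_sim_config(n_neurons = 4, seed = 11))
  v2 <- simulate_patch(patch_sim_config(n_neurons = 4, seed = 11))
  expect_identical(v1$traces[[3]]$vmem, v2$traces[[3]]$vmem)

  k1 <- simulate_spiketrain(spike_sim_config(seed = 11))
  k2 <- simulate_spiketrain(spike_sim_config(seed = 11))
  expect_identical(k1$train$spike_times, k2$train$spike_times)
})

test_that("disabling the SE renewal process yields drift + noise only", {
  sim <- simulate_photometry(photometry_sim_config(
    duration = 3600, se_interval_model = NULL, seed = 5))
  expect_length(sim$truth$se_times, 0)
  # after isosbestic subtraction and baseline correction the signal is pure
  # noise: nothing approaches the default SE amplitude scale (~25 noise SDs)
  corr <- correct_baseline(subtract_background(sim$trace))
  expect_lt(max(abs(corr$signal)), 12)
})

test_that("complete hazard suppression plants no SE inside the window", {
  for (s in 1:5) {
    sim <- simulate_photometry(photometry_sim_config(
      duration = 43200, injection_time = 10800, suppression_duration = 10800,
      suppression_factor = 0, seed = s))
    inside <- sim$truth$se_times > 10800 & sim$truth$se_times < 21600
    expect_false(any(inside))
  }
})

test_that("acquisition grid matches the 5 s on / 10 s off duty cycle", {
  cfg <- photometry_sim_config(duration = 600, seed = 1)
  sim <- simulate_photometry(cfg)
  gaps <- diff(sim$trace$time)
  dt <- 1 / cfg$sample_rate
  boundary <- gaps > dt * 1.5
  expect_true(all(abs(gaps[!boundary] - dt) < 1e-9))
  # off-duty gap: duty_off seconds between the end of one on-period and the
  # start of the next, measured sample-to-sample as duty_off + dt
  expect_true(all(abs(gaps[boundary] - dt - cfg$duty_off) < 1e-9))
  expect_true(all(sim$trace$mask == 1L))
})

test_that("isosbestic channel carries no SE kernel energy", {
  cfg <- photometry_sim_config(duration = 14400, isosbestic_artifact_gain = 0,
                               seed = 7)
  sim <- simulate_photometry(cfg)
  # reconstruct the planted kernel train on the acquisition grid
  tt <- sim$trace$time
  train <- numeric(length(tt))
  for (t0 in sim$truth$se_times) {
    d <- tt - t0
    train <- train + ifelse(d >= 0, exp(-d / cfg$kernel_decay) -
                              exp(-d / cfg$kernel_rise), 0)
  }
  expect_lt(abs(cor(sim$trace$f405, train)), 0.05)
  expect_gt(cor(sim$trace$f465, train), 0.5)
})

test_that("slice simulator respects independence and epoch rate scaling", {
  # sync_fraction = 0: no latent group ever recruits >= 2 cells
  sim <- simulate_slice_network(slice_sim_config(
    duration = 3600, sync_fraction = 0, seed = 3))
  expect_length(sim$truth$mse_memberships, 0)

  # drug_rate_factor = 0: no planted event inside the epoch
  for (s in 1:5) {
    sim <- simulate_slice_network(slice_sim_config(
      duration = 2400, drug_epoch = c(800, 1600), drug_rate_factor = 0,
      seed = s))
    all_t <- unlist(sim$truth$per_cell_event_times)
    expect_false(any(all_t >= 800 & all_t < 1600))
  }
})

test_that("planted slice event rate matches the configured 22.9 events/cell/h", {
  sim <- simulate_slice_network(slice_sim_config(
    n_cells = 10, duration = 7200, cell_event_rate = 22.9,
    sync_fraction = 0, seed = 12))
  n_events <- sum(lengths(sim$truth$per_cell_event_times))
  expected <- 22.9 * 10 * 2
  se3 <- 3 * sqrt(expected)   # Poisson sampling error
  expect_lt(abs(n_events - expected), se3)
})

test_that("patch simulator plants bimodal responses consistent with its flags", {
  # noiseless fixed-amplitude responders measure exactly -9.9 mV
  cfg <- patch_sim_config(n_neurons = 3, responder_fraction = 1,
                          membrane_noise_sd = 0,
                          response_amplitude = dist_spec("constant",
                                                         value = -9.9),
                          seed = 2)
  sim <- simulate_patch(cfg)
  for (tr in sim$traces) {
    resp <- quantify_vmem_response(tr)
    expect_equal(resp$delta_vmem, -9.9, tolerance = 1e-6)
    expect_true(resp$responder)
  }

  # responder count is Binomial(n, 0.4) and flags match the truth record
  cfg <- patch_sim_config(n_neurons = 50, responder_fraction = 0.40, seed = 9)
  sim <- simulate_patch(cfg)
  k <- sum(sim$truth$responder_flags)
  expect_gte(k, qbinom(0.0005, 50, 0.4))
  expect_lte(k, qbinom(0.9995, 50, 0.4))
  expect_identical(sim$truth$true_delta_vmem != 0, sim$truth$responder_flags)
})

test_that("dual-antagonist scaling abolishes the planted response", {
  cfg <- patch_sim_config(n_neurons = 10, responder_fraction = 1,
                          antagonist = "both", membrane_noise_sd = 0.3,
                          seed = 4)
  sim <- simulate_patch(cfg)
  deltas <- vapply(sim$traces, function(tr)
    quantify_vmem_response(tr)$delta_vmem, 0)
  expect_true(all(deltas > -5))   # all blocked: no responder-level change
})

test_that("spike trains follow the configured piecewise Poisson rates", {
  # factor 1: homogeneous throughout, rate recovered within 3 SE
  sim <- simulate_spiketrain(spike_sim_config(
    baseline_rate = 1.48, cno_rate_factor = 1, duration = 3600, seed = 5))
  n <- length(sim$train$spike_times)
  expect_lt(abs(n - 1.48 * 3600), 3 * sqrt(1.48 * 3600))

  # factor 0: silent inside every application window
  sim <- simulate_spiketrain(spike_sim_config(
    cno_rate_factor = 0, cno_application_windows = list(c(100, 300)),
    duration = 600, seed = 6))
  st <- sim$train$spike_times
  expect_false(any(st >= 100 & st < 300))

  # overlapping windows are a configuration error
  expect_error(spike_sim_config(cno_application_windows =
                                  list(c(0, 100), c(50, 150))),
               "overlap")
})

test_that("invalid simulator configurations are rejected", {
  expect_error(photometry_sim_config(kernel_rise = 30, kernel_decay = 25),
               "kernel_rise")
  expect_error(photometry_sim_config(suppression_factor = 1.5), "suppression")
  expect_error(slice_sim_config(n_cells = 1), "n_cells")
  expect_error(slice_sim_config(drug_epoch = c(100, 50)), "drug_epoch")
  expect_error(slice_sim_config(duration = 100, drug_epoch = c(50, 200)),
               "outside")
  expect_error(patch_sim_config(responder_fraction = 2), "responder_fraction")
  expect_error(dist_spec("normal", mean = 1), "sd")
})
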