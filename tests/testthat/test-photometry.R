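make_trace <- function(time, f465, f405) {
  new_dual_channel_trace(time, f465, f405, meta = list(animal_id = "t"))
}

test_that("isosbestic subtraction removes the reference channel", {
  tt <- seq(0, 99.9, by = 0.1)
  x <- sin(tt / 5) + 3
  # identical channels cancel exactly in default mode
  tr <- make_trace(tt, x, x)
  expect_true(all(subtract_background(tr)$signal == 0))
  # zero reference leaves the calcium channel untouched
  tr <- make_trace(tt, x, rep(0, length(tt)))
  expect_identical(subtract_background(tr)$signal, x)
  # affine mode recovers a gain/offset-mismatched shared component
  shared <- cumsum(rnorm(length(tt), 0, 0.05))
  tr <- make_trace(tt, 2 + shared, 5 + 0.5 * shared)
  out <- subtract_background(tr, fit_isosbestic = TRUE)
  expect_lt(max(abs(out$signal)), 1e-8)
})

test_that("shared artifact is removed by default-mode subtraction", {
  cfg <- photometry_sim_config(duration = 7200,
                               isosbestic_artifact_gain = 1, seed = 21)
  sim <- simulate_photometry(cfg)
  corr <- subtract_background(sim$trace)
  artifact <- sim$trace$meta$artifact
  expect_lt(abs(cor(corr$signal, artifact)), 0.05)
})

test_that("baseline correction removes drift but preserves transients", {
  tt <- seq(0, 14400 - 0.5, by = 0.5)
  # constant signal maps to (approximately) zero
  out <- correct_baseline(rep(7, length(tt)), time = tt)
  expect_lt(max(abs(out$signal)), 1e-9)
  # pure linear drift: residual below 5% of the total drift range
  drift <- 3 * tt / max(tt)
  out <- correct_baseline(drift, time = tt)
  expect_lt(max(abs(out$signal)), 0.05 * 3)
  # planted transients keep their amplitude within 10% on top of drift
  peaks_at <- c(3000, 7000, 11000)
  sig <- drift
  for (t0 in peaks_at) {
    d <- tt - t0
    k <- ifelse(d >= 0, exp(-d / 25) - exp(-d / 1.5), 0)
    sig <- sig + 8 * k / max(k)
  }
  out <- correct_baseline(sig, time = tt)
  for (t0 in peaks_at) {
    got <- max(out$signal[abs(tt - t0) < 50])
    expect_lt(abs(got - 8) / 8, 0.10)
  }
  # short recordings fall back to a global quantile with a warning
  expect_warning(correct_baseline(rnorm(100), time = seq(0, 99)), "shorter")
})

test_that("z-scoring is exact, affine-invariant and idempotent", {
  z <- zscore(c(1, 2, 3), time = 0:2)
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(sd(z$z), 1, tolerance = 1e-12)
  x <- rnorm(500)
  z1 <- zscore(x, time = seq_along(x))$z
  z2 <- zscore(5 * x - 3, time = seq_along(x))$z
  expect_equal(z1, z2, tolerance = 1e-12)
  z3 <- zscore(z1, time = seq_along(x))$z
  expect_equal(z3, z1, tolerance = 1e-12)
  expect_error(zscore(rep(2, 10), time = 1:10), "degenerate")
})

test_that("peak detection agrees exactly with the exhaustive oracle", {
  set.seed(42)
  for (rep in 1:20) {
    x <- cumsum(rnorm(1000))
    pt <- zscore(x, time = seq_along(x) - 1)
    got <- detect_peaks(pt, min_prominence = 0)
    idx <- oracle_local_maxima(pt$z)
    expect_equal(got$time, pt$time[idx])
    proms <- vapply(idx, function(k) oracle_prominence(pt$z, k), 0)
    expect_equal(got$prominence, proms, tolerance = 1e-12)
    # prominence filtering is a plain subset rule
    got1 <- detect_peaks(pt, min_prominence = 1)
    expect_equal(got1$time, pt$time[idx][proms >= 1])
  }
})

test_that("peak detection handles degenerate shapes", {
  # monotone trace has no peaks
  pt <- structure(list(time = 0:99, z = as.numeric(0:99),
                       processing_log = character()),
                  class = "processed_trace")
  expect_equal(nrow(detect_peaks(pt)), 0L)
  # single triangular pulse: one peak at its apex, height preserved
  z <- c(rep(0, 40), seq(0, 5, length.out = 21), seq(4.75, 0, length.out = 20),
         rep(0, 40))
  pt <- structure(list(time = seq_along(z) - 1, z = z,
                       processing_log = character()),
                  class = "processed_trace")
  got <- detect_peaks(pt)
  expect_equal(nrow(got), 1L)
  expect_equal(got$height, 5)
  # plateau maxima resolve to the plateau midpoint
  z <- c(0, 1, 3, 3, 3, 1, 0)
  pt <- structure(list(time = 0:6, z = z, processing_log = character()),
                  class = "processed_trace")
  expect_equal(detect_peaks(pt)$time, 3)
})

test_that("SE classification applies the 1/3-of-max and 160-s rules", {
  zt <- function(n) structure(list(time = seq_len(n) - 1, z = rnorm(n),
                                   processing_log = character()),
                              class = "processed_trace")
  peaks <- function(t, h) structure(
    data.frame(time = t, height = h, prominence = h),
    class = c("peak_table", "data.frame"))

  tr <- zt(2000)
  # a single peak always passes (it is 3x above max/3)
  ses <- classify_ses(peaks(1000, 10), tr)
  expect_equal(nrow(ses), 1L)
  expect_equal(ses$peak_time, 1000)

  # hand-worked case: threshold 3 removes (400,2); (100,4) is within 160 s
  # of the kept (0,9)
  ses <- classify_ses(peaks(c(0, 100, 400), c(9, 4, 2)), tr)
  expect_equal(nrow(ses), 1L)
  expect_equal(ses$peak_time, 0)

  # empty input yields an empty SE set
  expect_equal(nrow(classify_ses(peaks(numeric(0), numeric(0)), tr)), 0L)
})

test_that("greedy spacing resolution equals the exhaustive oracle", {
  zt <- structure(list(time = seq(0, 1999), z = rnorm(2000),
                       processing_log = character()),
                  class = "processed_trace")
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    t <- sort(runif(n, 0, 1500))
    h <- runif(n, 1, 10)
    pk <- structure(data.frame(time = t, height = h, prominence = h),
                    class = c("peak_table", "data.frame"))
    got <- classify_ses(pk, zt)$peak_time
    want <- oracle_classify_times(t, h)
    expect_equal(got, want)
  }
})

test_that("classified SE sets satisfy their invariants on simulated data", {
  for (s in c(2, 13)) {
    sim <- simulate_photometry(photometry_sim_config(duration = 43200,
                                                     seed = s))
    ses <- detect_ses(sim$trace)
    expect_gt(nrow(ses), 0)
    if (nrow(ses) > 1) expect_gt(min(diff(ses$peak_time)), 160)
    expect_true(all(ses$onset_time <= ses$peak_time))
  }
})

test_that("SE calls are equivariant to a common additive offset", {
  sim <- simulate_photometry(photometry_sim_config(duration = 14400, seed = 8))
  tr <- sim$trace
  shifted <- new_dual_channel_trace(tr$time, tr$f465 + 50, tr$f405 + 50,
                                    tr$mask, tr$meta)
  s1 <- detect_ses(tr)
  s2 <- detect_ses(shifted)
  expect_equal(s1$peak_time, s2$peak_time)
  expect_equal(s1$amplitude, s2$amplitude, tolerance = 1e-9)
})

test_that("SE shape metrics match closed-form geometry", {
  # symmetric triangle, base 40 s, height 8: FWHM is 20 s
  tt <- seq(0, 600, by = 0.5)
  z <- pmax(0, 8 * (1 - abs(tt - 300) / 20))
  pt <- structure(list(time = tt, z = z, processing_log = character()),
                  class = "processed_trace")
  sh <- se_shape(pt, 300)
  expect_equal(sh$fwhm, 20, tolerance = 0.1)
  expect_equal(sh$amplitude, 8, tolerance = 0.05)
  expect_true(sh$fwhm_defined)

  # Gaussian pulse: FWHM = 2.355 sigma within one sample spacing
  for (sigma in c(10, 25)) {
    z <- 6 * exp(-(tt - 300)^2 / (2 * sigma^2))
    pt <- structure(list(time = tt, z = z, processing_log = character()),
                    class = "processed_trace")
    sh <- se_shape(pt, 300)
    expect_lt(abs(sh$fwhm - 2.355 * sigma), 0.5 + 0.05 * sigma)
  }

  # onset precedes the peak
  expect_lte(sh$onset_time, 300)
})

test_that("planted SE amplitudes are recovered within 10%", {
  cfg <- photometry_sim_config(duration = 21600, seed = 31)
  sim <- simulate_photometry(cfg)
  ses <- detect_ses(sim$trace)
  rec <- event_recovery(ses$peak_time, sim$truth$se_times, tol = 20)
  expect_gte(rec$f1, 0.95)
  # compare matched amplitudes on the z scale: planted amplitude (in noise-SD
  # units) over the post-subtraction z denominator
  zden <- sd(correct_baseline(subtract_background(sim$trace))$signal)
  measured <- planted <- numeric(0)
  for (i in seq_len(nrow(ses))) {
    j <- which.min(abs(sim$truth$se_times - ses$peak_time[i]))
    if (abs(sim$truth$se_times[j] - ses$peak_time[i]) <= 20) {
      measured <- c(measured, ses$amplitude[i])
      planted <- c(planted, sim$truth$se_amplitudes[j] * cfg$noise_sd / zden)
    }
  }
  expect_lt(abs(mean(measured) - mean(planted)) / mean(planted), 0.10)
  expect_true(all(abs(measured - planted) / planted < 0.25))
})

test_that("SE timeline arithmetic matches the worked example", {
  h <- 3600
  ses <- structure(
    data.frame(peak_time = c(-2, 1, 3, 6) * h + 10 * h,
               amplitude = rep(5, 4),
               onset_time = c(-2, 1, 3, 6) * h + 10 * h,
               fwhm = rep(30, 4), fwhm_defined = rep(TRUE, 4)),
    class = c("se_set", "data.frame"),
    time_range = c(0, 20 * h))
  tl <- se_timeline(ses, injection_time = 10 * h)
  expect_equal(tl$baseline_count, 1L)
  expect_equal(unname(tl$bin_counts), c(2L, 1L))
  expect_equal(tl$latency_to_first, 1 * h)
  expect_equal(tl$inter_se_intervals[1], 2 * h)

  # no SE after injection: latency flagged undefined, bins zero
  tl0 <- se_timeline(ses[1, ], injection_time = 10 * h)
  expect_false(tl0$latency_defined)
  expect_true(is.na(tl0$latency_to_first))
  expect_equal(sum(tl0$bin_counts), 0L)

  # injection outside the recording is an input error
  expect_error(se_timeline(ses, injection_time = 30 * h), "outside")
})
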