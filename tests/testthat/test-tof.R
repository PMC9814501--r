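irf_default <- irf_from_pulses(0.3, 4)

test_that("TOF calibration recovers exact and noisy constants", {
  peaks <- data.frame(mz = c(27, 38, 53, 67.5, 108))
  peaks$flight_time <- mz_to_time(peaks$mz, k = 1, t_offset = 0)
  cal <- tof_calibration_fit(peaks)
  expect_equal(cal$k, 1, tolerance = 1e-12)
  expect_equal(cal$t_offset, 0, tolerance = 1e-12)

  # two peaks: exact solve, zero residuals
  two <- peaks[1:2, ]
  cal2 <- tof_calibration_fit(two)
  resid <- two$flight_time - mz_to_time(two$mz, cal2$k, cal2$t_offset)
  expect_equal(resid, c(0, 0), tolerance = 1e-12)

  expect_error(tof_calibration_fit(peaks[1, , drop = FALSE]),
               class = "chargemig_calibration_error")
  expect_error(tof_calibration_fit(data.frame(mz = c(27, 27),
                                              flight_time = c(5, 6))),
               class = "chargemig_calibration_error")
})

test_that("noisy calibration covers the true constant at the stated rate", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    peaks <- data.frame(mz = c(27, 38, 53, 67.5, 108))
    peaks$flight_time <- mz_to_time(peaks$mz, 1.3, 0.2) + rnorm(5, 0, 0.01)
    cal <- tof_calibration_fit(peaks)
    if (abs(cal$k - 1.3) <= 3 * cal$k_err) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("m/z to flight time round trip is exact", {
  for (s in 1:20) {
    set.seed(s)
    k <- runif(1, 0.5, 3); t0 <- runif(1, -0.5, 0.5)
    mz <- runif(10, 5, 200)
    expect_equal(time_to_mz(mz_to_time(mz, k, t0), k, t0), mz,
                 tolerance = 1e-12)
  }
})

test_that("window integration isolates the dication from neighbour masses", {
  cfg <- dataset_config(delay_grid = seq(-6, 10, 2), n_scans = 1,
                        noise_sigma = 0, seed = 1)
  ds <- simulate_pumpprobe_dataset(cfg, irf_default)
  sp <- simulate_tof_spectra(ds, scan = 1)
  tr <- extract_ion_trace(sp, 67.5)
  truth <- ds[ds$scan == 1 & ds$label == "dication", ]
  expect_equal(tr$yield, truth$yield, tolerance = 1e-4)
  empty <- suppressWarnings(extract_ion_trace(sp, 150.5, half_width = 0.25))
  expect_true(all(empty$yield == 0))
  expect_error(extract_ion_trace(sp, 67.5, half_width = 0),
               class = "chargemig_invalid")
})

test_that("a peak at 67.0 does not leak into the 67.5 window", {
  tt <- seq(7, 9, by = 0.002)
  counts <- dnorm(tt, mz_to_time(67, 1, 0.2), 0.0035) * 0.002
  sp <- tibble::tibble(delay_fs = 0, flight_time = tt, counts = counts)
  attr(sp, "k") <- 1; attr(sp, "t_offset") <- 0.2
  tr67.5 <- suppressWarnings(extract_ion_trace(sp, 67.5, half_width = 0.25))
  tr67 <- extract_ion_trace(sp, 67, half_width = 0.25)
  expect_lt(tr67.5$yield, 1e-4)
  expect_equal(tr67$yield, 1, tolerance = 1e-3)
})

test_that("scan averaging produces the right mean and SEM", {
  tr <- tibble::tibble(delay_fs = 1:5, yield = c(1, 2, 3, 4, 5), sem = 0)
  same <- replicate(7, tr, simplify = FALSE)
  avg <- average_scans(same)
  expect_equal(avg$yield, tr$yield)
  expect_equal(avg$sem, rep(0, 5))

  # SEM approaches s/sqrt(7) for known noise
  set.seed(42)
  sems <- replicate(200, {
    scans <- lapply(1:7, function(i)
      tibble::tibble(delay_fs = 1:5, yield = rnorm(5, 10, 0.35), sem = 0))
    mean(average_scans(scans)$sem)
  })
  expect_equal(mean(sems), 0.35 / sqrt(7), tolerance = 0.05)

  bad <- same; bad[[2]]$delay_fs <- 2:6
  expect_error(average_scans(bad), class = "chargemig_invalid")
  expect_warning(single <- average_scans(same[1]), "single scan")
  expect_equal(single$sem, rep(0, 5))
})

test_that("extraction plus averaging recovers the generator curves", {
  # paired check over seeds: the scan mean is unbiased, so the bias
  # standardised by the true SEM (0.05 * peak / sqrt(7)) behaves like
  # |N(0,1)| with mean sqrt(2/pi) ~ 0.8
  z <- c()
  for (s in 1:20) {
    cfg <- dataset_config(delay_grid = seq(-5, 15, 2.5), seed = s)
    ds <- simulate_pumpprobe_dataset(cfg, irf_default)
    avg <- average_scans(channel_traces(ds, "dication"))
    truth <- attr(ds, "truth")
    tdic <- truth[truth$label == "dication", ]
    sem_true <- 0.05 * max(abs(tdic$yield)) / sqrt(7)
    z <- c(z, abs(avg$yield - tdic$yield) / sem_true)
  }
  expect_lt(mean(z), 1.2)
  expect_gt(mean(z), 0.4)
})

test_that("time zero is located from step-like references", {
  t <- seq(-20, 30, 1)
  y <- 1 + 0.4 * pnorm((t - 0) / irf_default$sigma)
  tr <- tibble::tibble(delay_fs = t, yield = y, sem = 0)
  fz <- find_time_zero(tr, irf_default)
  expect_equal(fz$t0, 0, tolerance = 1e-6)

  y2 <- 1 + 0.4 * pnorm((t - 1.5) / irf_default$sigma)
  fz2 <- find_time_zero(tibble::tibble(delay_fs = t, yield = y2, sem = 0),
                        irf_default)
  expect_equal(fz2$t0, 1.5, tolerance = 1e-6)

  flat <- tibble::tibble(delay_fs = t, yield = rep(1, length(t)), sem = 0)
  expect_error(find_time_zero(flat, irf_default),
               class = "chargemig_no_step_error")
})
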