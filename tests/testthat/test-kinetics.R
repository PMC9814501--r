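test_that("step-decay model matches its unconvolved limits", {
  expect_equal(model_step_decay(-5, t0 = 0, amplitude = 2, baseline = 0.3,
                                tau1 = 24, sigma_irf = 0), 0.3)
  expect_equal(model_step_decay(24, t0 = 0, amplitude = 2, baseline = 0.3,
                                tau1 = 24, sigma_irf = 0), 0.3 + 2 * exp(-1))
  expect_error(model_step_decay(0, tau1 = -1), class = "chargemig_invalid")
})

test_that("analytic IRF convolution agrees with brute-force quadrature", {
  tt <- seq(-8, 60, length.out = 100)
  for (par in list(c(2.32, 1.703), c(24, 1.703), c(24, 5), c(0.5, 0.2))) {
    a <- chargemig:::emg_core(tt, par[1], par[2])
    b <- quad_emg(tt, par[1], par[2])
    expect_equal(a, b, tolerance = 1e-9)
  }
  # the full rise-decay curve against quadrature of its two branches
  y <- model_rise_decay(tt, t0 = 3, amplitude = 1.4, baseline = 0.1,
                        tau1 = 2.32, tau2 = 24, sigma_irf = 1.703)
  yq <- 0.1 + 1.4 * 24 / (24 - 2.32) *
    (quad_emg(tt - 3, 24, 1.703) - quad_emg(tt - 3, 2.32, 1.703))
  expect_equal(y, yq, tolerance = 1e-9)
})

test_that("rise-decay population starts at zero and peaks where predicted", {
  expect_equal(model_rise_decay(5, t0 = 5, baseline = 0.2, tau1 = 2.32,
                                tau2 = 24, sigma_irf = 0), 0.2)
  peak_pred <- 2.32 * 24 * log(24 / 2.32) / (24 - 2.32)
  expect_equal(peak_pred, 6.003, tolerance = 1e-3)
  opt <- stats::optimize(function(t) model_rise_decay(t, tau1 = 2.32, tau2 = 24),
                         c(0, 20), maximum = TRUE)
  expect_equal(opt$maximum, peak_pred, tolerance = 1e-3)
  expect_error(model_rise_decay(0, tau1 = 5, tau2 = 4),
               class = "chargemig_invalid")
})

test_that("rise-decay converges to step-decay as the risetime vanishes", {
  # pointwise convergence is first order in tau1: the residual is
  # tau1/(tau2 - tau1) * emg(tau2) plus a boundary term of size
  # tau1/(sigma sqrt(2 pi)) from the vanishing rise branch
  tt <- seq(-5, 50, 0.5)
  a <- model_step_decay(tt, tau1 = 24, sigma_irf = 1.7)
  d4 <- max(abs(model_rise_decay(tt, tau1 = 1e-4, tau2 = 24,
                                 sigma_irf = 1.7) - a))
  d3 <- max(abs(model_rise_decay(tt, tau1 = 1e-3, tau2 = 24,
                                 sigma_irf = 1.7) - a))
  bound <- function(tau1) tau1 / (24 - tau1) + tau1 / (1.7 * sqrt(2 * pi))
  expect_lt(d4, bound(1e-4))
  expect_lt(d3, bound(1e-3))
  expect_equal(d3 / d4, 10, tolerance = 0.05) # first-order rate
  # the unconvolved curves converge at the tau1/tau2 rate pointwise for
  # s > 0 (at s = 0 the step model jumps to 1 while the rise starts at 0)
  tp <- tt[tt >= 0.5]
  d0 <- max(abs(model_rise_decay(tp, tau1 = 1e-4, tau2 = 24, sigma_irf = 0) -
                  model_step_decay(tp, tau1 = 24, sigma_irf = 0)))
  expect_lt(d0, 1e-5)
})

test_that("convolved models are shift- and scale-covariant", {
  tt <- seq(-10, 40, 0.5)
  y0 <- model_rise_decay(tt, t0 = 0, tau1 = 2.32, tau2 = 24, sigma_irf = 1.7)
  y5 <- model_rise_decay(tt + 5, t0 = 5, tau1 = 2.32, tau2 = 24, sigma_irf = 1.7)
  expect_equal(y0, y5, tolerance = 1e-12)
  y2 <- model_rise_decay(tt, t0 = 0, amplitude = 3, tau1 = 2.32, tau2 = 24,
                         sigma_irf = 1.7)
  expect_equal(y2, 3 * y0, tolerance = 1e-12)
})

test_that("noiseless traces are recovered exactly", {
  tt <- seq(-20, 60, 1)
  tr <- tibble::tibble(
    delay_fs = tt,
    yield = model_rise_decay(tt, t0 = 0.3, amplitude = 1.2, baseline = 0.05,
                             tau1 = 2.32, tau2 = 24, sigma_irf = 1.703),
    sem = 0)
  fit <- fit_ion_trace(tr, "B", sigma_irf = 1.703, n_boot = 0)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(est[["t0"]], 0.3, tolerance = 1e-5)
  expect_equal(est[["amplitude"]], 1.2, tolerance = 1e-5)
  expect_equal(est[["baseline"]], 0.05, tolerance = 1e-5)
  expect_equal(est[["tau1"]], 2.32, tolerance = 1e-5)
  expect_equal(est[["tau2"]], 24, tolerance = 1e-4)
})

test_that("bootstrap intervals are seeded and bracket the estimates", {
  set.seed(77)
  tt <- seq(-20, 60, 1)
  y <- model_rise_decay(tt, tau1 = 2.32, tau2 = 24, sigma_irf = 1.703) +
    rnorm(length(tt), 0, 0.02)
  tr <- tibble::tibble(delay_fs = tt, yield = y, sem = 0.02)
  f1 <- fit_ion_trace(tr, "B", sigma_irf = 1.703, n_boot = 60, seed = 3)
  f2 <- fit_ion_trace(tr, "B", sigma_irf = 1.703, n_boot = 60, seed = 3)
  expect_identical(f1$params, f2$params)
  expect_true(all(f1$params$conf.low <= f1$params$estimate))
  expect_true(all(f1$params$conf.high >= f1$params$estimate))
  td <- tidy(f1)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  gl <- glance(f1)
  expect_equal(gl$n_points, length(tt))
})

test_that("fits reject undersized traces", {
  tr <- tibble::tibble(delay_fs = 1:6, yield = rnorm(6), sem = 0)
  expect_error(fit_ion_trace(tr, "B", n_boot = 0),
               class = "chargemig_fit_error")
})

test_that("photon order counts photons from log-log slopes", {
  quad <- tibble::tibble(intensity = c(1, 2, 4) * 1e12,
                         yield = c(1, 4, 16))
  po <- photon_order(quad)
  expect_equal(po$slope, 2, tolerance = 1e-12)
  expect_identical(po$n_photons, 2L)
  lin <- tibble::tibble(intensity = c(1, 2, 4) * 1e12, yield = c(2, 4, 8))
  expect_identical(photon_order(lin)$n_photons, 1L)
  expect_error(photon_order(tibble::tibble(intensity = c(1, 2) * 1e12,
                                           yield = c(1, 4))),
               class = "chargemig_invalid")
  expect_error(photon_order(tibble::tibble(intensity = c(1, 2, -1),
                                           yield = c(1, 4, 2))),
               class = "chargemig_invalid")
})
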