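# Rate-equation curve models for delay-dependent ion yields, and their
# weighted nonlinear least-squares fits with bootstrap confidence intervals.
#
# Model A ("step-decay"): a population created directly at time zero that
# decays exponentially with lifetime tau1 -- the fragment-cation response.
# Model B ("rise-decay"): opposing rates, population starting at zero,
# rising with tau1 and decaying with the slower tau2 -- the intact-dication
# response. Both are convolved with a Gaussian instrument response of
# standard deviation sigma_irf; the convolution is analytic (exponentially
# modified Gaussian, erfcx-stabilised), quadrature is kept only as a test
# oracle.

# H(s) exp(-s/tau) convolved with N(0, sigma^2); unit step amplitude.
# Evaluated entirely in log space,
#   emg = exp(sigma^2/(2 tau^2) - s/tau + log Phi(s/sigma - sigma/tau)),
# which is finite for any argument (the erfcx(u) * gaussian product form
# overflows for strongly negative u).
emg_core <- function(s, tau, sigma) {
  if (tau <= 0) stop_invalid("tau must be > 0")
  if (sigma < 0) stop_invalid("sigma_irf must be >= 0")
  if (sigma == 0) return(ifelse(s < 0, 0, exp(-s / tau)))
  exp(sigma^2 / (2 * tau^2) - s / tau +
        stats::pnorm(s / sigma - sigma / tau, log.p = TRUE))
}

#' Step-decay ion-yield model (model A)
#'
#' Ideal curve `H(t - t0) * amplitude * exp(-(t - t0)/tau1) + baseline`,
#' convolved with a Gaussian instrument response of standard deviation
#' `sigma_irf` (fs). The convolution is the exponentially modified Gaussian
#' closed form, numerically safe for large `sigma/tau`.
#'
#' @param t Delay(s) in fs.
#' @param t0 Time zero in fs.
#' @param amplitude Step amplitude.
#' @param baseline Constant offset.
#' @param tau1 Decay lifetime in fs, `> 0`.
#' @param sigma_irf Instrument-response standard deviation in fs (0 for the
#'   ideal curve).
#' @return Model yield(s).
#' @export
#' @examples
#' model_step_decay(0:10, t0 = 0, amplitude = 1, tau1 = 24, sigma_irf = 1.7)
model_step_decay <- function(t, t0 = 0, amplitude = 1, baseline = 0,
                             tau1, sigma_irf = 0) {
  baseline + amplitude * emg_core(t - t0, tau1, sigma_irf)
}

#' Rise-decay ion-yield model (model B)
#'
#' Opposing-rates population: zero before `t0`, rising with lifetime `tau1`
#' and decaying with the slower lifetime `tau2`:
#' `H(s) * amplitude * tau2/(tau2 - tau1) * (exp(-s/tau2) - exp(-s/tau1))`,
#' `s = t - t0`, Gaussian-convolved as in [model_step_decay()]. The
#' unconvolved curve peaks at `t0 + tau1 tau2 log(tau2/tau1)/(tau2 - tau1)`.
#'
#' @inheritParams model_step_decay
#' @param tau2 Decay lifetime in fs, must exceed `tau1`.
#' @return Model yield(s).
#' @export
model_rise_decay <- function(t, t0 = 0, amplitude = 1, baseline = 0,
                             tau1, tau2, sigma_irf = 0) {
  if (tau2 <= tau1) stop_invalid("tau2 must exceed tau1 (slower decay)")
  s <- t - t0
  baseline + amplitude * tau2 / (tau2 - tau1) *
    (emg_core(s, tau2, sigma_irf) - emg_core(s, tau1, sigma_irf))
}

kinetic_model_fun <- function(model) {
  switch(model,
    step_decay = function(t, p) model_step_decay(
      t, p[["t0"]], p[["amplitude"]], p[["baseline"]], p[["tau1"]], p[["sigma_irf"]]),
    rise_decay = function(t, p) model_rise_decay(
      t, p[["t0"]], p[["amplitude"]], p[["baseline"]], p[["tau1"]], p[["tau2"]], p[["sigma_irf"]])
  )
}

normalise_model_name <- function(model) {
  switch(tolower(model),
    a = , step = , step_decay = "step_decay",
    b = , rise = , rise_decay = "rise_decay",
    stop_invalid("unknown kinetic model: ", model)
  )
}

# starting values from the trace itself; several t0 candidates because a
# noisy steepest-rise location can seed a pathological local optimum
kinetic_init <- function(delay, yield, model, sigma_irf) {
  base <- stats::median(yield[delay < stats::quantile(delay, 0.2)])
  if (!is.finite(base)) base <- min(yield)
  amp <- max(yield) - base
  if (amp == 0) amp <- 1
  # smoothed steepest change (either sign, for negative steps)
  dy <- diff(yield)
  ks <- min(5, length(dy))
  dys <- stats::filter(dy, rep(1 / ks, ks), sides = 2)
  t0_slope <- delay[which.max(abs(dys))]
  # first crossing of the half level
  half <- base + (yield[which.max(abs(yield - base))] - base) / 2
  cross <- which(diff(sign(yield - half)) != 0)
  t0_half <- if (length(cross)) delay[cross[1]] else t0_slope
  list(t0 = unique(c(t0_slope, t0_half, 0)),
       amplitude = amp, baseline = base,
       tau1 = if (model == "rise_decay") 2 else 20,
       tau2 = 20, sigma_irf = sigma_irf)
}

# Weighted SSR minimisation in a transformed parameter space:
# tau1 = exp(th[ltau1]), tau2 = tau1 + exp(th[ldelta]) keeps the lifetime
# ordering constraint smooth.
fit_kinetic_ls <- function(delay, yield, w, model, init, fixed) {
  free_names <- setdiff(
    if (model == "rise_decay") c("t0", "amplitude", "baseline", "tau1", "tau2")
    else c("t0", "amplitude", "baseline", "tau1"),
    names(fixed)
  )
  fn <- kinetic_model_fun(model)

  to_theta <- function(p) {
    th <- c()
    for (nm in free_names) {
      th[[nm]] <- switch(nm,
        tau1 = log(p[["tau1"]]),
        tau2 = log(max(p[["tau2"]] - p[["tau1"]], 1e-6)),
        p[[nm]])
    }
    unlist(th)
  }
  from_theta <- function(th) {
    p <- as.list(fixed)
    for (nm in free_names) p[[nm]] <- th[[nm]]
    if ("tau1" %in% free_names) p$tau1 <- exp(th[["tau1"]])
    if ("tau2" %in% free_names) p$tau2 <- p$tau1 + exp(th[["tau2"]])
    p$sigma_irf <- fixed$sigma_irf %||% init$sigma_irf
    p
  }
  ssr <- function(th) {
    p <- from_theta(th)
    r <- yield - fn(delay, p)
    sum(w * r^2)
  }
  th0 <- to_theta(init)
  opt <- stats::optim(th0, ssr, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  opt <- stats::optim(opt$par, ssr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  # final Nelder-Mead polish guards against BFGS stalling on kinked surfaces
  opt <- stats::optim(opt$par, ssr, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-15))
  p <- from_theta(opt$par)
  list(params = p, ssr = opt$value, converged = opt$convergence == 0,
       theta = opt$par, free_names = free_names,
       refit = function(y2, init2) {
         ssr2 <- function(th) {
           pp <- from_theta(th)
           r <- y2 - fn(delay, pp)
           sum(w * r^2)
         }
         o <- stats::optim(init2, ssr2, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-12))
         from_theta(o$par)
       })
}

#' Fit a kinetic model to an ion trace
#'
#' Weighted nonlinear least squares (weights `1/sem^2`; unweighted when any
#' `sem` is zero or missing) of [model_step_decay()] or [model_rise_decay()]
#' to a delay-resolved ion trace, with 68% confidence intervals from a
#' seeded residual-resampling bootstrap (percentile method). The lifetime
#' ordering `tau2 > tau1` is enforced by fitting `tau2 = tau1 + exp(.)`.
#'
#' @param trace A data frame with columns `delay_fs`, `yield` and optionally
#'   `sem` (as produced by [average_scans()]).
#' @param model `"rise_decay"` (alias `"B"`) or `"step_decay"` (alias `"A"`).
#' @param sigma_irf Instrument-response standard deviation in fs, or an
#'   [instrument_response()]. Fixed during the fit.
#' @param t0 Optional fixed time zero in fs (e.g. shared from a fragment
#'   step); if `NULL`, `t0` is a free parameter.
#' @param init Optional named list of starting values.
#' @param n_boot Number of bootstrap replicates for the 68% intervals
#'   (0 skips the bootstrap; intervals are then `NA`).
#' @param seed Integer seed making the bootstrap deterministic.
#' @return A `kinetic_fit` object; see [tidy.kinetic_fit()] and
#'   [glance.kinetic_fit()].
#' @export
fit_ion_trace <- function(trace, model = "rise_decay", sigma_irf = 0,
                          t0 = NULL, init = NULL, n_boot = 500, seed = 1) {
  model <- normalise_model_name(model)
  if (inherits(sigma_irf, "instrument_response")) sigma_irf <- sigma_irf$sigma
  delay <- trace$delay_fs
  yield <- trace$yield
  sem <- trace$sem %||% rep(0, length(yield))
  n_free <- (if (model == "rise_decay") 5 else 4) - (!is.null(t0))
  if (length(delay) < 2 * n_free)
    cond_error("chargemig_fit_error",
               "trace needs at least twice as many points as free parameters")
  w <- if (all(sem > 0)) 1 / sem^2 else rep(1, length(yield))

  init0 <- kinetic_init(delay, yield, model, sigma_irf)
  if (!is.null(init)) init0[names(init)] <- init
  fixed <- list(sigma_irf = sigma_irf)
  if (!is.null(t0)) fixed$t0 <- t0
  init0$sigma_irf <- sigma_irf

  # multi-start over the t0 candidates; keep the best optimum
  t0_cands <- if (is.null(t0)) unique(init0$t0) else init0$t0[1]
  fit <- NULL
  for (tc in t0_cands) {
    ini <- init0
    ini$t0 <- tc
    cand <- fit_kinetic_ls(delay, yield, w, model, ini, fixed)
    if (is.null(fit) || cand$ssr < fit$ssr) fit <- cand
  }
  fn <- kinetic_model_fun(model)
  fitted <- fn(delay, fit$params)
  resid <- yield - fitted

  boot <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    reps <- matrix(NA_real_, n_boot, length(fit$free_names),
                   dimnames = list(NULL, fit$free_names))
    for (b in seq_len(n_boot)) {
      yb <- fitted + sample(resid, replace = TRUE)
      pb <- fit$refit(yb, fit$theta)
      reps[b, ] <- unlist(pb[fit$free_names])
    }
    boot <- reps
  }

  est <- unlist(fit$params[fit$free_names])
  ci <- if (!is.null(boot)) {
    lo <- apply(boot, 2, stats::quantile, 0.16, names = FALSE)
    hi <- apply(boot, 2, stats::quantile, 0.84, names = FALSE)
    # percentile intervals need not bracket the point estimate exactly;
    # widen minimally so the reported interval always contains it
    list(lo = pmin(lo, est), hi = pmax(hi, est))
  } else list(lo = rep(NA_real_, length(est)), hi = rep(NA_real_, length(est)))

  params <- tibble::tibble(
    term = fit$free_names,
    estimate = unname(est),
    conf.low = unname(ci$lo),
    conf.high = unname(ci$hi)
  )
  fixed_tbl <- tibble::tibble(
    term = names(fixed), estimate = unlist(fixed, use.names = FALSE),
    conf.low = NA_real_, conf.high = NA_real_
  )
  structure(
    list(
      model = model,
      params = params,
      fixed = fixed_tbl,
      estimates = fit$params,
      data = tibble::tibble(delay_fs = delay, yield = yield, sem = sem,
                            fitted = fitted, resid = resid),
      residual_rms = sqrt(mean(resid^2)),
      n_points = length(yield),
      n_boot = n_boot,
      seed = seed,
      converged = fit$converged,
      boot = boot
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> model %s, %d points, residual rms %.4g\n",
              x$model, x$n_points, x$residual_rms))
  print(x$params)
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high` (68% bootstrap percentile interval).
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) x$params

#' One-row fit summary
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, number of points, residual rms,
#'   bootstrap size, convergence flag.
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_points = x$n_points,
                 residual_rms = x$residual_rms, n_boot = x$n_boot,
                 converged = x$converged)
}

#' Extract a fitted parameter
#'
#' @param fit A `kinetic_fit`.
#' @param term Parameter name (e.g. `"tau1"`).
#' @return The point estimate (fixed parameters are looked up too).
#' @export
coef_kinetic <- function(fit, term) {
  tab <- rbind(fit$params[, c("term", "estimate")], fit$fixed[, c("term", "estimate")])
  i <- match(term, tab$term)
  if (is.na(i)) stop_invalid("no such parameter: ", term)
  tab$estimate[i]
}

#' Photon order of an ionisation yield
#'
#' Ordinary least squares of `log(yield)` on `log(intensity)`: the slope
#' estimates the number of probe photons in a multiphoton step, reported
#' with its standard error and rounded photon count.
#'
#' @param data A data frame with columns `intensity` (W/cm^2) and `yield`,
#'   or a numeric vector of intensities.
#' @param yields Yields, when `data` is a bare vector.
#' @return A one-row tibble: `slope`, `slope_err`, `n_photons`.
#' @export
#' @examples
#' photon_order(tibble::tibble(intensity = c(1, 2, 4) * 1e12,
#'                             yield = c(1, 4, 16)))
photon_order <- function(data, yields = NULL) {
  if (is.data.frame(data)) {
    intensities <- data$intensity
    yields <- data$yield
  } else intensities <- data
  if (length(intensities) < 3) stop_invalid("need at least 3 points")
  if (any(intensities <= 0) || any(yields <= 0))
    stop_invalid("intensities and yields must be positive")
  fit <- stats::lm(log(yields) ~ log(intensities))
  sl <- stats::coef(fit)[[2]]
  se <- sqrt(stats::vcov(fit)[2, 2])
  tibble::tibble(slope = sl, slope_err = se, n_photons = as.integer(round(sl)))
}
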