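# Time-of-flight spectra: calibration, window integration, scan averaging
# and time-zero determination.
#
# Flight-time law: t = k * sqrt(m/z) + t_offset, with k in
# us (u/e)^(-1/2) and t_offset in us.

#' Fit a time-of-flight mass calibration
#'
#' Least squares of flight time on `sqrt(m/z)`; with exactly two distinct
#' peaks the solve is exact (zero residuals).
#'
#' @param peaks Data frame with columns `mz` (u/e) and `flight_time` (us);
#'   at least two distinct m/z values.
#' @return A one-row tibble: `k`, `t_offset`, `k_err`, `t_offset_err`
#'   (standard errors are `NA` for the exact two-peak solve).
#' @export
tof_calibration_fit <- function(peaks) {
  if (nrow(peaks) < 2 || length(unique(peaks$mz)) < 2)
    cond_error("chargemig_calibration_error",
               "need at least two peaks at distinct m/z")
  fit <- stats::lm(flight_time ~ sqrt(mz), data = peaks)
  co <- stats::coef(fit)
  se <- if (nrow(peaks) > 2) sqrt(diag(stats::vcov(fit))) else c(NA_real_, NA_real_)
  tibble::tibble(k = co[[2]], t_offset = co[[1]],
                 k_err = se[[2]], t_offset_err = se[[1]])
}

#' Convert between m/z and flight time
#'
#' @param mz m/z values (u/e).
#' @param flight_time Flight times (us).
#' @param k,t_offset Calibration constants.
#' @return `mz_to_time()` returns flight times; `time_to_mz()` m/z values.
#' @export
mz_to_time <- function(mz, k, t_offset = 0) k * sqrt(mz) + t_offset

#' @rdname mz_to_time
#' @export
time_to_mz <- function(flight_time, k, t_offset = 0) {
  if (k <= 0) stop_invalid("k must be > 0")
  ((flight_time - t_offset) / k)^2
}

#' Simulate time-of-flight spectra from a pump-probe dataset
#'
#' Places a Gaussian flight-time peak per channel, with area equal to the
#' channel yield at each delay, on a common flight-time axis (one scan of
#' the dataset). Spectra start above m/z 4 (helium gated off).
#'
#' @param scan_data One scan of a `delay_scan` (subset with `scan == i`),
#'   or a full `delay_scan` from which `scan` selects one.
#' @param scan Scan index used when `scan_data` holds several scans.
#' @param k,t_offset Calibration constants (us, us).
#' @param peak_sigma Peak width in us.
#' @param bin_width Flight-time bin width in us.
#' @param mz_range m/z range covered by the axis.
#' @return A tibble of class `tof_scan`: columns `delay_fs`, `flight_time`,
#'   `counts`; calibration attached as attributes.
#' @export
simulate_tof_spectra <- function(scan_data, scan = 1, k = 1, t_offset = 0.2,
                                 peak_sigma = 0.0035, bin_width = 0.003,
                                 mz_range = c(5, 150)) {
  if ("scan" %in% names(scan_data)) scan_data <- scan_data[scan_data$scan == scan, ]
  tt <- seq(mz_to_time(mz_range[1], k, t_offset),
            mz_to_time(mz_range[2], k, t_offset), by = bin_width)
  out <- scan_data |>
    dplyr::group_by(.data$delay_fs) |>
    dplyr::group_modify(function(d, key) {
      counts <- rep(0, length(tt))
      for (i in seq_len(nrow(d))) {
        tc <- mz_to_time(d$mz[i], k, t_offset)
        counts <- counts +
          d$yield[i] * stats::dnorm(tt, tc, peak_sigma) * bin_width
      }
      tibble::tibble(flight_time = tt, counts = counts)
    }) |>
    dplyr::ungroup()
  out <- tibble::new_tibble(out, class = "tof_scan")
  attr(out, "k") <- k
  attr(out, "t_offset") <- t_offset
  out
}

#' Extract a delay-dependent ion trace from calibrated spectra
#'
#' For each delay, sums the counts whose back-converted m/z lies within
#' `mz +/- half_width`. The default window of 0.25 u/e resolves the
#' dication at 67.5 u/e from the singly charged fragments at 67 and 68.
#'
#' @param spectra A `tof_scan` (long tibble `delay_fs`, `flight_time`,
#'   `counts` with calibration attributes), or any data frame with those
#'   columns plus `k`/`t_offset` passed explicitly.
#' @param mz Centre of the integration window (u/e).
#' @param half_width Window half-width (u/e), `> 0`.
#' @param k,t_offset Calibration (defaults from the `tof_scan` attributes).
#' @param label Optional channel label for the result.
#' @return An ion-trace tibble: `delay_fs`, `yield`, `sem` (zero; single
#'   scan), with `mz` and `label` attributes.
#' @export
extract_ion_trace <- function(spectra, mz, half_width = 0.25,
                              k = attr(spectra, "k"),
                              t_offset = attr(spectra, "t_offset"),
                              label = NULL) {
  if (half_width <= 0) stop_invalid("half_width must be > 0")
  if (is.null(k) || is.null(t_offset)) stop_invalid("calibration required")
  back_mz <- time_to_mz(spectra$flight_time, k, t_offset)
  inside <- abs(back_mz - mz) <= half_width
  if (!any(inside)) warning("integration window is empty everywhere; zero trace")
  out <- spectra |>
    dplyr::mutate(inside = inside) |>
    dplyr::group_by(.data$delay_fs) |>
    dplyr::summarise(yield = sum(.data$counts[.data$inside]), .groups = "drop") |>
    dplyr::mutate(sem = 0)
  attr(out, "mz") <- mz
  attr(out, "label") <- label %||% sprintf("mz%.1f", mz)
  out
}

#' Average repeated scans of an ion trace
#'
#' Point-wise mean across scans with the standard error of the mean
#' (sample standard deviation over `sqrt(n)`, `ddof = 1`).
#'
#' @param traces A list of trace tibbles on identical delay grids, or a
#'   long data frame with a `scan` column.
#' @return An averaged trace tibble: `delay_fs`, `yield`, `sem`.
#' @export
average_scans <- function(traces) {
  if (is.data.frame(traces)) {
    if (!"scan" %in% names(traces)) stop_invalid("data frame needs a scan column")
    traces <- lapply(split(traces, traces$scan), function(x)
      x[, c("delay_fs", "yield")])
  }
  grids <- lapply(traces, function(x) x$delay_fs)
  if (!all(vapply(grids, function(g) identical(g, grids[[1]]), logical(1))))
    stop_invalid("all scans must share one delay grid")
  n <- length(traces)
  y <- do.call(cbind, lapply(traces, function(x) x$yield))
  if (n == 1) {
    warning("single scan: sem undefined, set to 0")
    sem <- rep(0, nrow(y))
  } else {
    sem <- apply(y, 1, stats::sd) / sqrt(n)
  }
  tibble::tibble(delay_fs = grids[[1]], yield = rowMeans(y), sem = sem)
}

#' Locate time zero from a step-like reference trace
#'
#' Fits `yield = baseline + A * Phi((t - t0)/sigma_irf)` (`Phi` the standard
#' normal CDF) to a reference channel showing a prompt step (fragment
#' cations, or a rare-gas double-ionisation reference) and returns the
#' fitted time zero with its standard error.
#'
#' @param reference A trace tibble (`delay_fs`, `yield`, `sem`).
#' @param irf An [instrument_response()] or sigma in fs.
#' @return A one-row tibble: `t0`, `t0_err`.
#' @export
find_time_zero <- function(reference, irf) {
  sigma <- if (inherits(irf, "instrument_response")) irf$sigma else irf
  y <- reference$yield
  t <- reference$delay_fs
  sem <- reference$sem %||% rep(0, length(y))
  rng <- diff(range(y))
  if (rng == 0 || (stats::median(sem) > 0 && rng < 3 * stats::median(sem)))
    cond_error("chargemig_no_step_error",
               "reference trace shows no usable step (range < 3x median sem)")
  t0_init <- t[which.max(abs(diff(y)))]
  a_init <- y[length(y)] - y[1]
  b_init <- y[1]
  fit <- stats::nls(
    yield ~ b + a * stats::pnorm((delay_fs - t0) / max(sigma, 1e-6)),
    data = data.frame(delay_fs = t, yield = y),
    start = list(b = b_init, a = a_init, t0 = t0_init),
    algorithm = "port", # handles the zero-residual (noiseless) case
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
  )
  est <- stats::coef(fit)[["t0"]]
  err <- tryCatch(summary(fit)$coefficients["t0", "Std. Error"],
                  error = function(e) 0) # singular for zero-residual data
  tibble::tibble(t0 = est, t0_err = err)
}
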