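# Synthetic pump-probe datasets.
#
# Emulates the delay-resolved partial ion yields of an XUV-pump /
# NIR-probe time-of-flight experiment on adenine: step-like fragment
# channels (m/z 27, 38, 53 up, 108 down) and the delayed rise-decay intact
# dication channel at m/z 67.5 u/e, scanned repeatedly (default seven
# scans) with additive Gaussian noise, plus NIR-intensity series of the
# dication yield. Noise is i.i.d. across delay points and scans, with
# standard deviation noise_sigma times the peak absolute model yield of the
# channel, so the scan-average SEM scales as 1/sqrt(n_scans).

#' Default ion channels of the adenine pump-probe experiment
#'
#' Fragment cations at m/z 27, 38 and 53 u/e rise step-like at time zero
#' and decay slowly; the parent at 108 u/e shows a negative step (fragment
#' gain at the expense of the large ions); the intact parent dication at
#' 67.5 u/e follows the rise-decay model with the fitted dication
#' parameters (risetime 2.32 fs, decay 24 fs).
#'
#' @return A tibble with columns `label`, `mz`, `model`, `t0`, `amplitude`,
#'   `baseline`, `tau1`, `tau2`.
#' @export
default_channels <- function() {
  tibble::tribble(
    ~label,       ~mz,  ~model,       ~t0, ~amplitude, ~baseline, ~tau1, ~tau2,
    "frag27",     27,   "step_decay",   0,       0.25,         1,   150,    NA,
    "frag38",     38,   "step_decay",   0,       0.20,         1,   200,    NA,
    "frag53",     53,   "step_decay",   0,       0.30,         1,   180,    NA,
    "dication",   67.5, "rise_decay",   0,       1.00,         0,  2.32,    24,
    "parent108",  108,  "step_decay",   0,      -0.30,         1,   300,    NA
  )
}

#' Configuration of a synthetic pump-probe dataset
#'
#' @param delay_grid Strictly increasing pump-probe delays in fs. Default
#'   -20 to 60 fs in 1 fs steps, covering both dication time constants.
#' @param channels A channel table as in [default_channels()].
#' @param n_scans Number of repeated scans (default 7).
#' @param noise_sigma Relative noise level: per-point Gaussian standard
#'   deviation as a fraction of the channel's peak absolute model yield
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(delay_grid = seq(-20, 60, by = 1),
                           channels = default_channels(),
                           n_scans = 7, noise_sigma = 0.05, seed = 1) {
  if (any(diff(delay_grid) <= 0)) stop_invalid("delay grid must be strictly increasing")
  if (n_scans < 1) stop_invalid("n_scans must be >= 1")
  bad <- setdiff(channels$model, c("step_decay", "rise_decay"))
  if (length(bad))
    cond_error("chargemig_config_error", "unknown response model: ",
               paste(bad, collapse = ", "))
  structure(list(delay_grid = delay_grid, channels = channels,
                 n_scans = as.integer(n_scans), noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "dataset_config")
}

channel_curve <- function(ch, delay, sigma_irf) {
  if (ch$model == "step_decay") {
    model_step_decay(delay, ch$t0, ch$amplitude, ch$baseline, ch$tau1, sigma_irf)
  } else {
    model_rise_decay(delay, ch$t0, ch$amplitude, ch$baseline, ch$tau1, ch$tau2,
                     sigma_irf)
  }
}

#' Simulate a delay-resolved pump-probe dataset
#'
#' Evaluates each channel's response model on the delay grid (convolved
#' with the instrument response) and adds i.i.d. Gaussian noise per scan
#' and delay point. Bit-identical under a fixed seed.
#'
#' @param config A [dataset_config()].
#' @param irf An [instrument_response()] (or sigma in fs).
#' @return A tibble of class `delay_scan` with columns `scan`, `label`,
#'   `mz`, `delay_fs`, `yield`; the noiseless truth curves are attached as
#'   `attr(, "truth")` and the config as `attr(, "config")`.
#' @export
#' @examples
#' ds <- simulate_pumpprobe_dataset(dataset_config(seed = 1), irf_from_pulses(0.3, 4))
#' head(ds)
simulate_pumpprobe_dataset <- function(config, irf = irf_from_pulses(0.3, 4)) {
  if (inherits(irf, "instrument_response")) irf <- irf$sigma
  set.seed(config$seed)
  delay <- config$delay_grid
  truth <- purrr::map_dfr(seq_len(nrow(config$channels)), function(i) {
    ch <- config$channels[i, ]
    tibble::tibble(label = ch$label, mz = ch$mz, delay_fs = delay,
                   yield = channel_curve(ch, delay, irf))
  })
  out <- purrr::map_dfr(seq_len(config$n_scans), function(s) {
    d <- truth
    scale <- d |>
      dplyr::group_by(.data$label) |>
      dplyr::mutate(peak = max(abs(.data$yield))) |>
      dplyr::pull(.data$peak)
    d$yield <- d$yield +
      stats::rnorm(nrow(d), 0, config$noise_sigma * scale)
    d$scan <- s
    d
  })
  out <- out[, c("scan", "label", "mz", "delay_fs", "yield")]
  out <- tibble::new_tibble(out, class = "delay_scan")
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  attr(out, "sigma_irf") <- irf
  out
}

#' Per-scan traces of one channel
#'
#' @param scan A `delay_scan` (from [simulate_pumpprobe_dataset()]).
#' @param label Channel label, or `mz` value via `mz =`.
#' @param mz Alternative channel selector.
#' @return A list of per-scan trace tibbles (`delay_fs`, `yield`, `sem`),
#'   suitable for [average_scans()].
#' @export
channel_traces <- function(scan, label = NULL, mz = NULL) {
  sel <- if (!is.null(label)) scan$label == label
         else if (!is.null(mz)) abs(scan$mz - mz) < 1e-9
         else stop_invalid("give label or mz")
  d <- scan[sel, ]
  if (nrow(d) == 0) stop_invalid("no such channel")
  lapply(split(d, d$scan), function(x)
    tibble::tibble(delay_fs = x$delay_fs, yield = x$yield, sem = 0))
}

#' Simulate an NIR-intensity series of the dication yield
#'
#' `yield_i = c * I_i^n * (1 + eps_i)` with `eps_i ~ N(0, noise_rel^2)`:
#' the n-photon power law behind the quadratic intensity scaling of the
#' dication.
#'
#' @param n_photons Photon order (integer `>= 1`).
#' @param intensities Intensities in W/cm^2 (positive). Default 8 points
#'   spanning the explored 7e12 to 1.4e13 W/cm^2 range.
#' @param noise_rel Relative noise (default 0.05).
#' @param seed Integer seed.
#' @param scale Prefactor `c`.
#' @return A tibble with columns `intensity`, `yield`.
#' @export
simulate_intensity_series <- function(n_photons = 2,
                                      intensities = seq(7e12, 1.4e13, length.out = 8),
                                      noise_rel = 0.05, seed = 1, scale = 1e-26) {
  if (n_photons < 1) stop_invalid("n_photons must be >= 1")
  if (any(intensities <= 0)) stop_invalid("intensities must be positive")
  set.seed(seed)
  eps <- stats::rnorm(length(intensities), 0, noise_rel)
  tibble::tibble(intensity = intensities,
                 yield = scale * intensities^n_photons * (1 + eps))
}

#' Mass-to-charge ratio from a molecular formula
#'
#' @param formula Molecular formula, e.g. `"C5H5N5"` for adenine.
#' @param charge Charge state (`>= 1`).
#' @param mode `"nominal"` (integer isotope masses; exact arithmetic),
#'   `"monoisotopic"` or `"average"`.
#' @return m/z in u/e.
#' @export
#' @examples
#' mz_from_formula("C5H5N5", charge = 2)  # intact adenine dication: 67.5
mz_from_formula <- function(formula, charge = 1,
                            mode = c("nominal", "monoisotopic", "average")) {
  mode <- match.arg(mode)
  if (charge < 1) stop_invalid("charge must be >= 1")
  masses <- list(
    nominal      = c(C = 12, H = 1, N = 14, O = 16, S = 32, P = 31),
    monoisotopic = c(C = 12, H = 1.0078250319, N = 14.0030740052,
                     O = 15.9949146221, S = 31.97207069, P = 30.97376151),
    average      = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974)
  )[[mode]]
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop_invalid("cannot parse formula: ", formula)
  total <- 0
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- as.integer(gsub("[^0-9]", "", p))
    if (is.na(n)) n <- 1L
    if (!el %in% names(masses)) stop_invalid("unknown element: ", el)
    total <- total + n * masses[[el]]
  }
  total / charge
}
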