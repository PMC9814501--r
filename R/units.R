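# Unit conventions: fs and eV at every public interface, Hartree atomic
# units inside the propagators. Conversion constants are fixed once here.

#' Physical constants used throughout
#'
#' Fixed conversion constants: `hartree_ev` (1 Hartree in eV), `au_time_fs`
#' (1 atomic unit of time in fs), `hbar_ev_fs` (reduced Planck constant in
#' eV fs, the product of the former two), `intensity_au` (the atomic unit of
#' intensity in W/cm^2) and `nir_photon_ev` (the default 1.77 eV probe
#' photon energy).
#'
#' @format A named list of scalars.
#' @export
cm_constants <- list(
  hartree_ev   = 27.21139,
  au_time_fs   = 0.02418884,
  hbar_ev_fs   = 27.21139 * 0.02418884,
  intensity_au = 3.50945e16,
  nir_photon_ev = 1.77
)

ev_to_au <- function(e) e / cm_constants$hartree_ev
au_to_ev <- function(e) e * cm_constants$hartree_ev
fs_to_au <- function(t) t / cm_constants$au_time_fs
au_to_fs <- function(t) t * cm_constants$au_time_fs

# Scaled complementary error function exp(x^2) erfc(x), overflow-safe for
# large positive x (log-space via the normal upper tail).
erfcx <- function(x) {
  exp(log(2) + x * x + stats::pnorm(x * sqrt(2), lower.tail = FALSE, log.p = TRUE))
}

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("chargemig_invalid", "error")))
}

cond_error <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "chargemig_error", "error")))
}
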