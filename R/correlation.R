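#' Three-dark-state FCS correlation function
#'
#' Evaluates the model autocorrelation amplitude for free 3D diffusion through
#' a 3D-Gaussian detection volume combined with reversible transitions into
#' three dark states (protonated, triplet, redox):
#'
#' \deqn{G(\tau) = \frac{1}{N(1-P-T-R)}
#'   \left(1+\frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1+\frac{\tau}{\beta^2\tau_D}\right)^{-1/2}
#'   \left(1-P-T-R + P e^{-\tau/\tau_{prot}} + T e^{-\tau/\tau_T}
#'        + R e^{-\tau/\tau_R}\right) + 1}
#'
#' @param params An [fcs_params()] object.
#' @param tau Lag time(s) in seconds, `>= 0`; vectorized.
#' @return Numeric vector of correlation amplitudes `G(tau)`, same length as
#'   `tau`. `G` decays monotonically from `1/(N(1-P-T-R)) + 1` at zero lag to 1
#'   at long lags.
#' @examples
#' fcs_correlation(fcs_params(N = 1), tau = 0) # 2
#' @export
fcs_correlation <- function(params, tau) {
  validate_fcs_params(params)
  if (any(tau < 0)) stop("lag times must be >= 0", call. = FALSE)
  bright <- 1 - params$P - params$T - params$R
  diff_term <- fcs_diffusion_factor(tau, params$tau_D, params$beta)
  dark <- bright +
    params$P * exp(-tau / params$tau_prot) +
    params$T * exp(-tau / params$tau_T) +
    params$R * exp(-tau / params$tau_R)
  diff_term * dark / (params$N * bright) + 1
}

# 3D-Gaussian diffusion factor (1+tau/tau_D)^-1 (1+tau/(beta^2 tau_D))^-1/2
fcs_diffusion_factor <- function(tau, tau_D, beta) {
  (1 + tau / tau_D)^(-1) * (1 + tau / (beta^2 * tau_D))^(-1 / 2)
}

#' Evaluate the FCS model on a lag grid
#'
#' Vectorized convenience wrapper producing a curve tibble compatible with
#' [fit_fcs()].
#'
#' @param params An [fcs_params()] object.
#' @param lag_grid Strictly increasing, positive lag times (s). Defaults to the
#'   semi-log correlator emulation grid of [fcs_lag_grid()].
#' @param ... Metadata columns recycled along the curve (e.g. `curve_id`,
#'   `sample_id`, `ph`, `buffer_name`, `buffer_conc`, `mean_intensity`).
#' @return A tibble with columns `lag`, `g`, plus any metadata columns.
#' @examples
#' fcs_model_curve(fcs_params(N = 2, P = 0.3, tau_prot = 8e-6), curve_id = "a")
#' @export
fcs_model_curve <- function(params, lag_grid = fcs_lag_grid(), ...) {
  if (length(lag_grid) > 0) {
    if (any(lag_grid <= 0)) stop("lag grid must be positive", call. = FALSE)
    if (any(diff(lag_grid) <= 0)) {
      stop("lag grid must be strictly increasing", call. = FALSE)
    }
  }
  tibble::tibble(lag = as.numeric(lag_grid),
                 g = fcs_correlation(params, as.numeric(lag_grid)),
                 ...)
}

#' Default semi-log lag grid
#'
#' Log-spaced lag grid emulating the semi-log output of a hardware correlator.
#'
#' @param n Number of lags.
#' @param from,to Range of lag times (s).
#' @return Numeric vector of strictly increasing lags.
#' @export
fcs_lag_grid <- function(n = 128, from = 1e-7, to = 1) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Molecular brightness
#'
#' Mean detected fluorescence per actively fluorescing molecule: the recorded
#' average intensity divided by the average number of bright (non-dark)
#' fluorophores in the detection volume, `<F> / (N (1 - T - P - R))`.
#'
#' @param mean_intensity Average detected fluorescence intensity (counts/s),
#'   `>= 0`.
#' @param params An [fcs_params()] object supplying `N` and the dark fractions.
#' @return Brightness in counts/s per molecule.
#' @examples
#' molecular_brightness(1e5, fcs_params(N = 4, T = 0.25, P = 0.15, R = 0.10))
#' @export
molecular_brightness <- function(mean_intensity, params) {
  validate_fcs_params(params)
  if (any(mean_intensity < 0)) stop("mean_intensity must be >= 0", call. = FALSE)
  mean_intensity / (params$N * (1 - params$T - params$P - params$R))
}

#' Two-pKa titration curve
#'
#' Normalized molecular brightness of a compound with two protonatable groups
#' as a function of pH (sum of two logistic transitions plus an offset).
#' Strictly increasing in pH; tends to `c` at low pH and `1 + c` at high pH.
#'
#' @param tp A [titration_params()] object (or named list with `a`, `pKa1`,
#'   `pKa2`, `c`).
#' @param pH pH value(s); vectorized.
#' @return Numeric vector of normalized brightness values.
#' @examples
#' titration_value(titration_params(0.41, 6.8, 8.7), pH = seq(5, 10, 0.5))
#' @export
titration_value <- function(tp, pH) {
  tp$a / (1 + 10^(tp$pKa1 - pH)) + (1 - tp$a) / (1 + 10^(tp$pKa2 - pH)) + tp$c
}
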