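#' Two-state protonation equilibrium at a given pH
#'
#' Protonated (dark) fraction and protonation relaxation time implied by the
#' linear rate law: `k_prot = k_off + kappa_on [H+]`, `tau_prot = 1/k_prot`,
#' and `P = kappa_on [H+] / (kappa_on [H+] + k_off)` (the protonated form is
#' dark).
#'
#' @param kappa_on Protonation rate constant (1/(M s)).
#' @param k_off Deprotonation rate (1/s).
#' @param ph pH value(s); vectorized.
#' @return A tibble with columns `ph`, `P` and `tau_prot`.
#' @examples
#' protonation_at_ph(7.35e12, 5.28e4, ph = 8) # P ~ 0.58, tau_prot ~ 7.9 us
#' @export
protonation_at_ph <- function(kappa_on, k_off, ph) {
  check_positive(kappa_on = kappa_on)
  if (k_off < 0) stop("k_off must be >= 0", call. = FALSE)
  h <- 10^(-ph)
  k_on <- kappa_on * h
  tibble::tibble(ph = ph, P = k_on / (k_on + k_off),
                 tau_prot = 1 / (k_on + k_off))
}

assemble_params <- function(spec, ph) {
  eq <- protonation_at_ph(spec$kappa_on, spec$k_off, ph)
  fcs_params(N = spec$N, tau_D = spec$tau_D, beta = spec$beta,
             P = eq$P, tau_prot = eq$tau_prot,
             T = spec$T, tau_T = spec$tau_T,
             R = spec$R, tau_R = spec$tau_R)
}

#' Generate a synthetic FCS curve
#'
#' Evaluates the three-dark-state model at the protonation equilibrium for the
#' given pH and applies seeded multiplicative noise: each value becomes
#' `G * (1 + eps)` with `eps ~ Normal(0, sd)`, `sd = noise_eps *
#' (G - 1 + 0.05)` — amplitude-proportional with a floor of 0.05 so the
#' long-lag tail stays noisy, as in measured curves — truncated (clamped) at
#' five standard deviations. The same seed always reproduces the same curve,
#' independently of the caller's RNG state.
#'
#' @param spec A one-row sample tibble (see [fluorescein_samples()] /
#'   [sample_spec()]) with columns `sample_id`, `kappa_on`, `k_off`, `N`,
#'   `tau_D`, `beta`, `T`, `tau_T`, `R`, `tau_R`.
#' @param ph pH of the curve.
#' @param noise_eps Relative noise amplitude (0 gives the exact model curve).
#' @param lag_grid Lag times (s); default [fcs_lag_grid()].
#' @param seed Integer seed.
#' @param curve_id Identifier stored with the curve.
#' @return A curve tibble (`lag`, `g`, `curve_id`, `sample_id`, `ph`).
#' @export
generate_fcs_curve <- function(spec, ph, noise_eps = 0.02,
                               lag_grid = fcs_lag_grid(), seed = 1,
                               curve_id = paste0(spec$sample_id, "_pH", ph)) {
  if (noise_eps < 0) stop("noise_eps must be >= 0", call. = FALSE)
  params <- assemble_params(spec, ph)
  g0 <- fcs_correlation(params, lag_grid)
  g <- g0
  if (noise_eps > 0) {
    sd <- noise_eps * (g0 - 1 + 0.05)
    eps <- withr::with_seed(seed, stats::rnorm(length(g0), 0, sd))
    eps <- pmin(pmax(eps, -5 * sd), 5 * sd)
    g <- g0 * (1 + eps)
  }
  out <- tibble::tibble(lag = lag_grid, g = g, curve_id = curve_id,
                        sample_id = spec$sample_id, ph = ph)
  # per-point noise scale, usable as fitting weights (spec$weights = "g_sd"),
  # in the role of the error estimates hardware correlators report
  if (noise_eps > 0) out$g_sd <- noise_eps * (g0 - 1 + 0.05) * g0
  out
}

#' Generate a pH series of synthetic curves with a ground-truth manifest
#'
#' One curve per pH, all sharing the sample's photophysics and diffusion
#' parameters while `P` and `tau_prot` follow the protonation equilibrium —
#' the structure assumed by the global fitting protocol. The manifest records
#' the generating parameters per curve so that benchmarks never need to reach
#' into generator internals.
#'
#' @inheritParams generate_fcs_curve
#' @param ph_list pH values (>= 2).
#' @return A list with elements `curves` (stacked curve tibble) and `manifest`
#'   (list with the sample spec, per-curve ground truth tibble, `noise_eps`
#'   and `seed`).
#' @examples
#' s <- generate_ph_series(sample_spec("ND12-flu"), seq(8, 9, length.out = 5),
#'                         noise_eps = 0, seed = 1)
#' s$manifest$truth
#' @export
generate_ph_series <- function(spec, ph_list, noise_eps = 0.02, seed = 1,
                               lag_grid = fcs_lag_grid()) {
  if (length(ph_list) < 2) stop("need >= 2 pH values", call. = FALSE)
  curves <- purrr::map2_dfr(ph_list, seq_along(ph_list), function(ph, i) {
    generate_fcs_curve(spec, ph, noise_eps, lag_grid, seed = seed + i)
  })
  truth <- dplyr::mutate(protonation_at_ph(spec$kappa_on, spec$k_off, ph_list),
                         curve_id = paste0(spec$sample_id, "_pH", ph_list),
                         .before = 1)
  list(curves = curves,
       manifest = list(spec = spec, truth = truth,
                       noise_eps = noise_eps, seed = seed))
}

#' Generate a synthetic brightness titration series
#'
#' Normalized molecular brightness points following the two-pKa titration
#' curve of the sample, with seeded additive Gaussian noise of standard
#' deviation `noise_eps`.
#'
#' @inheritParams generate_ph_series
#' @return A list with `points` (tibble `ph`, `nmb`) and `manifest` (the
#'   generating [titration_params()], `noise_eps`, `seed`).
#' @export
generate_brightness_series <- function(spec, ph_list, noise_eps = 0.02,
                                       seed = 1) {
  if (length(ph_list) < 2) stop("need >= 2 pH values", call. = FALSE)
  if (is.na(spec$pKa1) || is.na(spec$pKa2)) {
    stop("sample `", spec$sample_id, "` has no bundled pKa pair", call. = FALSE)
  }
  tp <- titration_params(spec$a1, spec$pKa1, spec$pKa2, c = 0)
  nmb <- titration_value(tp, ph_list)
  if (noise_eps > 0) {
    nmb <- nmb + withr::with_seed(seed,
                                  stats::rnorm(length(ph_list), 0, noise_eps))
  }
  list(points = tibble::tibble(ph = ph_list, nmb = nmb),
       manifest = list(spec = spec, titration = tp,
                       noise_eps = noise_eps, seed = seed))
}
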