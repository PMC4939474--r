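#' Configuration for the three-pathway proton-exchange simulator
#'
#' Full parameterization of the kinetic Monte Carlo model of proton exchange
#' at a fluorophore-labeled nanodisc: bulk-surface exchange (pathway I,
#' adsorption at rate `k_ads * [H+]` and desorption at
#' `k_des0 + k_scav * buffer_conc`), 2D surface diffusion with capture by the
#' central fluorophore (pathway II), and direct bulk/buffer exchange with the
#' fluorophore (pathway III).
#'
#' @param disc_diameter Nanodisc diameter (nm).
#' @param a_f Capture radius of the central fluorophore (nm); default 0.5 nm,
#'   the order of a lipid headgroup.
#' @param D_s Surface proton diffusion coefficient (nm^2/s); default `2e7`
#'   (= 2e-7 cm^2/s).
#' @param k_des0 Intrinsic surface desorption rate `1/tau_s` (1/s); default
#'   `1e6` (dwell time ~1 us).
#' @param k_ads Surface adsorption rate constant for the whole disc
#'   (1/(M s)). The default is calibrated (see [calibrate_adsorption()]) so
#'   that the buffer-free 12-nm-disc simulation reproduces the measured
#'   `kappa_on` of membrane-anchored fluorescein, 7.35e12 1/(M s).
#' @param kappa_on_bulk Direct water-proton protonation rate constant of the
#'   dye (1/(M s)); default 4e10, the free-dye value.
#' @param k_off Intrinsic deprotonation rate of the dye (1/s).
#' @param ph Bulk pH; default 8.1 as in the buffer-series experiments.
#' @param buffer `NULL` (no buffer), a buffer name understood by
#'   [buffer_spec()], or a one-row tibble with columns `name`, `pKa`,
#'   `kappa_BH`, `kappa_B`, `k_scav`.
#' @param buffer_conc Total buffer concentration (M).
#' @param dt Surface diffusion time step (s). Must satisfy
#'   `dt * (k_des0 + k_scav * buffer_conc) < 0.1`.
#' @param min_events Minimum number of completed protonation and deprotonation
#'   events before stopping (>= 100).
#' @param t_max Maximum simulated time (s); reaching it first flags the result
#'   as under-converged.
#' @param seed Integer seed; identical configurations give bit-identical
#'   results.
#' @return A list of class `"mc_config"`.
#' @export
mc_config <- function(disc_diameter = 12, a_f = 0.5, D_s = 2e7,
                      k_des0 = 1e6, k_ads = 1.74e13,
                      kappa_on_bulk = 4e10, k_off = 5.28e4,
                      ph = 8.1, buffer = NULL, buffer_conc = 0,
                      dt = 1e-9, min_events = 2000, t_max = 30,
                      seed = 1) {
  if (is.character(buffer)) buffer <- buffer_spec(buffer)
  cfg <- list(disc_diameter = disc_diameter, a_f = a_f, D_s = D_s,
              k_des0 = k_des0, k_ads = k_ads,
              kappa_on_bulk = kappa_on_bulk, k_off = k_off,
              ph = ph, buffer = buffer, buffer_conc = buffer_conc,
              dt = dt, min_events = as.integer(min_events), t_max = t_max,
              seed = as.integer(seed))
  validate_mc_config(cfg)
  structure(cfg, class = "mc_config")
}

validate_mc_config <- function(cfg) {
  check_positive(disc_diameter = cfg$disc_diameter, a_f = cfg$a_f,
                 D_s = cfg$D_s, dt = cfg$dt, t_max = cfg$t_max)
  if (cfg$a_f >= cfg$disc_diameter / 2) {
    stop("capture radius a_f must be smaller than the disc radius",
         call. = FALSE)
  }
  if (cfg$k_des0 < 0 || cfg$k_ads < 0 || cfg$kappa_on_bulk < 0 ||
      cfg$k_off < 0 || cfg$buffer_conc < 0) {
    stop("rates and concentrations must be >= 0", call. = FALSE)
  }
  if (cfg$min_events < 100) stop("min_events must be >= 100", call. = FALSE)
  if (!is.null(cfg$buffer)) {
    b <- cfg$buffer
    need <- c("pKa", "kappa_BH", "kappa_B", "k_scav")
    if (!all(need %in% names(b))) {
      stop("buffer must have fields ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (b$pKa <= 0 || b$pKa >= 14) stop("buffer pKa must be in (0, 14)",
                                        call. = FALSE)
    if (b$kappa_BH < 0 || b$kappa_B < 0 || b$k_scav < 0) {
      stop("buffer rate constants must be >= 0", call. = FALSE)
    }
  }
  if (cfg$dt * mc_total_desorption(cfg) >= 0.1) {
    stop("dt * (k_des0 + k_scav * buffer_conc) must be < 0.1; ",
         "reduce dt (see sweep_buffer() for automatic adjustment)",
         call. = FALSE)
  }
  invisible(cfg)
}

mc_total_desorption <- function(cfg) {
  k_scav <- if (is.null(cfg$buffer)) 0 else cfg$buffer$k_scav
  cfg$k_des0 + k_scav * cfg$buffer_conc
}

# first-order rates seen by the dye and by the surface, from a config
mc_rates <- function(cfg) {
  h <- 10^(-cfg$ph)
  if (is.null(cfg$buffer) || cfg$buffer_conc == 0) {
    bh <- 0; bm <- 0
  } else {
    f <- buffer_protonated_fraction(cfg$ph, cfg$buffer$pKa)
    bh <- cfg$buffer_conc * f
    bm <- cfg$buffer_conc - bh
  }
  kBH <- if (is.null(cfg$buffer)) 0 else cfg$buffer$kappa_BH
  kB <- if (is.null(cfg$buffer)) 0 else cfg$buffer$kappa_B
  list(h = h,
       r_on_III = cfg$kappa_on_bulk * h + kBH * bh,
       r_off = cfg$k_off + kB * bm,
       k_des = mc_total_desorption(cfg),
       k_ads_rate = cfg$k_ads * h)
}

#' Run the three-pathway proton-exchange simulation
#'
#' Simulates the protonation state of a membrane-anchored fluorophore under
#' the event rules of the three-pathway model (see [mc_config()]) and returns
#' dwell-time estimators: `k_on_eff = 1/mean(deprotonated dwell)`,
#' `k_off_eff = 1/mean(protonated dwell)`, and the experimentally observable
#' protonation relaxation rate `k_prot = k_on_eff + k_off_eff`. Protonation
#' events are decomposed into surface capture (pathway II) and direct exchange
#' (pathway III). The Monte Carlo standard error of `k_prot` is estimated by a
#' per-dwell bootstrap.
#'
#' @param config An [mc_config()].
#' @param n_boot Bootstrap resamples for the standard error.
#' @return A one-row tibble with `k_on_eff`, `k_off_eff`, `k_prot`,
#'   `se_k_prot`, `frac_II`, `frac_III`, `rate_II`, `rate_III` (the pathway
#'   partial on-rates `frac * k_on_eff`), `n_events`, `t_sim` (sum of all
#'   completed dwells), `under_converged` and `seed`.
#' @examples
#' cfg <- mc_config(k_ads = 0, min_events = 200, seed = 42)
#' simulate_antenna(cfg) # pure two-state telegraph limit
#' @export
simulate_antenna <- function(config, n_boot = 200) {
  validate_mc_config(config)
  r <- mc_rates(config)
  out <- mc_simulate_cpp(R_disc = config$disc_diameter / 2, a_f = config$a_f,
                         D_s = config$D_s, k_des = r$k_des,
                         k_ads_rate = r$k_ads_rate,
                         r_on_III = r$r_on_III, r_off = r$r_off,
                         dt = config$dt, min_events = config$min_events,
                         t_max = config$t_max, seed = config$seed,
                         n_boot = as.integer(n_boot))
  n_on <- out$n_on_events
  frac_II <- if (n_on > 0) out$n_pathway_II / n_on else NA_real_
  tibble::tibble(
    k_on_eff = out$k_on_eff, k_off_eff = out$k_off_eff,
    k_prot = out$k_on_eff + out$k_off_eff,
    se_k_prot = out$se_k_prot,
    frac_II = frac_II, frac_III = 1 - frac_II,
    rate_II = frac_II * out$k_on_eff,
    rate_III = (1 - frac_II) * out$k_on_eff,
    n_events = n_on + out$n_off_events,
    t_sim = out$sum_deprot_dwell + out$sum_prot_dwell,
    under_converged = out$under_converged,
    seed = config$seed)
}

#' Capture probability of a surface proton
#'
#' Fraction of random walkers, started uniformly on the disc, that reach the
#' central capture radius before desorbing — the pathway II efficiency, and
#' the mean-field link between the adsorption flux and the effective
#' protonation rate.
#'
#' @param disc_radius Disc radius (nm).
#' @param a_f Capture radius (nm), `< disc_radius`.
#' @param D_s Surface diffusion coefficient (nm^2/s).
#' @param k_des Desorption rate (1/s); per-step desorption probability
#'   `k_des * dt`.
#' @param n_walkers Number of walkers.
#' @param dt Time step (s).
#' @param seed Integer seed.
#' @return A one-row tibble with `p`, `se` and `n_walkers`.
#' @export
capture_probability <- function(disc_radius, a_f, D_s, k_des,
                                n_walkers = 20000, dt = 1e-9, seed = 1) {
  check_positive(disc_radius = disc_radius, a_f = a_f, D_s = D_s, dt = dt)
  if (a_f >= disc_radius) stop("a_f must be < disc_radius", call. = FALSE)
  if (k_des < 0) stop("k_des must be >= 0", call. = FALSE)
  if (k_des * dt >= 0.1) stop("k_des * dt must be < 0.1", call. = FALSE)
  out <- mc_capture_prob_cpp(disc_radius, a_f, D_s, k_des,
                             as.integer(n_walkers), dt, seed,
                             max_steps = 1e7)
  tibble::as_tibble(out)
}

#' Calibrate the adsorption rate constant against a measured kappa_on
#'
#' Bisection on `k_ads` until the buffer-free simulated effective protonation
#' rate constant `k_on_eff / [H+]` matches a target second-order rate constant
#' (e.g. the measured `kappa_on` of a nanodisc sample) within `tol`. The seed
#' schedule is derived from the config seed, so the calibration is
#' deterministic.
#'
#' @param config A buffer-free [mc_config()].
#' @param target_kappa_on Target effective protonation rate constant
#'   (1/(M s)); must exceed `kappa_on_bulk` (otherwise no antenna flux is
#'   needed and `k_ads = 0` is returned).
#' @param tol Relative tolerance on the achieved value.
#' @param max_iter Maximum bisection iterations.
#' @param k_ads_max Upper bound of the search (1/(M s)); targets requiring a
#'   larger adsorption constant raise an error reporting the maximum
#'   achievable rate constant. The default is far above any plausible
#'   membrane proton flux.
#' @return A list with `k_ads`, `achieved_kappa_on`, `n_iter` and `history`
#'   (tibble of all evaluations).
#' @export
calibrate_adsorption <- function(config, target_kappa_on, tol = 0.05,
                                 max_iter = 40, k_ads_max = 1e15) {
  validate_mc_config(config)
  if (!is.null(config$buffer) && config$buffer_conc > 0) {
    stop("calibration requires a buffer-free config", call. = FALSE)
  }
  check_positive(target_kappa_on = target_kappa_on)
  h <- 10^(-config$ph)
  hist <- list()
  i <- 0L
  eval_kappa <- function(k_ads) {
    i <<- i + 1L
    cfg <- config
    cfg$k_ads <- k_ads
    cfg$seed <- config$seed + i
    res <- simulate_antenna(cfg)
    hist[[i]] <<- tibble::tibble(iter = i, k_ads = k_ads,
                                 kappa = res$k_on_eff / h)
    res$k_on_eff / h
  }
  if (target_kappa_on <= config$kappa_on_bulk * 1.0001) {
    return(list(k_ads = 0, achieved_kappa_on = config$kappa_on_bulk,
                n_iter = 0L, history = tibble::tibble()))
  }
  lo <- 0
  hi <- min(2 * (target_kappa_on - config$kappa_on_bulk), k_ads_max)
  k_hi <- eval_kappa(hi)
  # the effective rate constant is essentially linear in k_ads (independent
  # surface protons), so extrapolate the capture efficiency before expanding
  p_eff <- max((k_hi - config$kappa_on_bulk) / hi, 1e-12)
  if (config$kappa_on_bulk + k_ads_max * p_eff < target_kappa_on * 0.999 &&
      hi >= k_ads_max) {
    stop("target kappa_on unreachable below k_ads_max; maximum achievable ~",
         format(config$kappa_on_bulk + k_ads_max * p_eff, digits = 4),
         " 1/(M s)", call. = FALSE)
  }
  n_expand <- 0L
  while (k_hi < target_kappa_on && n_expand < 12L) {
    lo <- hi
    hi <- min(2 * hi, k_ads_max)
    n_expand <- n_expand + 1L
    k_hi <- eval_kappa(hi)
    if (hi >= k_ads_max && k_hi < target_kappa_on) break
  }
  if (k_hi < target_kappa_on) {
    stop("target kappa_on unreachable; maximum achieved ",
         format(k_hi, digits = 4), " 1/(M s) at k_ads = ",
         format(hi, digits = 4), call. = FALSE)
  }
  k_mid <- NA_real_
  mid <- hi
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    k_mid <- eval_kappa(mid)
    if (abs(k_mid - target_kappa_on) / target_kappa_on <= tol) break
    if (k_mid < target_kappa_on) lo <- mid else hi <- mid
  }
  list(k_ads = mid, achieved_kappa_on = k_mid, n_iter = i,
       history = dplyr::bind_rows(hist))
}

#' Sweep the buffer concentration
#'
#' Runs [simulate_antenna()] at each buffer concentration with a common seed
#' schedule, reporting the overall protonation relaxation rate together with
#' the pathway II and III partial on-rates. The time step is tightened
#' automatically where the buffer-enhanced desorption rate would violate the
#' step-probability bound (`dt * k_des < 0.05`).
#'
#' @param config An [mc_config()] with a buffer set.
#' @param concentrations Total buffer concentrations (M), sorted ascending.
#' @return A tibble of class `"antenna_sweep"`: one row per concentration with
#'   `conc` plus all [simulate_antenna()] columns.
#' @export
sweep_buffer <- function(config,
                         concentrations = 10^seq(log10(1e-4), log10(5e-2),
                                                 length.out = 12)) {
  validate_mc_config(config)
  if (is.null(config$buffer)) stop("config has no buffer", call. = FALSE)
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be sorted ascending", call. = FALSE)
  }
  rows <- purrr::imap(concentrations, function(conc, i) {
    cfg <- config
    cfg$buffer_conc <- conc
    cfg$seed <- config$seed + i
    k_des <- mc_total_desorption(cfg)
    cfg$dt <- min(config$dt, 0.05 / k_des)
    dplyr::bind_cols(tibble::tibble(conc = conc), simulate_antenna(cfg))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("antenna_sweep", class(out))
  out
}

#' Sweep the nanodisc diameter
#'
#' Runs one simulation per disc diameter at a fixed adsorption flux density:
#' the whole-disc adsorption constant is scaled in proportion to the membrane
#' area, `k_ads(d) = k_ads * (d / disc_diameter)^2`.
#'
#' @param config An [mc_config()]; its `k_ads`/`disc_diameter` pair defines
#'   the flux density.
#' @param diameters Disc diameters (nm), each `> 2 a_f`.
#' @return A tibble of class `"antenna_sweep"` with a `diameter` column plus
#'   all [simulate_antenna()] columns.
#' @export
sweep_disc_size <- function(config, diameters = c(8, 10, 12, 15, 18)) {
  validate_mc_config(config)
  if (any(diameters <= 2 * config$a_f)) {
    stop("diameters must exceed 2 * a_f", call. = FALSE)
  }
  rows <- purrr::imap(diameters, function(d, i) {
    cfg <- config
    cfg$disc_diameter <- d
    cfg$k_ads <- config$k_ads * (d / config$disc_diameter)^2
    cfg$seed <- config$seed + i
    dplyr::bind_cols(tibble::tibble(diameter = d), simulate_antenna(cfg))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("antenna_sweep", class(out))
  out
}
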