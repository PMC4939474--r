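test_that("config invariants are enforced", {
  expect_error(mc_config(a_f = 7, disc_diameter = 12), "capture radius")
  expect_error(mc_config(min_events = 50), "min_events")
  expect_error(mc_config(dt = 2e-7), "dt")
  expect_error(mc_config(buffer = "phosphate", buffer_conc = 0.05,
                         dt = 1e-9), "dt")
  expect_error(mc_config(buffer = "nope"), "unknown buffer")
})

test_that("with no surface pathway the simulator is a two-state telegraph", {
  h <- 10^-8.1
  cfg <- mc_config(k_ads = 0, min_events = 2000, seed = 42)
  r <- simulate_antenna(cfg)
  expect_equal(r$frac_III, 1)
  expect_equal(r$frac_II, 0)
  k_expected <- 4e10 * h + 5.28e4
  expect_lt(abs(r$k_prot - k_expected), 3 * r$se_k_prot)
})

test_that("dwell estimators agree with an independent Gillespie oracle", {
  h <- 10^-8.1
  r_on <- 4e10 * h
  r_off <- 5.28e4
  n <- 2000
  for (sd in 1:10) {
    r <- simulate_antenna(mc_config(k_ads = 0, min_events = n, seed = sd))
    o <- oracle_telegraph(r_on, r_off, n, seed = 500 + sd)
    se_on <- sqrt((r$k_on_eff / sqrt(n))^2 + o$se_k_on^2)
    se_off <- sqrt((r$k_off_eff / sqrt(n))^2 + o$se_k_off^2)
    expect_lt(abs(r$k_on_eff - o$k_on), 3 * se_on)
    expect_lt(abs(r$k_off_eff - o$k_off), 3 * se_off)
  }
})

test_that("event bookkeeping and dwell sums are exact", {
  cfg <- mc_config(buffer = "phosphate", buffer_conc = 1e-3,
                   min_events = 1000, seed = 5)
  r <- simulate_antenna(cfg)
  expect_equal(r$frac_II + r$frac_III, 1)
  expect_equal(r$k_prot, r$k_on_eff + r$k_off_eff)
  expect_equal(r$rate_II + r$rate_III, r$k_on_eff, tolerance = 1e-12)
  # n/k_on_eff + n/k_off_eff reconstructs the simulated time to machine
  # precision because the estimators are 1/mean(dwell)
  n_on <- r$n_events / 2
  expect_equal(n_on / r$k_on_eff + n_on / r$k_off_eff, r$t_sim,
               tolerance = 1e-12)
  expect_gt(r$se_k_prot, 0)
})

test_that("identical configurations give bit-identical results", {
  cfg <- mc_config(buffer = "phosphate", buffer_conc = 2e-3,
                   min_events = 500, seed = 77)
  expect_identical(simulate_antenna(cfg), simulate_antenna(cfg))
  cfg2 <- mc_config(buffer = "phosphate", buffer_conc = 2e-3,
                    min_events = 500, seed = 78)
  expect_false(identical(simulate_antenna(cfg)$k_prot,
                         simulate_antenna(cfg2)$k_prot))
})

test_that("reaching t_max before min_events flags the result", {
  cfg <- mc_config(k_ads = 0, min_events = 10000, t_max = 1e-3, seed = 1)
  r <- simulate_antenna(cfg)
  expect_true(r$under_converged)
})

test_that("buffer-driven protonation is linear in concentration", {
  # only the protonated-buffer pathway active: k_on_eff = kappa_BH [BH]
  buf <- tibble::tibble(name = "test", pKa = 7.2, kappa_BH = 3e7,
                        kappa_B = 0, k_scav = 0)
  cc <- seq(1e-3, 9e-3, length.out = 5)
  kon <- vapply(seq_along(cc), function(i) {
    cfg <- mc_config(k_ads = 0, kappa_on_bulk = 0, buffer = buf,
                     buffer_conc = cc[i], min_events = 2000, seed = 40 + i)
    simulate_antenna(cfg)$k_on_eff
  }, 0)
  fit <- stats::lm(kon ~ cc)
  expect_gt(summary(fit)$r.squared, 0.99)
  # slope matches kappa_BH * protonated fraction
  fBH <- buffer_protonated_fraction(8.1, 7.2)
  expect_equal(unname(stats::coef(fit)[2]), 3e7 * fBH, tolerance = 0.1)
})

test_that("capture probability has the right limits and no step-size bias", {
  # no desorption on a reflecting disc: eventual capture is certain
  p0 <- capture_probability(6, 0.5, 2e7, k_des = 0, n_walkers = 300, seed = 1)
  expect_equal(p0$p, 1)
  # desorption much faster than diffusion: capture almost never happens
  pfast <- capture_probability(6, 0.5, 2e7, k_des = 5e9, n_walkers = 2000,
                               dt = 1e-11, seed = 2)
  expect_lt(pfast$p, 0.02)
  # refinement: dt = 1e-9 and 2.5e-10 agree within 3 combined SE
  p1 <- capture_probability(6, 0.5, 2e7, 1e6, n_walkers = 20000, dt = 1e-9,
                            seed = 2)
  p2 <- capture_probability(6, 0.5, 2e7, 1e6, n_walkers = 20000, dt = 2.5e-10,
                            seed = 3)
  expect_lt(abs(p1$p - p2$p), 3 * sqrt(p1$se^2 + p2$se^2))
  # larger capture radius -> higher capture probability
  pbig <- capture_probability(6, 1.0, 2e7, 1e6, n_walkers = 20000, seed = 4)
  expect_gt(pbig$p, p1$p)
})

test_that("zero-buffer protonation matches the mean-field adsorption picture", {
  h <- 10^-8.1
  cfg <- mc_config(min_events = 20000, seed = 9)
  r <- simulate_antenna(cfg)
  pc <- capture_probability(6, 0.5, 2e7, 1e6, n_walkers = 50000, seed = 5)
  predicted <- cfg$kappa_on_bulk * h + cfg$k_ads * h * pc$p
  expect_lt(abs(r$k_on_eff - predicted) / predicted, 0.10)
})

test_that("adsorption calibration reaches its target and responds to geometry", {
  # no antenna needed when the target equals the bulk rate constant
  cfg <- mc_config(min_events = 2000, seed = 31)
  cal0 <- calibrate_adsorption(cfg, target_kappa_on = 4e10)
  expect_equal(cal0$k_ads, 0)
  # closed loop at the measured 12-nm value
  cal <- calibrate_adsorption(cfg, target_kappa_on = 7.35e12)
  expect_gt(cal$k_ads, 0)
  cfg2 <- cfg
  cfg2$k_ads <- cal$k_ads
  cfg2$min_events <- 10000
  r <- simulate_antenna(cfg2)
  expect_lt(abs(r$k_on_eff / 10^-8.1 - 7.35e12) / 7.35e12, 0.10)
  # doubling the capture radius lowers the required adsorption constant
  cfg_big <- mc_config(a_f = 1.0, min_events = 2000, seed = 31)
  cal_big <- calibrate_adsorption(cfg_big, target_kappa_on = 7.35e12)
  expect_lt(cal_big$k_ads, cal$k_ads)
  expect_error(calibrate_adsorption(cfg, target_kappa_on = 1e18),
               "unreachable")
})

test_that("buffer sweeps decompose pathways and disc sweeps scale the flux", {
  cfg <- mc_config(buffer = "phosphate", min_events = 4000, seed = 13)
  sw <- sweep_buffer(cfg, concentrations = 10^seq(-4, log10(0.05),
                                                  length.out = 8))
  expect_equal(nrow(sw), 8)
  expect_true(all(abs(sw$frac_II + sw$frac_III - 1) < 1e-12))
  # pathway II partial rate monotone non-increasing within noise
  expect_true(all(diff(sw$rate_II) < 3 * max(sw$se_k_prot)))
  # pathway III partial rate linear in concentration
  fit <- stats::lm(rate_III ~ conc, data = sw)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_error(sweep_buffer(cfg, c(2e-3, 1e-3)), "ascending")
  # disc sweep: area-proportional adsorption, k_on_eff grows with diameter
  ds <- sweep_disc_size(mc_config(min_events = 4000, seed = 3),
                        diameters = c(8, 12, 18))
  expect_true(all(diff(ds$k_on_eff) > 0))
  expect_error(sweep_disc_size(mc_config(), diameters = c(0.8, 12)),
               "exceed")
})

test_that("a tiny disc approaches the adsorption-limited protonation rate", {
  # diameter barely above the capture diameter: every adsorbed proton is
  # captured essentially instantly while the dye is deprotonated
  h <- 10^-8.1
  cfg <- mc_config(disc_diameter = 1.4, a_f = 0.5, k_ads = 1e12,
                   kappa_on_bulk = 0, min_events = 4000, seed = 8)
  r <- simulate_antenna(cfg)
  expect_lt(abs(r$k_on_eff - 1e12 * h) / (1e12 * h), 0.10)
  expect_equal(r$frac_II, 1)
})
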