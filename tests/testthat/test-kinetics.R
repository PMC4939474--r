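test_that("kprot_points pairs 1/tau_prot with [H+] in order", {
  tbl <- tibble::tibble(curve_id = c("a", "b"), tau_prot = c(7.9e-6, 1e-5),
                        ph = c(8, 9))
  pts <- kprot_points(tbl)
  expect_equal(pts$h_conc, c(1e-8, 1e-9))
  expect_equal(pts$k_prot, 1 / c(7.9e-6, 1e-5))
  expect_equal(pts$curve_id, c("a", "b"))
  # Table-1-style arithmetic: k_prot at pH 9 and 8 for kappa_on = 7.35e12
  eq <- protonation_at_ph(7.35e12, 5.28e4, c(9, 8))
  pts2 <- kprot_points(tibble::tibble(curve_id = c("p9", "p8"),
                                      tau_prot = eq$tau_prot, ph = c(9, 8)))
  expect_equal(pts2$k_prot, c(6.015e4, 1.263e5), tolerance = 1e-3)
  expect_error(kprot_points(tibble::tibble(curve_id = "x", tau_prot = 1e-5,
                                           ph = NA_real_)), "x")
})

test_that("rate-law regression recovers exact lines and reports exclusions", {
  h <- c(1, 2, 5, 10) * 1e-9
  pts <- tibble::tibble(h_conc = h, k_prot = 6.72e4 + 7.54e12 * h)
  fit <- fit_protonation(pts, h_max = 1e-8)
  expect_equal(fit$kappa_on, 7.54e12, tolerance = 1e-9)
  expect_equal(fit$k_off, 6.72e4, tolerance = 1e-9)
  expect_equal(fit$n_points, 4L)
  # two points give the exact interpolating line
  fit2 <- fit_protonation(pts[c(1, 4), ], h_max = 1e-8)
  expect_equal(fit2$kappa_on, 7.54e12, tolerance = 1e-12)
  # points above h_max are excluded and counted
  pts3 <- dplyr::bind_rows(pts, tibble::tibble(h_conc = 1e-6, k_prot = 1e9))
  fit3 <- fit_protonation(pts3, h_max = 1e-8)
  expect_equal(fit3$n_excluded, 1L)
  expect_equal(fit3$kappa_on, 7.54e12, tolerance = 1e-9)
  expect_error(fit_protonation(pts[1, ], h_max = 1e-8), ">= 2 points")
})

test_that("noisy rate-law regression recovers the slope within 15%", {
  withr::with_seed(42, {
    h <- seq(1e-9, 1e-8, length.out = 8)
    k_true <- 5.28e4 + 7.35e12 * h
    pts <- tibble::tibble(h_conc = h,
                          k_prot = k_true * (1 + rnorm(8, 0, 0.05)))
  })
  fit <- fit_protonation(pts, h_max = 1e-8)
  expect_lt(abs(fit$kappa_on - 7.35e12) / 7.35e12, 0.15)
  expect_gt(fit$se_kappa_on, 0)
})

test_that("negative intercepts are reported with a warning, not clamped", {
  pts <- tibble::tibble(h_conc = c(1e-9, 1e-8), k_prot = c(1e3, 1e5))
  expect_warning(fit <- fit_protonation(pts, h_max = 1e-8), "negative")
  expect_true(fit$negative_intercept)
  expect_lt(fit$k_off, 0)
})

test_that("titration fit recovers a noiseless two-pKa curve", {
  tp <- titration_params(0.41, 6.8, 8.7, c = 0)
  ph <- seq(5, 10, 0.25)
  fit <- fit_titration(tibble::tibble(ph = ph, nmb = titration_value(tp, ph)))
  expect_equal(fit$params$a, 0.41, tolerance = 1e-3)
  expect_equal(fit$params$pKa1, 6.8, tolerance = 1e-3)
  expect_equal(fit$params$pKa2, 8.7, tolerance = 1e-3)
  expect_lt(abs(fit$params$c), 1e-3)
  expect_true(fit$converged)
  expect_lte(fit$params$pKa1, fit$params$pKa2) # ordering convention
})

test_that("degenerate and reduced titration inputs are handled", {
  ph <- seq(5, 10, 0.5)
  fit <- fit_titration(tibble::tibble(ph = ph, nmb = rep(0.3, length(ph))))
  expect_true(fit$degenerate)
  # a = 0 data reduce to a single-site titration recovered via pKa2
  tp0 <- titration_params(0, 6, 8.2, c = 0)
  fit0 <- fit_titration(tibble::tibble(ph = ph,
                                       nmb = titration_value(tp0, ph)))
  expect_equal(fit0$params$pKa2, 8.2, tolerance = 1e-3)
  expect_lt(fit0$params$a, 0.01)
  expect_error(fit_titration(tibble::tibble(ph = c(7, 7.1, 7.2, 7.3),
                                            nmb = 1:4 / 4)), "span")
  expect_error(fit_titration(tibble::tibble(ph = c(5, 9), nmb = c(0, 1))),
               ">= 4")
})

test_that("antenna geometry relations are mutually inverse and scale correctly", {
  expect_equal(antenna_radius(D_s = 2e7, tau_s = 1e-6), sqrt(2 * 2e7 * 1e-6 / pi))
  expect_equal(round(antenna_radius(2e7, 1e-6), 2), 3.57)
  expect_equal(dwell_time(R_PCA = 5, D_s = 2e7), pi * 25 / (4e7))
  expect_equal(signif(dwell_time(5, 2e7), 3), 1.96e-6)
  withr::with_seed(5, {
    for (i in 1:20) {
      D <- 10^runif(1, 5, 9); tau <- 10^runif(1, -8, -4)
      expect_equal(dwell_time(antenna_radius(D, tau), D), tau,
                   tolerance = 1e-12)
    }
  })
  # quadrupling the dwell time doubles the antenna radius
  expect_equal(antenna_radius(2e7, 4e-6) / antenna_radius(2e7, 1e-6), 2)
  expect_error(antenna_radius(-1, 1e-6), "positive")
})

test_that("membrane-area arithmetic reproduces the printed disc and annulus areas", {
  expect_equal(disc_area(9), pi * 81 / 4)
  expect_equal(round(disc_area(9), 1), 63.6)
  expect_equal(round(annulus_area(12, 6.5), 1), 79.9)
  expect_equal(round(annulus_area(9, 6.5), 1), 30.4)
  expect_equal(round(disc_area(12)), 113)
  expect_error(annulus_area(6, 6.5), "smaller")
})

test_that("rate-constant fold changes match the reported enhancement factors", {
  expect_equal(fold_change(3.1e13, 7.71e12), 4.02, tolerance = 1e-3)
  expect_equal(fold_change(7.71e12, 1.44e11), 53.5, tolerance = 1e-2)
  expect_equal(fold_change(2, 2), 1)
  expect_error(fold_change(0, 1), "positive")
  # every nanodisc-anchored kappa_on exceeds the free-dye value >100-fold
  tbl <- fluorescein_samples()
  flu <- tbl$kappa_on[tbl$sample_id == "flu-water"]
  for (sid in c("ND9-flu", "ND12-flu", "ND12-CytcO-flu")) {
    expect_gt(fold_change(tbl$kappa_on[tbl$sample_id == sid], flu), 100)
  }
})

test_that("replicate summaries give mean and sd per column", {
  d <- tibble::tibble(kappa_on = c(7e12, 7.5e12, 8e12))
  out <- summarize_replicates(d, kappa_on)
  expect_equal(out$mean_kappa_on, 7.5e12)
  expect_equal(out$sd_kappa_on, stats::sd(d$kappa_on))
})
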