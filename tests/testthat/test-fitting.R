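nm_all <- c("N", "tau_D", "beta", "P", "tau_prot", "T", "tau_T", "R", "tau_R")

test_that("fit spec partitions parameters and validates bounds", {
  sp <- fit_spec()
  expect_setequal(c(sp$shared, sp$per_curve), nm_all)
  sp2 <- fit_spec(fixed = list(beta = 5))
  expect_false("beta" %in% c(sp2$shared, sp2$per_curve))
  expect_error(fit_spec(shared = "N"), "shared and per-curve")
  expect_error(fit_spec(shared = "tau_D", per_curve = "N"), "exactly one")
  expect_error(fit_spec(bounds = list(P = c(0.5, 0.2))), "lo < hi")
  expect_error(fit_spec(shared = "bogus"), "unknown")
})

test_that("triplet bounds are installed and intersected", {
  sp <- apply_triplet_bounds(fit_spec())
  expect_equal(sp$bounds$tau_T, c(1.4e-6, 1.5e-6))
  expect_equal(sp$bounds$T, c(0.24, 0.28))
  # a pre-existing tighter bound is kept
  sp2 <- apply_triplet_bounds(fit_spec(bounds = list(tau_T = c(1.42e-6, 2e-6))))
  expect_equal(sp2$bounds$tau_T, c(1.42e-6, 1.5e-6))
})

test_that("noiseless single-curve fit recovers parameters from a perturbed start", {
  p <- fcs_params(N = 2, tau_D = 4e-4, beta = 5, P = 0.3, tau_prot = 8e-6,
                  T = 0.26, tau_T = 1.45e-6, R = 0.05, tau_R = 5e-5)
  d <- fcs_model_curve(p, curve_id = "c1")
  init <- do.call(fcs_params, as.list(unlist(p[nm_all]) * 1.5))
  f <- fit_fcs(d, init = init)
  est <- unlist(f$params[1, nm_all])
  expect_true(all(abs(est - unlist(p[nm_all])) / unlist(p[nm_all]) < 1e-3))
  expect_true(f$converged)
  # refitting from the solution does not materially lower the cost
  f2 <- fit_fcs(d, init = do.call(fcs_params, as.list(est)))
  expect_lte(f$cost - f2$cost, 1e-8 * max(f$cost, 1e-12))
})

test_that("pure-diffusion curves give exact (N, tau_D) recovery", {
  p0 <- fcs_params(N = 3, tau_D = 2e-4, beta = 5)
  d0 <- fcs_model_curve(p0, curve_id = "c0")
  sp <- fit_spec(fixed = list(P = 0, T = 0, R = 0, beta = 5, tau_prot = 5e-6,
                              tau_T = 1.5e-6, tau_R = 5e-5),
                 per_curve = c("N", "tau_D"), shared = character(0))
  f <- fit_fcs(d0, sp)
  expect_equal(f$params$N, 3, tolerance = 1e-6)
  expect_equal(f$params$tau_D, 2e-4, tolerance = 1e-6)
})

test_that("underdetermined or degenerate curves are rejected", {
  p <- fcs_params()
  d_small <- fcs_model_curve(p, fcs_lag_grid(5))
  expect_error(fit_fcs(d_small), "fewer")
  d_const <- tibble::tibble(lag = fcs_lag_grid(30), g = 1.5)
  expect_error(fit_fcs(d_const, fit_spec(fixed = list(
    beta = 5, T = 0, tau_T = 1e-6, R = 0, tau_R = 1e-5, P = 0,
    tau_prot = 1e-5), per_curve = c("N", "tau_D"), shared = character(0))),
    "degenerate")
})

test_that("global fit of a noiseless pH series recovers every parameter", {
  spec <- sample_spec("ND12-flu")
  s <- generate_ph_series(spec, seq(8, 9, length.out = 10), noise_eps = 0,
                          seed = 1)
  f <- fit_fcs(s$curves, apply_triplet_bounds(fit_spec(fixed = list(beta = 5))))
  tr <- s$manifest$truth
  expect_true(all(abs(f$params$tau_prot - tr$tau_prot) / tr$tau_prot < 1e-3))
  expect_true(all(abs(f$params$P - tr$P) / tr$P < 1e-3))
  expect_equal(unname(f$shared["tau_D"]), spec$tau_D, tolerance = 1e-3)
  expect_equal(unname(f$shared["T"]), spec$T, tolerance = 1e-3)
  expect_equal(unname(f$shared["tau_R"]), spec$tau_R, tolerance = 1e-3)
  # shared parameters are identical across curves by construction
  expect_equal(length(unique(f$params$tau_D)), 1L)
})

test_that("noisy series recovery meets the pilot-calibrated tolerances", {
  # 2% multiplicative noise, fixed seed; tolerances fixed by pilot runs of
  # the generator at these study conditions
  spec <- sample_spec("ND12-flu")
  s <- generate_ph_series(spec, seq(8, 9, length.out = 10), noise_eps = 0.02,
                          seed = 1)
  f <- fit_fcs(s$curves, apply_triplet_bounds(
    fit_spec(fixed = list(beta = 5), weights = "g_sd")))
  tr <- s$manifest$truth
  e_tp <- abs(f$params$tau_prot - tr$tau_prot) / tr$tau_prot
  e_P <- abs(f$params$P - tr$P) / tr$P
  expect_lt(stats::median(e_tp), 0.10)
  expect_gte(sum(e_tp < 0.25), 9)
  expect_gte(sum(e_P < 0.15), 9)
})

test_that("global cost is invariant under curve reordering", {
  spec <- sample_spec("ND12-flu")
  s <- generate_ph_series(spec, c(8, 8.5, 9), noise_eps = 0.01, seed = 4)
  sp <- apply_triplet_bounds(fit_spec(fixed = list(beta = 5), weights = "g_sd"))
  f1 <- fit_fcs(s$curves, sp)
  rev_ids <- rev(unique(s$curves$curve_id))
  curves_rev <- dplyr::bind_rows(lapply(rev_ids, function(id) {
    s$curves[s$curves$curve_id == id, ]
  }))
  f2 <- fit_fcs(curves_rev, sp)
  expect_equal(f1$cost, f2$cost, tolerance = 1e-6)
})

test_that("a fully per-curve global fit reproduces independent single fits", {
  spec <- sample_spec("ND12-flu")
  s <- generate_ph_series(spec, c(8.2, 8.8), noise_eps = 0, seed = 2)
  sp <- fit_spec(shared = character(0),
                 per_curve = setdiff(nm_all, "beta"),
                 fixed = list(beta = 5))
  f_joint <- fit_fcs(s$curves, sp)
  costs <- vapply(unique(s$curves$curve_id), function(id) {
    fit_fcs(s$curves[s$curves$curve_id == id, ], sp)$cost
  }, 0)
  expect_equal(f_joint$cost, sum(costs), tolerance = 1e-6)
})

test_that("fits honor the triplet box constraints", {
  spec <- sample_spec("ND12-flu") # generator triplet fraction 0.26
  s <- generate_ph_series(spec, c(8, 8.5, 9), noise_eps = 0.02, seed = 3)
  f <- fit_fcs(s$curves, apply_triplet_bounds(
    fit_spec(fixed = list(beta = 5), weights = "g_sd")))
  # tiny slack for the log-scale round trip at the box edge
  expect_true(all(f$params$T >= 0.24 - 1e-9 & f$params$T <= 0.28 + 1e-9))
  expect_true(all(f$params$tau_T >= 1.4e-6 * (1 - 1e-9) &
                    f$params$tau_T <= 1.5e-6 * (1 + 1e-9)))
})

test_that("parameter-recovery bias is below 5% in the median over replicates", {
  spec <- sample_spec("ND12-flu")
  sp <- apply_triplet_bounds(fit_spec(fixed = list(beta = 5),
                                      weights = "g_sd"))
  bias_tp <- bias_P <- c()
  for (k in 1:20) {
    s <- generate_ph_series(spec, seq(8, 9, length.out = 10),
                            noise_eps = 0.02, seed = 1000 + 17 * k)
    f <- fit_fcs(s$curves, sp)
    tr <- s$manifest$truth
    bias_tp <- c(bias_tp, (f$params$tau_prot - tr$tau_prot) / tr$tau_prot)
    bias_P <- c(bias_P, (f$params$P - tr$P) / tr$P)
  }
  expect_lt(abs(stats::median(bias_tp)), 0.05)
  expect_lt(abs(stats::median(bias_P)), 0.05)
})

test_that("tidy/glance/augment expose the fit in tabular form", {
  p <- fcs_params(N = 2, tau_D = 4e-4, P = 0.3, tau_prot = 8e-6,
                  T = 0.26, R = 0.05)
  d <- fcs_model_curve(p, curve_id = "c1")
  f <- fit_fcs(d, init = do.call(fcs_params,
                                 as.list(unlist(p[nm_all]) * 1.2)))
  td <- tidy(f)
  expect_setequal(unique(td$term), nm_all)
  expect_true(all(c("estimate", "std.error", "role") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$n_points, 128L)
  aug <- augment(f)
  expect_equal(aug$g - aug$.fitted, aug$.resid)
})
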