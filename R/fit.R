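#' Fit the FCS model to one curve or globally to a curve series
#'
#' Weighted Levenberg-Marquardt least-squares fitting of the three-dark-state
#' FCS model. With a single curve this is an ordinary per-curve fit; with
#' several curves (distinguished by a `curve_id` column) the parameters listed
#' as `shared` in the [fit_spec()] are estimated jointly across all curves in
#' one optimization, while `per_curve` parameters vary freely per curve —
#' the global-analysis protocol for pH and buffer series, where diffusion and
#' triplet/redox photophysics do not change between conditions.
#'
#' Scale parameters (`N`, the relaxation times, `beta`) are optimized on a
#' log10 scale; the dark fractions are optimized linearly under their box
#' constraints. When no `init` is given, starting values are derived from the
#' data and refined by per-curve prefits with a coarse multistart over
#' `tau_prot` (see Details); the full optimization is then iterated with
#' per-curve polish steps until the cost stops improving.
#'
#' @param data Tibble of correlation data with numeric columns `lag` (s,
#'   strictly increasing within a curve) and `g`, an optional `curve_id`
#'   column, and optional metadata columns (`ph`, `buffer_name`, `buffer_conc`,
#'   `mean_intensity`, `sample_id`, `g_sd`) carried through to the result.
#' @param spec An [fit_spec()]; defaults to shared photophysics/diffusion and
#'   per-curve `N`, `P`, `tau_prot`.
#' @param init An [fcs_params()] used as the common starting point, or `NULL`
#'   for staged data-driven initialization.
#' @param control Passed to [minpack.lm::nls.lm.control()]; defaults to
#'   `ftol = 1e-10`, `maxiter = 1000`.
#' @param max_polish Maximum number of polish cycles of the auto-initialized
#'   fit (ignored when `init` is supplied).
#' @return An object of class `"fcs_fit"`. Use [tidy()][generics::tidy] for the
#'   per-curve parameter table with standard errors, [glance()][generics::glance]
#'   for the fit summary, and [augment()][generics::augment] for fitted values
#'   and residuals. The element `shared` holds the joint parameter estimates.
#' @examples
#' p <- fcs_params(N = 2, tau_D = 2e-4, P = 0.3, tau_prot = 8e-6,
#'                 T = 0.26, R = 0.05)
#' d <- fcs_model_curve(p, curve_id = "c1")
#' f <- fit_fcs(d)
#' glance(f)
#' @export
fit_fcs <- function(data, spec = fit_spec(), init = NULL,
                    control = minpack.lm::nls.lm.control(ftol = 1e-10,
                                                         maxiter = 1000),
                    max_polish = 2) {
  stopifnot(inherits(spec, "fcs_fit_spec"))
  data <- tibble::as_tibble(data)
  if (!all(c("lag", "g") %in% names(data))) {
    stop("data must have columns `lag` and `g`", call. = FALSE)
  }
  if (!"curve_id" %in% names(data)) data$curve_id <- "curve_1"
  ids <- unique(data$curve_id)
  curves <- lapply(ids, function(id) data[data$curve_id == id, , drop = FALSE])
  names(curves) <- ids
  for (id in ids) {
    cv <- curves[[id]]
    if (nrow(cv) == 0) stop("empty curve ", id, call. = FALSE)
    if (any(!is.finite(cv$lag)) || any(!is.finite(cv$g))) {
      stop("non-finite data in curve ", id, call. = FALSE)
    }
    if (any(cv$lag <= 0) || any(diff(cv$lag) <= 0)) {
      stop("lags must be positive and strictly increasing in curve ", id,
           call. = FALSE)
    }
    if (stats::sd(cv$g) == 0) {
      stop("degenerate (constant) correlation values in curve ", id,
           call. = FALSE)
    }
  }

  n_curves <- length(ids)
  free_shared <- spec$shared
  free_pc <- spec$per_curve
  n_free <- length(free_shared) + n_curves * length(free_pc)
  n_points <- nrow(data)
  if (n_points < n_free) {
    stop("fewer data points (", n_points, ") than free parameters (", n_free,
         ")", call. = FALSE)
  }
  if (n_curves == 1 && nrow(curves[[1]]) < n_free) {
    stop("curve has fewer points than free parameters", call. = FALSE)
  }

  # weights: per-point standard deviations -> 1/sd multipliers
  wts <- lapply(curves, function(cv) {
    if (is.null(spec$weights)) rep(1, nrow(cv))
    else {
      if (!spec$weights %in% names(cv)) {
        stop("weight column `", spec$weights, "` not found", call. = FALSE)
      }
      sd <- cv[[spec$weights]]
      if (any(!is.finite(sd)) || any(sd <= 0)) {
        stop("per-point standard deviations must be positive", call. = FALSE)
      }
      1 / sd
    }
  })

  # starting values ----------------------------------------------------------
  auto <- is.null(init)
  if (auto) {
    init_list <- staged_init(curves, wts, spec, control)
  } else {
    validate_fcs_params(init)
    init_list <- rep(list(unlist(init[fcs_param_names()])), n_curves)
  }

  fit <- global_lm(curves, wts, spec, init_list, control)
  if (auto && n_curves > 1) {
    for (cycle in seq_len(max_polish)) {
      prev <- fit$cost
      polished <- polish_init(curves, wts, spec, fit, control)
      refit <- global_lm(curves, wts, spec, polished, control)
      if (refit$cost < fit$cost) fit <- refit
      if (prev - refit$cost <= 1e-3 * prev) break
    }
  }

  par_hat <- fit$par_hat
  cost <- fit$cost
  assemble <- fit$assemble
  n_sh <- length(free_shared)
  n_pc <- length(free_pc)

  # linearized standard errors from a forward-difference Jacobian ------------
  se <- rep(NA_real_, length(par_hat))
  if (n_points > n_free && n_free > 0) {
    J <- num_jacobian(fit$resid_fn, par_hat)
    cv_mat <- try(solve(crossprod(J)), silent = TRUE)
    if (!inherits(cv_mat, "try-error")) {
      s2 <- cost / (n_points - n_free)
      se <- sqrt(pmax(diag(cv_mat) * s2, 0))
    }
  }

  shared_est <- stats::setNames(par_hat[seq_len(n_sh)], free_shared)
  shared_se <- stats::setNames(se[seq_len(n_sh)], free_shared)

  par_rows <- lapply(seq_len(n_curves), function(j) {
    tibble::as_tibble(assemble(par_hat, j)[fcs_param_names()])
  })
  params_tbl <- dplyr::bind_cols(tibble::tibble(curve_id = ids),
                                 dplyr::bind_rows(par_rows))
  se_rows <- lapply(seq_len(n_curves), function(j) {
    v <- stats::setNames(rep(NA_real_, 9), fcs_param_names())
    v[free_shared] <- shared_se
    if (n_pc > 0) v[free_pc] <- se[n_sh + (j - 1L) * n_pc + seq_len(n_pc)]
    tibble::as_tibble(as.list(v))
  })
  se_tbl <- dplyr::bind_cols(tibble::tibble(curve_id = ids),
                             dplyr::bind_rows(se_rows))

  fitted <- unlist(lapply(seq_len(n_curves), function(j) {
    fcs_model_eval(assemble(par_hat, j), curves[[j]]$lag)
  }), use.names = FALSE)
  data_out <- dplyr::bind_rows(curves)
  data_out$.fitted <- fitted
  data_out$.resid <- data_out$g - fitted

  # per-curve metadata: columns constant within every curve (drops per-point
  # columns such as the weight column)
  meta_cols <- setdiff(names(data), c("lag", "g", ".fitted", ".resid"))
  constant <- vapply(meta_cols, function(nm) {
    all(vapply(curves, function(cv) length(unique(cv[[nm]])) == 1L, TRUE))
  }, TRUE)
  meta <- dplyr::distinct(dplyr::select(data_out,
                                        dplyr::all_of(meta_cols[constant])))

  structure(list(params = params_tbl, stderr = se_tbl,
                 shared = shared_est, shared_se = shared_se,
                 spec = spec, cost = cost, converged = fit$converged,
                 info = fit$info, message = fit$message,
                 n_iter = fit$n_iter, n_curves = n_curves,
                 n_points = n_points, n_free = n_free,
                 data = data_out, meta = meta),
            class = "fcs_fit")
}

# one joint Levenberg-Marquardt solve over shared + per-curve parameters
global_lm <- function(curves, wts, spec, init_list, control) {
  free_shared <- spec$shared
  free_pc <- spec$per_curve
  n_curves <- length(curves)
  n_sh <- length(free_shared)
  n_pc <- length(free_pc)

  start_shared <- if (n_sh > 0) init_list[[1]][free_shared] else numeric(0)
  start_pc <- unlist(lapply(init_list, function(v) v[free_pc]),
                     use.names = FALSE)
  par0 <- c(start_shared, start_pc)
  lower <- c(vapply(free_shared, function(nm) spec$bounds[[nm]][1], 0),
             rep(vapply(free_pc, function(nm) spec$bounds[[nm]][1], 0),
                 n_curves))
  upper <- c(vapply(free_shared, function(nm) spec$bounds[[nm]][2], 0),
             rep(vapply(free_pc, function(nm) spec$bounds[[nm]][2], 0),
                 n_curves))
  par0 <- pmin(pmax(par0, lower), upper)

  assemble <- function(par, j) {
    p <- spec$fixed
    if (n_sh > 0) p[free_shared] <- par[seq_len(n_sh)]
    if (n_pc > 0) p[free_pc] <- par[n_sh + (j - 1L) * n_pc + seq_len(n_pc)]
    p
  }
  resid_fn <- function(par) {
    unlist(lapply(seq_len(n_curves), function(j) {
      p <- assemble(par, j)
      (curves[[j]]$g - fcs_model_eval(p, curves[[j]]$lag)) * wts[[j]]
    }), use.names = FALSE)
  }

  par_names <- c(free_shared, rep(free_pc, n_curves))
  is_log <- !(par_names %in% c("P", "T", "R"))
  to_opt <- function(v) ifelse(is_log, log10(pmax(v, 1e-300)), v)
  from_opt <- function(v) ifelse(is_log, 10^v, v)
  fit <- minpack.lm::nls.lm(par = to_opt(par0),
                            fn = function(th) resid_fn(from_opt(th)),
                            lower = to_opt(lower), upper = to_opt(upper),
                            control = control)
  list(par_hat = from_opt(fit$par), cost = sum(fit$fvec^2),
       converged = fit$info %in% 1:4, info = fit$info,
       message = fit$message, n_iter = fit$niter,
       assemble = assemble, resid_fn = resid_fn)
}

# model evaluation from a plain named list, with a guard keeping the bright
# fraction positive while the optimizer explores the boundary
fcs_model_eval <- function(p, tau) {
  bright <- max(1 - p$P - p$T - p$R, 1e-9)
  diff_term <- fcs_diffusion_factor(tau, p$tau_D, p$beta)
  dark <- bright +
    p$P * exp(-tau / p$tau_prot) +
    p$T * exp(-tau / p$tau_T) +
    p$R * exp(-tau / p$tau_R)
  diff_term * dark / (p$N * bright) + 1
}

# Staged data-driven initialization: each curve is prefit on its per-curve
# parameters alone, with the remaining parameters pinned at data-driven
# guesses and a coarse multistart over tau_prot (the dark-state exponentials
# are prone to label switching when started far away).
staged_init <- function(curves, wts, spec, control) {
  base <- lapply(curves, auto_init)
  # prefit the per-curve parameters plus the scale of the diffusion term;
  # shared photophysics stay pinned at their data-driven guesses here
  free_a <- union(spec$per_curve, intersect(spec$shared, c("N", "tau_D")))
  if (length(free_a) == 0) return(base)
  for (j in seq_along(curves)) {
    v0 <- base[[j]]
    v0[names(spec$fixed)] <- unlist(spec$fixed)
    base[[j]][free_a] <- multistart_pc(curves[[j]], wts[[j]], v0,
                                       free_a, spec$bounds, control)
  }
  # shared starting values: median of the per-curve prefits
  for (nm in spec$shared) {
    med <- stats::median(vapply(base, function(v) v[[nm]], 0))
    base <- lapply(base, function(v) { v[nm] <- med; v })
  }
  base
}

# refine per-curve parameters with the shared parameters pinned at their
# current joint estimates
polish_init <- function(curves, wts, spec, fit, control) {
  free_pc <- spec$per_curve
  lapply(seq_along(curves), function(j) {
    v0 <- unlist(fit$assemble(fit$par_hat, j)[fcs_param_names()])
    if (length(free_pc) == 0) return(v0)
    v0[free_pc] <- multistart_pc(curves[[j]], wts[[j]], v0, free_pc,
                                 spec$bounds, control)
    v0
  })
}

multistart_pc <- function(cv, w, v0, free_pc, bounds, control) {
  tp_starts <- if ("tau_prot" %in% free_pc) {
    c(1e-6, 3e-6, 8e-6, 2e-5, 5e-5)
  } else NA
  best <- NULL
  for (tp0 in tp_starts) {
    v <- v0
    if (!is.na(tp0)) v["tau_prot"] <- tp0
    res <- lm_core(cv$lag, cv$g, w, v, free_pc, bounds, control)
    if (is.null(best) || res$cost < best$cost) best <- res
  }
  best$par
}

# single-curve least-squares solve over `free_names`, all other parameters
# held at `fixed_vals`; scale parameters on log10
lm_core <- function(lag, g, w, fixed_vals, free_names, bounds, control) {
  is_log <- !(free_names %in% c("P", "T", "R"))
  tr <- function(v) ifelse(is_log, log10(pmax(v, 1e-300)), v)
  inv <- function(v) ifelse(is_log, 10^v, v)
  lo <- vapply(free_names, function(nm) bounds[[nm]][1], 0)
  hi <- vapply(free_names, function(nm) bounds[[nm]][2], 0)
  start <- pmin(pmax(fixed_vals[free_names], lo), hi)
  fn <- function(th) {
    v <- fixed_vals
    v[free_names] <- inv(th)
    (g - fcs_model_eval(as.list(v), lag)) * w
  }
  fit <- minpack.lm::nls.lm(par = tr(start), fn = fn,
                            lower = tr(lo), upper = tr(hi), control = control)
  list(par = stats::setNames(inv(fit$par), free_names),
       cost = sum(fit$fvec^2))
}

# Data-driven starting values. The dark-state relaxations (us range) decay
# well before typical diffusion times, so the diffusion amplitude and time are
# estimated from the curve beyond a 20-us reference lag; the excess zero-lag
# amplitude over the extrapolated diffusion amplitude gives the total dark
# fraction.
auto_init <- function(cv) {
  h <- cv$g - 1
  amp1 <- max(h[1], .Machine$double.eps)
  i_ref <- which(cv$lag >= 2e-5)[1]
  if (is.na(i_ref) || h[i_ref] <= 0) i_ref <- max(1L, floor(length(h) / 2))
  href <- max(h[i_ref], .Machine$double.eps)
  i_half <- which(cv$lag > cv$lag[i_ref] & h <= href / 2)[1]
  tau_D0 <- if (!is.na(i_half)) cv$lag[i_half] else stats::median(cv$lag)
  tau_D0 <- max(tau_D0, 1.2 * cv$lag[i_ref])
  amp_diff <- href * (1 + cv$lag[i_ref] / tau_D0)
  N0 <- min(max(1 / amp_diff, 1e-3), 1e5)
  dark0 <- min(max(1 - amp_diff / amp1, 0.33), 0.95)
  P0 <- min(max(dark0 - 0.31, 0.02), 0.9)
  c(N = N0, tau_D = tau_D0, beta = 5, P = P0, tau_prot = 5e-6,
    T = 0.26, tau_T = 1.45e-6, R = 0.05, tau_R = 5e-5)
}

num_jacobian <- function(fn, par, rel_step = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (k in seq_along(par)) {
    h <- rel_step * max(abs(par[k]), 1e-12)
    pk <- par
    pk[k] <- pk[k] + h
    J[, k] <- (fn(pk) - f0) / h
  }
  -J # fvec is (data - model); Jacobian of the model
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("<fcs_fit> ", x$n_curves, " curve(s), ", x$n_points, " points, cost ",
      format(x$cost, digits = 6), if (!x$converged) " (NOT converged)", "\n",
      sep = "")
  if (length(x$shared) > 0) {
    cat("shared: ", paste(names(x$shared), signif(x$shared, 4),
                          sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy an FCS fit into a per-curve parameter table
#'
#' @param x An `fcs_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `curve_id`, `term`, `estimate`, `std.error`
#'   and `role` (`"shared"`, `"per_curve"` or `"fixed"`).
#' @export
tidy.fcs_fit <- function(x, ...) {
  est <- tidyr::pivot_longer(x$params, -"curve_id",
                             names_to = "term", values_to = "estimate")
  se <- tidyr::pivot_longer(x$stderr, -"curve_id",
                            names_to = "term", values_to = "std.error")
  out <- dplyr::left_join(est, se, by = c("curve_id", "term"))
  role <- function(term) {
    dplyr::case_when(term %in% x$spec$shared ~ "shared",
                     term %in% x$spec$per_curve ~ "per_curve",
                     TRUE ~ "fixed")
  }
  dplyr::mutate(out, role = role(.data$term))
}

#' One-row summary of an FCS fit
#'
#' @param x An `fcs_fit` object.
#' @param ... Unused.
#' @return A tibble with `cost`, `converged`, `n_iter`, `n_curves`, `n_points`,
#'   `df_residual`.
#' @export
glance.fcs_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, converged = x$converged, n_iter = x$n_iter,
                 n_curves = x$n_curves, n_points = x$n_points,
                 df_residual = x$n_points - x$n_free)
}

#' Data with fitted values and residuals
#'
#' @param x An `fcs_fit` object.
#' @param ... Unused.
#' @return The input data with `.fitted` and `.resid` columns appended.
#' @export
augment.fcs_fit <- function(x, ...) {
  x$data
}
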