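#' Protonation relaxation rate versus proton concentration
#'
#' Pairs the fitted protonation relaxation rate `k_prot = 1/tau_prot` of each
#' curve with the bulk proton concentration `[H+] = 10^(-pH)` from the curve
#' metadata, the input to the linear rate-law regression of
#' [fit_protonation()].
#'
#' @param fit An `fcs_fit` object whose curve metadata includes a `ph` column,
#'   or a data frame with columns `curve_id`, `tau_prot` and `ph`.
#' @return A tibble with columns `curve_id`, `ph`, `h_conc` (M) and
#'   `k_prot` (1/s), in curve order.
#' @export
kprot_points <- function(fit) {
  if (inherits(fit, "fcs_fit")) {
    tbl <- dplyr::left_join(fit$params, fit$meta, by = "curve_id")
  } else {
    tbl <- tibble::as_tibble(fit)
  }
  if (!"ph" %in% names(tbl) || anyNA(tbl$ph)) {
    missing <- if ("ph" %in% names(tbl)) {
      tbl$curve_id[is.na(tbl$ph)]
    } else tbl$curve_id
    stop("missing pH metadata for curve(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$tau_prot <= 0)) stop("tau_prot must be > 0", call. = FALSE)
  tibble::tibble(curve_id = tbl$curve_id, ph = tbl$ph,
                 h_conc = 10^(-tbl$ph), k_prot = 1 / tbl$tau_prot)
}

#' Protonation rate-law regression
#'
#' Fits the linear rate law `k_prot = k_off + kappa_on [H+]` by ordinary least
#' squares over the points with `[H+] <= h_max`. The slope is the second-order
#' protonation rate constant `kappa_on` (1/(M s)) and the intercept the
#' deprotonation rate `k_off` (1/s). Restricting to the high-pH regime (low
#' `[H+]`) selects the window where the membrane acts as a fully active proton
#' collecting antenna; the default `h_max = 1e-8` M corresponds to the
#' 1-10 nM window (pH 9-8) used for nanodisc samples.
#'
#' @param points Data frame with columns `h_conc` (M) and `k_prot` (1/s),
#'   e.g. from [kprot_points()].
#' @param h_max Upper admissible proton concentration (M).
#' @return An object of class `"protonation_fit"` with elements `kappa_on`,
#'   `k_off`, `se_kappa_on`, `se_k_off`, `n_points`, `n_excluded`, `h_range`
#'   and `negative_intercept` (a negative fitted `k_off` is reported, not
#'   clamped). `tidy()` and `glance()` methods are provided.
#' @examples
#' pts <- tibble::tibble(h_conc = c(1, 2, 5, 10) * 1e-9,
#'                       k_prot = 6.72e4 + 7.54e12 * c(1, 2, 5, 10) * 1e-9)
#' fit_protonation(pts)
#' @export
fit_protonation <- function(points, h_max = 1e-8) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("h_conc", "k_prot") %in% names(points)))
  keep <- points$h_conc <= h_max
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) < 2) {
    stop("need >= 2 points with [H+] <= h_max (have ", nrow(pts), ")",
         call. = FALSE)
  }
  fit <- stats::lm(k_prot ~ h_conc, data = pts)
  co <- suppressWarnings(summary(fit))$coefficients # exact fits are fine
  k_off <- co["(Intercept)", "Estimate"]
  out <- structure(list(
    kappa_on = co["h_conc", "Estimate"],
    k_off = k_off,
    se_kappa_on = co["h_conc", "Std. Error"],
    se_k_off = co["(Intercept)", "Std. Error"],
    n_points = nrow(pts),
    n_excluded = sum(!keep),
    h_range = range(pts$h_conc),
    negative_intercept = k_off < 0,
    lm = fit), class = "protonation_fit")
  if (out$negative_intercept) {
    warning("fitted k_off is negative; reported unclamped", call. = FALSE)
  }
  out
}

#' @export
print.protonation_fit <- function(x, ...) {
  cat("<protonation_fit> kappa_on = ", format(x$kappa_on, digits = 4),
      " 1/(M s) (SE ", format(x$se_kappa_on, digits = 3),
      "), k_off = ", format(x$k_off, digits = 4),
      " 1/s (SE ", format(x$se_k_off, digits = 3), "), n = ", x$n_points,
      "\n", sep = "")
  invisible(x)
}

#' @rdname fit_protonation
#' @param x A `protonation_fit` object.
#' @param ... Unused.
#' @export
tidy.protonation_fit <- function(x, ...) {
  tibble::tibble(term = c("kappa_on", "k_off"),
                 estimate = c(x$kappa_on, x$k_off),
                 std.error = c(x$se_kappa_on, x$se_k_off))
}

#' @rdname fit_protonation
#' @export
glance.protonation_fit <- function(x, ...) {
  tibble::tibble(n_points = x$n_points, n_excluded = x$n_excluded,
                 h_min = x$h_range[1], h_max = x$h_range[2],
                 r.squared = suppressWarnings(summary(x$lm))$r.squared,
                 negative_intercept = x$negative_intercept)
}

#' Fit the two-pKa titration curve to brightness data
#'
#' Least-squares fit of the double-sigmoid normalized-molecular-brightness
#' titration model (see [titration_value()]) to `(pH, NMB)` points. The
#' returned parameters follow the convention `pKa1 <= pKa2`; if the optimizer
#' crosses the ordering, the two sites are swapped together with the amplitude
#' (`a <-> 1 - a`).
#'
#' @param points Data frame with columns `ph` and `nmb`; at least 4 points
#'   spanning more than one pH unit.
#' @param init A [titration_params()] starting point, or `NULL` for a
#'   data-driven start.
#' @return An object of class `"titration_fit"` with elements `params`
#'   (a [titration_params()]), `stderr` (named vector), `converged`,
#'   `degenerate` and `cost`; plus `tidy()`/`glance()` methods.
#' @examples
#' tp <- titration_params(0.41, 6.8, 8.7)
#' pts <- tibble::tibble(ph = seq(5, 10, 0.25),
#'                       nmb = titration_value(tp, seq(5, 10, 0.25)))
#' fit_titration(pts)
#' @export
fit_titration <- function(points, init = NULL) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("ph", "nmb") %in% names(points)))
  if (nrow(points) < 4) stop("need >= 4 titration points", call. = FALSE)
  if (diff(range(points$ph)) <= 1) {
    stop("titration points must span more than 1 pH unit", call. = FALSE)
  }
  degenerate <- stats::sd(points$nmb) < 1e-12
  if (degenerate) {
    tp <- titration_params(0.5, mean(points$ph), mean(points$ph),
                           c = points$nmb[1])
    return(structure(list(params = tp,
                          stderr = c(a = NA, pKa1 = NA, pKa2 = NA, c = NA),
                          converged = FALSE, degenerate = TRUE, cost = 0),
                     class = "titration_fit"))
  }
  if (is.null(init)) {
    qs <- stats::quantile(points$ph, c(0.3, 0.7))
    init <- titration_params(0.5, qs[[1]], qs[[2]], c = min(points$nmb))
  }
  par0 <- c(init$a, init$pKa1, init$pKa2, init$c)
  lower <- c(0, 0, 0, -10)
  upper <- c(1, 14, 14, 10)
  fn <- function(par) {
    tp <- list(a = par[1], pKa1 = par[2], pKa2 = par[3], c = par[4])
    points$nmb - titration_value(tp, points$ph)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = fn, lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-12, maxiter = 1000))
  par <- fit$par
  se <- rep(NA_real_, 4)
  if (nrow(points) > 4) {
    J <- num_jacobian(fn, par)
    cv <- try(solve(crossprod(J)), silent = TRUE)
    if (!inherits(cv, "try-error")) {
      se <- sqrt(pmax(diag(cv) * sum(fit$fvec^2) / (nrow(points) - 4), 0))
    }
  }
  if (par[2] > par[3]) { # enforce pKa1 <= pKa2
    par <- c(1 - par[1], par[3], par[2], par[4])
    se <- se[c(1, 3, 2, 4)]
  }
  structure(list(params = titration_params(par[1], par[2], par[3], par[4]),
                 stderr = stats::setNames(se, c("a", "pKa1", "pKa2", "c")),
                 converged = fit$info %in% 1:4, degenerate = FALSE,
                 cost = sum(fit$fvec^2)),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  p <- x$params
  cat("<titration_fit> pKa1 = ", round(p$pKa1, 3), " (a = ", round(p$a, 3),
      "), pKa2 = ", round(p$pKa2, 3), ", c = ", signif(p$c, 3),
      if (x$degenerate) " [degenerate]",
      if (!x$converged && !x$degenerate) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_titration
#' @param x A `titration_fit` object.
#' @param ... Unused.
#' @export
tidy.titration_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(term = c("a", "pKa1", "pKa2", "c"),
                 estimate = c(p$a, p$pKa1, p$pKa2, p$c),
                 std.error = unname(x$stderr))
}

#' @rdname fit_titration
#' @export
glance.titration_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, converged = x$converged,
                 degenerate = x$degenerate)
}

#' Summarize replicate kinetics estimates
#'
#' Mean and standard deviation of rate constants across independent
#' experiments (replicate fits of the same sample).
#'
#' @param data Data frame of per-replicate estimates.
#' @param ... Columns to summarize (tidyselect).
#' @return A tibble with one `mean_*` and `sd_*` column per input column.
#' @export
summarize_replicates <- function(data, ...) {
  dplyr::summarize(tibble::as_tibble(data), dplyr::across(
    c(...), list(mean = mean, sd = stats::sd), .names = "{.fn}_{.col}"))
}
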