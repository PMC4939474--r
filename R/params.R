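#' FCS model parameter set
#'
#' Bundles the nine parameters of the three-dark-state FCS correlation model:
#' translational diffusion of the fluorescent species through a 3D-Gaussian
#' detection volume plus reversible transitions into three dark states
#' (protonated, triplet, redox).
#'
#' @param N Mean number of fluorescent particles in the detection volume (> 0).
#' @param tau_D Translational diffusion time through the detection volume (s).
#' @param beta Ratio of the axial to lateral extension of the detection
#'   volume (> 1). Typical confocal setups have `beta` around 5.
#' @param P Fraction of fluorophores in the protonated (dark) state, in `[0, 1)`.
#' @param tau_prot Protonation relaxation time (s); its inverse is the total
#'   protonation relaxation rate `k_prot`.
#' @param T Triplet-state fraction, in `[0, 1)`.
#' @param tau_T Triplet relaxation time (s).
#' @param R Redox dark-state fraction, in `[0, 1)`.
#' @param tau_R Redox relaxation time (s).
#'
#' @details The dark fractions must satisfy `P + T + R < 1`: the prefactor of
#'   the correlation amplitude is `1 / (N (1 - P - T - R))` and diverges as the
#'   bright fraction vanishes. All times are in seconds.
#'
#' @return A named list of class `"fcs_params"`.
#' @examples
#' p <- fcs_params(N = 2, tau_D = 2e-4, P = 0.3, tau_prot = 8e-6)
#' fcs_correlation(p, tau = 1e-5)
#' @export
fcs_params <- function(N = 1, tau_D = 1e-4, beta = 5,
                       P = 0, tau_prot = 5e-6,
                       T = 0, tau_T = 1.45e-6,
                       R = 0, tau_R = 5e-5) {
  p <- list(N = N, tau_D = tau_D, beta = beta, P = P, tau_prot = tau_prot,
            T = T, tau_T = tau_T, R = R, tau_R = tau_R)
  p <- lapply(p, as.numeric)
  validate_fcs_params(p)
  structure(p, class = "fcs_params")
}

#' @rdname fcs_params
#' @param x Object to test or validate.
#' @export
is_fcs_params <- function(x) inherits(x, "fcs_params")

validate_fcs_params <- function(p) {
  nm <- fcs_param_names()
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0) {
    stop("missing FCS parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- unlist(p[nm])
  if (any(!is.finite(v))) stop("all FCS parameters must be finite", call. = FALSE)
  if (p$N <= 0) stop("N must be > 0", call. = FALSE)
  if (p$beta <= 1) stop("beta must be > 1", call. = FALSE)
  for (f in c("P", "T", "R")) {
    if (p[[f]] < 0 || p[[f]] >= 1) {
      stop(f, " must lie in [0, 1)", call. = FALSE)
    }
  }
  if (p$P + p$T + p$R >= 1) {
    stop("dark fractions P + T + R must be < 1 (got ",
         format(p$P + p$T + p$R), ")", call. = FALSE)
  }
  for (f in c("tau_D", "tau_prot", "tau_T", "tau_R")) {
    if (p[[f]] <= 0) stop(f, " must be > 0", call. = FALSE)
  }
  invisible(p)
}

fcs_param_names <- function() {
  c("N", "tau_D", "beta", "P", "tau_prot", "T", "tau_T", "R", "tau_R")
}

#' @export
print.fcs_params <- function(x, ...) {
  cat("<fcs_params>\n")
  v <- unlist(x[fcs_param_names()])
  print(signif(v, 5))
  invisible(x)
}

#' Two-pKa titration parameter set
#'
#' Parameters of the double-sigmoid titration curve used for the normalized
#' molecular brightness of a fluorophore with two protonatable groups:
#' `NMB(pH) = a / (1 + 10^(pKa1 - pH)) + (1 - a) / (1 + 10^(pKa2 - pH)) + c`.
#'
#' @param a Amplitude of the first (lower-pKa) transition, in `[0, 1]`.
#' @param pKa1,pKa2 The two apparent pKa values; by convention `pKa1 <= pKa2`.
#' @param c Baseline offset.
#' @return A named list of class `"titration_params"`.
#' @examples
#' tp <- titration_params(a = 0.41, pKa1 = 6.8, pKa2 = 8.7)
#' titration_value(tp, pH = 8.7)
#' @export
titration_params <- function(a, pKa1, pKa2, c = 0) {
  if (a < 0 || a > 1) stop("a must lie in [0, 1]", call. = FALSE)
  if (pKa1 > pKa2) stop("pKa1 must be <= pKa2 (ordering convention)", call. = FALSE)
  structure(list(a = as.numeric(a), pKa1 = as.numeric(pKa1),
                 pKa2 = as.numeric(pKa2), c = as.numeric(c)),
            class = "titration_params")
}
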