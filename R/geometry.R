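#' Proton-collecting antenna geometry
#'
#' For two-dimensional diffusion along the membrane surface, the antenna
#' radius is related to the mean-square displacement of a proton during its
#' average surface dwell time: `R_PCA = sqrt(2 D_s tau_s / pi)`.
#' `antenna_radius()` and `dwell_time()` are exact inverses of each other.
#'
#' @param D_s Lateral surface proton diffusion coefficient (nm^2/s);
#'   `2e7` nm^2/s equals `2e-7` cm^2/s.
#' @param tau_s Mean proton dwell time on the surface (s).
#' @param R_PCA Proton-collecting antenna radius (nm).
#' @return `antenna_radius()`: radius in nm; `dwell_time()`: dwell time in s.
#' @examples
#' antenna_radius(D_s = 2e7, tau_s = 1e-6) # ~3.57 nm
#' dwell_time(R_PCA = 5, D_s = 2e7)        # ~1.96 us
#' @export
antenna_radius <- function(D_s, tau_s) {
  check_positive(D_s = D_s, tau_s = tau_s)
  sqrt(2 * D_s * tau_s / pi)
}

#' @rdname antenna_radius
#' @export
dwell_time <- function(R_PCA, D_s) {
  check_positive(R_PCA = R_PCA, D_s = D_s)
  pi * R_PCA^2 / (2 * D_s)
}

#' Membrane area arithmetic
#'
#' Lipid membrane area of a circular nanodisc (`disc_area`) and of the annular
#' lipid region remaining around an inserted protein of given diameter
#' (`annulus_area`).
#'
#' @param diameter,nd_diameter Nanodisc diameter (nm).
#' @param protein_diameter Diameter of the inserted protein (nm); must be
#'   smaller than the disc diameter.
#' @return Area in nm^2.
#' @examples
#' disc_area(9)          # ~64 nm^2
#' annulus_area(12, 6.5) # ~80 nm^2
#' annulus_area(9, 6.5)  # ~30 nm^2
#' @export
disc_area <- function(diameter) {
  check_positive(diameter = diameter)
  pi * diameter^2 / 4
}

#' @rdname disc_area
#' @export
annulus_area <- function(nd_diameter, protein_diameter) {
  check_positive(nd_diameter = nd_diameter, protein_diameter = protein_diameter)
  if (any(protein_diameter >= nd_diameter)) {
    stop("protein diameter must be smaller than the disc diameter",
         call. = FALSE)
  }
  pi * (nd_diameter^2 - protein_diameter^2) / 4
}

#' Fold change between two rate constants
#'
#' @param kappa_a,kappa_b Positive rate constants (same units).
#' @return The ratio `kappa_a / kappa_b`.
#' @examples
#' fold_change(7.71e12, 1.44e11) # ~50-fold antenna enhancement
#' @export
fold_change <- function(kappa_a, kappa_b) {
  check_positive(kappa_a = kappa_a, kappa_b = kappa_b)
  kappa_a / kappa_b
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]])) || any(args[[nm]] <= 0)) {
      stop(nm, " must be positive and finite", call. = FALSE)
    }
  }
  invisible(TRUE)
}
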