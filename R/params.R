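#' Physical parameters for tissue oxygen transport
#'
#' Bundles the physical constants of the diffusion--consumption model. The
#' internal unit system is micrometres for length, seconds for time and
#' nmol cm^-3 for concentration, which keeps all quantities at O(1)--O(100)
#' and the linear systems well conditioned. The defaults are literature values
#' for brain parenchyma: `D` = 2e-5 cm^2/s = 2000 um^2/s, maximal metabolic
#' rate `M` (CMRO2_max) up to 2.4 umol cm^-3 min^-1 = 40 nmol cm^-3 s^-1,
#' half-saturation `K` (EC50) of about a tenth of the arteriolar inlet
#' concentration `phi_max` = 137 nmol cm^-3, and oxygen solubility
#' `alpha` = 1.39 nmol cm^-3 mmHg^-1 (used to convert to partial pressures).
#'
#' @param D tissue diffusion coefficient (um^2/s), strictly positive.
#' @param M maximal metabolic rate of oxygen (nmol cm^-3 s^-1), >= 0.
#'   `M = 0` gives the nonreactive (pure diffusion) problem.
#' @param K half-saturation concentration of the Michaelis-Menten kinetics
#'   (nmol cm^-3); must be > 0 whenever `M > 0`.
#' @param alpha oxygen solubility (nmol cm^-3 mmHg^-1).
#' @param phi_max reference arteriolar inlet concentration (nmol cm^-3).
#' @return An object of class `ox_params` (a named list).
#' @export
#' @examples
#' p <- ox_params()                      # nonreactive defaults
#' pr <- ox_params(M = 40)               # with metabolism at CMRO2_max
ox_params <- function(D = 2000, M = 0, K = 13.7, alpha = 1.39,
                      phi_max = 137) {
  stopifnot(is.numeric(D), length(D) == 1L, D > 0,
            is.numeric(M), length(M) == 1L, M >= 0,
            is.numeric(K), length(K) == 1L,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(phi_max), length(phi_max) == 1L, phi_max > 0)
  if (M > 0 && K <= 0)
    stop("half-saturation K must be > 0 when the metabolic rate M is > 0")
  structure(list(D = D, M = M, K = K, alpha = alpha, phi_max = phi_max),
            class = "ox_params")
}

#' @export
print.ox_params <- function(x, ...) {
  cat("Tissue oxygen transport parameters (um, s, nmol/cm^3):\n")
  cat(sprintf("  D       = %g um^2/s\n", x$D))
  cat(sprintf("  M       = %g nmol cm^-3 s^-1 (CMRO2_max)\n", x$M))
  cat(sprintf("  K       = %g nmol cm^-3 (EC50)\n", x$K))
  cat(sprintf("  alpha   = %g nmol cm^-3 mmHg^-1\n", x$alpha))
  cat(sprintf("  phi_max = %g nmol cm^-3\n", x$phi_max))
  invisible(x)
}

#' Effective wall exchange coefficient of a circular vessel
#'
#' Combines the diffusive permeability of the vessel wall with intravascular
#' concentration gradients into a single effective exchange coefficient
#' relating the flux per unit length to the difference between the
#' cross-section averaged intravascular concentration and the
#' perimeter-averaged tissue concentration:
#' \deqn{K_{eff} = \frac{8 \pi D_\beta}{1 + 4 D_\beta / (K_m R)}}
#'
#' @param D_beta diffusion coefficient in blood (um^2/s), > 0.
#' @param K_m diffusive permeability of the vessel wall (um/s), > 0.
#' @param R vessel radius (um), > 0.
#' @return Effective exchange coefficient (um^2/s), in `[0, 8 pi D_beta)`.
#' @export
#' @examples
#' effective_permeability(D_beta = 1400, K_m = 20, R = 4.8)
effective_permeability <- function(D_beta, K_m, R) {
  if (any(D_beta <= 0) || any(K_m <= 0) || any(R <= 0))
    stop("all arguments of effective_permeability() must be strictly positive")
  8 * pi * D_beta / (1 + 4 * D_beta / (K_m * R))
}

#' Laminar capillary-density table for cortical layers I-IV
#'
#' Layer-specific capillary length density (CLD), equivalent two-dimensional
#' source density (E2DSD) of a cross-section, cortical depth range, arteriolar
#' and capillary oxygen partial pressures, and the capillary-to-arteriole
#' concentration ratio used by the periarteriolar gradient study.
#'
#' @return A data.frame with one row per layer (I-IV) and columns
#'   `layer`, `cld` (m mm^-3), `e2dsd` (mm^-2), `depth_min`, `depth_max` (um),
#'   `po2_pa`, `po2_cap` (mmHg) and `phi_cap_ratio` (dimensionless).
#' @export
#' @examples
#' layer_table()
layer_table <- function() {
  data.frame(
    layer = c("I", "II", "III", "IV"),
    cld = c(0.8, 0.94, 1.08, 1.2),
    e2dsd = c(250, 325, 400, 475),
    depth_min = c(0, 100, 200, 300),
    depth_max = c(100, 200, 300, 400),
    po2_pa = c(99, 92, 87, 85),
    po2_cap = c(39, 42, 44, 47),
    phi_cap_ratio = c(0.4, 0.45, 0.5, 0.55),
    stringsAsFactors = FALSE
  )
}
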