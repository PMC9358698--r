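# Isomorph -> V1-morph -> mass-mass parameter conversion.
#
# Standard DEB parameter sets (e.g. from the Add-my-Pet collection) are
# energy-length parameters of isomorphs.  Treating such an organism as a
# V1-morph with a fixed reference structural volume V_d, the area-specific
# rates become volume-specific by division by L_d = V_d^{1/3}; dividing the
# volume-specific energies by the energy density of structure mu_E [M_V]
# then yields the dimensionless mass-mass parameters used by the ecosystem
# model.

#' Isomorph energy-length DEB parameter set
#'
#' @param pAm_area Area-specific maximum assimilation rate \{pAm\}
#'   (J/cm^2/d).
#' @param v_dot Energy conductance (cm/d).
#' @param pM_vol Volume-specific maintenance rate (J/cm^3/d).
#' @param EG_vol Volume-specific cost of growth (J/cm^3).
#' @param kappa_X Digestion efficiency of food to reserve, in (0, 1].
#' @param L_d Reference structural length \eqn{V_d^{1/3}} (cm) at which the
#'   V1-morph approximation is anchored.
#' @param muE_MV Energy density of structure \eqn{\mu_E [M_V]} (J/cm^3).
#' @return A list of class \code{"isomorph_params"}.
#' @export
isomorph_params <- function(pAm_area, v_dot, pM_vol, EG_vol,
                            kappa_X, L_d, muE_MV) {
  vals <- c(pAm_area = pAm_area, v_dot = v_dot, pM_vol = pM_vol,
            EG_vol = EG_vol, kappa_X = kappa_X, L_d = L_d, muE_MV = muE_MV)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all isomorph parameters must be positive and finite", call. = FALSE)
  if (kappa_X > 1) stop("`kappa_X` must lie in (0, 1]", call. = FALSE)
  structure(as.list(vals), class = "isomorph_params")
}

#' Default water-flea (Daphnia magna) isomorph parameter set
#'
#' The consumer of the default ecosystem parameterization: an Add-my-Pet
#' style isomorph record for \emph{Daphnia magna}, anchored at the length
#' at puberty as reference structural length.
#'
#' @return An [isomorph_params()] object.
#' @export
daphnia_isomorph_params <- function() {
  isomorph_params(pAm_area = 313, v_dot = 0.186, pM_vol = 1200,
                  EG_vol = 4400, kappa_X = 0.9, L_d = 0.07, muE_MV = 3556)
}

#' Convert isomorph to V1-morph energy-length parameters
#'
#' Fixing the reference volume, the area-specific assimilation rate becomes
#' volume-specific, \eqn{[\dot p_{Am}] = \{\dot p_{Am}\} / L_d}, and the
#' energy conductance becomes the specific energy conductance
#' \eqn{\dot k_E = \dot v / L_d}.
#'
#' @param iso An [isomorph_params()] object.
#' @return List with \code{pAm_vol} (J/cm^3/d) and \code{k_E} (1/d).
#' @export
isomorph_to_v1_energy_length <- function(iso) {
  stopifnot(inherits(iso, "isomorph_params"))
  list(pAm_vol = iso$pAm_area / iso$L_d, k_E = iso$v_dot / iso$L_d)
}

#' Convert energy-length V1-morph parameters to mass-mass parameters
#'
#' Divides each volume-specific energy parameter by the energy density of
#' structure: \eqn{j_{EAm} = [\dot p_{Am}] / \mu_E[M_V]},
#' \eqn{j_{EM} = [\dot p_M] / \mu_E[M_V]},
#' \eqn{y_{EV} = [E_G] / \mu_E[M_V]}; the conductance carries over
#' unchanged.  The returned \code{j_EAm} is on the assimilation basis;
#' see [max_consumption_from_assimilation()] for the consumption basis.
#'
#' @param iso An [isomorph_params()] object.
#' @return A [v1_params()] object.
#' @export
energy_length_to_mass_mass <- function(iso) {
  stopifnot(inherits(iso, "isomorph_params"))
  el <- isomorph_to_v1_energy_length(iso)
  v1_params(j_EAm = el$pAm_vol / iso$muE_MV,
            k_E = el$k_E,
            j_EM = iso$pM_vol / iso$muE_MV,
            y_EV = iso$EG_vol / iso$muE_MV)
}

#' Maximum consumption rate from the maximum assimilation rate
#'
#' Assimilation is what survives digestion, so the mass-specific maximum
#' consumption (ingestion) rate is the assimilation rate divided by the
#' digestion efficiency: \eqn{j_{assim} / \kappa_X}.
#'
#' @param j_assim Mass-specific maximum assimilation rate (1/d).
#' @param kappa_X Digestion efficiency in (0, 1].
#' @return Mass-specific maximum consumption rate (1/d).
#' @export
max_consumption_from_assimilation <- function(j_assim, kappa_X) {
  if (j_assim < 0) stop("`j_assim` must be >= 0", call. = FALSE)
  if (kappa_X <= 0 || kappa_X > 1)
    stop("`kappa_X` must lie in (0, 1]", call. = FALSE)
  j_assim / kappa_X
}
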