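# The ecosystem parameter record and default state.
#
# All pools are in umol C/L (ammonia in umol N/L), time in days, so
# half-saturation constants and pool masses share units and the scaled
# densities x = M/K are dimensionless.

# state vector layout: 11 explicit pools + the two nutrients
.state_names <- c("M_PP", "M_PD", "M_PV", "M_PE",
                  "M_VC", "M_EC",
                  "M_VP", "M_E1P", "M_E2P",
                  "M_VD", "M_ED",
                  "M_C", "M_N")

# columns of the flux matrix (nutrients close the balance and have none)
.pool_cols <- c("PP", "PD", "PV", "PE", "VC", "EC",
                "VP", "E1P", "E2P", "VD", "ED")

# processes (rows of the flux matrix)
.process_rows <- c("A1C", "A2C", "GC", "DC", "HC",
                   "A1P", "A2P", "GP", "DP",
                   "A1D", "A2D", "A3D", "A4D", "GD", "DD")

# rate parameters subject to Arrhenius temperature correction: everything
# of dimension per-time (maximum uptake/synthesis rates, maintenance
# rates, conductances, the death rate); half-saturations, yields and
# stoichiometric coefficients are not rates and are never corrected
.arrhenius_rates <- c("j_VP_AC_m", "j_VD_AC_m",
                      "j_E1P_A1P_m", "j_E2P_A2P_m",
                      "j_PP_A1D_m", "j_PD_A2D_m", "j_PV_A3D_m", "j_PE_A4D_m",
                      "j_EC_MC", "j_E1P_MP", "j_E2P_MP", "j_ED_MD",
                      "k_EC", "k_E1P", "k_E2P", "k_ED",
                      "h_C")

#' State-variable, pool and process names of the ecosystem model
#'
#' @return Character vectors: \code{ecosystem_state_names()} the 13 state
#'   variables (four detritus pools, consumer structure and reserve,
#'   producer structure and two reserves, decomposer structure and
#'   reserve, carbon dioxide, ammonia); \code{flux_matrix_dimnames()} the
#'   15 process rows and 11 pool columns of the flux matrix.
#' @export
ecosystem_state_names <- function() .state_names

#' @rdname ecosystem_state_names
#' @export
flux_matrix_dimnames <- function() list(process = .process_rows,
                                        pool = .pool_cols)

#' Default ecosystem parameter set
#'
#' The full parameter record of the canonical community model: half
#' saturation constants, maximum uptake/synthesis rates, maintenance
#' rates, energy conductances, the consumer background death rate, reserve
#' return fractions, the preference parameter, all conversion yields and
#' nitrogen contents, plus the seasonal [forcing_params()].  Rate
#' parameters are stated at the reference temperature \code{T_1}.
#'
#' The consumer rates derive from a water-flea isomorph record via the
#' V1-morph conversion chain ([daphnia_isomorph_params()],
#' [energy_length_to_mass_mass()], [max_consumption_from_assimilation()]):
#' the maximum consumption of producer structure is the converted maximum
#' consumption rate, and consumption of decomposer structure is taken half
#' as fast.  Nitrogen contents follow a molar C:N of 6.6 (Redfield) for
#' all structures, reserves and detritus except the carbohydrate producer
#' reserve (no nitrogen) and the nitrogen-rich producer reserve (0.8).
#'
#' @param ... Named overrides for individual entries, e.g.
#'   \code{default_ecosystem_params(rho = 0.05)}.  Unknown names are an
#'   error.
#' @return A list of class \code{"ecosystem_params"}.
#' @export
default_ecosystem_params <- function(...) {
  daphnia <- energy_length_to_mass_mass(daphnia_isomorph_params())
  j_cons <- max_consumption_from_assimilation(daphnia$j_EAm, 0.9)
  p <- list(
    # half-saturation constants (umol C/L, umol N/L for K_N2; light in
    # MJ/m^2/d)
    K_PP = 0.1, K_PD = 0.1, K_PV = 0.1, K_PE = 0.1,
    K_VP = 2, K_VD = 5,
    J_K_L1 = 25, J_K_L2 = 22,
    K_C1 = 3.2, K_C2 = 6.4, K_N2 = 0.43,
    # maximum mass-specific rates (1/d)
    j_VP_AC_m = j_cons,
    j_VD_AC_m = 0.5 * j_cons,
    j_E1P_A1P_m = 5.1, j_E2P_A2P_m = 1.0,
    j_PP_A1D_m = 1.4, j_PD_A2D_m = 1.4, j_PV_A3D_m = 1.4, j_PE_A4D_m = 1.4,
    # maintenance rates (1/d)
    j_EC_MC = daphnia$j_EM,
    j_E1P_MP = 0.054, j_E2P_MP = 0.012,
    j_ED_MD = 0.192,
    # specific energy conductances (1/d)
    k_EC = daphnia$k_E, k_E1P = 5.2, k_E2P = 5.2, k_ED = 14.5,
    # consumer background death rate (1/d); one value behind the several
    # symbols used for it in the DEB literature
    h_C = 0.01,
    # return fractions of rejected producer reserves and SU preference
    kappa_E1 = 0.7, kappa_E2 = 0.7,
    rho = 0.01,
    # conversion yields (C-mol per C-mol)
    y_EC_VP = 0.5, y_EC_E1P = 0.8, y_EC_E2P = 0.8, y_PP_VP = 0.5,
    y_EC_VD = 0.5, y_EC_ED = 0.8, y_PD_VD = 0.5,
    y_ED_PP = 0.5, y_ED_PD = 0.5, y_ED_PV = 0.5, y_ED_PE = 0.5,
    y_EC_VC = daphnia$y_EV,
    y_E1P_VP = 1.25, y_E2P_VP = 1.5,
    y_ED_VD = 1.492,
    # nitrogen content per carbon (N-mol per C-mol), by flux-matrix column
    n_N_PP = 0.15, n_N_PD = 0.15, n_N_PV = 0.15, n_N_PE = 0.15,
    n_N_VC = 0.15, n_N_EC = 0.15,
    n_N_VP = 0.15, n_N_E1P = 0, n_N_E2P = 0.8,
    n_N_VD = 0.15, n_N_ED = 0.15,
    forcing = forcing_params(),
    # rate names exempted from temperature correction
    arrhenius_exclusions = character()
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(over)] <- over
  }
  validate_ecosystem_params(structure(p, class = "ecosystem_params"))
}

#' Validate an ecosystem parameter record
#'
#' Checks positivity of rates, half-saturations and yields, the ranges of
#' the return fractions and nitrogen contents, and the forcing record.
#'
#' @param p An \code{"ecosystem_params"} list.
#' @return \code{p}, invisibly unchanged, or an error naming the offending
#'   entry.
#' @export
validate_ecosystem_params <- function(p) {
  nonneg <- c("j_EC_MC", "j_E1P_MP", "j_E2P_MP", "j_ED_MD", "h_C")
  pos <- c("K_PP", "K_PD", "K_PV", "K_PE", "K_VP", "K_VD",
           "J_K_L1", "J_K_L2", "K_C1", "K_C2", "K_N2",
           setdiff(.arrhenius_rates, nonneg),
           "rho",
           grep("^y_", names(p), value = TRUE))
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter `", nm, "` must be a single positive number",
           call. = FALSE)
  }
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter `", nm, "` must be a single non-negative number",
           call. = FALSE)
  }
  for (nm in grep("^n_N_", names(p), value = TRUE))
    if (p[[nm]] < 0)
      stop("parameter `", nm, "` must be >= 0", call. = FALSE)
  for (nm in c("kappa_E1", "kappa_E2"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("parameter `", nm, "` must lie in [0, 1]", call. = FALSE)
  if (!inherits(p$forcing, "forcing_params"))
    stop("`forcing` must be a forcing_params() record", call. = FALSE)
  if (!is.character(p$arrhenius_exclusions) ||
      !all(p$arrhenius_exclusions %in% .arrhenius_rates))
    stop("`arrhenius_exclusions` must name rate parameters (",
         paste(.arrhenius_rates, collapse = ", "), ")", call. = FALSE)
  invisible(p)
}

#' @export
print.ecosystem_params <- function(x, ...) {
  cat("Canonical community model parameters\n")
  cat(sprintf("  consumer:   j_VP_AC_m = %.3f, j_EC_MC = %.3f, k_EC = %.3f, h_C = %g\n",
              x$j_VP_AC_m, x$j_EC_MC, x$k_EC, x$h_C))
  cat(sprintf("  producer:   j_E1P_A1P_m = %.2f, j_E2P_A2P_m = %.2f, k_E1P = %.2f\n",
              x$j_E1P_A1P_m, x$j_E2P_A2P_m, x$k_E1P))
  cat(sprintf("  decomposer: j_P*_m = %.2f, j_ED_MD = %.3f, k_ED = %.2f\n",
              x$j_PP_A1D_m, x$j_ED_MD, x$k_ED))
  cat(sprintf("  preference rho = %g, return fractions kappa_E = (%g, %g)\n",
              x$rho, x$kappa_E1, x$kappa_E2))
  cat("  (", length(grep("^y_", names(x))), "yields,",
      length(grep("^n_N_", names(x))), "nitrogen contents, seasonal forcing )\n")
  invisible(x)
}

#' Default initial state of the ecosystem
#'
#' The 13-component initial condition of the reference simulation: small
#' winter stocks of all living groups and detritus, most carbon as
#' dissolved carbon dioxide and most nitrogen as ammonia.
#'
#' @param ... Named overrides for individual components.
#' @return Named numeric vector over [ecosystem_state_names()] (umol C/L;
#'   \code{M_N} in umol N/L).
#' @export
default_initial_state <- function(...) {
  s <- c(M_PP = 2.66e-2, M_PD = 7.986e-3, M_PV = 2.66e-4, M_PE = 6.66e-6,
         M_VC = 1.02e-1, M_EC = 6.66e-3,
         M_VP = 3.99e-3, M_E1P = 3.99e-3, M_E2P = 3.99e-3,
         M_VD = 2.66e-3, M_ED = 1.33e-3,
         M_C = 15.8, M_N = 0.974)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(s))
    if (length(unknown))
      stop("unknown state component(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    s[names(over)] <- unlist(over)
  }
  if (any(s < 0)) stop("state components must be >= 0", call. = FALSE)
  s
}

# nitrogen content per pool column, in column order
.n_N_vector <- function(p) {
  c(p$n_N_PP, p$n_N_PD, p$n_N_PV, p$n_N_PE, p$n_N_VC, p$n_N_EC,
    p$n_N_VP, p$n_N_E1P, p$n_N_E2P, p$n_N_VD, p$n_N_ED)
}

#' Conserved carbon and nitrogen totals of a state
#'
#' Total carbon is the sum of the 11 organic pools plus carbon dioxide;
#' total nitrogen weights each pool by its nitrogen content and adds
#' ammonia.  Both are exact invariants of the dynamics because the
#' nutrient derivatives are defined as minus the summed organic net rates.
#'
#' @param state Named 13-component state vector.
#' @param p An \code{"ecosystem_params"} record.
#' @return Named numeric vector \code{c(total_C, total_N)}.
#' @export
conserved_totals <- function(state, p) {
  pools <- state[seq_len(11L)]
  c(total_C = sum(pools) + state[["M_C"]],
    total_N = sum(.n_N_vector(p) * pools) + state[["M_N"]])
}
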