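# The canonical community model proper: every mass flux between the 11
# organic pools, assembled into the signed process-by-pool flux matrix,
# and the 13 time-derivatives with exact nutrient closure.
#
# Sign convention: a flux that removes mass from a pool column is
# negative, one that adds is positive.  Cells not touched by a process
# are exactly zero.  Nutrient dynamics are not modelled directly: carbon
# dioxide receives minus the summed net organic carbon rates and ammonia
# minus the nitrogen-weighted sum, which closes both balances to floating
# point by construction.

# multiply the Arrhenius-corrected rate parameters by `arrh`, respecting
# the exclusion list
.scale_params <- function(p, arrh) {
  if (arrh == 1) return(p)
  nms <- setdiff(.arrhenius_rates, p$arrhenius_exclusions)
  p[nms] <- lapply(p[nms], `*`, arrh)
  p
}

.zero_rows <- function(rows) {
  matrix(0, nrow = length(rows), ncol = length(.pool_cols),
         dimnames = list(rows, .pool_cols))
}

#' Maintenance split between reserve and structure
#'
#' Somatic maintenance is a fixed demand paid through a demand-driven
#' preference SU ([preference_su_demand()]) that prefers mobilized reserve
#' over structure.  The structure-derived arrival flux is set exactly equal
#' to the demand ("just sufficient for paying all maintenance"), so the
#' demand can always be met; whatever the SU does not take from structure
#' is channelled straight back and never enters the mass balance.  The
#' structure share is converted at the growth cost \code{y}, and the split
#' closes exactly: \code{from_reserve + y * from_structure = demand}.
#'
#' @param J_mobilized Mobilized reserve flux arriving at the SU
#'   (C-mol reserve per day), \code{>= 0}.
#' @param demand Total maintenance demand in reserve units
#'   (C-mol reserve per day), \code{>= 0}.
#' @param y Reserve cost per unit structure (C-mol per C-mol), \code{> 0}.
#' @param rho Preference parameter of the SU, \code{> 0}.
#' @return List with \code{from_reserve} (reserve units) and
#'   \code{from_structure} (structure units), both \code{>= 0}.
#' @export
maintenance_split <- function(J_mobilized, demand, y, rho) {
  if (demand < 0) stop("`demand` must be >= 0", call. = FALSE)
  if (demand == 0) return(list(from_reserve = 0, from_structure = 0))
  su <- preference_su_demand(J1 = J_mobilized, J2 = demand, kP = demand,
                             rho = rho)
  list(from_reserve = su$flux_preferred,
       from_structure = su$flux_alternative / y)
}

#' Consumer process fluxes
#'
#' The five consumer rows of the flux matrix: predation on producer and
#' decomposer structure as a two-prey type II response sharing one
#' denominator, co-ingestion of prey reserves in proportion to prey
#' reserve density, assimilation into consumer reserve with the conversion
#' yields, the structure fraction not assimilated egested as faeces;
#' reserve mobilization, the preference-SU maintenance split, growth from
#' the reserve remainder; and background death with the hyperbolic
#' reserve-density modifier routing structure and reserve into the
#' dead-consumer detritus pools.
#'
#' @param state Named 13-component state vector.
#' @param p An \code{"ecosystem_params"} record (rates at reference
#'   temperature).
#' @param arrh Arrhenius correction factor applied to the rate parameters.
#' @return A 5 x 11 signed flux matrix (rows \code{A1C}, \code{A2C},
#'   \code{GC}, \code{DC}, \code{HC}).
#' @export
consumer_fluxes <- function(state, p, arrh = 1) {
  .check_state(state)
  p <- .scale_params(p, arrh)
  fm <- .zero_rows(c("A1C", "A2C", "GC", "DC", "HC"))
  M_VC <- state[["M_VC"]]
  if (M_VC <= 0) return(fm)

  M_VP <- state[["M_VP"]]; M_VD <- state[["M_VD"]]
  m_E1P <- if (M_VP > 0) state[["M_E1P"]] / M_VP else 0
  m_E2P <- if (M_VP > 0) state[["M_E2P"]] / M_VP else 0
  m_ED <- if (M_VD > 0) state[["M_ED"]] / M_VD else 0
  m_EC <- state[["M_EC"]] / M_VC

  # predation: two-prey type II on scaled structure densities
  x_P <- M_VP / p$K_VP
  x_D <- M_VD / p$K_VD
  den <- 1 + x_P + x_D
  J_VP <- -M_VC * p$j_VP_AC_m * x_P / den
  J_VD <- -M_VC * p$j_VD_AC_m * x_D / den

  fm["A1C", "VP"] <- J_VP
  fm["A1C", "E1P"] <- m_E1P * J_VP
  fm["A1C", "E2P"] <- m_E2P * J_VP
  fm["A1C", "EC"] <- -(p$y_EC_VP + p$y_EC_E1P * m_E1P +
                         p$y_EC_E2P * m_E2P) * J_VP
  fm["A1C", "PP"] <- -p$y_PP_VP * J_VP

  fm["A2C", "VD"] <- J_VD
  fm["A2C", "ED"] <- m_ED * J_VD
  fm["A2C", "EC"] <- -(p$y_EC_VD + p$y_EC_ED * m_ED) * J_VD
  fm["A2C", "PD"] <- -p$y_PD_VD * J_VD

  # mobilization, maintenance split, growth
  r_VC <- (p$k_EC * m_EC - p$j_EC_MC) / (m_EC + p$y_EC_VC)
  J_mob <- (p$k_EC - r_VC) * m_EC * M_VC          # = -J_EC,CC >= 0
  demand <- p$j_EC_MC * M_VC
  ms <- maintenance_split(J_mob, demand, p$y_EC_VC, p$rho)

  fm["DC", "EC"] <- -ms$from_reserve
  fm["DC", "VC"] <- -ms$from_structure
  growth_res <- J_mob - ms$from_reserve           # reserve left for growth
  fm["GC", "EC"] <- -growth_res
  fm["GC", "VC"] <- growth_res / p$y_EC_VC

  # background death, saturating in reserve density
  death <- p$h_C * M_VC * (m_EC / p$y_EC_VC) / (1 + m_EC / p$y_EC_VC)
  fm["HC", "PV"] <- death
  fm["HC", "VC"] <- -death
  fm["HC", "PE"] <- m_EC * death
  fm["HC", "EC"] <- -m_EC * death
  fm
}

#' Producer assimilation fluxes
#'
#' Synthesis of the two producer reserves by complementary-substrate SUs:
#' reserve 1 (carbohydrate) from light and carbon dioxide (two
#' non-substitutable substrates), reserve 2 (nitrogenous) from light,
#' carbon dioxide and ammonia (three).  Each scaled availability is the
#' driver divided by its half-saturation constant, and the saturation
#' level \eqn{f} follows [su_parallel_complementary()] with unit
#' processing capacity, so \eqn{f \in [0, 1)}.
#'
#' @inheritParams consumer_fluxes
#' @param J_L Light available to the producer after self-shading
#'   (MJ/m^2/d).
#' @return A 2 x 11 signed flux matrix (rows \code{A1P}, \code{A2P}).
#' @export
producer_assimilation <- function(state, J_L, p, arrh = 1) {
  .check_state(state)
  if (J_L < 0) stop("`J_L` must be >= 0", call. = FALSE)
  p <- .scale_params(p, arrh)
  fm <- .zero_rows(c("A1P", "A2P"))
  M_VP <- state[["M_VP"]]
  if (M_VP <= 0) return(fm)
  x_L1 <- J_L / p$J_K_L1
  x_C1 <- state[["M_C"]] / p$K_C1
  f_P1 <- su_parallel_complementary(c(x_L1, x_C1), kmax = 1)
  x_L2 <- J_L / p$J_K_L2
  x_C2 <- state[["M_C"]] / p$K_C2
  x_N2 <- state[["M_N"]] / p$K_N2
  f_P2 <- su_parallel_complementary(c(x_L2, x_C2, x_N2), kmax = 1)
  fm["A1P", "E1P"] <- M_VP * p$j_E1P_A1P_m * f_P1
  fm["A2P", "E2P"] <- M_VP * p$j_E2P_A2P_m * f_P2
  fm
}

# producer maintenance/growth machinery at a trial specific growth rate r;
# `pT` must already be temperature-scaled
.producer_balance <- function(r, state, pT) {
  M_VP <- state[["M_VP"]]
  m <- c(state[["M_E1P"]], state[["M_E2P"]]) / M_VP
  k <- c(pT$k_E1P, pT$k_E2P)
  jm <- c(pT$j_E1P_MP, pT$j_E2P_MP)
  yv <- c(pT$y_E1P_VP, pT$y_E2P_VP)
  J_mob <- pmax(0, m * (k - r) * M_VP)   # mobilized reserve fluxes
  from_res <- numeric(2)
  from_struct <- numeric(2)
  for (i in 1:2) {
    ms <- maintenance_split(J_mob[i], jm[i] * M_VP, yv[i], pT$rho)
    from_res[i] <- ms$from_reserve
    from_struct[i] <- ms$from_structure
  }
  avail <- pmax(0, J_mob - from_res)     # reserve left for the growth SU
  a <- avail / yv                        # in structure units
  J_G <- if (a[1] > 0 && a[2] > 0)
    1 / (1 / a[1] + 1 / a[2] - 1 / (a[1] + a[2])) else 0
  list(J_mob = J_mob, from_res = from_res, from_struct = from_struct,
       avail = avail, J_G = J_G,
       residual = (J_G - sum(from_struct)) / M_VP - r)
}

#' Implicit producer growth-rate solve and growth/dissipation fluxes
#'
#' The producer pays maintenance from each reserve (and, failing that,
#' from structure) through two demand-driven preference SUs, and builds
#' structure from the two reserve remainders through a growth SU with two
#' non-substitutable substrates.  Because mobilization depends on the
#' specific growth rate \eqn{\dot r} while \eqn{\dot r} is the net outcome
#' of growth minus structural maintenance, \eqn{\dot r} solves the scalar
#' equation
#' \deqn{g(\dot r) = (J_{VP,GP}(\dot r) - J^{MP}_{V_1P}(\dot r)
#'       - J^{MP}_{V_2P}(\dot r)) / M_{VP} - \dot r = 0,}
#' found by bracketed root-finding (the bracket
#' \eqn{[-(j_{E_1P,MP}/y_{E_1P,VP} + j_{E_2P,MP}/y_{E_2P,VP}) -
#' \max \dot k_{E_iP},\; \max \dot k_{E_iP}]} always encloses a sign
#' change).  Of each reserve flux rejected by the growth SU a fraction
#' \eqn{\kappa_{E_i}} returns to the reserve and the rest dissipates; the
#' rejected amount is the non-negative difference between the reserve
#' offered to the SU and what the SU consumed, which is the only reading
#' under which total mass balances.
#'
#' @inheritParams consumer_fluxes
#' @return List with \code{r} (the solved specific growth rate, 1/day),
#'   \code{fluxes} (a 2 x 11 signed matrix, rows \code{GP} and \code{DP})
#'   and \code{residual} (the value of \eqn{g} at the root).
#' @export
producer_growth_solve <- function(state, p, arrh = 1) {
  .check_state(state)
  pT <- .scale_params(p, arrh)
  fm <- .zero_rows(c("GP", "DP"))
  M_VP <- state[["M_VP"]]
  if (M_VP <= 0)
    return(list(r = 0, fluxes = fm, residual = 0))

  k_max <- max(pT$k_E1P, pT$k_E2P)
  lo <- -(pT$j_E1P_MP / pT$y_E1P_VP + pT$j_E2P_MP / pT$y_E2P_VP) - k_max
  hi <- k_max
  g <- function(r) .producer_balance(r, state, pT)$residual
  g_lo <- g(lo); g_hi <- g(hi)
  if (!(g_lo > 0 && g_hi < 0))
    stop("producer growth solve: no sign change in bracket [", lo, ", ", hi,
         "]; g = (", g_lo, ", ", g_hi, ")", call. = FALSE)
  root <- stats::uniroot(g, lower = lo, upper = hi, f.lower = g_lo,
                         f.upper = g_hi, tol = 1e-13 * max(1, k_max))$root
  bal <- .producer_balance(root, state, pT)
  # polish by bisection if the accepted step is not tight enough
  if (abs(bal$residual) > 1e-12 * max(1, k_max)) {
    lo2 <- root - 1e-8; hi2 <- root + 1e-8
    while (g(lo2) <= 0) lo2 <- lo2 - 1e-8
    while (g(hi2) >= 0) hi2 <- hi2 + 1e-8
    for (it in 1:60) {
      mid <- 0.5 * (lo2 + hi2)
      if (g(mid) > 0) lo2 <- mid else hi2 <- mid
    }
    root <- 0.5 * (lo2 + hi2)
    bal <- .producer_balance(root, state, pT)
  }

  yv <- c(pT$y_E1P_VP, pT$y_E2P_VP)
  kap <- c(pT$kappa_E1, pT$kappa_E2)
  rejected <- pmax(0, bal$avail - yv * bal$J_G)
  fm["GP", "VP"] <- bal$J_G
  fm["GP", c("E1P", "E2P")] <- -yv * bal$J_G
  fm["DP", "VP"] <- -sum(bal$from_struct)
  fm["DP", c("E1P", "E2P")] <- -(1 - kap) * rejected - bal$from_res
  list(r = root, fluxes = fm, residual = bal$residual)
}

#' Decomposer process fluxes
#'
#' The six decomposer rows: uptake of the four detritus pools as a
#' four-substrate substitutable SU (multi-prey type II sharing one
#' denominator), assimilation into decomposer reserve with the per-pool
#' yields, then mobilization, preference-SU maintenance split and growth,
#' structurally identical to the consumer.
#'
#' @inheritParams consumer_fluxes
#' @return A 6 x 11 signed flux matrix (rows \code{A1D} to \code{A4D},
#'   \code{GD}, \code{DD}).
#' @export
decomposer_fluxes <- function(state, p, arrh = 1) {
  .check_state(state)
  p <- .scale_params(p, arrh)
  fm <- .zero_rows(c("A1D", "A2D", "A3D", "A4D", "GD", "DD"))
  M_VD <- state[["M_VD"]]
  if (M_VD <= 0) return(fm)

  pools <- c("PP", "PD", "PV", "PE")
  x <- c(state[["M_PP"]] / p$K_PP, state[["M_PD"]] / p$K_PD,
         state[["M_PV"]] / p$K_PV, state[["M_PE"]] / p$K_PE)
  jmax <- c(p$j_PP_A1D_m, p$j_PD_A2D_m, p$j_PV_A3D_m, p$j_PE_A4D_m)
  yE <- c(p$y_ED_PP, p$y_ED_PD, p$y_ED_PV, p$y_ED_PE)
  den <- 1 + sum(x)
  removal <- -jmax * x / den * M_VD
  for (i in 1:4) {
    row <- paste0("A", i, "D")
    fm[row, pools[i]] <- removal[i]
    fm[row, "ED"] <- -yE[i] * removal[i]
  }

  m_ED <- state[["M_ED"]] / M_VD
  r_VD <- (p$k_ED * m_ED - p$j_ED_MD) / (m_ED + p$y_ED_VD)
  J_mob <- (p$k_ED - r_VD) * m_ED * M_VD
  demand <- p$j_ED_MD * M_VD
  ms <- maintenance_split(J_mob, demand, p$y_ED_VD, p$rho)
  fm["DD", "ED"] <- -ms$from_reserve
  fm["DD", "VD"] <- -ms$from_structure
  growth_res <- J_mob - ms$from_reserve
  fm["GD", "ED"] <- -growth_res
  fm["GD", "VD"] <- growth_res / p$y_ED_VD
  fm
}

.check_state <- function(state) {
  if (length(state) != 13L)
    stop("`state` must have 13 components", call. = FALSE)
  if (any(state < 0))
    stop("state components must be >= 0; offending: ",
         paste(.state_names[state < 0], collapse = ", "), call. = FALSE)
  invisible(state)
}

#' Assemble the full process-by-pool flux matrix
#'
#' Evaluates the seasonal drivers at time \code{t} (temperature once, its
#' Arrhenius factor applied to every rate parameter; irradiance attenuated
#' by producer self-shading) and stacks all process rows from
#' [consumer_fluxes()], [producer_assimilation()],
#' [producer_growth_solve()] and [decomposer_fluxes()] into the signed
#' 15 x 11 flux matrix.  Cells not touched by any process are exactly 0.
#'
#' @inheritParams consumer_fluxes
#' @param t Time (day), phase of the seasonal forcing.
#' @return A matrix of class \code{"flux_matrix"} with the process rows
#'   and pool columns of [flux_matrix_dimnames()], in umol C/L/d; the
#'   solved producer growth rate is attached as attribute
#'   \code{"r_producer"}.
#' @export
assemble_flux_matrix <- function(state, t, p) {
  .check_state(state)
  fp <- p$forcing
  arrh <- arrhenius_factor(seasonal_temperature(t, fp), fp)
  J_L <- self_shaded_light(seasonal_irradiance(t, fp), state[["M_VP"]], fp)
  gp <- producer_growth_solve(state, p, arrh)
  fm <- rbind(consumer_fluxes(state, p, arrh),
              producer_assimilation(state, J_L, p, arrh),
              gp$fluxes,
              decomposer_fluxes(state, p, arrh))
  fm <- fm[.process_rows, , drop = FALSE]
  attr(fm, "r_producer") <- gp$r
  class(fm) <- c("flux_matrix", class(fm))
  fm
}

#' @export
print.flux_matrix <- function(x, digits = 4, ...) {
  cat("Process-by-pool flux matrix (umol C/L/d)\n")
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(signif(y, digits), ...)
  invisible(x)
}

#' Time derivatives of the 13-component ecosystem state
#'
#' Column sums of the flux matrix give the net rate of each of the 11
#' organic pools; carbon dioxide receives minus their total and ammonia
#' minus their nitrogen-weighted total, so total carbon and total nitrogen
#' are conserved identically.
#'
#' @inheritParams assemble_flux_matrix
#' @return Named numeric vector of the 13 derivatives (umol C/L/d; umol
#'   N/L/d for \code{M_N}).
#' @export
ecosystem_derivatives <- function(t, state, p) {
  fm <- assemble_flux_matrix(state, t, p)
  net <- colSums(fm)
  d <- c(net, -sum(net), -sum(.n_N_vector(p) * net))
  names(d) <- .state_names
  d
}
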