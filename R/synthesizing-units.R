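# Closed-form synthesizing-unit (SU) rate laws.
#
# A synthesizing unit is a generalized enzyme: a server that binds arriving
# substrate "particles" (a Poisson stream) and releases product.  Its
# pseudo-steady-state throughput yields the saturating kinetics used
# throughout DEB models.  Substrates are either substitutable (each alone
# suffices for product formation) or non-substitutable/complementary (all
# are required).  All functions here are the closed-form stationary rates;
# su_markov_oracle() provides the independent brute-force equilibrium.

#' Single-substrate SU throughput (Holling type II)
#'
#' Stationary processing rate of a synthesizing unit handling one substrate:
#' the classic hyperbolic (disc-equation) functional response
#' \eqn{\dot k \, X / (K + X)}.
#'
#' @param X Substrate density (amount per volume), \code{>= 0}.
#' @param K Half-saturation density, \code{> 0}.
#' @param kmax Maximum processing rate (per time), \code{> 0}.
#' @return The processing rate, in \code{[0, kmax)}.
#' @examples
#' su_single(X = 2, K = 2, kmax = 1)  # half saturation -> 0.5
#' @export
su_single <- function(X, K, kmax) {
  if (K <= 0) stop("`K` must be > 0", call. = FALSE)
  if (kmax <= 0) stop("`kmax` must be > 0", call. = FALSE)
  if (any(X < 0)) stop("`X` must be >= 0", call. = FALSE)
  kmax * X / (K + X)
}

#' Multi-substrate substitutable SU throughput
#'
#' Stationary per-substrate processing rates of an SU offered \code{n}
#' substitutable substrates, the multi-prey Holling type II response:
#' \eqn{\dot k_i (X_i/K_i) / (1 + \sum_j X_j/K_j)}.
#'
#' @param X Numeric vector of substrate densities, all \code{>= 0}.
#' @param K Numeric vector of half-saturation densities, all \code{> 0}.
#' @param kmax Numeric vector of per-substrate maximum processing rates,
#'   all \code{> 0}.
#' @return Numeric vector of per-substrate rates; \code{rate[i]} lies in
#'   \code{[0, kmax[i])} and the function reduces to [su_single()] for
#'   \code{n = 1}.
#' @export
su_substitutable <- function(X, K, kmax) {
  n <- length(X)
  if (n < 1L) stop("at least one substrate is required", call. = FALSE)
  if (length(K) != n || length(kmax) != n)
    stop("`X`, `K` and `kmax` must have equal length", call. = FALSE)
  if (any(X < 0)) stop("`X` must be >= 0", call. = FALSE)
  if (any(K <= 0) || any(kmax <= 0))
    stop("`K` and `kmax` must be > 0", call. = FALSE)
  x <- X / K
  kmax * x / (1 + sum(x))
}

#' Demand-driven preference SU
#'
#' An SU offered two substitutable substrates with a preference for the
#' first: an item of substrate 1 displaces a bound item of substrate 2.
#' Under demand kinetics the product formation rate is fixed at the demand
#' \code{kP} and the dissociation rate \eqn{\dot k} (with
#' \eqn{\dot k_1 = \dot k}, \eqn{\dot k_2 = \rho \dot k}) is tuned to meet
#' it.  Eliminating the occupancies turns the delivery balance into the
#' quadratic \eqn{A \dot k^2 + B \dot k + C = 0} with
#' \deqn{A = \rho (y_1 J_1 + y_2 J_2 - k_P)}
#' \deqn{B = y_1 J_1 (J_1 + J_2) - (J_1 \rho + J_1 + J_2) k_P}
#' \deqn{C = -J_1 (J_1 + J_2) k_P}
#' solved on the \eqn{(-B + \sqrt{B^2 - 4AC})/(2A)} branch.  When
#' \eqn{|A|} is negligible relative to \eqn{|B|} the equation degenerates
#' and the linear root \eqn{-C/B} is used instead, which keeps the solution
#' continuous across the degeneracy.
#'
#' The flux delivered from the preferred substrate is
#' \eqn{y_1 \dot k J_1 / (\dot k + J_1)}; the alternative flux is defined
#' as the remainder \code{kP - flux_preferred} so that the demand budget
#' closes exactly in floating point.  At \code{J1 = 0} the quadratic
#' collapses to \eqn{\dot k = 0} and the whole demand is met from the
#' alternative substrate.
#'
#' @param J1 Arrival flux of the preferred substrate (amount per time),
#'   \code{>= 0}.
#' @param J2 Arrival flux of the less-preferred substrate, \code{>= 0}.
#' @param kP Demanded product rate, \code{> 0}.
#' @param rho Preference parameter \eqn{\rho = \dot k_2 / \dot k_1},
#'   \code{> 0}; small values express strong preference for substrate 1.
#' @param y1,y2 Product yield per particle of substrate 1 and 2.
#' @return A list with components \code{k_diss} (the solved dissociation
#'   rate), \code{flux_preferred} and \code{flux_alternative} (product
#'   rates summing exactly to \code{kP}).
#' @export
preference_su_demand <- function(J1, J2, kP, rho, y1 = 1, y2 = 1) {
  if (kP <= 0) stop("`kP` must be > 0", call. = FALSE)
  if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (J1 < 0 || J2 < 0) stop("arrival fluxes must be >= 0", call. = FALSE)
  if (y1 <= 0 || y2 <= 0) stop("yields must be > 0", call. = FALSE)

  if (J1 == 0) {
    # quadratic collapses to k = 0: demand is met entirely from substrate 2
    return(list(k_diss = 0, flux_preferred = 0, flux_alternative = kP))
  }

  A <- rho * (y1 * J1 + y2 * J2 - kP)
  B <- y1 * J1 * (J1 + J2) - (J1 * rho + J1 + J2) * kP
  C <- -J1 * (J1 + J2) * kP

  # delivery rate at dissociation rate k (the balance the root must solve)
  delivery <- function(k) {
    y1 * k * J1 / (k + J1) +
      y2 * rho * k^2 * J2 / ((k + J1) * (rho * k + J1 + J2))
  }

  if (abs(A) < 1e-12 * abs(B)) {
    # near-degenerate quadratic: the finite root is -C/B; if that is not
    # admissible the true root diverges (supply barely meets the demand and
    # the SU must cycle infinitely fast)
    k <- -C / B
    if (!is.finite(k) || k < 0) k <- Inf
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0)
      stop("preference SU: negative discriminant (J1 = ", J1, ", J2 = ", J2,
           ", kP = ", kP, ", rho = ", rho, ")", call. = FALSE)
    sq <- sqrt(disc)
    # cancellation-free evaluation of both roots, then keep the positive
    # root that actually balances the demand
    r1 <- if (B <= 0) (-B + sq) / (2 * A) else (2 * C) / (-B - sq)
    r2 <- if (B <= 0) (2 * C) / (-B + sq) else (-B - sq) / (2 * A)
    cand <- c(r1, r2)
    cand <- cand[is.finite(cand) & cand >= 0]
    k <- if (length(cand))
      cand[which.min(abs(vapply(cand, delivery, 0) - kP))] else NA_real_
  }
  if (is.infinite(k)) {
    if (y1 * J1 + y2 * J2 < kP * (1 - 1e-9))
      stop("preference SU: supply y1*J1 + y2*J2 = ", y1 * J1 + y2 * J2,
           " cannot meet demand kP = ", kP, call. = FALSE)
    fp <- min(y1 * J1, kP)
    return(list(k_diss = Inf, flux_preferred = fp,
                flux_alternative = kP - fp))
  }
  if (!is.finite(k) || k < 0 ||
      abs(delivery(k) - kP) > 1e-6 * kP)
    stop("preference SU: no positive dissociation rate meets the demand ",
         "(supply y1*J1 + y2*J2 = ", y1 * J1 + y2 * J2,
         " vs demand kP = ", kP, ")", call. = FALSE)

  fp <- y1 * k * J1 / (k + J1)
  fp <- min(max(fp, 0), kP)
  list(k_diss = k, flux_preferred = fp, flux_alternative = kP - fp)
}

#' Parallel complementary (non-substitutable) SU throughput
#'
#' Stationary product rate of an SU that requires all of \code{n >= 2}
#' non-substitutable substrates, bound in parallel (the binding of one does
#' not block the others).  For two substrates the rate is
#' \deqn{\dot J_C = (1/k_{max} + 1/J_A + 1/J_B - 1/(J_A+J_B))^{-1},}
#' and in general the reciprocal rate is the inclusion-exclusion sum
#' \eqn{1/k_{max} + \sum_{\emptyset \ne S} (-1)^{|S|+1} (\sum_{i \in S}
#' J_i)^{-1}} over subsets of the arrival fluxes.  The n > 2 form is
#' validated against the Markov-chain equilibrium oracle in the test suite
#' rather than taken on faith.
#'
#' @param arrivals Numeric vector of \code{n >= 2} arrival fluxes,
#'   all \code{>= 0}.
#' @param kmax Optional maximum processing rate; omit (\code{NULL}) for an
#'   SU whose product release is not rate-limited, as for the producer
#'   growth SU.
#' @return The product formation rate; 0 whenever any arrival is 0, and
#'   never exceeding \code{min(kmax, min(arrivals))}.
#' @export
su_parallel_complementary <- function(arrivals, kmax = NULL) {
  n <- length(arrivals)
  if (n < 2L) stop("at least two substrates are required", call. = FALSE)
  if (any(arrivals < 0)) stop("arrival fluxes must be >= 0", call. = FALSE)
  if (!is.null(kmax) && kmax <= 0) stop("`kmax` must be > 0", call. = FALSE)
  if (any(arrivals == 0)) return(0)
  inv <- if (is.null(kmax)) 0 else 1 / kmax
  for (m in seq_len(n)) {
    sign <- if (m %% 2L == 1L) 1 else -1
    subset_sums <- utils::combn(arrivals, m, FUN = sum)
    inv <- inv + sign * sum(1 / subset_sums)
  }
  1 / inv
}

#' Sequential complementary SU throughput
#'
#' As [su_parallel_complementary()], but the substrates must bind one after
#' the other in a fixed order, so the expected cycle time is the plain sum
#' of servicing and interarrival times:
#' \eqn{\dot J_C = (1/k_{max} + \sum_i 1/J_i)^{-1}}.  Sequential processing
#' is always slower than parallel processing on identical inputs.
#'
#' @inheritParams su_parallel_complementary
#' @param kmax Maximum processing rate, required here.
#' @return The product formation rate; 0 if any arrival is 0.
#' @export
su_sequential <- function(arrivals, kmax) {
  if (length(arrivals) < 2L)
    stop("at least two substrates are required", call. = FALSE)
  if (any(arrivals < 0)) stop("arrival fluxes must be >= 0", call. = FALSE)
  if (kmax <= 0) stop("`kmax` must be > 0", call. = FALSE)
  if (any(arrivals == 0)) return(0)
  1 / (1 / kmax + sum(1 / arrivals))
}

#' Liebig minimum-operator approximation
#'
#' The classical law-of-the-minimum alternative to the complementary SU:
#' the rate is limited by the scarcest substrate alone,
#' \eqn{k_{max} \min_i X_i/(K_i + X_i)}.  Provided only for comparison with
#' [su_parallel_complementary()]; the SU form is smooth where the minimum
#' operator has kinks.
#'
#' @param X Numeric vector of substrate densities, \code{>= 0}.
#' @param K Numeric vector of half-saturation densities, \code{> 0}.
#' @param kmax Maximum processing rate, \code{> 0}.
#' @return The Liebig-limited rate.
#' @export
su_minimum_operator <- function(X, K, kmax) {
  if (length(X) != length(K))
    stop("`X` and `K` must have equal length", call. = FALSE)
  if (any(X < 0)) stop("`X` must be >= 0", call. = FALSE)
  if (any(K <= 0) || kmax <= 0)
    stop("`K` and `kmax` must be > 0", call. = FALSE)
  kmax * min(X / (K + X))
}
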