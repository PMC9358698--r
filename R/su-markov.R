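# Brute-force stationary-distribution oracle for synthesizing units.
#
# Every SU in this package is, underneath, a continuous-time Markov chain
# over binding states.  The closed-form rates are pseudo-steady-state
# solutions of those chains; this file solves the stationary linear system
# directly so the closed forms can be checked against an independent route.

#' Stationary occupancies and throughput of an SU state chain
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum \pi = 1} for the stationary
#' distribution of a finite continuous-time Markov chain and returns the
#' product throughput \eqn{\sum_s p_s \pi_s}, where \eqn{p_s} is the
#' product formation rate while in state \eqn{s}.
#'
#' @param rates Square matrix of non-negative transition rates;
#'   \code{rates[i, j]} is the rate of jumping from state \code{i} to state
#'   \code{j}.  The diagonal is ignored.
#' @param production Numeric vector of per-state product formation rates
#'   (typically dissociation rate times yield for the states that release
#'   product, 0 elsewhere).
#' @return List with \code{occupancy} (stationary probabilities, summing to
#'   1) and \code{throughput}.
#' @seealso [markov_su_single()], [markov_su_substitutable()],
#'   [markov_su_preference()], [markov_su_parallel()] for chain builders.
#' @export
su_markov_oracle <- function(rates, production) {
  n <- nrow(rates)
  if (is.null(n) || n != ncol(rates))
    stop("`rates` must be a square matrix", call. = FALSE)
  if (length(production) != n)
    stop("`production` must have one entry per state", call. = FALSE)
  if (any(rates[row(rates) != col(rates)] < 0))
    stop("transition rates must be >= 0", call. = FALSE)
  Q <- rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- tryCatch(qr.solve(A, b),
                 error = function(e) stop("chain is reducible or singular: ",
                                          conditionMessage(e), call. = FALSE))
  if (any(pi < -1e-9))
    stop("chain is reducible: negative stationary probabilities", call. = FALSE)
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  list(occupancy = pi, throughput = sum(production * pi))
}

#' Binding chains for the standard SU types
#'
#' Constructors for the transition-rate matrix and production vector of the
#' SU state chains, ready to pass to [su_markov_oracle()]:
#' \describe{
#'   \item{\code{markov_su_single}}{two states (empty, busy); arrival
#'     \code{J}, dissociation \code{k}.}
#'   \item{\code{markov_su_substitutable}}{\code{n + 1} states (empty, or
#'     busy with substrate \code{i}); the per-substrate throughput is
#'     \code{k[i]} times the occupancy of state \code{i + 1}.}
#'   \item{\code{markov_su_preference}}{three states; an arriving preferred
#'     item displaces a bound alternative item without product formation.}
#'   \item{\code{markov_su_parallel}}{\eqn{2^n} states, one per subset of
#'     bound substrates; product is released from the fully bound state at
#'     rate \code{kmax}.}
#' }
#'
#' @param J,J1,J2 Arrival fluxes (per SU) of the substrates.
#' @param k,k1,k2 Dissociation rates.
#' @param arrivals Numeric vector of arrival fluxes, one per substrate.
#' @param kmax Dissociation (product release) rate from the fully bound
#'   state.
#' @param y1,y2 Product yields per substrate particle.
#' @return List with \code{rates}, \code{production} and, for the parallel
#'   chain, \code{states} (the subset labels).
#' @export
markov_su_single <- function(J, k) {
  rates <- matrix(0, 2, 2)
  rates[1, 2] <- J
  rates[2, 1] <- k
  list(rates = rates, production = c(0, k))
}

#' @rdname markov_su_single
#' @export
markov_su_substitutable <- function(J, k) {
  n <- length(J)
  stopifnot(length(k) == n)
  rates <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    rates[1, i + 1] <- J[i]
    rates[i + 1, 1] <- k[i]
  }
  list(rates = rates, production = c(0, k))
}

#' @rdname markov_su_single
#' @export
markov_su_preference <- function(J1, J2, k1, k2, y1 = 1, y2 = 1) {
  # states: 1 empty, 2 preferred bound, 3 alternative bound
  rates <- matrix(0, 3, 3)
  rates[1, 2] <- J1
  rates[1, 3] <- J2
  rates[3, 2] <- J1   # displacement, no product released
  rates[2, 1] <- k1
  rates[3, 1] <- k2
  list(rates = rates, production = c(0, y1 * k1, y2 * k2))
}

#' @rdname markov_su_single
#' @export
markov_su_parallel <- function(arrivals, kmax) {
  n <- length(arrivals)
  stopifnot(n >= 2, kmax > 0)
  nstates <- 2L^n
  # state s (1-based) encodes bound substrates in bits of s - 1
  bound <- function(s, i) bitwAnd(s - 1L, bitwShiftL(1L, i - 1L)) > 0L
  rates <- matrix(0, nstates, nstates)
  for (s in seq_len(nstates)) {
    for (i in seq_len(n)) {
      if (!bound(s, i))
        rates[s, s + bitwShiftL(1L, i - 1L)] <- arrivals[i]
    }
  }
  rates[nstates, 1] <- kmax
  production <- numeric(nstates)
  production[nstates] <- kmax
  list(rates = rates, production = production,
       states = vapply(seq_len(nstates) - 1L, function(s)
         paste(rev(as.integer(intToBits(s))[seq_len(n)]), collapse = ""), ""))
}
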