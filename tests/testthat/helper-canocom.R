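# Shared fixtures for the test suite.  The long reference runs are
# computed once per session and reused across files.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, config) {
  if (!exists(name, envir = .run_cache))
    assign(name, run_simulation(config), envir = .run_cache)
  get(name, envir = .run_cache)
}

default_run <- function() cached_run("default", simulation_config())

half_tol_run <- function()
  cached_run("half_tol", simulation_config(rtol = 5e-9, atol = 5e-11))

# a strictly positive random ecosystem state on realistic scales
random_state <- function() {
  s <- default_initial_state()
  s[] <- s * exp(stats::runif(13, -1, 1))
  s
}

# independent scalar root-find for the preference-SU dissociation rate:
# solve delivery(k) = kP directly on the printed balance
pref_su_root_oracle <- function(J1, J2, kP, rho, y1 = 1, y2 = 1) {
  delivery <- function(k)
    y1 * k * J1 / (k + J1) +
      y2 * rho * k^2 * J2 / ((k + J1) * (rho * k + J1 + J2))
  f <- function(k) delivery(k) - kP
  hi <- kP
  while (f(hi) < 0 && hi < 1e18) hi <- hi * 10
  stats::uniroot(f, c(0, hi), tol = 1e-15 * max(1, kP))$root
}

# damped fixed-point iteration for the producer specific growth rate,
# independent of the bracketed root-finder in the package
producer_fixed_point_oracle <- function(state, p, arrh = 1,
                                        alpha = 0.1, tol = 1e-11,
                                        maxit = 50000) {
  phi <- function(r) {
    # implied growth rate: run the maintenance/growth SUs at trial rate r
    M_VP <- state[["M_VP"]]
    m <- c(state[["M_E1P"]], state[["M_E2P"]]) / M_VP
    k <- c(p$k_E1P, p$k_E2P) * arrh
    jm <- c(p$j_E1P_MP, p$j_E2P_MP) * arrh
    yv <- c(p$y_E1P_VP, p$y_E2P_VP)
    avail <- numeric(2); fs <- numeric(2)
    for (i in 1:2) {
      J1 <- max(0, m[i] * (k[i] - r) * M_VP)
      ms <- maintenance_split(J1, jm[i] * M_VP, yv[i], p$rho)
      avail[i] <- max(0, J1 - ms$from_reserve)
      fs[i] <- ms$from_structure
    }
    a <- avail / yv
    J_G <- if (all(a > 0)) 1 / (1 / a[1] + 1 / a[2] - 1 / sum(a)) else 0
    (J_G - sum(fs)) / M_VP
  }
  r <- 0
  for (i in seq_len(maxit)) {
    r_new <- r + alpha * (phi(r) - r)
    if (abs(r_new - r) < tol) return(r_new)
    r <- r_new
  }
  stop("fixed-point iteration did not converge")
}
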