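# independent term-wise assembly of the whole flux matrix, written flat
# (every process equation spelled out) and using the scalar root-find and
# fixed-point oracles from the helpers instead of the package's solver
# code paths
oracle_flux_matrix <- function(state, t, p) {
  fp <- p$forcing
  arrh <- exp(fp$T_A / fp$T_1 - fp$T_A / seasonal_temperature(t, fp))
  J_L <- seasonal_irradiance(t, fp) * exp(-fp$K_S * state[["M_VP"]])
  dn <- flux_matrix_dimnames()
  fm <- matrix(0, length(dn$process), length(dn$pool), dimnames = dn)
  sget <- function(nm) state[[nm]]

  split_oracle <- function(J1, demand, y) {
    if (demand == 0) return(list(res = 0, struct = 0))
    if (J1 <= 0) return(list(res = 0, struct = demand / y))
    k <- pref_su_root_oracle(J1, demand, demand, p$rho)
    res <- k * J1 / (k + J1)
    list(res = res, struct = (demand - res) / y)
  }

  M_VC <- sget("M_VC")
  if (M_VC > 0) {
    m_E1P <- if (sget("M_VP") > 0) sget("M_E1P") / sget("M_VP") else 0
    m_E2P <- if (sget("M_VP") > 0) sget("M_E2P") / sget("M_VP") else 0
    m_ED <- if (sget("M_VD") > 0) sget("M_ED") / sget("M_VD") else 0
    m_EC <- sget("M_EC") / M_VC
    x_P <- sget("M_VP") / p$K_VP; x_D <- sget("M_VD") / p$K_VD
    J_VP <- -M_VC * p$j_VP_AC_m * arrh * x_P / (1 + x_P + x_D)
    J_VD <- -M_VC * p$j_VD_AC_m * arrh * x_D / (1 + x_P + x_D)
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
    r_VC <- (p$k_EC * arrh * m_EC - p$j_EC_MC * arrh) /
      (m_EC + p$y_EC_VC)
    J1 <- (p$k_EC * arrh - r_VC) * m_EC * M_VC
    sp <- split_oracle(J1, p$j_EC_MC * arrh * M_VC, p$y_EC_VC)
    fm["DC", "EC"] <- -sp$res
    fm["DC", "VC"] <- -sp$struct
    fm["GC", "EC"] <- -(J1 - sp$res)
    fm["GC", "VC"] <- (J1 - sp$res) / p$y_EC_VC
    death <- p$h_C * arrh * M_VC * (m_EC / p$y_EC_VC) /
      (1 + m_EC / p$y_EC_VC)
    fm["HC", "PV"] <- death; fm["HC", "VC"] <- -death
    fm["HC", "PE"] <- m_EC * death; fm["HC", "EC"] <- -m_EC * death
  }

  M_VP <- sget("M_VP")
  if (M_VP > 0) {
    x_L1 <- J_L / p$J_K_L1; x_C1 <- sget("M_C") / p$K_C1
    f1 <- if (x_L1 > 0 && x_C1 > 0)
      1 / (1 + 1 / x_L1 + 1 / x_C1 - 1 / (x_L1 + x_C1)) else 0
    x_L2 <- J_L / p$J_K_L2; x_C2 <- sget("M_C") / p$K_C2
    x_N2 <- sget("M_N") / p$K_N2
    f2 <- if (x_L2 > 0 && x_C2 > 0 && x_N2 > 0)
      1 / (1 + 1 / x_L2 + 1 / x_C2 + 1 / x_N2 - 1 / (x_L2 + x_C2) -
             1 / (x_L2 + x_N2) - 1 / (x_C2 + x_N2) +
             1 / (x_L2 + x_C2 + x_N2)) else 0
    fm["A1P", "E1P"] <- M_VP * p$j_E1P_A1P_m * arrh * f1
    fm["A2P", "E2P"] <- M_VP * p$j_E2P_A2P_m * arrh * f2
    r <- producer_fixed_point_oracle(state, p, arrh)
    m <- c(sget("M_E1P"), sget("M_E2P")) / M_VP
    k <- c(p$k_E1P, p$k_E2P) * arrh
    jm <- c(p$j_E1P_MP, p$j_E2P_MP) * arrh
    yv <- c(p$y_E1P_VP, p$y_E2P_VP)
    kap <- c(p$kappa_E1, p$kappa_E2)
    avail <- numeric(2); fs <- numeric(2); res <- numeric(2)
    for (i in 1:2) {
      J1 <- max(0, m[i] * (k[i] - r) * M_VP)
      sp <- split_oracle(J1, jm[i] * M_VP, yv[i])
      res[i] <- sp$res; fs[i] <- sp$struct
      avail[i] <- max(0, J1 - sp$res)
    }
    a <- avail / yv
    J_G <- if (all(a > 0)) 1 / (1 / a[1] + 1 / a[2] - 1 / sum(a)) else 0
    rej <- pmax(0, avail - yv * J_G)
    fm["GP", "VP"] <- J_G
    fm["GP", c("E1P", "E2P")] <- -yv * J_G
    fm["DP", "VP"] <- -sum(fs)
    fm["DP", c("E1P", "E2P")] <- -(1 - kap) * rej - res
  }

  M_VD <- sget("M_VD")
  if (M_VD > 0) {
    x <- c(sget("M_PP") / p$K_PP, sget("M_PD") / p$K_PD,
           sget("M_PV") / p$K_PV, sget("M_PE") / p$K_PE)
    jm4 <- c(p$j_PP_A1D_m, p$j_PD_A2D_m, p$j_PV_A3D_m, p$j_PE_A4D_m) * arrh
    yE <- c(p$y_ED_PP, p$y_ED_PD, p$y_ED_PV, p$y_ED_PE)
    pools <- c("PP", "PD", "PV", "PE")
    for (i in 1:4) {
      rem <- -jm4[i] * x[i] / (1 + sum(x)) * M_VD
      fm[paste0("A", i, "D"), pools[i]] <- rem
      fm[paste0("A", i, "D"), "ED"] <- -yE[i] * rem
    }
    m_ED <- sget("M_ED") / M_VD
    r_VD <- (p$k_ED * arrh * m_ED - p$j_ED_MD * arrh) / (m_ED + p$y_ED_VD)
    J1 <- (p$k_ED * arrh - r_VD) * m_ED * M_VD
    sp <- split_oracle(J1, p$j_ED_MD * arrh * M_VD, p$y_ED_VD)
    fm["DD", "ED"] <- -sp$res
    fm["DD", "VD"] <- -sp$struct
    fm["GD", "ED"] <- -(J1 - sp$res)
    fm["GD", "VD"] <- (J1 - sp$res) / p$y_ED_VD
  }
  fm
}

p_def <- default_ecosystem_params()

test_that("maintenance split closes the demand budget exactly", {
  set.seed(801)
  for (i in 1:40) {
    demand <- runif(1, 0.01, 2)
    J <- runif(1, 0, 3 * demand)
    y <- runif(1, 0.8, 2)
    ms <- maintenance_split(J, demand, y, rho = 10^runif(1, -3, 0))
    expect_gte(ms$from_reserve, 0)
    expect_gte(ms$from_structure, 0)
    expect_equal(ms$from_reserve + y * ms$from_structure, demand,
                 tolerance = 1e-12)
  }
  # no mobilized reserve: everything from structure
  ms <- maintenance_split(0, 1.2, y = 1.5, rho = 0.01)
  expect_equal(ms$from_reserve, 0)
  expect_equal(ms$from_structure, 1.2 / 1.5)
  # overwhelming reserve: structure untouched
  ms <- maintenance_split(1e8, 1, y = 1.5, rho = 0.01)
  expect_lt(ms$from_structure, 1e-6)
})

test_that("consumer fluxes vanish without consumers and keep prey ratios", {
  s <- default_initial_state(M_VC = 0)
  fm <- consumer_fluxes(s, p_def)
  expect_true(all(fm == 0))
  # equal scaled prey densities: removal ratio is the ratio of maxima (2:1)
  s <- default_initial_state(M_VP = 3 * p_def$K_VP, M_VD = 3 * p_def$K_VD)
  fm <- consumer_fluxes(s, p_def)
  expect_equal(fm["A1C", "VP"] / fm["A2C", "VD"],
               p_def$j_VP_AC_m / p_def$j_VD_AC_m)
  # faeces production is tied to structure removal by the faeces yield
  expect_equal(fm["A1C", "PP"], -p_def$y_PP_VP * fm["A1C", "VP"])
  expect_equal(fm["A2C", "PD"], -p_def$y_PD_VD * fm["A2C", "VD"])
})

test_that("reserve-rich consumers pay maintenance from reserves", {
  s <- default_initial_state(M_VC = 1, M_EC = 50)
  fm <- consumer_fluxes(s, p_def)
  demand <- p_def$j_EC_MC * 1
  expect_gt(-fm["DC", "EC"] / demand, 0.999)
  expect_lt(-fm["DC", "VC"], 1e-3 * demand)
})

test_that("consumer budget identity links growth and maintenance rows", {
  set.seed(802)
  for (i in 1:10) {
    s <- random_state()
    fm <- consumer_fluxes(s, p_def, arrh = 1)
    m_EC <- s[["M_EC"]] / s[["M_VC"]]
    r_VC <- (p_def$k_EC * m_EC - p_def$j_EC_MC) / (m_EC + p_def$y_EC_VC)
    J_mob <- (p_def$k_EC - r_VC) * m_EC * s[["M_VC"]]
    demand <- p_def$j_EC_MC * s[["M_VC"]]
    lhs <- fm["GC", "VC"] + fm["DC", "VC"]
    expect_equal(lhs, (J_mob - demand) / p_def$y_EC_VC, tolerance = 1e-9)
  }
})

test_that("producer assimilation needs every substrate of each reserve", {
  s <- default_initial_state(M_N = 0)
  fm <- producer_assimilation(s, J_L = 10, p_def)
  expect_equal(fm["A2P", "E2P"], 0)    # no ammonia, no nitrogen reserve
  expect_gt(fm["A1P", "E1P"], 0)       # carbohydrate reserve unaffected
  # saturation: both responses approach their maxima
  s <- default_initial_state(M_C = 1e9, M_N = 1e9)
  fm <- producer_assimilation(s, J_L = 1e9, p_def)
  expect_equal(fm["A1P", "E1P"],
               s[["M_VP"]] * p_def$j_E1P_A1P_m, tolerance = 1e-6)
  expect_equal(fm["A2P", "E2P"],
               s[["M_VP"]] * p_def$j_E2P_A2P_m, tolerance = 1e-6)
})

test_that("three-substrate producer response matches its Markov chain", {
  # all scaled densities at 1: the closed form gives 6/17
  f <- su_parallel_complementary(c(1, 1, 1), kmax = 1)
  expect_equal(f, 6 / 17, tolerance = 1e-12)
  ch <- markov_su_parallel(c(1, 1, 1), kmax = 1)
  expect_equal(su_markov_oracle(ch$rates, ch$production)$throughput,
               6 / 17, tolerance = 1e-10)
})

test_that("producer growth solve: starvation boundary and residual", {
  # no reserves at all: no growth, shrinkage pays maintenance
  s <- default_initial_state(M_E1P = 0, M_E2P = 0)
  gp <- producer_growth_solve(s, p_def)
  expect_equal(gp$fluxes["GP", "VP"], 0)
  expect_lt(gp$r, 0)
  expect_lt(abs(gp$residual), 1e-10)
  # no producer at all: all rows zero
  s <- default_initial_state(M_VP = 0)
  gp <- producer_growth_solve(s, p_def)
  expect_true(all(gp$fluxes == 0))
})

test_that("producer growth agrees with the fixed-point oracle", {
  # abundant reserves and no maintenance: r = J_G / M_VP at the root
  p0 <- default_ecosystem_params(j_E1P_MP = 0, j_E2P_MP = 0)
  s <- default_initial_state(M_VP = 1, M_E1P = 2, M_E2P = 1.5)
  gp <- producer_growth_solve(s, p0)
  expect_equal(gp$r, gp$fluxes["GP", "VP"] / 1)
  r_fp <- producer_fixed_point_oracle(s, p0)
  expect_lt(abs(gp$r - r_fp), 1e-8)
  # generic random states under the default parameters
  set.seed(803)
  for (i in 1:8) {
    s <- random_state()
    gp <- producer_growth_solve(s, p_def)
    expect_lt(abs(gp$residual), 1e-10)
    expect_lt(abs(gp$r - producer_fixed_point_oracle(s, p_def)), 1e-8)
  }
})

test_that("decomposer fluxes share the four-prey denominator", {
  s <- default_initial_state(M_PP = 0, M_PD = 0, M_PV = 0, M_PE = 0)
  fm <- decomposer_fluxes(s, p_def)
  expect_true(all(fm[c("A1D", "A2D", "A3D", "A4D"), ] == 0))
  # symmetric pools with equal parameters: equal fluxes
  s <- default_initial_state(M_PP = 0.05, M_PD = 0.05, M_PV = 0.05,
                             M_PE = 0.05)
  fm <- decomposer_fluxes(s, p_def)
  rem <- c(fm["A1D", "PP"], fm["A2D", "PD"], fm["A3D", "PV"],
           fm["A4D", "PE"])
  expect_equal(rem, rep(rem[1], 4))
  # a single active pool reduces to the substitutable SU rate
  s <- default_initial_state(M_PP = 0.3, M_PD = 0, M_PV = 0, M_PE = 0)
  fm <- decomposer_fluxes(s, p_def)
  x <- 0.3 / p_def$K_PP
  expect_equal(fm["A1D", "PP"],
               -p_def$j_PP_A1D_m * x / (1 + x) * s[["M_VD"]])
  expect_equal(fm["A1D", "PP"],
               -su_substitutable(0.3, p_def$K_PP, p_def$j_PP_A1D_m) *
                 s[["M_VD"]])
})

test_that("flux matrix matches an independent term-wise assembly", {
  # reference initial state at t = 0 plus random states and times
  s0 <- default_initial_state()
  fm <- assemble_flux_matrix(s0, t = 0, p_def)
  oracle <- oracle_flux_matrix(s0, t = 0, p_def)
  expect_equal(unclass(fm), oracle, tolerance = 1e-7, ignore_attr = TRUE)
  set.seed(804)
  for (i in 1:5) {
    s <- random_state()
    t <- runif(1, 0, 365)
    fm <- assemble_flux_matrix(s, t, p_def)
    expect_equal(unclass(fm), oracle_flux_matrix(s, t, p_def),
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("flux matrix structure: zeros, proportionality, sign discipline", {
  # lifeless water: nothing moves
  s <- default_initial_state(M_VC = 0, M_EC = 0, M_VP = 0, M_E1P = 0,
                             M_E2P = 0, M_VD = 0, M_ED = 0)
  fm <- assemble_flux_matrix(s, t = 100, p_def)
  expect_true(all(fm == 0))
  # cells never touched by a process stay exactly zero
  s <- random_state()
  fm <- assemble_flux_matrix(s, t = 40, p_def)
  expect_identical(unname(fm["A1C", "VC"]), 0)
  expect_identical(unname(fm["GC", "PP"]), 0)
  expect_identical(unname(fm["A1P", "VP"]), 0)
  expect_identical(unname(fm["GD", "PE"]), 0)
  # faeces cell is tied to the structure-removal cell
  expect_equal(fm["A1C", "PP"], -p_def$y_PP_VP * fm["A1C", "VP"])
  # sign discipline: assimilation adds to reserves, removal subtracts
  expect_lte(fm["A1C", "VP"], 0)
  expect_gte(fm["A1C", "EC"], 0)
  expect_gte(fm["A1P", "E1P"], 0)
  expect_lte(fm["DD", "ED"], 0)
})

test_that("derivatives conserve carbon and nitrogen identically", {
  set.seed(805)
  nN <- c(0.15, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15, 0, 0.8, 0.15, 0.15)
  for (i in 1:10) {
    s <- random_state()
    d <- ecosystem_derivatives(runif(1, 0, 1825), s, p_def)
    expect_equal(sum(d[1:11]) + d[["M_C"]], 0, tolerance = 1e-14)
    expect_equal(sum(nN * d[1:11]) + d[["M_N"]], 0, tolerance = 1e-14)
  }
})

test_that("producer reserve dissipation reduces to maintenance when all
           rejected reserve returns", {
  p1 <- default_ecosystem_params(kappa_E1 = 1, kappa_E2 = 1)
  s <- random_state()
  gp <- producer_growth_solve(s, p1)
  m <- c(s[["M_E1P"]], s[["M_E2P"]]) / s[["M_VP"]]
  for (i in 1:2) {
    col <- c("E1P", "E2P")[i]
    J1 <- max(0, m[i] * (c(p1$k_E1P, p1$k_E2P)[i] - gp$r) * s[["M_VP"]])
    ms <- maintenance_split(J1, c(p1$j_E1P_MP, p1$j_E2P_MP)[i] * s[["M_VP"]],
                            c(p1$y_E1P_VP, p1$y_E2P_VP)[i], p1$rho)
    expect_equal(gp$fluxes["DP", col], -ms$from_reserve, tolerance = 1e-10)
  }
})
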