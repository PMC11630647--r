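test_that("temperature law: half-inactivation, limits, and E0-independence", {
  tl <- temp_law(E0 = 0.013, dG_cat = 7e4, T_eq = 312, dH_eq = 4e5)
  # at T = T_eq the equilibrium denominator is exactly 2
  TK <- tl$T_eq
  kB <- 1.380649e-23; hP <- 6.62607015e-34; R <- 8.314462618
  eyring <- tl$E0 * kB * TK / hP * exp(-tl$dG_cat / (R * TK))
  expect_equal(temperature_factor(TK - 273.15, tl), eyring / 2,
               tolerance = 1e-12)

  # very sharp inactivation below T_eq: denominator -> 1
  tl2 <- temp_law(E0 = 1, dG_cat = 5e4, T_eq = 309, dH_eq = 1e7)
  TK2 <- 298.15
  expect_equal(temperature_factor(25, tl2),
               1 * kB * TK2 / hP * exp(-5e4 / (R * TK2)), tolerance = 1e-9)

  # the 308/298 K ratio is independent of E0 (computed from scratch here)
  ratio_expected <- (308 / 298) * exp(-5e4 / R * (1 / 308 - 1 / 298)) *
    (1 + exp(2e5 / R * (1 / 309 - 1 / 298))) /
    (1 + exp(2e5 / R * (1 / 309 - 1 / 308)))
  for (E0 in c(1e-3, 1, 42)) {
    tl3 <- temp_law(E0 = E0, dG_cat = 5e4, T_eq = 309, dH_eq = 2e5)
    expect_equal(temperature_factor(308 - 273.15, tl3) /
                   temperature_factor(298 - 273.15, tl3),
                 ratio_expected, tolerance = 1e-10)
  }

  # constant variant returns the constant
  expect_equal(temperature_factor(c(25, 37), 0.4), c(0.4, 0.4))
  expect_error(temperature_factor(31, NaN), "temp_law|constant")
})

test_that("temperature law has a unique interior maximum", {
  tl <- temp_law(E0 = 0.011, dG_cat = 7e4, T_eq = 312, dH_eq = 4e5)
  Ts <- seq(5, 55, by = 0.05)
  v <- temperature_factor(Ts, tl)
  d <- diff(v)
  # strictly increasing, then strictly decreasing: exactly one sign change
  expect_equal(sum(diff(sign(d)) != 0), 1L)
  i <- which.max(v)
  expect_gt(i, 1); expect_lt(i, length(Ts))
})

test_that("uptake rate: zero substrate, half-saturation, hand value", {
  p0 <- kinetic_params(
    uptake = rate_block(1, Km = 1, K = c(G = 1, n = Inf, PX = Inf, X = Inf),
                        nonremovable = c(Km = TRUE)),
    production = rate_block(0.1, Km = 0.1),
    maintenance = rate_block(0.01, Km = Inf))
  expect_equal(uptake_rate(0, 0, 0, 30, 31, p0), 0)
  # c = 1, Km = 1, K_G = 1, G = 1: 1 * 1/2 * 1/2 = 0.25
  expect_equal(uptake_rate(1, 0, 0, 30, 31, p0), 0.25)
  # no inhibitions, G = Km: half saturation
  p1 <- p0; p1$uptake <- rate_block(1, Km = 2, nonremovable = c(Km = TRUE))
  expect_equal(uptake_rate(2, 0, 0, 30, 31, p1), 0.5)
  expect_error(uptake_rate(-1, 0, 0, 30, 31, p0), "negative")
})

test_that("maintenance rate: empty product, activation terms, hand value", {
  base <- kinetic_params(
    uptake = rate_block(1, Km = 1, nonremovable = c(Km = TRUE)),
    production = rate_block(0.1, Km = 0.1),
    maintenance = rate_block(0.01, Km = Inf))
  expect_equal(maintenance_rate(1, 5, 2, 0.5, 40, 31, base), 0.01)
  # c = 0.01, K_g = 1 (gamma = 1), K_PX = 1 (PX = 1): 0.01 * 2 * 2 = 0.04
  p <- base
  p$maintenance <- rate_block(0.01, Km = 1,
                              K = c(G = Inf, n = Inf, PX = 1, X = Inf))
  expect_equal(maintenance_rate(1, 0, 0, 1, 30, 31, p), 0.04)
  expect_equal(maintenance_rate(0, 0, 0, 0, 30, 31, p), 0.01)
})

test_that("production rate: zero surplus, half-saturation, inhibition factor", {
  p <- kinetic_params(
    uptake = rate_block(1, Km = 1, nonremovable = c(Km = TRUE)),
    production = rate_block(0.2, Km = 0.05),
    maintenance = rate_block(0.01, Km = Inf))
  expect_equal(production_uptake_rate(0.1, 0.1, 0, 0, 0, 30, 31, p), 0)
  # surplus below maintenance is clamped at zero
  expect_equal(production_uptake_rate(0.05, 0.1, 0, 0, 0, 30, 31, p), 0)
  # s = Km: half saturation
  expect_equal(production_uptake_rate(0.15, 0.1, 0, 0, 0, 30, 31, p), 0.1)
  # n = K_n, s >> Km: approaches gmax/2
  p2 <- p
  p2$production <- rate_block(0.2, Km = 1e-6,
                              K = c(G = Inf, n = 2, PX = Inf, X = Inf))
  expect_equal(production_uptake_rate(1, 0, 0, 2, 0, 30, 31, p2), 0.1,
               tolerance = 1e-5)
})

test_that("growth partition preserves additivity and matches hand arithmetic", {
  p <- kinetic_params(
    uptake = rate_block(1, Km = 1, nonremovable = c(Km = TRUE)),
    production = rate_block(0.1, Km = 0.1),
    maintenance = rate_block(0.01, Km = Inf),
    yields = c(Y_XrG = 0.5, Y_PG = 0.9))
  # gamma_circ 0.3, gamma_pi 0.1, gamma_alpha 0.05, Xr/X = 0.8
  g <- growth_partition(0.3, 0.1, 0.05, p, Xr = 24, X = 30)
  expect_equal(g$g_mu, 0.15)
  expect_equal(g$pi, 0.1 * 0.9 * 0.8)       # 0.072
  expect_equal(g$mu, 0.072 + 0.15 * 0.5 * 0.8)  # 0.132
  # P = 0 and g_mu = 0: mu = pi = g_pi * Y_PG
  g2 <- growth_partition(0.15, 0.1, 0.05, p, Xr = 30, X = 30)
  expect_equal(g2$g_mu, 0)
  expect_equal(g2$mu, g2$pi)
  expect_equal(g2$pi, 0.1 * 0.9)
  # additivity to machine precision over random evaluations
  set.seed(42)
  for (k in 1:25) {
    gc <- runif(1, 0, 0.6); gp <- runif(1, 0, 0.2); ga <- runif(1, 0, 0.2)
    X <- runif(1, 10, 80); Xr <- X * runif(1, 0.7, 1)
    gg <- growth_partition(gc, gp, ga, p, Xr, X)
    expect_equal(gg$g_mu + gp + ga, gc, tolerance = 1e-14)
  }
})

test_that("parameter counting and masks match the model structure", {
  tr <- make_truth_params("reduced_default")
  expect_identical(count_params(tr, "total"), 29L)
  expect_identical(count_params(tr, "fittable"), 27L)
  expect_identical(count_params(tr, "active"), 12L)
  full <- make_truth_params("full_default")
  expect_identical(count_params(full, "active"), 27L)
})
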