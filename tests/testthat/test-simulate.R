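test_that("state derivatives match the balance equations", {
  s <- c(X = 30, P = 3, G = 0.1, V = 1.3)
  expect_equal(ode_rhs(s, f = 0, Gf = 390, mu = 0, pi_ = 0, gamma = 0),
               c(X = 0, P = 0, G = 0, V = 0))
  # hand arithmetic on the balances
  d <- ode_rhs(s, f = 0.05, Gf = 390, mu = 0.1, pi_ = 0.01, gamma = 0.2)
  expect_equal(unname(d["X"]), 0.1 * 30 - 0.05 / 1.3 * 30, tolerance = 1e-12)
  expect_equal(unname(d["P"]), 0.01 * 30 - 0.05 / 1.3 * 3, tolerance = 1e-12)
  expect_equal(unname(d["G"]), -0.2 * 30 + 0.05 / 1.3 * (390 - 0.1),
               tolerance = 1e-12)
  expect_equal(unname(d["V"]), 0.05)
  # pure dilution conserves total biomass: d(XV)/dt = Xdot*V + X*Vdot = 0
  d0 <- ode_rhs(s, f = 0.08, Gf = 390, mu = 0, pi_ = 0, gamma = 0)
  expect_equal(unname(d0["X"] * s["V"] + s["X"] * d0["V"]), 0,
               tolerance = 1e-12)
  expect_error(ode_rhs(c(X = 1, P = 0, G = 0, V = -1), 0, 390, 0, 0, 0),
               "V <= 0")
})

test_that("feed laws evaluate and clamp as specified", {
  fe <- feed_spec("exponential", f0 = 2, mu_f = 0)
  expect_equal(feed_rate(c(0, 5, 10), fe), rep(2, 3))
  fe2 <- feed_spec("exponential", f0 = 1, mu_f = 0.1)
  expect_equal(feed_rate(10, fe2), exp(1))
  # the linear law printed for the optimized process: 0.022 + 0.0053 t
  fl <- feed_spec("linear", phi1 = 0.022, phi2 = 0.0053)
  expect_equal(feed_rate(10, fl), 0.075)
  fneg <- feed_spec("linear", phi1 = -1, phi2 = 0.1)
  expect_warning(v <- feed_rate(c(0, 20), fneg), "clamped")
  expect_equal(v, c(0, 1))
  fp <- feed_spec("piecewise", knots = data.frame(t = c(0, 1, 2),
                                                  f = c(0, 2, 2)))
  expect_equal(feed_rate(c(0.5, 1.5, 3), fp), c(1, 2, 2))
})

test_that("base feed follows the linear law with clamping", {
  p <- base_feed_params()    # a = 13900e-7, b = -1.1e-7
  expect_equal(base_feed(30, 1.3, 0.1, p),
               30 * 1.3 * 1e-7 * (13900 * 0.1 - 1.1), tolerance = 1e-12)
  expect_equal(base_feed(0, 1.3, 0.1, p), 0)
  mu0 <- -p$b / p$a   # root of the linear law
  expect_equal(base_feed(30, 1.3, mu0, p), 0)
  expect_equal(base_feed(30, 1.3, mu0 - 0.01, p), 0)  # clamped below the root
})

test_that("simulator conserves mass under zero kinetics and handles events", {
  zero <- kinetic_params(
    uptake = rate_block(0, Km = 1, nonremovable = c(Km = TRUE)),
    production = rate_block(0, Km = 0.1),
    maintenance = rate_block(0, Km = Inf))
  ctrl <- control_profile(feed_spec("exponential", f0 = 2, mu_f = 0),
                          temperature = 31, Gf = 1, tend = 10, base = NULL)
  x0 <- c(X = 30, P = 3, G = 0, V = 1)
  tr <- simulate_process(zero, ctrl, events = NULL, x0 = x0,
                         times = seq(0, 10, 0.5))
  # constant volumetric feed f/Gf = 2 L/h: V = V0 + 2 t, X V = const
  expect_equal(tr$V, 1 + 2 * tr$t, tolerance = 1e-8)
  expect_equal(tr$X * tr$V, rep(30, nrow(tr)), tolerance = 1e-6)
  expect_equal(tr$P * tr$V, rep(3, nrow(tr)), tolerance = 1e-6)

  # one sampling event: V jumps by exactly the sampled volume, X P G continuous
  ev <- data.frame(time = 5, volume = 0.035)
  tr2 <- simulate_process(zero, ctrl, events = ev, x0 = x0,
                          times = sort(c(seq(0, 10, 0.25), 5 + 1e-8)))
  pre <- which(tr2$t == 5)           # pre-event value reported at the event
  post <- pre + 1L                   # just after the jump
  expect_equal(tr2$V[pre], 1 + 2 * 5, tolerance = 1e-8)
  expect_equal(tr2$V[post], 1 + 2 * 5 - 0.035, tolerance = 1e-6)
  # concentrations continuous across the jump; removed mass = conc * volume
  expect_lt(abs(tr2$X[post] - tr2$X[pre]), 1e-6)
  expect_lt(abs(tr2$P[post] - tr2$P[pre]), 1e-6)
  expect_equal(tr2$X[pre] * tr2$V[pre] - tr2$X[post] * tr2$V[post],
               tr2$X[pre] * 0.035, tolerance = 1e-4)
})

test_that("simulated trajectories agree with a tight-tolerance reference", {
  tr <- fx_truth()
  ctrl <- control_profile(feed_spec("exponential", f0 = 8.5, mu_f = 0.12),
                          temperature = 31, Gf = 390, tend = 12)
  ev <- data.frame(time = c(2, 4, 6, 8, 10), volume = 0.035)
  x0 <- c(X = 30, P = 0, G = 0, V = 1.3)
  grid <- seq(0, 12, 0.25)
  a <- simulate_process(tr, ctrl, ev, x0, times = grid)
  b <- simulate_process(tr, ctrl, ev, x0, times = grid,
                        atol = c(1e-10, 1e-10, 1e-11, 1e-12), rtol = 1e-11)
  for (v in c("X", "P", "G", "V"))
    expect_lt(max(abs(a[[v]] - b[[v]])) / max(abs(b[[v]])), 1e-4)
})

test_that("substrate mass balance closes on a noise-free simulation", {
  tr <- fx_truth()
  ctrl <- control_profile(feed_spec("exponential", f0 = 8.5, mu_f = 0.12),
                          temperature = 31, Gf = 390, tend = 12, base = NULL)
  x0 <- c(X = 30, P = 0, G = 0, V = 1.3)
  grid <- seq(0, 12, 0.01)
  a <- simulate_process(tr, ctrl, events = NULL, x0 = x0, times = grid)
  fed <- kinfed:::cumtrapz(a$t, a$f_substrate)           # g substrate fed
  consumed <- kinfed:::cumtrapz(a$t, a$g_circ * a$Xr * a$V)
  remaining <- a$G * a$V
  i <- length(grid)
  expect_lt(abs(fed[i] - remaining[i] - consumed[i]) / fed[i], 0.005)
})

test_that("trajectory invariants hold on the synthetic campaign", {
  recs <- fx_dataset_clean()
  for (r in recs[c(1, 6, 8)]) {
    tru <- attr(r, "truth")
    expect_true(all(tru$X >= 0 & tru$P >= 0 & tru$G >= 0 & tru$V > 0))
    expect_true(all(tru$P <= tru$X + 1e-9))
    expect_true(all(tru$n >= 0))
  }
  # strictly increasing total biomass at the design center
  tru <- attr(recs[[1]], "truth")
  expect_true(all(diff(tru$X * tru$V) > 0))
})
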