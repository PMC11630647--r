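small_cfg <- function(ne = 40, nk = 5, ...)
  collocation_config(n_elements = ne, n_control = nk, ...)

test_that("collocated rollout reproduces the forward simulator", {
  tr <- fx_truth()
  cns <- ocp_constraints()
  nlp <- transcribe_ocp(tr, small_cfg(ne = 60), cns)
  tk <- nlp$control_times
  fk <- (0.12 * 30 * 1.3 / 0.55) * exp(0.12 * tk)
  res <- nlp$evaluate(fk, rep(31, length(tk)))
  fs <- feed_spec("piecewise", knots = data.frame(t = nlp$tgrid,
                                                  f = res$traj$feed))
  ctrl <- control_profile(fs, temperature = 31, Gf = 390, tend = 12)
  sim <- simulate_process(tr, ctrl, events = cns$events,
                          x0 = c(X = 30, P = 0, G = 0, V = 1.3),
                          times = nlp$tgrid)
  sel <- nlp$tgrid %in% c(2, 4, 6, 8, 10, 12)   # sampling times
  for (v in c("X", "P", "G", "V"))
    expect_lt(max(abs(res$traj[[v]][sel] - sim[[v]][sel])) / max(abs(sim[[v]])),
              0.01)
})

test_that("constant controls incur zero smoothness penalty", {
  tr <- fx_truth()
  nlp <- transcribe_ocp(tr, small_cfg(), ocp_constraints())
  res <- nlp$evaluate(rep(5, 5), rep(31, 5))
  expect_identical(res$penalty, 0)
  expect_equal(res$objective, res$ypx)
  # zero feed has zero penalty too (0/0 convention)
  res0 <- nlp$evaluate(rep(0, 5), rep(31, 5))
  expect_identical(res0$penalty, 0)
})

test_that("objective decomposition holds at any point", {
  tr <- fx_truth()
  nlp <- transcribe_ocp(tr, small_cfg(), ocp_constraints())
  res <- nlp$evaluate(c(2, 5, 9, 14, 20), c(29, 31, 33, 35, 34))
  expect_gt(res$penalty, 0)
  expect_equal(res$objective + res$penalty, res$ypx, tolerance = 1e-14)
})

test_that("solver recovers the temperature optimum of the production law", {
  # production is the only temperature-dependent rate, so with the feed
  # pinned the yield-optimal constant temperature is the law's argmax
  tr <- fx_truth()
  Topt_law <- optimize(function(T) temperature_factor(T, tr$production$temp),
                       c(25, 40), maximum = TRUE)$maximum
  cns <- ocp_constraints(feed_bounds = c(8, 8))   # feed pinned
  nlp <- transcribe_ocp(tr, small_cfg(ne = 30, nk = 3, c_temp = 0), cns)
  sol <- solve_ocp(nlp, init = list(feed = rep(8, 3), temp = rep(31, 3)),
                   maxit = 150)
  expect_lt(max(abs(sol$profile$temp - Topt_law)), 0.2)
  expect_equal(sol$objective + sol$penalty_term, sol$yield_term,
               tolerance = 1e-12)
})

test_that("restarting the solver at its own solution is stationary", {
  tr <- fx_truth()
  cns <- ocp_constraints(feed_bounds = c(8, 8))
  nlp <- transcribe_ocp(tr, small_cfg(ne = 20, nk = 3, c_temp = 0), cns)
  s1 <- solve_ocp(nlp, init = list(feed = rep(8, 3), temp = rep(31, 3)),
                  maxit = 150)
  s2 <- solve_ocp(nlp, init = list(feed = s1$profile$feed,
                                   temp = s1$profile$temp), maxit = 150)
  expect_lt(abs(s2$objective - s1$objective), 1e-8)
})

test_that("stronger regularization never roughens the controls", {
  tr <- fx_truth()
  tv <- function(u) sum(abs(diff(u)))
  tvs <- vapply(c(1e-4, 1e-3), function(cc) {
    nlp <- transcribe_ocp(tr, small_cfg(ne = 20, nk = 5, c_temp = cc,
                                        c_feed = cc), ocp_constraints())
    sol <- solve_ocp(nlp, maxit = 80)
    tv(sol$profile$temp) + tv(sol$profile$feed)
  }, numeric(1))
  expect_lte(tvs[2], tvs[1] + 1e-6)
})

test_that("quasi-steady variant removes the substrate state", {
  tr <- fx_truth()
  nlp <- transcribe_ocp(tr, small_cfg(), ocp_constraints(),
                        quasi_steady = TRUE)
  res <- nlp$evaluate(rep(8, 5), rep(31, 5))
  expect_true(all(res$traj$G == 0))
  # zero feed: no uptake, biomass/product evolve on maintenance only
  res0 <- nlp$evaluate(rep(0, 5), rep(31, 5))
  expect_true(all(res0$traj$P < 1e-9))
  expect_lt(res0$traj$X[nrow(res0$traj)], 30)   # starving culture declines
})

test_that("full and quasi-steady optima agree when uptake is fast", {
  tr <- fx_truth()   # uptake saturates well above the demands probed here
  cns <- ocp_constraints(feed_bounds = c(6, 12), T_bounds = c(30, 37))
  cfg <- small_cfg(ne = 30, nk = 3)
  sol_full <- solve_ocp(transcribe_ocp(tr, cfg, cns), maxit = 100)
  sol_qs <- solve_ocp(transcribe_ocp(tr, cfg, cns, quasi_steady = TRUE),
                      maxit = 100)
  expect_lt(abs(sol_qs$yield_term / sol_full$yield_term - 1), 0.02)
})

test_that("linear feed approximation is exact on already-linear profiles", {
  tr <- fx_truth()
  nlp <- transcribe_ocp(tr, small_cfg(ne = 30, nk = 5), ocp_constraints())
  tk <- nlp$control_times
  feed <- 2 + 0.8 * tk
  res <- nlp$evaluate(feed, rep(31, 5))
  fake <- structure(list(profile = list(t = tk, feed = feed,
                                        temp = rep(31, 5)),
                         trajectory = res$traj, yield_term = res$ypx),
                    class = "kinfed_ocp")
  lin <- approximate_feed_linear(fake, nlp)
  expect_equal(lin$phi1, 2, tolerance = 1e-9)
  expect_equal(lin$phi2, 0.8, tolerance = 1e-9)
  expect_lt(max(abs(lin$rel_change)), 1e-9)
  # constant feed: zero slope
  res_c <- nlp$evaluate(rep(5, 5), rep(31, 5))
  fake_c <- structure(list(profile = list(t = tk, feed = rep(5, 5),
                                          temp = rep(31, 5)),
                           trajectory = res_c$traj, yield_term = res_c$ypx),
                      class = "kinfed_ocp")
  expect_equal(approximate_feed_linear(fake_c, nlp)$phi2, 0,
               tolerance = 1e-9)
})

test_that("volume feasibility is reported and enforced by penalty", {
  tr <- fx_truth()
  cns <- ocp_constraints(Vmax = 1.6)
  nlp <- transcribe_ocp(tr, small_cfg(), cns)
  res <- nlp$evaluate(rep(40, 5), rep(31, 5))   # heavy feed: V > Vmax
  expect_gt(res$v_violation, 0)
  sol <- solve_ocp(nlp, maxit = 100)
  expect_lt(sol$v_violation, 1e-3)
})
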