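# small exact observations on a designed covariate grid (no simulation):
# rates generated directly from a known parameter set
make_exact_obs <- function(n = 60, seed = 2) {
  set.seed(seed)
  G <- exp(runif(n, log(0.05), log(20)))
  ngen <- runif(n, 0, 2)
  PX <- runif(n, 0, 0.25)
  X <- runif(n, 20, 70)
  Tc <- sample(c(27, 29, 31, 33, 35, 36.5), n, replace = TRUE)
  p <- fx_truth()
  gc <- uptake_rate(G, ngen, PX, X, Tc, p)
  ga <- maintenance_rate(gc, G, ngen, PX, X, Tc, p)
  gp <- production_uptake_rate(gc, ga, G, ngen, PX, X, Tc, p)
  obs <- data.frame(run_id = "grid", t = seq_len(n), g_circ = gc,
                    g_alpha = ga, g_pi = gp, g_mu = gc - ga - gp,
                    G = G, n = ngen, PX = PX, X = X, Temp = Tc,
                    weight = 1, valid_uptake = TRUE)
  class(obs) <- c("rate_observations", "data.frame")
  obs
}

test_that("exact observations are fitted to numerical zero with true masks", {
  obs <- make_exact_obs()
  masks <- fx_true_masks()
  tr <- fx_truth()
  fu <- fit_rate(obs, "uptake", mask = masks$uptake, seed = 1)
  expect_lt(fu$rss, 1e-10 * fu$tss)
  expect_lt(relerr(10^fu$par[["lc"]], 0.55), 0.01)
  expect_lt(relerr(10^fu$par[["lKm"]], 0.05), 0.01)
  expect_lt(relerr(10^fu$par[["lK_G"]], 20), 0.01)
  fm <- fit_rate(obs, "maintenance", mask = masks$maintenance, seed = 1)
  expect_lt(fm$rss, 1e-10 * fm$tss)
  expect_lt(relerr(10^fm$par[["lKm"]], 0.4), 0.01)
  fp <- fit_rate(obs, "production", mask = masks$production, seed = 1)
  expect_lt(fp$rss, 1e-8 * fp$tss)
  expect_lt(relerr(10^fp$par[["lK_n"]], 3), 0.01)
  expect_lt(templaw_relerr(fp$block$temp, tr$production$temp), 0.01)
})

test_that("a constant-only model fits the weighted mean", {
  obs <- make_exact_obs(n = 40)
  mask <- c(temp = FALSE, Km = FALSE, G = FALSE, n = FALSE, PX = FALSE,
            X = FALSE)
  f <- fit_rate(obs, "maintenance", mask = mask, seed = 1)
  ybar <- weighted.mean(obs$g_alpha, obs$weight)
  expect_equal(10^f$par[["lc"]], ybar, tolerance = 1e-6)
  expect_equal(f$rss, sum(obs$weight * (obs$g_alpha - ybar)^2),
               tolerance = 1e-8)
})

test_that("duplicating every row doubles the objective, not the estimates", {
  obs <- make_exact_obs(n = 30)
  obs$g_alpha <- obs$g_alpha * exp(rnorm(30, 0, 0.05))  # some noise
  mask <- fx_true_masks()$maintenance
  f1 <- fit_rate(obs, "maintenance", mask = mask, seed = 1)
  obs2 <- rbind(obs, obs)
  class(obs2) <- class(obs)
  f2 <- fit_rate(obs2, "maintenance", mask = mask, seed = 1)
  expect_equal(f2$par, f1$par, tolerance = 1e-4)
  expect_equal(f2$rss, 2 * f1$rss, tolerance = 1e-3)
})

test_that("identical seeds give bitwise-identical fits", {
  obs <- make_exact_obs(n = 30)
  f1 <- fit_rate(obs, "uptake", mask = fx_true_masks()$uptake, seed = 7)
  f2 <- fit_rate(obs, "uptake", mask = fx_true_masks()$uptake, seed = 7)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$rss, f2$rss)
})

test_that("F-test matches an independent numerical evaluation", {
  expect_equal(f_test(1, 1, 1, 10), 1)
  expect_equal(f_test(0, 0, 1, 10), 1)
  expect_equal(f_test(0, 0.5, 1, 10), 0)
  # F = 10 on (1, 10) dof: integrate the F density independently
  dens <- function(x, d1, d2)
    sqrt((d1 * x)^d1 * d2^d2 / (d1 * x + d2)^(d1 + d2)) /
      (x * beta(d1 / 2, d2 / 2))
  p_num <- integrate(dens, 10, Inf, d1 = 1, d2 = 10, rel.tol = 1e-10)$value
  expect_equal(f_test(1, 2, 1, 10), p_num, tolerance = 1e-8)
  expect_equal(round(f_test(1, 2, 1, 10), 4), 0.0101)
  # scale invariance of F and p
  expect_equal(f_test(2, 4, 1, 10), f_test(1, 2, 1, 10))
  # optimizer-noise flooring
  expect_equal(f_test(1, 0.999, 1, 10), 1)
  expect_error(f_test(1, 2, 1, 0), "df_residual")
})

test_that("corrected AIC follows the printed small-sample formula", {
  expect_equal(aicc(1, 1, 10), 10 * (log(1) + 1) + 2 + 2 / 6)  # 12.3333...
  expect_equal(aicc(1, 1, 10), 12 + 1 / 3)
  # scaling rss by e raises the criterion by exactly n_points
  expect_equal(aicc(exp(1) * 3, 2, 20) - aicc(3, 2, 20), 20)
  # quirk of the as-printed formula: the log(RSS/#v) term can reward extra
  # parameters at equal RSS (direct evaluation at rss = 1, n = 10)
  expect_equal(aicc(1, 2, 10), 10 * (log(1 / 2) + 1) + 4 + 6 / 5)
  expect_equal(aicc(1, 3, 10), 10 * (log(1 / 3) + 1) + 6 + 12 / 4)
  expect_gt(aicc(1, 2, 10), aicc(1, 3, 10))
  expect_error(aicc(1, 7, 10), "undefined")
  # the standard variant uses rss/n and always prefers fewer at equal rss
  expect_equal(aicc(1, 1, 10, variant = "standard"),
               10 * log(1 / 10) + 2 + 4 / 8)
  expect_lt(aicc(1, 2, 10, variant = "standard"),
            aicc(1, 3, 10, variant = "standard"))
})

test_that("goodness of fit matches hand arithmetic", {
  set.seed(1)
  meas <- rnorm(10)
  # rescale predictions so RSS/TSS = 0.3 exactly
  tss <- sum((meas - mean(meas))^2)
  resid <- meas - mean(meas)
  pred <- meas - resid * sqrt(0.3)
  g <- goodness(pred, meas, n_vars = 2)
  expect_equal(g$r2, 0.7, tolerance = 1e-12)
  expect_equal(g$r2_adj, 1 - (0.3 * tss / 7) / (tss / 9), tolerance = 1e-12)
  expect_equal(g$rel_err, (meas - pred) / mean(meas))
  # perfect prediction and mean-only prediction
  expect_equal(goodness(meas, meas, 2)$r2, 1)
  expect_equal(goodness(rep(mean(meas), 10), meas, 2)$r2, 0)
  expect_error(goodness(rep(1, 5), rep(2, 5), 1), "constant")
})

test_that("backward elimination recovers sparse structure on exact data", {
  obs <- make_exact_obs()
  masks <- fx_true_masks()
  for (rt in c("uptake", "maintenance", "production")) {
    el <- eliminate_terms(obs, rt, alpha = 0.2, seed = 1,
                          control = fx_fast_control())
    expect_identical(el$mask, masks[[rt]])
    # removed terms never re-enter and the trace respects the iteration cap
    expect_lte(max(el$trace$iteration),
               sum(kinfed:::.full_mask()[kinfed:::.removable_terms(rt)]) + 1)
  }
})

test_that("alpha = 1 removes exactly the terms whose removal is free", {
  # removal rule: drop the worst term iff p >= alpha; at the degenerate
  # alpha = 1 that is every term with p = 1 -- on exact data, all four
  # spurious maintenance terms and nothing else
  obs <- make_exact_obs(n = 40)
  el <- eliminate_terms(obs, "maintenance", alpha = 1, seed = 1,
                        control = fx_fast_control())
  expect_identical(el$mask, fx_true_masks()$maintenance)
  expect_identical(sum(el$trace$removed), 4L)
  expect_lte(max(el$trace$iteration), 7)
})

test_that("the uptake Michaelis constant is never removable", {
  obs <- make_exact_obs(n = 40)
  el <- eliminate_terms(obs, "uptake", alpha = 1, seed = 1,
                        control = fx_fast_control())
  expect_true(el$mask[["Km"]])
  expect_error(fit_rate(obs, "uptake",
                        mask = c(temp = TRUE, Km = FALSE, G = FALSE,
                                 n = FALSE, PX = FALSE, X = FALSE)),
               "cannot be removed")
})

test_that("exhaustive AICc search enumerates all admissible masks", {
  obs <- make_exact_obs(n = 50)
  ex <- exhaustive_aicc_select(obs, "uptake", seed = 1,
                               control = fx_fast_control())
  expect_identical(nrow(ex$table), 32L)   # 2^5: Km always present
  expect_identical(ex$mask, fx_true_masks()$uptake)
  expect_true(all(c("mask", "n_params", "rss", "aicc") %in% names(ex$table)))
  expect_identical(anyDuplicated(ex$table$mask), 0L)
})

test_that("cross-validated alpha selection is well-behaved", {
  recs <- fx_dataset_clean()[c(1, 5, 6, 8)]
  sel <- select_alpha(recs, alpha_grid = 0.2, seed = 1, folds = 1:2,
                      control = fx_fast_control())
  expect_equal(sel$alpha, 0.2)
  # fold order does not change the per-level errors
  sel2 <- select_alpha(recs, alpha_grid = 0.2, seed = 1, folds = 2:1,
                       control = fx_fast_control())
  expect_equal(sort(sel$errors[1, ]), sort(sel2$errors[1, ]))
  expect_error(select_alpha(recs[1:2]), "at least 3")
})
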