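# shared fixtures, built once per test session (lazily, cached)

.fx <- new.env(parent = emptyenv())

fx_truth <- function() {
  if (is.null(.fx$truth)) .fx$truth <- make_truth_params("reduced_default")
  .fx$truth
}

# the 12-run noise-free synthetic campaign
fx_dataset_clean <- function() {
  if (is.null(.fx$ds_clean))
    .fx$ds_clean <- generate_dataset(fx_truth(), noise = noise_spec(0, 0, 0),
                                     seed = 1)
  .fx$ds_clean
}

# the same campaign with the default measurement noise
fx_dataset_noisy <- function() {
  if (is.null(.fx$ds_noisy))
    .fx$ds_noisy <- generate_dataset(fx_truth(), noise = noise_spec(),
                                     seed = 1)
  .fx$ds_noisy
}

# exact rate observations: true rates and covariates straight from the
# noise-free simulator trajectories (no spline step)
fx_obs_exact <- function() {
  if (!is.null(.fx$obs_exact)) return(.fx$obs_exact)
  recs <- fx_dataset_clean()
  obs <- do.call(rbind, lapply(recs, function(r) {
    tru <- attr(r, "truth")
    usable <- any(r$offline$G > r$loq & !r$offline$G_censored)
    w <- rep(1, nrow(tru)); w[c(1, nrow(tru))] <- 0.5
    data.frame(run_id = r$run_id, t = tru$t,
               g_circ = tru$g_circ, g_alpha = tru$g_alpha,
               g_pi = tru$g_pi, g_mu = tru$g_mu,
               G = tru$G, n = tru$n, PX = tru$P / tru$X, X = tru$X,
               Temp = tru$Temp, weight = w,
               valid_uptake = usable & tru$G > r$loq)
  }))
  class(obs) <- c("rate_observations", "data.frame")
  .fx$obs_exact <- obs
  obs
}

# spline-estimated observations from the noise-free campaign
fx_obs_spline <- function() {
  if (is.null(.fx$obs_spline))
    .fx$obs_spline <- estimate_rates(fx_dataset_clean(), smoothing = 0)
  .fx$obs_spline
}

# true term masks of the reduced synthetic model
fx_true_masks <- function() {
  list(
    uptake = c(temp = FALSE, Km = TRUE, G = TRUE, n = FALSE, PX = FALSE,
               X = FALSE),
    maintenance = c(temp = FALSE, Km = TRUE, G = FALSE, n = FALSE, PX = TRUE,
                    X = FALSE),
    production = c(temp = TRUE, Km = TRUE, G = FALSE, n = TRUE, PX = FALSE,
                   X = FALSE))
}

# fast optimizer settings for tests that loop over many fits
fx_fast_control <- function() de_control(pop_factor = 10, maxiter = 400)

# per-rate eliminations at alpha = 0.2, cached for reuse across test blocks
fx_elim <- function(route = c("exact", "spline")) {
  route <- match.arg(route)
  key <- paste0("elim_", route)
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  obs <- if (route == "exact") fx_obs_exact() else fx_obs_spline()
  out <- lapply(c("uptake", "maintenance", "production"), function(rt)
    eliminate_terms(obs, rt, alpha = 0.2, seed = 1))
  names(out) <- c("uptake", "maintenance", "production")
  .fx[[key]] <- out
  out
}

# relative error helper
relerr <- function(est, truth) abs(est / truth - 1)

# compare a fitted temperature law against the truth as a function of T
templaw_relerr <- function(fit_temp, true_temp, Ts = seq(26, 37, by = 0.5)) {
  max(relerr(temperature_factor(Ts, fit_temp),
             temperature_factor(Ts, true_temp)))
}
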