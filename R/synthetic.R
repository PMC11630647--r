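#' Central composite design over feed coefficient and temperature
#'
#' The default emulates a 12-run training campaign: one center point run four
#' times, four star (axial) points at \eqn{\pm\sqrt2} coded units on one
#' factor, and four factorial points at \eqn{\pm 1} on both factors.
#'
#' @param center named numeric `c(mu_f=, T=)`, the center condition.
#' @param step factor steps `c(mu_f=, T=)` corresponding to one coded unit.
#' @param n_center number of center replicates.
#' @param star_scale axial distance in coded units (default `sqrt(2)`).
#' @return an object of class `design_spec`; its `points` element is a
#'   data.frame with columns `run_id`, `mu_f`, `T`, `role`.
#' @export
design_spec <- function(center = c(mu_f = 0.12, T = 31),
                        step = c(mu_f = 0.03, T = 3),
                        n_center = 4, star_scale = sqrt(2)) {
  cc <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  pts <- rbind(
    data.frame(mu_f = rep(0, n_center), T = rep(0, n_center), role = "center"),
    data.frame(mu_f = c(-star_scale, star_scale, 0, 0),
               T = c(0, 0, -star_scale, star_scale), role = "star"),
    data.frame(mu_f = cc$a, T = cc$b, role = "factorial"))
  pts$mu_f <- center[["mu_f"]] + pts$mu_f * step[["mu_f"]]
  pts$T <- center[["T"]] + pts$T * step[["T"]]
  pts <- cbind(run_id = sprintf("run%02d", seq_len(nrow(pts))), pts)
  structure(list(center = center, step = step, n_center = n_center,
                 star_scale = star_scale, points = pts),
            class = "design_spec")
}

#' Measurement noise specification
#'
#' Multiplicative log-normal noise, parameterized so the relative standard
#' deviation of `measured/true` equals the requested value and its mean is 1
#' (no bias): `sdlog = sqrt(log(1 + rel^2))`, `meanlog = -sdlog^2/2`.  Never
#' produces negative concentrations.
#'
#' @param rel_sd_X,rel_sd_P,rel_sd_G relative SDs for biomass, product and
#'   substrate measurements.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(rel_sd_X = 0.03, rel_sd_P = 0.15, rel_sd_G = 0.05) {
  stopifnot(rel_sd_X >= 0, rel_sd_P >= 0, rel_sd_G >= 0)
  structure(list(rel_sd_X = rel_sd_X, rel_sd_P = rel_sd_P,
                 rel_sd_G = rel_sd_G), class = "noise_spec")
}

.mult_noise <- function(x, rel) {
  if (rel <= 0) return(x)
  s <- sqrt(log(1 + rel^2))
  x * stats::rlnorm(length(x), meanlog = -s^2 / 2, sdlog = s)
}

#' Synthetic "truth" kinetic parameter sets
#'
#' Documented synthetic parameter presets used as ground truth for
#' simulation studies and recovery tests.  `reduced_default` has the sparse
#' structure retained after term elimination on the case-study-like process
#' (3 uptake + 3 maintenance + 6 production = 12 active fitted parameters):
#' Michaelis-Menten uptake with substrate self-inhibition, maintenance
#' activated by uptake and by the product load, and temperature-dependent
#' production inhibited by the number of generations.  `full_default` embeds
#' the same truth in the fully active 27-parameter structure (inactive terms
#' are given near-neutral constants).  Values are invented but produce
#' trajectories qualitatively like a recombinant-protein fed-batch (biomass
#' ~30 to ~50-70 g/L, product up to ~11 g/L over 12 h, temperature optimum
#' near 36 C with most of the attainable yield gain coming from temperature).
#'
#' @param preset `"reduced_default"` or `"full_default"`.
#' @return a [kinetic_params()] object.
#' @export
make_truth_params <- function(preset = c("reduced_default", "full_default")) {
  preset <- match.arg(preset)
  upt <- rate_block(temp = 0.55, Km = 0.05, K = c(G = 20, n = Inf, PX = Inf, X = Inf),
                    nonremovable = c(Km = TRUE))
  mnt <- rate_block(temp = 0.06, Km = 0.4, K = c(G = Inf, n = Inf, PX = 0.3, X = Inf))
  prd <- rate_block(temp = temp_law(E0 = 0.011, dG_cat = 7e4, T_eq = 312, dH_eq = 4e5),
                    Km = 0.12, K = c(G = Inf, n = 3, PX = Inf, X = Inf))
  p <- kinetic_params(uptake = upt, production = prd, maintenance = mnt)
  if (preset == "full_default") {
    # embed in the full structure: switch every term on with near-neutral
    # constants (large K = weak effect) so the model is exactly fittable
    big <- 1e3
    p$uptake <- rate_block(temp = temp_law(E0 = .law_E0_for(0.55, 2e4), dG_cat = 2e4,
                                           T_eq = 320, dH_eq = 3e5),
                           Km = 0.05, K = c(G = 20, n = big, PX = big, X = big * 30),
                           nonremovable = c(Km = TRUE))
    p$maintenance <- rate_block(temp = temp_law(E0 = .law_E0_for(0.06, 2e4), dG_cat = 2e4,
                                                T_eq = 320, dH_eq = 3e5),
                                Km = 0.4, K = c(G = big, n = big, PX = 0.3, X = big * 30))
    p$production <- rate_block(temp = temp_law(E0 = 0.011, dG_cat = 7e4,
                                               T_eq = 312, dH_eq = 4e5),
                               Km = 0.12, K = c(G = big, n = 3, PX = big, X = big * 30))
  }
  p
}

# E0 such that the law's Eyring part equals `rate` at the internal reference
# temperature (ignoring the inactivation denominator)
.law_E0_for <- function(rate, dG_cat) {
  rate / (.kB * .Tref / .hP * exp(-dG_cat / (.Rgas * .Tref)))
}

#' Simulate one synthetic fermentation run
#'
#' Simulates a 12 h production phase with an exponential substrate feed
#' (`f0 = mu_f X0 V0 / Y_XrG`, the classical seed value for a target
#' specific growth rate), 35 mL sampling events every 2 h, and corrupts the
#' offline measurements with seeded multiplicative noise.  Online feed and
#' temperature are stored noise-free.  Substrate readings below the limit of
#' quantification are reported censored at `loq/2`.
#'
#' @param truth a [kinetic_params()] ground-truth set.
#' @param point named numeric `c(mu_f=, T=)` design condition.
#' @param noise a [noise_spec()].
#' @param seed integer seed for the noise draws.
#' @param run_id identifier stored in the record.
#' @param X0,V0,Gf,tend,dt_sample,sample_vol,loq protocol constants: initial
#'   biomass (g/L) and volume (L), feed concentration (g/L), production-phase
#'   length (h), sampling interval (h), sample volume (L), and G limit of
#'   quantification (g/L).
#' @param base base-feed model ([base_feed_params()]) or `NULL`.
#' @return a [process_record()]; its `truth` attribute carries the noise-free
#'   trajectory.
#' @export
generate_run <- function(truth, point, noise = noise_spec(), seed = 1,
                         run_id = "run01", X0 = 30, V0 = 1.3, Gf = 390,
                         tend = 12, dt_sample = 2, sample_vol = 0.035,
                         loq = 0.1, base = base_feed_params()) {
  f0 <- point[["mu_f"]] * X0 * V0 / truth$yields[["Y_XrG"]]
  fs <- feed_spec("exponential", f0 = f0, mu_f = point[["mu_f"]])
  ctrl <- control_profile(fs, temperature = point[["T"]], Gf = Gf,
                          tend = tend, base = base)
  ts <- seq(0, tend, by = dt_sample)
  ev_t <- ts[ts > 0 & ts < tend]
  events <- data.frame(time = ev_t, volume = rep(sample_vol, length(ev_t)))
  traj <- simulate_process(truth, ctrl, events, x0 = c(X = X0, P = 0, G = 0, V = V0),
                           times = sort(unique(c(seq(0, tend, by = 0.1), ts))))
  at <- traj[match(ts, traj$t), ]
  off <- with_seed(seed, data.frame(
    t = ts,
    X = .mult_noise(at$X, noise$rel_sd_X),
    P = .mult_noise(at$P, noise$rel_sd_P),
    G = .mult_noise(at$G, noise$rel_sd_G)))
  off$G_censored <- off$G < loq
  off$G[off$G_censored] <- loq / 2
  on_t <- seq(0, tend, by = 0.05)
  online <- data.frame(t = on_t, f = feed_rate(on_t, fs),
                       T = rep(point[["T"]], length(on_t)))
  rec <- process_record(run_id, off, online, V0 = V0, X0 = X0, Gf = Gf,
                        events = events, design_point = point, loq = loq,
                        base = base)
  attr(rec, "truth") <- at
  rec
}

#' Generate a full synthetic training dataset
#'
#' One run per design point (12 by default), reproducible from the seed:
#' run `i` uses seed `seed * 1000 + i`.  Following the emulated campaign,
#' the biomass concentration at induction varies from run to run: `X0` is
#' drawn uniformly from `X0_range` (seeded).  This run-to-run variation is
#' what separates the generations covariate `n` from total biomass `X`
#' across runs; pass `X0_range = c(30, 30)` for identical starts.
#'
#' @param truth a [kinetic_params()] ground-truth set.
#' @param design a [design_spec()].
#' @param noise a [noise_spec()].
#' @param seed integer master seed.
#' @param X0_range range (g/L) of the per-run induction biomass draw.
#' @param ... protocol constants forwarded to [generate_run()].
#' @return list of [process_record()] objects.
#' @export
generate_dataset <- function(truth, design = design_spec(),
                             noise = noise_spec(), seed = 1,
                             X0_range = c(20, 45), ...) {
  pts <- design$points
  X0s <- with_seed(seed, stats::runif(nrow(pts), X0_range[1], X0_range[2]))
  lapply(seq_len(nrow(pts)), function(i) {
    generate_run(truth, c(mu_f = pts$mu_f[i], T = pts$T[i]), noise = noise,
                 seed = (seed * 1000 + i) %% 2147483647,
                 run_id = pts$run_id[i], X0 = X0s[i], ...)
  })
}
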