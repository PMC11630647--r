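#' Substrate feed specification
#'
#' Feed profiles are specified as substrate mass flow (g/h); division by the
#' feed concentration `Gf` converts to volumetric flow for the volume
#' balance.  Supported kinds: `exponential` \eqn{f_0 e^{\mu_f t}}, `linear`
#' \eqn{\phi_1 + \phi_2 t} (clamped at 0 with a warning if negative), and
#' `piecewise` (linear interpolation between knots, constant beyond the last
#' knot).
#'
#' @param kind one of `"exponential"`, `"linear"`, `"piecewise"`.
#' @param f0 initial feed rate, g/h (exponential).
#' @param mu_f exponential feed coefficient, 1/h.
#' @param phi1,phi2 linear feed intercept (g/h) and slope (g/h^2).
#' @param knots data.frame with columns `t` (h) and `f` (g/h) for piecewise.
#' @return an object of class `feed_spec`.
#' @export
feed_spec <- function(kind = c("exponential", "linear", "piecewise"),
                      f0 = NULL, mu_f = NULL, phi1 = NULL, phi2 = NULL,
                      knots = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    exponential = {
      stopifnot(is.numeric(f0), is.numeric(mu_f), f0 >= 0)
      list(kind = kind, f0 = f0, mu_f = mu_f)
    },
    linear = {
      stopifnot(is.numeric(phi1), is.numeric(phi2))
      list(kind = kind, phi1 = phi1, phi2 = phi2)
    },
    piecewise = {
      stopifnot(is.data.frame(knots), all(c("t", "f") %in% names(knots)),
                all(diff(knots$t) > 0), all(knots$f >= 0))
      list(kind = kind, knots = knots)
    })
  structure(spec, class = "feed_spec")
}

#' Evaluate a feed profile
#'
#' @param t time, h (vectorized, >= 0).
#' @param spec a [feed_spec()].
#' @return substrate mass feed rate, g/h (never negative).
#' @export
feed_rate <- function(t, spec) {
  stopifnot(inherits(spec, "feed_spec"), all(t >= 0))
  f <- switch(spec$kind,
    exponential = spec$f0 * exp(spec$mu_f * t),
    linear = spec$phi1 + spec$phi2 * t,
    piecewise = stats::approx(spec$knots$t, spec$knots$f, xout = t,
                              rule = 2)$y)
  if (spec$kind == "linear" && any(f < 0)) {
    warnf("linear feed negative at some times; clamped to 0")
    f <- pmax(f, 0)
  }
  f
}

#' Base (pH-control) feed model
#'
#' Empirical linear model for the base addition used for pH control,
#' \eqn{f_{base} = X V (a\mu + b)}, clamped at zero.  The default
#' coefficients follow a regression of base addition against biomass growth:
#' `a = 13900e-7` L h/g, `b = -1.1e-7` L/(g h).
#'
#' @param X biomass, g/L; `V` volume, L; `mu` specific growth rate, 1/h.
#' @param V,mu see above.
#' @param p list with elements `a` and `b`.
#' @return base feed, L/h (>= 0).
#' @export
base_feed <- function(X, V, mu, p = base_feed_params()) {
  stopifnot(all(X >= 0), all(V >= 0))
  pmax(X * V * (p$a * mu + p$b), 0)
}

#' @rdname base_feed
#' @param a,b slope (L h/g) and intercept of the linear base-addition law.
#' @export
base_feed_params <- function(a = 13900e-7, b = -1.1e-7) list(a = a, b = b)

#' Fed-batch state derivatives
#'
#' The standard fed-batch balance equations:
#' \deqn{\dot X = \mu X - (f/V) X,\quad \dot P = \pi X - (f/V) P,}
#' \deqn{\dot G = -\gamma X + (f/V)(G_f - G),\quad \dot V = f}
#' where `f` is the total volumetric feed and \eqn{\gamma = \gamma^\circ
#' X_r/X} is uptake per total biomass.
#'
#' @param state named numeric `c(X=, P=, G=, V=)`.
#' @param f total volumetric feed, L/h.
#' @param Gf feed substrate concentration, g/L.
#' @param mu,pi_,gamma specific growth (1/h), production (1/h) and
#'   per-total-biomass uptake (g/g/h) rates.
#' @return named numeric vector of derivatives `(X, P, G, V)`.
#' @export
ode_rhs <- function(state, f, Gf, mu, pi_, gamma) {
  if (state[["V"]] <= 0) stopf("simulation failure: V <= 0")
  D <- f / state[["V"]]
  c(X = mu * state[["X"]] - D * state[["X"]],
    P = pi_ * state[["X"]] - D * state[["P"]],
    G = -gamma * state[["X"]] + D * (Gf - state[["G"]]),
    V = f)
}

#' Control profile for a fed-batch run
#'
#' @param feed a [feed_spec()].
#' @param temperature constant (degrees C) or data.frame with columns `t`, `T`
#'   interpolated linearly (constant beyond the knots).
#' @param Gf feed substrate concentration, g/L.
#' @param tend process end time, h.
#' @param base base-feed model from [base_feed_params()], or `NULL` to
#'   disable base addition.
#' @return an object of class `control_profile`.
#' @export
control_profile <- function(feed, temperature, Gf, tend,
                            base = base_feed_params()) {
  stopifnot(inherits(feed, "feed_spec"), Gf > 0, tend > 0)
  structure(list(feed = feed, temperature = temperature, Gf = Gf,
                 tend = tend, base = base), class = "control_profile")
}

# evaluate the temperature control at time t
profile_temperature <- function(ctrl, t) {
  tp <- ctrl$temperature
  if (is.numeric(tp) && length(tp) == 1L) rep(tp, length(t))
  else stats::approx(tp$t, tp$T, xout = t, rule = 2)$y
}

#' Simulate a fed-batch process
#'
#' Integrates the stiff fed-batch ODE system with `deSolve::lsoda` between
#' sampling events; at each event the broth volume drops by the sampled
#' volume while concentrations are continuous.  Substrate is the stiff state
#' and carries a tighter absolute tolerance (1e-8 g/L).
#'
#' @param params a [kinetic_params()] object.
#' @param controls a [control_profile()].
#' @param events data.frame with columns `time` (h) and `volume` (L removed),
#'   or `NULL`.
#' @param x0 named numeric initial state `c(X=, P=, G=, V=)`.
#' @param times output time grid (h); defaults to 121 points over the run.
#' @param atol,rtol integrator tolerances (atol recycled over `X, P, G, V`).
#' @return data.frame of class `kinfed_traj` with columns `t, X, P, G, V,
#'   f_substrate` (g/h), `f_base` (L/h), `Temp`, and the derived `n, Xr,
#'   g_circ, g_alpha, g_pi, g_mu, mu, pi`.
#' @export
simulate_process <- function(params, controls, events = NULL, x0,
                             times = NULL,
                             atol = c(1e-7, 1e-7, 1e-8, 1e-9), rtol = 1e-8) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(controls, "control_profile"))
  x0 <- x0[c("X", "P", "G", "V")]
  if (any(is.na(x0)) || x0[["X"]] < 0 || x0[["P"]] < 0 || x0[["G"]] < 0 ||
      x0[["V"]] <= 0) stopf("invalid initial state")
  if (x0[["P"]] > x0[["X"]]) stopf("invalid initial state: P > X")
  if (is.null(times)) times <- seq(0, controls$tend, length.out = 121)
  X0V0 <- x0[["X"]] * x0[["V"]]

  if (!is.null(events) && nrow(events)) {
    if (any(events$time <= 0) || any(events$time >= controls$tend))
      stopf("sampling events must lie strictly inside (0, tend)")
    times <- sort(unique(c(times, events$time)))
    evdat <- data.frame(var = "V", time = events$time,
                        value = -abs(events$volume), method = "add")
  } else evdat <- NULL

  rhs <- function(t, y, parms) {
    X <- max(y[1], 0); P <- max(y[2], 0); G <- max(y[3], 0); V <- y[4]
    if (V <= 0) stopf("simulation failure: V <= 0 at t = %.3f", t)
    Xr <- X - P
    if (Xr < -1e-6 * X) warnf("P exceeds X at t = %.2f (Xr = %.3g)", t, Xr)
    Xr <- max(Xr, 1e-12)
    n <- log2(max(X * V / X0V0, 1))
    Tc <- profile_temperature(controls, t)
    r <- process_rates(G, n, min(P, X), X, Tc, params)
    f_sub <- feed_rate(t, controls$feed)           # g/h
    f_base <- if (is.null(controls$base)) 0 else base_feed(X, V, r$mu, controls$base)
    f_vol <- f_sub / controls$Gf + f_base          # L/h
    gamma <- r$g_circ * Xr / X
    D <- f_vol / V
    list(c(r$mu * X - D * X,
           r$pi * X - D * P,
           -gamma * X + D * (controls$Gf - G),
           f_vol))
  }

  out <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol,
                      events = if (is.null(evdat)) NULL else list(data = evdat))
  if (attr(out, "istate")[1] < 0) stopf("simulation failure: integrator did not converge")
  out <- as.data.frame(out)
  names(out) <- c("t", "X", "P", "G", "V")
  neg <- vapply(out[c("X", "P", "G")], function(z) min(z), numeric(1))
  if (any(neg < -1e-6)) stopf("simulation failure: negative state beyond tolerance (%.3g)", min(neg))
  out$X <- pmax(out$X, 0); out$P <- pmax(out$P, 0); out$G <- pmax(out$G, 0)
  if (any(out$V <= 0)) stopf("simulation failure: V <= 0")

  out$Temp <- profile_temperature(controls, out$t)
  out$n <- log2(pmax(out$X * out$V / X0V0, 1))
  out$Xr <- pmax(out$X - out$P, 1e-12)
  r <- process_rates(out$G, out$n, pmin(out$P, out$X), out$X, out$Temp, params)
  out$f_substrate <- feed_rate(out$t, controls$feed)
  out$f_base <- if (is.null(controls$base)) 0 else base_feed(out$X, out$V, r$mu, controls$base)
  out <- cbind(out, r)
  class(out) <- c("kinfed_traj", "data.frame")
  out
}

#' Write a trajectory as tidy CSV
#'
#' @param traj a `kinfed_traj` data.frame from [simulate_process()].
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
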