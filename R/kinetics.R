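#' Temperature dependence of a maximum/minimum specific rate
#'
#' Evaluates the thermodynamic rate law (see [temp_law()]) at temperature
#' `T_C` in degrees Celsius.  The law combines an Eyring-type activation term
#' with a two-state (active/heat-inactivated) enzyme equilibrium: the rate
#' increases with temperature up to a unique interior maximum and collapses
#' above the half-inactivation temperature.  At `T = T_eq` (in kelvin) the
#' equilibrium denominator equals exactly 2.  If `p` is a plain constant
#' (temperature term inactive in the mask), that constant is returned.
#'
#' @param T_C temperature in degrees Celsius (vectorized); plausible range
#'   0-60.
#' @param p a [temp_law()] object or a single positive constant.
#' @return rate scale, same units as the rate the law governs (g/g/h).
#' @examples
#' tl <- temp_law(E0 = 0.013, dG_cat = 7e4, T_eq = 312, dH_eq = 4e5)
#' temperature_factor(c(31, 35.8), tl)
#' @export
temperature_factor <- function(T_C, p) {
  if (!inherits(p, "temp_law")) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p))
      stopf("temperature_factor: 'p' must be a temp_law or a finite constant")
    return(rep(p, length(T_C)))
  }
  if (any(!is.finite(T_C))) stopf("temperature_factor: non-finite temperature")
  TK <- T_C + .T0K
  num <- p$E0 * .kB * TK / .hP * exp(-p$dG_cat / (.Rgas * TK))
  den <- 1 + exp(p$dH_eq / .Rgas * (1 / p$T_eq - 1 / TK))
  num / den
}

# inhibition product: prod over active i of 1/(1 + i/K_i); covariates as a
# list with elements G, n, PX, X (vectors of equal length)
.inhibition_product <- function(b, cov) {
  out <- 1
  for (i in c("G", "n", "PX", "X"))
    if (b$mask[[i]]) out <- out / (1 + cov[[i]] / b$K[[i]])
  out
}

# activation product: prod over active i of (1 + i/K_i)
.activation_product <- function(b, cov) {
  out <- 1
  for (i in c("G", "n", "PX", "X"))
    if (b$mask[[i]]) out <- out * (1 + cov[[i]] / b$K[[i]])
  out
}

.check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(vals[[nm]] < 0, na.rm = TRUE)) stopf("negative %s not allowed", nm)
}

#' Specific substrate uptake rate
#'
#' Non-competitively inhibited Michaelis-Menten uptake per unit residual
#' biomass:
#' \deqn{\gamma^\circ = \gamma^\circ_{max}(T)\,\frac{G}{K_m^\circ+G}
#'   \prod_i \frac{1}{1+i/K_i^\circ}, \quad i \in \{G, n, P/X, X\}}
#' Inactive terms contribute a factor of 1.
#'
#' @param G substrate concentration, g/L (>= 0).
#' @param n generations since induction (log2 of total-biomass ratio).
#' @param PX product-to-biomass ratio, g/g.
#' @param X total biomass, g/L.
#' @param T_C temperature, degrees Celsius.
#' @param params a [kinetic_params()] object.
#' @return uptake rate, g substrate per g residual biomass per hour.
#' @export
uptake_rate <- function(G, n, PX, X, T_C, params) {
  .check_nonneg(G = G, n = n, PX = PX, X = X)
  b <- params$uptake
  gmax <- temperature_factor(T_C, if (b$mask[["temp"]]) b$temp else .const_of(b))
  sat <- if (b$mask[["Km"]]) G / (b$Km + G) else as.numeric(G > 0)
  gmax * sat * .inhibition_product(b, list(G = G, n = n, PX = PX, X = X))
}

# the constant form of a block's temp slot (used when mask says inactive)
.const_of <- function(b) {
  if (inherits(b$temp, "temp_law"))
    stopf("block holds a temperature law but its mask marks 'temp' inactive without a constant")
  b$temp
}

#' Specific maintenance uptake rate
#'
#' Minimum maintenance demand scaled up by activation terms:
#' \deqn{\gamma^\alpha = \gamma^\alpha_{min}(T) \prod_i (1+i/K_i^\alpha),
#'   \quad i \in \{\gamma^\circ, G, n, P/X, X\}}
#' The uptake-rate activation constant lives in the block's `Km` slot
#' (`K_g^\alpha`).
#'
#' @param g_circ specific substrate uptake rate, g/g/h (>= 0).
#' @inheritParams uptake_rate
#' @return maintenance rate, g/g/h; at least \eqn{\gamma^\alpha_{min}(T)}.
#' @export
maintenance_rate <- function(g_circ, G, n, PX, X, T_C, params) {
  .check_nonneg(g_circ = g_circ, G = G, n = n, PX = PX, X = X)
  b <- params$maintenance
  gmin <- temperature_factor(T_C, if (b$mask[["temp"]]) b$temp else .const_of(b))
  act <- if (b$mask[["Km"]]) 1 + g_circ / b$Km else 1
  gmin * act * .activation_product(b, list(G = G, n = n, PX = PX, X = X))
}

#' Specific production-directed substrate uptake rate
#'
#' Michaelis-Menten kinetics in the uptake surplus
#' \eqn{s = \max(\gamma^\circ - \gamma^\alpha, 0)} with non-competitive
#' inhibition:
#' \deqn{\gamma^\pi = \gamma^\pi_{max}(T)\,\frac{s}{K_m^\pi+s}
#'   \prod_i \frac{1}{1+i/K_i^\pi}}
#' The surplus is clamped at zero: production cannot run on a negative
#' surplus.
#'
#' @param g_circ,g_alpha uptake and maintenance rates, g/g/h.
#' @inheritParams uptake_rate
#' @return production-directed uptake rate, g/g/h.
#' @export
production_uptake_rate <- function(g_circ, g_alpha, G, n, PX, X, T_C, params) {
  b <- params$production
  s <- pmax(g_circ - g_alpha, 0)
  gmax <- temperature_factor(T_C, if (b$mask[["temp"]]) b$temp else .const_of(b))
  sat <- if (b$mask[["Km"]]) s / (b$Km + s) else as.numeric(s > 0)
  gmax * sat * .inhibition_product(b, list(G = G, n = n, PX = PX, X = X))
}

#' Partition uptake into growth and production rates
#'
#' Closes the additive uptake balance
#' \eqn{\gamma^\mu = \gamma^\circ - \gamma^\pi - \gamma^\alpha} and converts
#' the substrate fluxes into the specific production rate
#' \eqn{\pi = \gamma^\pi Y_{PG} X_r/X} and growth rate
#' \eqn{\mu = \pi + \gamma^\mu Y_{X_rG} X_r/X}.  The factor \eqn{X_r/X}
#' accounts for only the metabolically active residual biomass contributing.
#' A negative \eqn{\gamma^\mu} (starvation / degradation regime) is permitted.
#'
#' @param g_circ,g_pi,g_alpha specific substrate fluxes, g/g/h.
#' @param params a [kinetic_params()] object (yields are used).
#' @param Xr residual biomass, g/L (0 < Xr <= X).
#' @param X total biomass, g/L (> 0).
#' @return list with `g_mu` (g/g/h), `mu` (1/h), `pi` (1/h); additivity
#'   \eqn{\gamma^\mu + \gamma^\pi + \gamma^\alpha = \gamma^\circ} holds to
#'   machine precision.
#' @export
growth_partition <- function(g_circ, g_pi, g_alpha, params, Xr, X) {
  if (any(X <= 0) || any(Xr <= 0) || any(Xr > X * (1 + 1e-12)))
    stopf("growth_partition: need 0 < Xr <= X")
  g_mu <- g_circ - g_pi - g_alpha
  pi_ <- g_pi * params$yields[["Y_PG"]] * Xr / X
  mu <- pi_ + g_mu * params$yields[["Y_XrG"]] * Xr / X
  list(g_mu = g_mu, mu = mu, pi = pi_)
}

#' Evaluate all specific rates at given process covariates
#'
#' Convenience wrapper chaining [uptake_rate()], [maintenance_rate()],
#' [production_uptake_rate()] and [growth_partition()].
#'
#' @inheritParams uptake_rate
#' @param P product concentration, g/L.
#' @return data.frame with columns `g_circ`, `g_alpha`, `g_pi`, `g_mu`,
#'   `mu`, `pi`.
#' @export
process_rates <- function(G, n, P, X, T_C, params) {
  Xr <- X - P
  PX <- P / X
  gc <- uptake_rate(G, n, PX, X, T_C, params)
  ga <- maintenance_rate(gc, G, n, PX, X, T_C, params)
  gp <- production_uptake_rate(gc, ga, G, n, PX, X, T_C, params)
  part <- growth_partition(gc, gp, ga, params, Xr, X)
  data.frame(g_circ = gc, g_alpha = ga, g_pi = gp, g_mu = part$g_mu,
             mu = part$mu, pi = part$pi)
}
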