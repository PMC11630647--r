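# fast scalar-rate closure: precomputes block constants, avoids data.frame
# overhead inside the collocation inner loop
.make_rate_eval <- function(params) {
  pb <- function(b) {
    list(is_law = b$mask[["temp"]],
         temp = b$temp, Km = b$Km, K = b$K, mask = b$mask)
  }
  up <- pb(params$uptake); mn <- pb(params$maintenance); pr <- pb(params$production)
  YP <- params$yields[["Y_PG"]]; YX <- params$yields[["Y_XrG"]]
  tf <- function(s, TK) {
    if (s$is_law) {
      p <- s$temp
      p$E0 * .kB * TK / .hP * exp(-p$dG_cat / (.Rgas * TK)) /
        (1 + exp(p$dH_eq / .Rgas * (1 / p$T_eq - 1 / TK)))
    } else s$temp
  }
  inh <- function(s, G, n, PX, X) {
    f <- 1
    if (s$mask[["G"]]) f <- f / (1 + G / s$K[["G"]])
    if (s$mask[["n"]]) f <- f / (1 + n / s$K[["n"]])
    if (s$mask[["PX"]]) f <- f / (1 + PX / s$K[["PX"]])
    if (s$mask[["X"]]) f <- f / (1 + X / s$K[["X"]])
    f
  }
  act <- function(s, G, n, PX, X) {
    f <- 1
    if (s$mask[["G"]]) f <- f * (1 + G / s$K[["G"]])
    if (s$mask[["n"]]) f <- f * (1 + n / s$K[["n"]])
    if (s$mask[["PX"]]) f <- f * (1 + PX / s$K[["PX"]])
    if (s$mask[["X"]]) f <- f * (1 + X / s$K[["X"]])
    f
  }
  function(G, n, PX, X, Tc, g_circ_override = NULL) {
    TK <- Tc + .T0K
    gc <- if (is.null(g_circ_override)) {
      sat <- if (up$mask[["Km"]]) G / (up$Km + G) else as.numeric(G > 0)
      tf(up, TK) * sat * inh(up, G, n, PX, X)
    } else g_circ_override
    ga <- tf(mn, TK) * (if (mn$mask[["Km"]]) 1 + gc / mn$Km else 1) *
      act(mn, G, n, PX, X)
    s <- max(gc - ga, 0)
    gp <- tf(pr, TK) * (if (pr$mask[["Km"]]) s / (pr$Km + s) else as.numeric(s > 0)) *
      inh(pr, G, n, PX, X)
    gm <- gc - gp - ga
    Xr_X <- 1 - PX
    pi_ <- gp * YP * Xr_X
    mu <- pi_ + gm * YX * Xr_X
    list(g_circ = gc, g_alpha = ga, g_pi = gp, g_mu = gm, mu = mu, pi = pi_)
  }
}

# uptake capacity at saturating substrate (quasi-steady cap)
.uptake_cap <- function(params, n, PX, X, Tc) {
  b <- params$uptake
  gmax <- temperature_factor(Tc, if (b$mask[["temp"]]) b$temp else .const_of(b))
  f <- 1
  if (b$mask[["n"]]) f <- f / (1 + n / b$K[["n"]])
  if (b$mask[["PX"]]) f <- f / (1 + PX / b$K[["PX"]])
  if (b$mask[["X"]]) f <- f / (1 + X / b$K[["X"]])
  gmax * f
}

#' Collocation configuration for the optimal-control transcription
#'
#' The horizon is split into finite elements aligned with the sampling
#' events; on each element the smooth states (X, P, V) use a degree-1
#' collocation point at the element midpoint (implicit midpoint rule) while
#' the stiff substrate state uses the point at 1 (backward Euler).  Controls
#' are piecewise linear: their values are optimized at `n_control` knots and
#' interpolated to every element boundary, and the smoothness penalty of the
#' objective is evaluated on the element-boundary values.
#'
#' @param n_elements number of finite elements (default 100).
#' @param n_control number of control knots per control (default 13, about
#'   hourly on a 12 h horizon).
#' @param c_feed,c_temp smoothness penalty factors for the feed and
#'   temperature controls.
#' @param newton_tol,newton_maxit per-element Newton solve settings.
#' @return list of class `collocation_config`.
#' @export
collocation_config <- function(n_elements = 100, n_control = 13,
                               c_feed = 1e-4, c_temp = 1e-4,
                               newton_tol = 1e-10, newton_maxit = 30) {
  stopifnot(n_elements >= 2, n_control >= 2, c_feed >= 0, c_temp >= 0)
  structure(list(n_elements = n_elements, n_control = n_control,
                 c_feed = c_feed, c_temp = c_temp, newton_tol = newton_tol,
                 newton_maxit = newton_maxit), class = "collocation_config")
}

#' Constraint set of the optimal-control problem
#'
#' Defaults follow the case study: initial biomass 30 g/L (the center-point
#' mean), initial volume 1.3 L, feed substrate concentration 390 g/L, 35 mL
#' sampling events at t = 2, 4, 6, 8, 10 h, a 12 h horizon, maximum volume
#' 2.5 L, temperature bounds 25-40 C.
#'
#' @param X0,P0,G0,V0 initial state.
#' @param Gf feed substrate concentration, g/L.
#' @param tend process end time, h (fixed horizon).
#' @param Vmax maximum broth volume, L (`Inf` disables).
#' @param events sampling events (data.frame `time`, `volume`).
#' @param T_bounds,feed_bounds control bounds (degrees C; g/h).
#' @param base base-feed model or `NULL`.
#' @return list of class `ocp_constraints`.
#' @export
ocp_constraints <- function(X0 = 30, P0 = 0, G0 = 0, V0 = 1.3, Gf = 390,
                            tend = 12, Vmax = 2.5,
                            events = data.frame(time = c(2, 4, 6, 8, 10),
                                                volume = 0.035),
                            T_bounds = c(25, 40), feed_bounds = c(0, 100),
                            base = base_feed_params()) {
  stopifnot(V0 > 0, V0 < Vmax, X0 > 0, tend > 0, Gf > 0)
  structure(list(X0 = X0, P0 = P0, G0 = G0, V0 = V0, Gf = Gf, tend = tend,
                 Vmax = Vmax, events = events, T_bounds = T_bounds,
                 feed_bounds = feed_bounds, base = base),
            class = "ocp_constraints")
}

#' Transcribe the process model into a collocation program
#'
#' Builds the element grid (aligned with the sampling-event times), the
#' control parameterization and the collocated dynamics.  The collocation
#' equalities are eliminated sequentially: each element's implicit step is
#' solved by a damped Newton iteration to `newton_tol`, so every returned
#' trajectory satisfies the collocation constraints by construction and the
#' remaining decision variables are the control-knot values only.
#'
#' @param params a [kinetic_params()] object.
#' @param config a [collocation_config()].
#' @param constraints an [ocp_constraints()].
#' @param quasi_steady if `TRUE`, the substrate state is removed and uptake
#'   is linked algebraically to the feed (`G` identically 0, uptake =
#'   feed/(Xr V) capped at the kinetic maximum).
#' @return object of class `kinfed_nlp` with elements `rollout(feed, temp)`
#'   (collocated trajectory), `objective(z)`, `penalty(u_mat)`, bounds and
#'   grid descriptions.
#' @export
transcribe_ocp <- function(params, config = collocation_config(),
                           constraints = ocp_constraints(),
                           quasi_steady = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  cn <- constraints
  ev <- cn$events
  ev <- ev[ev$time > 0 & ev$time < cn$tend, , drop = FALSE]
  # element grid: distribute elements over inter-event segments by length
  brk <- sort(unique(c(0, ev$time, cn$tend)))
  seg_len <- diff(brk)
  n_seg <- pmax(1L, round(config$n_elements * seg_len / cn$tend))
  tgrid <- unlist(lapply(seq_along(seg_len), function(k)
    seq(brk[k], brk[k + 1], length.out = n_seg[k] + 1)[-1]))
  tgrid <- c(0, tgrid)
  ne <- length(tgrid) - 1L
  ev_after <- match(ev$time, tgrid)   # V jump applied after reaching this node
  tk <- seq(0, cn$tend, length.out = config$n_control)  # control knots

  rate_eval <- .make_rate_eval(params)
  X0V0 <- cn$X0 * cn$V0

  step <- function(y0, tmid, h, f_sub, Tc) {
    # y = (X, P, G, V) or (X, P, V) for quasi-steady
    nq <- length(y0)
    resid <- function(y1) {
      Xc <- (y0[1] + y1[1]) / 2; Pc <- (y0[2] + y1[2]) / 2
      Vc <- (y0[nq] + y1[nq]) / 2
      Gc <- if (quasi_steady) 0 else max(y1[3], 0)    # Radau point at 1
      Xc <- max(Xc, 1e-9); Pc <- max(Pc, 0)
      PX <- min(Pc / Xc, 1 - 1e-9)
      n_gen <- log2(max(Xc * Vc / X0V0, 1))
      if (quasi_steady) {
        Xr <- Xc * (1 - PX)
        gc_alg <- min(f_sub / (Xr * Vc),
                      .uptake_cap(params, n_gen, PX, Xc, Tc))
        r <- rate_eval(0, n_gen, PX, Xc, Tc, g_circ_override = gc_alg)
      } else r <- rate_eval(Gc, n_gen, PX, Xc, Tc)
      f_base <- if (is.null(cn$base)) 0 else
        max(Xc * Vc * (cn$base$a * r$mu + cn$base$b), 0)
      f_vol <- f_sub / cn$Gf + f_base
      D <- f_vol / Vc
      gamma <- r$g_circ * (1 - PX)
      dx <- c(r$mu * Xc - D * Xc, r$pi * Xc - D * Pc)
      if (!quasi_steady)
        dx <- c(dx, -gamma * Xc + D * (cn$Gf - Gc))
      dx <- c(dx, f_vol)
      y1 - y0 - h * dx
    }
    y1 <- y0  # initial guess: constant extrapolation
    sc <- pmax(abs(y0), 1e-3)
    J <- NULL
    for (it in seq_len(config$newton_maxit)) {
      r0 <- resid(y1)
      if (max(abs(r0 / sc)) < config$newton_tol) return(y1)
      if (is.null(J) || it %% 4L == 1L) {
        J <- matrix(0, nq, nq)
        for (j in seq_len(nq)) {
          e <- numeric(nq); e[j] <- 1e-7 * sc[j]
          J[, j] <- (resid(y1 + e) - r0) / e[j]
        }
      }
      dy <- tryCatch(solve(J, -r0), error = function(e) NULL)
      if (is.null(dy)) stopf("collocation step failed: singular Jacobian")
      lam <- 1
      repeat {
        y_try <- y1 + lam * dy
        if (y_try[nq] > 0 && max(abs(resid(y_try) / sc)) <=
            max(abs(r0 / sc)) * (1 - 0.1 * lam) + 1e-14) break
        lam <- lam / 2
        if (lam < 1e-4) break
      }
      y1 <- y1 + lam * dy
    }
    if (max(abs(resid(y1) / sc)) > 1e-6)
      stopf("collocation step did not converge at t = %.3f", tmid)
    y1
  }

  rollout <- function(feed_knots, temp_knots) {
    fb <- stats::approx(tk, feed_knots, xout = tgrid, rule = 2)$y  # boundary values
    Tb <- stats::approx(tk, temp_knots, xout = tgrid, rule = 2)$y
    y <- if (quasi_steady) c(cn$X0, cn$P0, cn$V0)
         else c(cn$X0, cn$P0, cn$G0, cn$V0)
    nq <- length(y)
    out <- matrix(NA_real_, ne + 1L, nq)
    out[1, ] <- y
    for (k in seq_len(ne)) {
      h <- tgrid[k + 1] - tgrid[k]
      tmid <- (tgrid[k] + tgrid[k + 1]) / 2
      f_mid <- (fb[k] + fb[k + 1]) / 2
      T_mid <- (Tb[k] + Tb[k + 1]) / 2
      y <- step(y, tmid, h, f_mid, T_mid)
      out[k + 1L, ] <- y   # pre-event value at the node (simulator convention)
      if (length(ix <- which(ev_after == k + 1L)))
        y[nq] <- y[nq] - sum(ev$volume[ix])
      if (y[nq] <= 0) stopf("collocation rollout: V <= 0")
    }
    traj <- as.data.frame(out)
    names(traj) <- if (quasi_steady) c("X", "P", "V") else c("X", "P", "G", "V")
    if (quasi_steady) traj$G <- 0
    traj <- cbind(t = tgrid, traj, feed = fb, Temp = Tb)
    traj
  }

  penalty <- function(fb, Tb) {
    relsq <- function(u) {
      a <- u[-length(u)]; b <- u[-1]
      s <- a + b
      sum(ifelse(s > 0, ((a - b) / s)^2, 0))
    }
    h <- 1 / ne   # element length in scaled time
    config$c_feed * h * relsq(fb) + config$c_temp * h * relsq(Tb)
  }

  structure(list(
    params = params, config = config, constraints = cn,
    quasi_steady = quasi_steady, tgrid = tgrid, control_times = tk,
    n_elements = ne,
    rollout = rollout,
    penalty = penalty,
    evaluate = function(feed_knots, temp_knots) {
      traj <- rollout(feed_knots, temp_knots)
      ypx <- traj$P[nrow(traj)] / traj$X[nrow(traj)]
      pen <- penalty(traj$feed, traj$Temp)
      vviol <- max(0, max(traj$V) - cn$Vmax)
      list(traj = traj, ypx = ypx, penalty = pen, v_violation = vviol,
           objective = ypx - pen)
    }), class = "kinfed_nlp")
}

#' Solve the regularized yield-maximization problem
#'
#' Maximizes final product-to-biomass yield \eqn{Y_{PX} = P(t_{end}) /
#' X(t_{end})} minus the control-smoothness penalty over the feed and
#' temperature knot values, subject to the collocated dynamics (eliminated
#' inside [transcribe_ocp()]), control bounds and the volume cap (enforced
#' by an exterior quadratic penalty, reported as a feasibility violation if
#' active).  Decision variables are scaled to the unit box; the
#' bound-constrained quasi-Newton solver `nlminb` with numerical gradients
#' does the outer minimization, optionally from several seeded starts.
#'
#' @param nlp a `kinfed_nlp` from [transcribe_ocp()].
#' @param init optional list with `feed` and `temp` knot vectors; default is
#'   the center-point exponential feed at constant 31 C.
#' @param multi_start number of seeded starts (best solution returned).
#' @param seed integer seed for the extra starts.
#' @param maxit iteration cap for each solve.
#' @return object of class `kinfed_ocp`: `profile` (knot times and values),
#'   `trajectory`, `objective`, `yield_term`, `penalty_term`, `convergence`.
#' @export
solve_ocp <- function(nlp, init = NULL, multi_start = 1, seed = 1,
                      maxit = 300) {
  stopifnot(inherits(nlp, "kinfed_nlp"))
  cn <- nlp$constraints
  tk <- nlp$control_times
  nk <- length(tk)
  if (is.null(init)) {
    f0 <- 0.12 * cn$X0 * cn$V0 / nlp$params$yields[["Y_XrG"]]
    init <- list(feed = pmin(f0 * exp(0.12 * tk), cn$feed_bounds[2]),
                 temp = rep(mean(c(31, mean(cn$T_bounds))), nk))
  }
  lower <- c(rep(cn$feed_bounds[1], nk), rep(cn$T_bounds[1], nk))
  upper <- c(rep(cn$feed_bounds[2], nk), rep(cn$T_bounds[2], nk))
  span <- upper - lower
  to_z <- function(u) (u - lower) / pmax(span, 1e-12)
  from_z <- function(z) lower + z * span   # span 0 pins the control
  obj <- function(z) {
    u <- from_z(z)
    res <- try(nlp$evaluate(u[1:nk], u[(nk + 1):(2 * nk)]), silent = TRUE)
    if (inherits(res, "try-error")) return(1e3)
    -(res$objective) + 1e4 * res$v_violation^2
  }
  z0 <- to_z(pmin(pmax(c(init$feed, init$temp), lower), upper))
  starts <- list(z0)
  if (multi_start > 1) {
    extra <- with_seed(seed, lapply(seq_len(multi_start - 1), function(i)
      pmin(pmax(z0 + stats::rnorm(length(z0), 0, 0.15), 0), 1)))
    starts <- c(starts, extra)
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::nlminb(s, obj, lower = 0, upper = 1,
                         control = list(iter.max = maxit, eval.max = 4 * maxit))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  u <- from_z(best$par)
  res <- nlp$evaluate(u[1:nk], u[(nk + 1):(2 * nk)])
  structure(list(
    profile = list(t = tk, feed = u[1:nk], temp = u[(nk + 1):(2 * nk)],
                   Gf = cn$Gf, tend = cn$tend),
    trajectory = res$traj, objective = res$objective,
    yield_term = res$ypx, penalty_term = res$penalty,
    v_violation = res$v_violation,
    convergence = best[c("convergence", "message", "iterations")],
    quasi_steady = nlp$quasi_steady), class = "kinfed_ocp")
}

#' @export
print.kinfed_ocp <- function(x, ...) {
  nt <- nrow(x$trajectory)
  cat(sprintf("optimal control solution%s\n",
              if (x$quasi_steady) " (quasi-steady substrate)" else ""))
  cat(sprintf("  final YPX = %.4f g/g (objective %.4f, penalty %.3g)\n",
              x$yield_term, x$objective, x$penalty_term))
  cat(sprintf("  final state: X = %.1f, P = %.2f g/L, V = %.2f L at t = %.1f h\n",
              x$trajectory$X[nt], x$trajectory$P[nt], x$trajectory$V[nt],
              x$trajectory$t[nt]))
  cat(sprintf("  temperature range [%.1f, %.1f] C, feed range [%.2f, %.2f] g/h\n",
              min(x$profile$temp), max(x$profile$temp),
              min(x$profile$feed), max(x$profile$feed)))
  invisible(x)
}

#' Quasi-steady variant of the optimal-control problem
#'
#' Removes the stiff substrate state: all fed substrate is taken up
#' immediately (G identically 0), with uptake linked to the feed through
#' \eqn{\gamma^\circ = f/(X_r V)} capped at the kinetic maximum.
#'
#' @inheritParams transcribe_ocp
#' @param ... forwarded to [solve_ocp()].
#' @return a `kinfed_ocp` result (its trajectory has `G = 0` throughout).
#' @export
quasi_steady_ocp <- function(params, config = collocation_config(),
                             constraints = ocp_constraints(), ...) {
  nlp <- transcribe_ocp(params, config, constraints, quasi_steady = TRUE)
  solve_ocp(nlp, ...)
}

#' Approximate an optimized feed profile by a straight line
#'
#' Least-squares line through the optimal feed values on the element
#' boundaries; re-simulates the process with the linear feed (same
#' temperature profile) and reports the relative change of the final yield,
#' biomass and product.
#'
#' @param result a `kinfed_ocp` from [solve_ocp()].
#' @param nlp the `kinfed_nlp` the result was solved on.
#' @return list with `phi1` (g/h), `phi2` (g/h^2), and `rel_change`
#'   (named: `YPX`, `X`, `P`).
#' @export
approximate_feed_linear <- function(result, nlp) {
  tr <- result$trajectory
  co <- stats::lm.fit(cbind(1, tr$t), tr$feed)$coefficients
  phi1 <- co[[1]]; phi2 <- co[[2]]
  tk <- nlp$control_times
  lin <- pmax(phi1 + phi2 * tk, 0)
  res <- nlp$evaluate(lin, result$profile$temp)
  nt <- nrow(tr)
  old <- c(YPX = result$yield_term, X = tr$X[nt], P = tr$P[nt])
  new <- c(YPX = res$ypx, X = res$traj$X[nrow(res$traj)],
           P = res$traj$P[nrow(res$traj)])
  list(phi1 = phi1, phi2 = phi2, rel_change = (new - old) / old)
}
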