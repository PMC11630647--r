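#' Differential-evolution / polish control settings
#'
#' @param pop_factor population size per dimension (population =
#'   `max(pop_min, pop_factor * n_dim)`).
#' @param pop_min minimum population size.
#' @param maxiter maximum number of generations.
#' @param tol relative convergence tolerance on the population spread.
#' @param CR crossover probability.
#' @param polish run a local `nlminb` refinement from the best member.
#' @return list of settings.
#' @export
de_control <- function(pop_factor = 15, pop_min = 20, maxiter = 2000,
                       tol = 1e-8, CR = 0.9, polish = TRUE) {
  list(pop_factor = pop_factor, pop_min = pop_min, maxiter = maxiter,
       tol = tol, CR = CR, polish = polish)
}

# seeded differential evolution (rand/1/bin, dithered F) over box bounds;
# fn takes a (pop x dim) matrix and returns a vector of objective values
.de_optim <- function(fn, lower, upper, seed = 1, control = de_control()) {
  d <- length(lower)
  np <- max(control$pop_min, control$pop_factor * d)
  with_seed(seed, {
    pop <- matrix(stats::runif(np * d, lower, upper), nrow = np, ncol = d,
                  byrow = TRUE)
    fit <- fn(pop)
    fit[!is.finite(fit)] <- .Machine$double.xmax
    for (it in seq_len(control$maxiter)) {
      idx <- t(vapply(seq_len(np), function(i) sample(np, 3), integer(3)))
      Fd <- stats::runif(np, 0.5, 1)
      mut <- pop[idx[, 1], , drop = FALSE] +
        Fd * (pop[idx[, 2], , drop = FALSE] - pop[idx[, 3], , drop = FALSE])
      mut <- pmin(pmax(mut, matrix(lower, np, d, byrow = TRUE)),
                  matrix(upper, np, d, byrow = TRUE))
      cross <- matrix(stats::runif(np * d) < control$CR, np, d)
      jrand <- cbind(seq_len(np), sample.int(d, np, replace = TRUE))
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mut, pop)
      ftrial <- fn(trial)
      ftrial[!is.finite(ftrial)] <- .Machine$double.xmax
      better <- ftrial <= fit
      pop[better, ] <- trial[better, , drop = FALSE]
      fit[better] <- ftrial[better]
      if (stats::sd(fit) <= control$tol * (abs(mean(fit)) + 1e-300)) break
    }
    best <- which.min(fit)
    par <- pop[best, ]; val <- fit[best]
    if (isTRUE(control$polish)) {
      sc <- function(x) fn(matrix(x, nrow = 1))
      pol <- try(stats::nlminb(par, sc, lower = lower, upper = upper,
                               control = list(iter.max = 500)), silent = TRUE)
      if (!inherits(pol, "try-error") && is.finite(pol$objective) &&
          pol$objective <= val) {
        par <- pmin(pmax(pol$par, lower), upper); val <- pol$objective
      }
    }
    list(par = par, value = val, iterations = it)
  })
}

# ---- fitting design: rows, target, covariates per rate equation ----

.removable_terms <- function(rate) {
  if (rate == "uptake") c("temp", "G", "n", "PX", "X")       # Km never removed
  else c("temp", "Km", "G", "n", "PX", "X")
}

.full_mask <- function() stats::setNames(rep(TRUE, 6), .term_names)

.build_design <- function(obs, rate) {
  obs <- as.data.frame(obs)
  if (rate == "uptake") {
    rows <- which(obs$valid_uptake & is.finite(obs$g_circ))
    y <- obs$g_circ[rows]; mcov <- obs$G[rows]
  } else if (rate == "maintenance") {
    rows <- which(is.finite(obs$g_alpha))
    y <- obs$g_alpha[rows]; mcov <- obs$g_circ[rows]
  } else if (rate == "production") {
    rows <- which(is.finite(obs$g_pi))
    y <- obs$g_pi[rows]
    mcov <- pmax(obs$g_circ[rows] - obs$g_alpha[rows], 0)
  } else stopf("unknown rate '%s'", rate)
  if (!length(rows)) stopf("no valid observations for rate '%s'", rate)
  list(rate = rate, y = y, w = obs$weight[rows],
       mcov = mcov,                       # saturation / activation covariate
       G = obs$G[rows], n = obs$n[rows], PX = obs$PX[rows], X = obs$X[rows],
       TK = obs$Temp[rows] + .T0K, rows = rows)
}

# parameter layout for a mask: slot names in transformed (mostly log10) space
.layout <- function(mask, des) {
  scale_of <- function(v) {
    v <- v[is.finite(v) & v > 0]
    if (!length(v)) 1 else mean(v)
  }
  sl <- list()
  if (mask[["temp"]])
    sl <- c(sl, list(
      c("lr0", -4, 1), c("ldG", 4, log10(2e5)), c("Teq", 300, 325),
      c("ldH", log10(5e4), 6)))
  else sl <- c(sl, list(c("lc", -4, 1)))
  if (mask[["Km"]]) {
    s <- log10(scale_of(des$mcov))
    sl <- c(sl, list(c("lKm", s - 3, s + 3)))
  }
  for (i in c("G", "n", "PX", "X")) if (mask[[i]]) {
    s <- log10(scale_of(des[[i]]))
    sl <- c(sl, list(c(paste0("lK_", i), s - 3, s + 3)))
  }
  nm <- vapply(sl, `[`, character(1), 1)
  list(names = nm,
       lower = as.numeric(vapply(sl, `[`, character(1), 2)),
       upper = as.numeric(vapply(sl, `[`, character(1), 3)))
}

# vectorized model prediction: th is (pop x dim), returns (n x pop)
.predict_matrix <- function(th, mask, des) {
  np <- nrow(th); n <- length(des$y)
  k <- 0L
  col <- function() { k <<- k + 1L; th[, k] }
  if (mask[["temp"]]) {
    r0 <- 10^col(); dG <- 10^col(); Teq <- col(); dH <- 10^col()
    base <- outer(des$TK / .Tref, r0) *
      exp(outer(1 / des$TK - 1 / .Tref, -dG / .Rgas)) /
      (1 + exp(outer(-1 / des$TK, dH / .Rgas) +
                 matrix(dH / .Rgas / Teq, n, np, byrow = TRUE)))
  } else {
    base <- matrix(10^col(), n, np, byrow = TRUE)
  }
  if (mask[["Km"]]) {
    Km <- 10^col()
    base <- base * (if (des$rate == "maintenance")
      1 + outer(des$mcov, 1 / Km)               # activation (1 + g/Kg)
    else des$mcov / (outer(rep(1, n), Km) + des$mcov))
  } else if (des$rate != "maintenance") {
    base <- base * (des$mcov > 0)               # saturated limit
  }
  for (i in c("G", "n", "PX", "X")) if (mask[[i]]) {
    K <- 10^col()
    f <- 1 + outer(des[[i]], 1 / K)
    base <- base * (if (des$rate == "maintenance") f else 1 / f)
  }
  base
}

# assemble a fitted rate_block from the transformed parameter vector
.block_from_par <- function(par, mask, rate) {
  nm <- names(par)
  geti <- function(x) unname(par[[x]])
  temp <- if (mask[["temp"]]) {
    dG <- 10^geti("ldG")
    r0 <- 10^geti("lr0")
    E0 <- r0 / (.kB * .Tref / .hP * exp(-dG / (.Rgas * .Tref)))
    temp_law(E0 = E0, dG_cat = dG, T_eq = geti("Teq"), dH_eq = 10^geti("ldH"))
  } else 10^geti("lc")
  Km <- if (mask[["Km"]]) 10^geti("lKm") else Inf
  K <- c(G = Inf, n = Inf, PX = Inf, X = Inf)
  for (i in c("G", "n", "PX", "X"))
    if (mask[[i]]) K[[i]] <- 10^geti(paste0("lK_", i))
  rate_block(temp, Km, K, mask = mask,
             nonremovable = if (rate == "uptake") c(Km = TRUE) else c(Km = FALSE))
}

#' Fit one rate equation to observed rates
#'
#' Minimizes the weighted sum of squared errors between the kinetic rate law
#' (restricted to the terms active in `mask`) and the observed rates, using
#' seeded differential evolution over box bounds in log-transformed
#' parameter space, followed by a local polish.  Each of the three rates is
#' fitted separately; production uses the observed uptake surplus
#' \eqn{\max(\hat\gamma^\circ - \hat\gamma^\alpha, 0)} as its covariate and
#' maintenance uses \eqn{\hat\gamma^\circ}.
#'
#' @param obs a `rate_observations` data.frame (see [observed_rates()]).
#' @param rate `"uptake"`, `"maintenance"` or `"production"`.
#' @param mask named logical over terms `temp, Km, G, n, PX, X`; default all
#'   active.
#' @param seed integer seed (identical seeds give identical fits).
#' @param control a [de_control()] list.
#' @param bounds optional 2-row matrix (`lower`, `upper`) overriding the
#'   default transformed-space bounds; columns follow the layout reported in
#'   the result's `par` names.
#' @return object of class `rate_fit`: fitted `block`, transformed `par`,
#'   `rss`, `tss`, `residuals`, `n_points`, `n_params`, `seed`.
#' @export
fit_rate <- function(obs, rate = c("uptake", "maintenance", "production"),
                     mask = NULL, seed = 1, control = de_control(),
                     bounds = NULL) {
  rate <- match.arg(rate)
  des <- .build_design(obs, rate)
  mask <- (mask %||% .full_mask())[.term_names]
  names(mask) <- .term_names
  if (rate == "uptake" && !mask[["Km"]])
    stopf("the uptake Michaelis constant cannot be removed")
  lay <- .layout(mask, des)
  if (!is.null(bounds)) { lay$lower <- bounds[1, ]; lay$upper <- bounds[2, ] }
  objective <- function(th) {
    pred <- .predict_matrix(th, mask, des)
    colSums(des$w * (pred - des$y)^2)
  }
  opt <- .de_optim(objective, lay$lower, lay$upper, seed = seed,
                   control = control)
  par <- stats::setNames(opt$par, lay$names)
  pred <- .predict_matrix(matrix(opt$par, nrow = 1), mask, des)[, 1]
  ybar <- sum(des$w * des$y) / sum(des$w)
  structure(list(rate = rate, block = .block_from_par(par, mask, rate),
                 par = par, mask = mask, rss = opt$value,
                 tss = sum(des$w * (des$y - ybar)^2),
                 residuals = des$y - pred, fitted = pred,
                 n_points = length(des$y), n_params = length(par),
                 rows = des$rows, seed = seed,
                 iterations = opt$iterations),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("rate fit (%s): %d parameters, %d points, rss = %.4g (R2 = %.3f)\n",
              x$rate, x$n_params, x$n_points, x$rss, 1 - x$rss / x$tss))
  print(round(x$par, 4))
  invisible(x)
}

#' F-test for a nested model reduction
#'
#' \deqn{F = \frac{(RSS_{red} - RSS_{full})/df_{rem}}{RSS_{full}/df_{res}}}
#' with the upper-tail p-value of the F distribution.  If the reduced model
#' fits better than the full one (global-optimizer noise), the reduced RSS
#' is floored at the full RSS, giving p = 1.  A full-model RSS of exactly 0
#' makes any increase infinitely significant (p = 0); two zero RSS values
#' give p = 1.
#'
#' @param rss_full,rss_reduced residual sums of squares (full nested in
#'   reduced's complement).
#' @param df_removed number of parameters dropped.
#' @param df_residual residual degrees of freedom of the full model.
#' @return upper-tail p-value.
#' @export
f_test <- function(rss_full, rss_reduced, df_removed, df_residual) {
  if (df_residual < 1) stopf("f_test: df_residual must be >= 1")
  if (rss_full < 0 || rss_reduced < 0) stopf("f_test: negative rss")
  rss_reduced <- max(rss_reduced, rss_full)
  if (rss_full == 0) return(if (rss_reduced == 0) 1 else 0)
  Fstat <- ((rss_reduced - rss_full) / df_removed) / (rss_full / df_residual)
  stats::pf(Fstat, df_removed, df_residual, lower.tail = FALSE)
}

#' Backward elimination of insignificant kinetic terms
#'
#' Iteratively: fit the model with all currently active terms, refit once
#' per removable term with that term left out, compute the F-test p-value of
#' each reduction, and remove the term with the highest p-value if it is at
#' least `alpha`; stop when every remaining term is significant.  The uptake
#' Michaelis constant is never removed (its removal admits physically
#' impossible negative substrate concentrations).  The temperature law is
#' one removable unit collapsing 4 parameters to 1 fitted constant
#' (`df_removed = 3`).  The iteration count is capped at the number of
#' removable terms plus one (7 for the most flexible rate equations).
#'
#' When both the full and the reduced RSS fall below `1e-12 * TSS` the data
#' are fitted exactly either way and the term is deemed removable (p := 1).
#'
#' @inheritParams fit_rate
#' @param alpha significance level in (0, 1).
#' @param mask starting mask (default: all terms active).
#' @param cache optional environment memoising fits by mask (shared across
#'   calls, e.g. over an alpha grid).
#' @return list with elements `mask` (final), `fit` (final `rate_fit`),
#'   `trace` (data.frame: iteration, candidate, rss_full, rss_without, F, p,
#'   removed) and `alpha`.
#' @export
eliminate_terms <- function(obs, rate, alpha = 0.2, seed = 1, mask = NULL,
                            control = de_control(), cache = NULL) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  mask <- (mask %||% .full_mask())[.term_names]
  names(mask) <- .term_names
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  memo_fit <- function(m) {
    key <- paste0(rate, ":", paste(as.integer(m), collapse = ""))
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- fit_rate(obs, rate, mask = m, seed = seed, control = control)
    cache[[key]]
  }
  removable <- .removable_terms(rate)
  max_iter <- sum(mask[removable]) + 1L
  trace <- NULL
  for (iter in seq_len(max_iter)) {
    full <- memo_fit(mask)
    df_res <- max(full$n_points - full$n_params, 1L)
    cands <- removable[mask[removable]]
    if (!length(cands)) break
    ps <- Fs <- rssw <- stats::setNames(numeric(length(cands)), cands)
    for (cd in cands) {
      m2 <- mask; m2[[cd]] <- FALSE
      red <- memo_fit(m2)
      df_rem <- full$n_params - red$n_params
      near0 <- full$tss * 1e-12
      p <- if (full$rss < near0 && red$rss < near0) 1
           else f_test(full$rss, red$rss, df_rem, df_res)
      rssr <- max(red$rss, full$rss)
      ps[[cd]] <- p
      Fs[[cd]] <- if (full$rss > 0)
        ((rssr - full$rss) / df_rem) / (full$rss / df_res) else Inf
      rssw[[cd]] <- red$rss
    }
    worst <- names(ps)[which.max(ps)]
    remove <- ps[[worst]] >= alpha
    trace <- rbind(trace, data.frame(
      iteration = iter, candidate = cands, rss_full = full$rss,
      rss_without = as.numeric(rssw), F = as.numeric(Fs), p = as.numeric(ps),
      removed = cands == worst & remove))
    if (!remove) break
    mask[[worst]] <- FALSE
  }
  final <- memo_fit(mask)
  list(mask = mask, fit = final, trace = trace, alpha = alpha)
}

#' Corrected Akaike information criterion
#'
#' Computed, in the `"printed"` variant, as
#' \deqn{AIC_C = \#p\,(\log(RSS/\#v) + 1) + 2\#v + \#v(1+\#v)/(\#p-\#v-3)}
#' with `#p` the number of points and `#v` the number of parameters.  Note
#' this differs from the textbook small-sample AICc, available as variant
#' `"standard"`: \eqn{\#p \log(RSS/\#p) + 2\#v + 2\#v(\#v+1)/(\#p-\#v-1)}.
#'
#' @param rss residual sum of squares.
#' @param n_params number of fitted parameters.
#' @param n_points number of data points.
#' @param variant `"printed"` (default) or `"standard"`.
#' @return the criterion value.
#' @export
aicc <- function(rss, n_params, n_points, variant = c("printed", "standard")) {
  variant <- match.arg(variant)
  if (variant == "printed") {
    if (n_points - n_params - 3 <= 0)
      stopf("aicc undefined: n_points - n_params - 3 <= 0")
    n_points * (log(rss / n_params) + 1) + 2 * n_params +
      n_params * (1 + n_params) / (n_points - n_params - 3)
  } else {
    if (n_points - n_params - 1 <= 0)
      stopf("aicc undefined: n_points - n_params - 1 <= 0")
    n_points * log(rss / n_points) + 2 * n_params +
      2 * n_params * (n_params + 1) / (n_points - n_params - 1)
  }
}

#' Exhaustive model selection by AICc
#'
#' Fits every admissible term mask for one rate equation (the uptake
#' Michaelis constant is always present; the temperature law is one on/off
#' unit) and returns the mask with the lowest corrected AIC.
#'
#' @inheritParams fit_rate
#' @param variant forwarded to [aicc()].
#' @return list with `mask` (best), `fit`, and `table` (one row per mask
#'   with rss, n_params and aicc).
#' @export
exhaustive_aicc_select <- function(obs, rate, seed = 1,
                                   control = de_control(),
                                   variant = "printed") {
  removable <- .removable_terms(rate)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(removable)))
  names(combos) <- removable
  rows <- list(); fits <- list()
  for (i in seq_len(nrow(combos))) {
    mask <- .full_mask()
    mask[removable] <- unlist(combos[i, ])
    fit <- fit_rate(obs, rate, mask = mask, seed = seed, control = control)
    rows[[i]] <- data.frame(
      mask = paste(.term_names[mask], collapse = "+"),
      n_params = fit$n_params, rss = fit$rss,
      aicc = aicc(fit$rss, fit$n_params, fit$n_points, variant = variant))
    fits[[i]] <- fit
  }
  tab <- do.call(rbind, rows)
  best <- which.min(tab$aicc)
  mask <- .full_mask(); mask[removable] <- unlist(combos[best, ])
  list(mask = mask, fit = fits[[best]], table = tab)
}

#' Goodness of fit
#'
#' Coefficient of determination \eqn{R^2 = 1 - RSS/TSS} (TSS around the
#' measured mean), its adjusted version with residual degrees of freedom
#' `#points - #vars - 1` and total degrees of freedom `#points - 1`, and
#' relative errors with respect to the measured mean.
#'
#' @param pred predicted values.
#' @param meas measured values.
#' @param n_vars number of model variables (parameters).
#' @return list with `r2`, `r2_adj`, `rel_err` (vector).
#' @export
goodness <- function(pred, meas, n_vars) {
  stopifnot(length(pred) == length(meas))
  np <- length(meas)
  if (np < 3) stopf("goodness: need at least 3 points")
  rss <- sum((pred - meas)^2)
  tss <- sum((meas - mean(meas))^2)
  if (tss == 0) stopf("goodness undefined for constant measurements")
  df_res <- np - n_vars - 1
  df_tot <- np - 1
  list(r2 = 1 - rss / tss,
       r2_adj = 1 - (rss / df_res) / (tss / df_tot),
       rel_err = (meas - pred) / mean(meas))
}

# default 13-level significance grid
alpha_grid_default <- function()
  c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30,
    0.40, 0.50)

#' Select the elimination significance level by cross-validation
#'
#' Leave-one-run-out: for each significance level, run term elimination and
#' fitting on all runs but one, simulate the held-out run under its own
#' controls, and score the squared error of the predicted final
#' product-to-biomass yield \eqn{Y_{PX} = P(t_{end})/X(t_{end})} against the
#' measured one.  The level with the lowest mean CV error wins; ties go to
#' the smallest level (more parsimonious downstream models).  Fits are
#' memoised by term mask, so the cost is per fold, not per fold x level.
#'
#' @param records list of [process_record()] objects (>= 3).
#' @param alpha_grid candidate significance levels (13 by default).
#' @param yields named numeric `c(Y_XrG=, Y_PG=)`.
#' @param smoothing forwarded to [estimate_rates()].
#' @param seed integer seed.
#' @param folds optional integer vector of run indices to hold out (default
#'   all runs).
#' @param control a [de_control()] list.
#' @return object of class `alpha_selection`: `alpha` (chosen), `cv` (per
#'   level mean CV error), `errors` (level x fold matrix), `masks` (final
#'   masks per rate from a full-data elimination at the chosen level).
#' @export
select_alpha <- function(records, alpha_grid = alpha_grid_default(),
                         yields = c(Y_XrG = 0.55, Y_PG = 0.9),
                         smoothing = NULL, seed = 1, folds = NULL,
                         control = de_control()) {
  if (length(records) < 3) stopf("need at least 3 runs for cross-validation")
  folds <- folds %||% seq_along(records)
  alpha_grid <- sort(alpha_grid)
  errs <- matrix(NA_real_, length(alpha_grid), length(folds),
                 dimnames = list(format(alpha_grid), NULL))
  for (j in seq_along(folds)) {
    hold <- folds[j]
    train <- records[-hold]
    obs <- estimate_rates(train, yields = yields, smoothing = smoothing)
    cache <- new.env(parent = emptyenv())
    for (a in seq_along(alpha_grid)) {
      fits <- lapply(c("uptake", "maintenance", "production"), function(rt)
        eliminate_terms(obs, rt, alpha = alpha_grid[a], seed = seed,
                        control = control, cache = cache))
      names(fits) <- c("uptake", "maintenance", "production")
      params <- kinetic_params(uptake = fits$uptake$fit$block,
                               production = fits$production$fit$block,
                               maintenance = fits$maintenance$fit$block,
                               yields = yields)
      ypx <- .predict_final_ypx(params, records[[hold]])
      meas <- records[[hold]]$offline
      ypx_meas <- meas$P[nrow(meas)] / meas$X[nrow(meas)]
      errs[a, j] <- (ypx - ypx_meas)^2
    }
  }
  cv <- rowMeans(errs)
  best <- which(cv <= min(cv) + 1e-15)[1]   # ties -> smallest alpha
  structure(list(alpha = alpha_grid[best], cv = cv, errors = errs,
                 alpha_grid = alpha_grid, seed = seed),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat("cross-validated significance level selection\n")
  print(data.frame(alpha = x$alpha_grid, cv_error = as.numeric(x$cv)))
  cat(sprintf("chosen alpha = %g\n", x$alpha))
  invisible(x)
}

# simulate a held-out record under its own (online) controls and return the
# predicted final product-to-biomass yield
.predict_final_ypx <- function(params, record) {
  fs <- feed_spec("piecewise",
                  knots = data.frame(t = record$online$t, f = record$online$f))
  Tprof <- data.frame(t = record$online$t, T = record$online$T)
  tend <- max(record$offline$t)
  ctrl <- control_profile(fs, temperature = Tprof, Gf = record$Gf,
                          tend = tend, base = record$base)
  x0 <- c(X = record$X0, P = 0, G = 0, V = record$V0)
  traj <- simulate_process(params, ctrl, events = record$events, x0 = x0,
                           times = c(0, tend))
  traj$P[nrow(traj)] / traj$X[nrow(traj)]
}
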