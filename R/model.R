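#' Fit the fed-batch kinetic process model to a multi-run dataset
#'
#' The main entry point of the fitting stage.  Chains the pipeline: spline
#' smoothing and rate estimation ([estimate_rates()]), optional
#' cross-validated choice of the elimination significance level
#' ([select_alpha()]), per-rate backward elimination of insignificant terms
#' ([eliminate_terms()]) or exhaustive AICc search
#' ([exhaustive_aicc_select()]), and assembly of the final
#' [kinetic_params()] set.
#'
#' @param records list of [process_record()] objects.
#' @param yields named numeric `c(Y_XrG=, Y_PG=)`, externally supplied
#'   substrate yields (g/g).
#' @param alpha elimination significance level; `NULL` selects it by
#'   leave-one-run-out cross-validation over `alpha_grid`.
#' @param alpha_grid candidate levels for the cross-validation (13 by
#'   default).
#' @param selection `"elimination"` (heuristic backward elimination) or
#'   `"aicc"` (exhaustive search by corrected AIC).
#' @param smoothing forwarded to [smooth_record()].
#' @param seed integer seed for all stochastic fitting.
#' @param control a [de_control()] list.
#' @param cv_folds optional integer vector restricting the CV folds.
#' @return an object of class `kinfed_fit` with components `params` (the
#'   fitted [kinetic_params()]), `fits` (per-rate `rate_fit`), `traces`
#'   (elimination traces), `observations`, `alpha`, `selection`, `records`.
#' @examples
#' \donttest{
#' truth <- make_truth_params("reduced_default")
#' recs <- generate_dataset(truth, noise = noise_spec(0, 0, 0), seed = 1)
#' fit <- fit_process_model(recs, alpha = 0.2, smoothing = 0, seed = 1)
#' print(fit)
#' }
#' @export
fit_process_model <- function(records, yields = c(Y_XrG = 0.55, Y_PG = 0.9),
                              alpha = 0.2, alpha_grid = alpha_grid_default(),
                              selection = c("elimination", "aicc"),
                              smoothing = NULL, seed = 1,
                              control = de_control(), cv_folds = NULL) {
  selection <- match.arg(selection)
  obs <- estimate_rates(records, yields = yields, smoothing = smoothing)
  sel_report <- NULL
  if (is.null(alpha) && selection == "elimination") {
    sel_report <- select_alpha(records, alpha_grid = alpha_grid,
                               yields = yields, smoothing = smoothing,
                               seed = seed, folds = cv_folds,
                               control = control)
    alpha <- sel_report$alpha
  }
  rates <- c("uptake", "maintenance", "production")
  if (selection == "elimination") {
    els <- lapply(rates, function(rt)
      eliminate_terms(obs, rt, alpha = alpha, seed = seed, control = control))
  } else {
    els <- lapply(rates, function(rt) {
      ex <- exhaustive_aicc_select(obs, rt, seed = seed, control = control)
      list(mask = ex$mask, fit = ex$fit, trace = ex$table, alpha = NA)
    })
  }
  names(els) <- rates
  params <- kinetic_params(uptake = els$uptake$fit$block,
                           production = els$production$fit$block,
                           maintenance = els$maintenance$fit$block,
                           yields = yields)
  structure(list(params = params,
                 fits = lapply(els, `[[`, "fit"),
                 traces = lapply(els, `[[`, "trace"),
                 masks = lapply(els, `[[`, "mask"),
                 observations = obs, alpha = alpha, selection = selection,
                 selection_report = sel_report, records = records,
                 yields = yields, seed = seed, call = match.call()),
            class = "kinfed_fit")
}

#' @export
print.kinfed_fit <- function(x, ...) {
  cat("Fed-batch kinetic process model fit\n")
  cat(sprintf("  %d runs, %d rate observations; selection: %s (alpha = %s)\n",
              length(x$records), nrow(x$observations), x$selection,
              format(x$alpha)))
  print(x$params)
  invisible(x)
}

#' @export
summary.kinfed_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$fits), function(rt) {
    f <- object$fits[[rt]]
    g <- goodness(f$fitted, f$fitted + f$residuals, f$n_params)
    data.frame(rate = rt, n_params = f$n_params, n_points = f$n_points,
               rss = f$rss, r2 = g$r2, r2_adj = g$r2_adj)
  }))
  structure(list(table = tab, alpha = object$alpha,
                 params = object$params), class = "summary.kinfed_fit")
}

#' @export
print.summary.kinfed_fit <- function(x, ...) {
  cat("Goodness of fit per rate equation\n")
  print(transform(x$table, rss = signif(rss, 4), r2 = round(r2, 3),
                  r2_adj = round(r2_adj, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.kinfed_fit <- function(object, ...) {
  out <- c()
  for (rt in c("uptake", "production", "maintenance")) {
    b <- object$params[[rt]]
    pre <- switch(rt, uptake = "circ", production = "pi", maintenance = "alpha")
    if (b$mask[["temp"]]) {
      tl <- b$temp
      out <- c(out, stats::setNames(
        c(tl$E0, tl$dG_cat, tl$T_eq, tl$dH_eq),
        paste0(pre, ".", c("E0", "dG_cat", "T_eq", "dH_eq"))))
    } else out <- c(out, stats::setNames(b$temp, paste0(pre, ".c")))
    if (b$mask[["Km"]])
      out <- c(out, stats::setNames(b$Km, paste0(pre, ".Km")))
    for (i in c("G", "n", "PX", "X")) if (b$mask[[i]])
      out <- c(out, stats::setNames(b$K[[i]], paste0(pre, ".K_", i)))
  }
  c(out, object$params$yields)
}

#' Predict specific rates at new covariates
#'
#' @param object a `kinfed_fit`.
#' @param newdata data.frame with columns `G`, `n`, `PX`, `X`, `Temp` (and
#'   `g_circ`, `g_alpha` used as covariates where available; otherwise the
#'   model's own cascade is used).
#' @param ... unused.
#' @return data.frame of predicted `g_circ`, `g_alpha`, `g_pi`, `g_mu`,
#'   `mu`, `pi`.
#' @export
predict.kinfed_fit <- function(object, newdata = NULL, ...) {
  nd <- newdata %||% object$observations
  p <- object$params
  gc <- uptake_rate(nd$G, nd$n, nd$PX, nd$X, nd$Temp, p)
  gc_cov <- if ("g_circ" %in% names(nd)) nd$g_circ else gc
  ga <- maintenance_rate(gc_cov, nd$G, nd$n, nd$PX, nd$X, nd$Temp, p)
  ga_cov <- if ("g_alpha" %in% names(nd)) nd$g_alpha else ga
  gp <- production_uptake_rate(gc_cov, ga_cov, nd$G, nd$n, nd$PX, nd$X,
                               nd$Temp, p)
  gm <- gc - gp - ga
  XrX <- 1 - nd$PX
  pi_ <- gp * p$yields[["Y_PG"]] * XrX
  mu <- pi_ + gm * p$yields[["Y_XrG"]] * XrX
  data.frame(g_circ = gc, g_alpha = ga, g_pi = gp, g_mu = gm, mu = mu,
             pi = pi_)
}

#' @export
residuals.kinfed_fit <- function(object, rate = c("uptake", "maintenance",
                                                  "production"), ...) {
  rate <- match.arg(rate)
  object$fits[[rate]]$residuals
}

#' Simulate a fed-batch run from a fitted model
#'
#' @param object a `kinfed_fit`.
#' @param nsim unused (one deterministic trajectory).
#' @param seed unused.
#' @param controls a [control_profile()].
#' @param events sampling events data.frame, or `NULL`.
#' @param x0 named initial state `c(X=, P=, G=, V=)`.
#' @param ... forwarded to [simulate_process()].
#' @return a `kinfed_traj` data.frame.
#' @export
simulate.kinfed_fit <- function(object, nsim = 1, seed = NULL, controls,
                                events = NULL, x0, ...) {
  simulate_process(object$params, controls, events = events, x0 = x0, ...)
}

#' @export
plot.kinfed_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (rt in c("uptake", "maintenance", "production")) {
    f <- x$fits[[rt]]
    meas <- f$fitted + f$residuals
    graphics::plot(meas, f$fitted, xlab = "observed rate (g/g/h)",
                   ylab = "fitted rate (g/g/h)", main = rt, ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
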