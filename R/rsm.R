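#' Fit a second-degree response-surface model
#'
#' Ordinary least squares of an endpoint target (default the final
#' product-to-biomass yield) on the six-term quadratic basis in the
#' exponential-feed coefficient and the temperature:
#' \deqn{y = c + c_f \mu_f + c_T T + c_{fT} \mu_f T + c_{f2} \mu_f^2 +
#'   c_{T2} T^2}
#' Variables are fitted on their natural scale.
#'
#' @param endpoints data.frame with columns `mu_f` (1/h), `T` (degrees C)
#'   and `y` (target value); at least 6 distinct design points spanning both
#'   factors (a central composite design suffices).
#' @return object of class `kinfed_rsm`: `coefficients` (named `c, c_f, c_T,
#'   c_fT, c_f2, c_T2`), the underlying `lm` fit, and `r2`/`r2_adj`.
#' @export
fit_rsm <- function(endpoints) {
  stopifnot(is.data.frame(endpoints),
            all(c("mu_f", "T", "y") %in% names(endpoints)))
  X <- with(endpoints, cbind(1, mu_f, T, mu_f * T, mu_f^2, T^2))
  colnames(X) <- c("c", "c_f", "c_T", "c_fT", "c_f2", "c_T2")
  qrX <- qr(X)
  if (qrX$rank < 6L) {
    bad <- colnames(X)[setdiff(seq_len(6L), qrX$pivot[seq_len(qrX$rank)])]
    stopf("rank-deficient design: cannot identify term(s) %s",
          paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ mu_f + T + I(mu_f * T) + I(mu_f^2) + I(T^2),
                   data = endpoints)
  cf <- stats::setNames(unname(stats::coef(fit)), colnames(X))
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  structure(list(coefficients = cf, lm = fit,
                 r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
                 p_values = stats::setNames(sm$coefficients[, 4], colnames(X))),
            class = "kinfed_rsm")
}

#' @export
print.kinfed_rsm <- function(x, ...) {
  cat("response-surface model (quadratic in mu_f and T)\n")
  print(round(x$coefficients, 6))
  cat(sprintf("R2 = %.3f, adjusted R2 = %.3f\n", x$r2, x$r2_adj))
  invisible(x)
}

#' @export
coef.kinfed_rsm <- function(object, ...) object$coefficients

#' @export
predict.kinfed_rsm <- function(object, newdata, ...) {
  cf <- object$coefficients
  with(newdata, cf[["c"]] + cf[["c_f"]] * mu_f + cf[["c_T"]] * T +
         cf[["c_fT"]] * mu_f * T + cf[["c_f2"]] * mu_f^2 + cf[["c_T2"]] * T^2)
}

#' Constrained optimum of a fitted response surface
#'
#' Locates the stationary point of the quadratic from its gradient and
#' classifies it via the eigenvalues of the quadratic-form matrix
#' (maximum / minimum / saddle).  If the stationary point is a maximum
#' inside the bounds it is returned; otherwise the quadratic is maximized on
#' the boundary of the rectangle (each edge is a 1-D quadratic, solved in
#' closed form).
#'
#' @param model a `kinfed_rsm` from [fit_rsm()].
#' @param bounds list with `mu_f = c(lo, hi)` and `T = c(lo, hi)` (the
#'   design region).
#' @return list with `mu_f`, `T`, `y`, `stationary` (type string), and
#'   `interior` (logical: optimum at the stationary point).
#' @export
rsm_optimum <- function(model, bounds = list(mu_f = c(0.06, 0.18),
                                             T = c(25, 37))) {
  cf <- model$coefficients
  A <- matrix(c(2 * cf[["c_f2"]], cf[["c_fT"]],
                cf[["c_fT"]], 2 * cf[["c_T2"]]), 2, 2)
  b <- c(cf[["c_f"]], cf[["c_T"]])
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  type <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum"
          else "saddle"
  stat <- tryCatch(solve(A, -b), error = function(e) NULL)
  eval_y <- function(mu_f, T)
    predict(model, data.frame(mu_f = mu_f, T = T))
  inside <- function(p)
    p[1] >= bounds$mu_f[1] && p[1] <= bounds$mu_f[2] &&
    p[2] >= bounds$T[1] && p[2] <= bounds$T[2]
  if (type == "maximum" && !is.null(stat) && inside(stat)) {
    return(list(mu_f = stat[1], T = stat[2], y = eval_y(stat[1], stat[2]),
                stationary = type, interior = TRUE))
  }
  # boundary maximization: each edge is a univariate quadratic
  best <- NULL
  consider <- function(mu_f, T) {
    y <- eval_y(mu_f, T)
    if (is.null(best) || y > best$y)
      best <<- list(mu_f = mu_f, T = T, y = y, stationary = type,
                    interior = FALSE)
  }
  edge_opt <- function(a2, a1, lo, hi) {
    # argmax of a2 x^2 + a1 x + const on [lo, hi]
    cand <- c(lo, hi)
    if (a2 < 0) cand <- c(cand, clamp(-a1 / (2 * a2), lo, hi))
    cand
  }
  for (mf in bounds$mu_f) {   # vertical edges: vary T
    a2 <- cf[["c_T2"]]; a1 <- cf[["c_T"]] + cf[["c_fT"]] * mf
    for (Tv in edge_opt(a2, a1, bounds$T[1], bounds$T[2])) consider(mf, Tv)
  }
  for (Tv in bounds$T) {      # horizontal edges: vary mu_f
    a2 <- cf[["c_f2"]]; a1 <- cf[["c_f"]] + cf[["c_fT"]] * Tv
    for (mf in edge_opt(a2, a1, bounds$mu_f[1], bounds$mu_f[2])) consider(mf, Tv)
  }
  best
}

#' Extract endpoint targets from a dataset for the RSM baseline
#'
#' Takes the last offline sample of each run as the endpoint; the default
#' target is the final product-to-biomass yield `P/X`.
#'
#' @param records list of [process_record()] objects.
#' @param target `"YPX"`, `"P"` or `"X"`.
#' @return data.frame with columns `run_id`, `mu_f`, `T`, `y`.
#' @export
rsm_endpoints <- function(records, target = c("YPX", "P", "X")) {
  target <- match.arg(target)
  do.call(rbind, lapply(records, function(r) {
    last <- r$offline[nrow(r$offline), ]
    y <- switch(target, YPX = last$P / last$X, P = last$P, X = last$X)
    data.frame(run_id = r$run_id, mu_f = r$design_point[["mu_f"]],
               T = r$design_point[["T"]], y = y)
  }))
}
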