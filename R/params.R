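#' Temperature law parameters
#'
#' Thermodynamic rate law for a maximum (or minimum) specific rate,
#' \deqn{\gamma(T) = E_0 \frac{k_B T}{h} \exp(-\Delta G_{cat}/(R T)) /
#'   \left[1 + \exp\{\Delta H_{eq}/R \, (1/T_{eq} - 1/T)\}\right]}
#' with temperature in kelvin internally.  `E0` is a hypothetical enzyme
#' concentration; it absorbs the \eqn{k_B T/h} magnitude, so its absolute
#' scale is not physically interpretable.  `T_eq` is the temperature at which
#' half of the enzyme pool is inactivated and `dH_eq` sets how abruptly the
#' rate collapses above it.
#'
#' @param E0 pre-exponential scale (> 0).
#' @param dG_cat activation energy, J/mol.
#' @param T_eq half-inactivation temperature, K (> 0).
#' @param dH_eq inactivation sharpness, J/mol (> 0).
#' @return an object of class `temp_law`.
#' @seealso [temperature_factor()]
#' @export
temp_law <- function(E0, dG_cat, T_eq, dH_eq) {
  vals <- c(E0 = E0, dG_cat = dG_cat, T_eq = T_eq, dH_eq = dH_eq)
  if (any(!is.finite(vals))) stopf("temp_law: non-finite parameter")
  if (E0 <= 0 || T_eq <= 0 || dH_eq <= 0)
    stopf("temp_law: E0, T_eq and dH_eq must be positive")
  structure(as.list(vals), class = "temp_law")
}

#' @export
print.temp_law <- function(x, ...) {
  cat(sprintf("temperature law: E0 = %.4g, dG_cat = %.4g J/mol, T_eq = %.2f K, dH_eq = %.4g J/mol\n",
              x$E0, x$dG_cat, x$T_eq, x$dH_eq))
  invisible(x)
}

# names of the multiplicative terms in one rate block
.term_names <- c("temp", "Km", "G", "n", "PX", "X")

#' One rate block of the kinetic model
#'
#' A rate block holds the multiplicative terms of one specific rate: `temp`
#' (a [temp_law()] or a plain positive constant), `Km` (the Michaelis
#' saturation constant for uptake/production, or the uptake-activation
#' constant for maintenance), and the named inhibition/activation constants
#' `K["G"]`, `K["n"]`, `K["PX"]`, `K["X"]`.  Terms set to `Inf` (or masked
#' out) contribute a factor of 1.
#'
#' @param temp a [temp_law()] object or a positive constant rate (g/g/h).
#' @param Km saturation (or activation) constant; units follow its covariate.
#' @param K named numeric vector of inhibition/activation constants.
#' @param mask optional named logical over terms
#'   `temp, Km, G, n, PX, X`; defaults to "finite constants are active".
#' @param nonremovable named logical flags marking terms the elimination
#'   algorithm must keep (e.g. `c(Km = TRUE)` for uptake).
#' @return an object of class `rate_block`.
#' @export
rate_block <- function(temp, Km, K = c(G = Inf, n = Inf, PX = Inf, X = Inf),
                       mask = NULL, nonremovable = c(Km = FALSE)) {
  K <- K[c("G", "n", "PX", "X")]
  names(K) <- c("G", "n", "PX", "X")
  if (is.null(mask))
    mask <- c(temp = inherits(temp, "temp_law"), Km = is.finite(Km),
              G = is.finite(K[["G"]]), n = is.finite(K[["n"]]),
              PX = is.finite(K[["PX"]]), X = is.finite(K[["X"]]))
  mask <- mask[.term_names]
  names(mask) <- .term_names
  nr <- stats::setNames(rep(FALSE, 6), .term_names)
  nr[names(nonremovable)] <- nonremovable
  if (mask[["Km"]] && !is.finite(Km)) stopf("active Km must be finite")
  active_K <- c("G", "n", "PX", "X")[mask[c("G", "n", "PX", "X")]]
  if (any(!is.finite(K[active_K]) | K[active_K] <= 0))
    stopf("active K constants must be positive and finite")
  structure(list(temp = temp, Km = Km, K = K, mask = mask, nonremovable = nr),
            class = "rate_block")
}

# number of fitted parameters in one block under its mask
n_params_block <- function(b) {
  (if (b$mask[["temp"]]) 4L else 1L) + sum(b$mask[c("Km", "G", "n", "PX", "X")])
}

#' Kinetic parameter set of the general fed-batch process model
#'
#' Bundles the three rate blocks (substrate uptake, maintenance, product
#' formation), each consisting of a temperature law (or a plain constant), a
#' saturation constant and up to four inhibition/activation constants, plus
#' the two substrate yields.  The full model carries 29 parameters: 27
#' fittable kinetic constants and the two yields, which are supplied
#' externally (e.g. from a genome-scale metabolic model).  Each term carries
#' an active/inactive flag; an inactive inhibition or activation term behaves
#' as its constant going to infinity (factor 1), and an inactive temperature
#' law is a plain fitted constant.
#'
#' @param uptake,production,maintenance rate blocks as produced by the
#'   internal constructor; lists with elements `temp` (a [temp_law()] or a
#'   positive constant), `Km`, `K` (named vector `G`, `n`, `PX`, `X`), `mask`.
#' @param yields named numeric, `Y_XrG` (residual-biomass-per-substrate,
#'   g/g) and `Y_PG` (product-per-substrate, g/g).
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(uptake, production, maintenance,
                           yields = c(Y_XrG = 0.55, Y_PG = 0.9)) {
  stopifnot(inherits(uptake, "rate_block"), inherits(production, "rate_block"),
            inherits(maintenance, "rate_block"))
  yields <- yields[c("Y_XrG", "Y_PG")]
  if (any(!is.finite(yields) | yields <= 0)) stopf("yields must be positive")
  structure(list(uptake = uptake, production = production,
                 maintenance = maintenance, yields = yields),
            class = "kinetic_params")
}

#' Count model parameters
#'
#' @param params a [kinetic_params()] object.
#' @param what `"total"` counts every parameter including the two externally
#'   supplied yields (29 for the full model); `"fittable"` counts only the
#'   kinetic constants estimated from data (27 for the full model);
#'   `"active"` counts fittable parameters active under the current mask.
#' @return integer count.
#' @export
count_params <- function(params, what = c("active", "fittable", "total")) {
  what <- match.arg(what)
  blocks <- params[c("uptake", "production", "maintenance")]
  act <- sum(vapply(blocks, n_params_block, integer(1)))
  if (what == "active") return(act)
  full <- sum(vapply(blocks, function(b) {
    b$mask[] <- TRUE
    n_params_block(b)
  }, integer(1)))
  if (what == "fittable") full else full + 2L
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Fed-batch kinetic parameter set\n")
  for (nm in c("uptake", "production", "maintenance")) {
    b <- x[[nm]]
    act <- .term_names[b$mask]
    cat(sprintf("  %-11s %d active parameter(s): %s\n", nm, n_params_block(b),
                paste(act, collapse = ", ")))
  }
  cat(sprintf("  yields: Y_XrG = %.3g, Y_PG = %.3g g/g\n",
              x$yields[["Y_XrG"]], x$yields[["Y_PG"]]))
  cat(sprintf("  %d of %d fittable parameters active\n",
              count_params(x, "active"), count_params(x, "fittable")))
  invisible(x)
}

# ---- serialization (lossless round-trip via plain lists / JSON) ----

block_to_list <- function(b) {
  K <- b$K
  K[!is.finite(K)] <- NA_real_   # JSON has no Inf; NA marks "inactive"
  list(temp = if (inherits(b$temp, "temp_law")) unclass(b$temp) else b$temp,
       temp_is_law = inherits(b$temp, "temp_law"),
       Km = if (is.finite(b$Km)) b$Km else NA_real_,
       K = as.list(K), mask = as.list(b$mask),
       nonremovable = as.list(b$nonremovable))
}

block_from_list <- function(l) {
  temp <- if (isTRUE(l$temp_is_law))
    temp_law(l$temp$E0, l$temp$dG_cat, l$temp$T_eq, l$temp$dH_eq)
  else as.numeric(l$temp)
  K <- vapply(l$K, function(x) if (is.null(x) || is.na(x)) Inf
              else as.numeric(x), numeric(1))
  Km <- if (is.null(l$Km) || is.na(l$Km)) Inf else as.numeric(l$Km)
  rate_block(temp, Km, K, mask = unlist(l$mask),
             nonremovable = unlist(l$nonremovable))
}

#' Write / read a kinetic parameter set
#'
#' Flat JSON serialization including the activity mask; round-trips
#' losslessly (full double precision).
#'
#' @param params a [kinetic_params()] object.
#' @param path file path.
#' @return `read_params` returns the restored [kinetic_params()] object;
#'   `write_params` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  l <- list(uptake = block_to_list(params$uptake),
            production = block_to_list(params$production),
            maintenance = block_to_list(params$maintenance),
            yields = as.list(params$yields))
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinetic_params(uptake = block_from_list(as.list(l$uptake)),
                 production = block_from_list(as.list(l$production)),
                 maintenance = block_from_list(as.list(l$maintenance)),
                 yields = unlist(l$yields))
}
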