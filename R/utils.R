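# physical constants (SI)
.kB   <- 1.380649e-23   # Boltzmann, J/K
.hP   <- 6.62607015e-34 # Planck, J s
.Rgas <- 8.314462618    # gas constant, J/mol/K
.Tref <- 305            # K, internal reference for the temperature-law reparameterization
.T0K  <- 273.15

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the R random seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so seeded internals do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# cumulative trapezoidal integral of y over x (same length as x, starts at 0)
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
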