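#' Serialize a fit result to JSON
#'
#' Writes the fitted parameter set (with mask), per-rate statistics, the
#' elimination traces and the seed, so a fit is fully reconstructable and
#' diffable.
#'
#' @param fit a `kinfed_fit` from [fit_process_model()].
#' @param path output file.
#' @export
write_fit <- function(fit, path) {
  l <- list(
    params = list(uptake = block_to_list(fit$params$uptake),
                  production = block_to_list(fit$params$production),
                  maintenance = block_to_list(fit$params$maintenance),
                  yields = as.list(fit$params$yields)),
    alpha = fit$alpha, selection = fit$selection, seed = fit$seed,
    rates = lapply(fit$fits, function(f)
      list(rate = f$rate, rss = f$rss, tss = f$tss, n_points = f$n_points,
           n_params = f$n_params, par = as.list(f$par))),
    traces = lapply(fit$traces, function(tr) as.data.frame(tr)))
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Read the kinetic parameter set out of a serialized fit or params file
#'
#' Accepts either a file written by [write_params()] or one written by
#' [write_fit()] (where the parameter set sits under a `params` key).
#'
#' @param path JSON file.
#' @return a [kinetic_params()] object.
#' @export
read_fit_params <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(l$params)) l <- l$params
  kinetic_params(uptake = block_from_list(as.list(l$uptake)),
                 production = block_from_list(as.list(l$production)),
                 maintenance = block_from_list(as.list(l$maintenance)),
                 yields = unlist(l$yields))
}

#' Serialize an optimal-control result to JSON (+ trajectory CSV)
#'
#' @param result a `kinfed_ocp` from [solve_ocp()].
#' @param path output JSON file; the collocated trajectory goes to the same
#'   name with extension `.csv`.
#' @export
write_ocp <- function(result, path) {
  l <- list(profile = result$profile, objective = result$objective,
            yield_term = result$yield_term,
            penalty_term = result$penalty_term,
            v_violation = result$v_violation,
            quasi_steady = result$quasi_steady,
            convergence = result$convergence)
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  utils::write.csv(result$trajectory, sub("\\.json$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}
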