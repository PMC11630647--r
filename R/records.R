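#' One fermentation run record
#'
#' Holds the offline measurements (biomass, product, substrate at sampling
#' times), the online controls (feed rate and temperature on a fine grid),
#' and the run metadata needed to reconstruct the volume.
#'
#' @param run_id character identifier.
#' @param offline data.frame with columns `t` (h), `X`, `P`, `G` (g/L) and
#'   optionally logical `G_censored` (below the limit of quantification).
#' @param online data.frame with columns `t` (h), `f` (substrate feed, g/h),
#'   `T` (degrees C).
#' @param V0 initial volume, L; `X0` initial biomass, g/L; `Gf` feed
#'   substrate concentration, g/L.
#' @param X0,Gf see above.
#' @param events data.frame with columns `time` (h), `volume` (L removed).
#' @param design_point named numeric `c(mu_f=, T=)` of the design condition.
#' @param loq limit of quantification for G, g/L.
#' @param base base-feed model used during the run ([base_feed_params()]).
#' @return an object of class `process_record`.
#' @export
process_record <- function(run_id, offline, online, V0, X0, Gf,
                           events = NULL, design_point = NULL, loq = 0.1,
                           base = base_feed_params()) {
  stopifnot(is.data.frame(offline), all(c("t", "X", "P", "G") %in% names(offline)),
            is.data.frame(online), all(c("t", "f", "T") %in% names(online)))
  if (is.unsorted(offline$t, strictly = TRUE))
    stopf("sample times must be strictly increasing")
  if (nrow(offline) < 4L) stopf("need at least 4 sample points per run")
  if (X0 <= 0 || V0 <= 0 || Gf <= 0) stopf("X0, V0, Gf must be positive")
  if (is.null(offline$G_censored)) offline$G_censored <- offline$G < loq
  if (is.null(events)) events <- data.frame(time = numeric(), volume = numeric())
  structure(list(run_id = as.character(run_id), offline = offline,
                 online = online, V0 = V0, X0 = X0, Gf = Gf, events = events,
                 design_point = design_point, loq = loq, base = base),
            class = "process_record")
}

#' @export
print.process_record <- function(x, ...) {
  cat(sprintf("process record '%s': %d samples over %.1f h; X0 = %.1f g/L, V0 = %.2f L, Gf = %.0f g/L\n",
              x$run_id, nrow(x$offline), max(x$offline$t), x$X0, x$V0, x$Gf))
  if (!is.null(x$design_point))
    cat(sprintf("  design point: mu_f = %.3f 1/h, T = %.1f C\n",
                x$design_point[["mu_f"]], x$design_point[["T"]]))
  invisible(x)
}

#' Write / read a multi-run dataset directory
#'
#' Layout: one directory per run containing `offline.csv`, `online.csv` and
#' `manifest.json`, plus a top-level `manifest.json` listing runs and the
#' generation seed.  All files are plain text; reading is the exact inverse
#' of writing.
#'
#' @param records list of [process_record()] objects.
#' @param dir dataset directory (created if missing).
#' @param meta optional named list stored in the dataset manifest (e.g.
#'   `seed`).
#' @return `read_dataset` returns a list of records; `write_dataset` returns
#'   `dir` invisibly.
#' @export
write_dataset <- function(records, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(records, `[[`, character(1), "run_id")
  jsonlite::write_json(c(list(runs = ids), meta),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (rec in records) {
    rd <- file.path(dir, rec$run_id)
    dir.create(rd, showWarnings = FALSE)
    utils::write.csv(rec$offline, file.path(rd, "offline.csv"), row.names = FALSE)
    utils::write.csv(rec$online, file.path(rd, "online.csv"), row.names = FALSE)
    man <- list(run_id = rec$run_id, V0 = rec$V0, X0 = rec$X0, Gf = rec$Gf,
                loq = rec$loq, base = rec$base,
                events = rec$events, design_point = as.list(rec$design_point))
    jsonlite::write_json(man, file.path(rd, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(man$runs, function(id) {
    rd <- file.path(dir, id)
    m <- jsonlite::read_json(file.path(rd, "manifest.json"), simplifyVector = TRUE)
    ev <- as.data.frame(m$events)
    if (!nrow(ev)) ev <- data.frame(time = numeric(), volume = numeric())
    process_record(run_id = m$run_id,
                   offline = utils::read.csv(file.path(rd, "offline.csv")),
                   online = utils::read.csv(file.path(rd, "online.csv")),
                   V0 = m$V0, X0 = m$X0, Gf = m$Gf, events = ev,
                   design_point = unlist(m$design_point), loq = m$loq,
                   base = m$base)
  })
}
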