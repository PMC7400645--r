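sidecarPath <- function(path) paste0(path, ".meta.json")

writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

#' Read and write package containers as delimited text + JSON
#'
#' Tabular data travel as CSV with a JSON metadata sidecar
#' (\code{<file>.meta.json}: frame intervals, trajectory boundaries,
#' units); models (transition matrices) travel as single JSON documents
#' with matrices as nested arrays.  Every writer's output is loadable by
#' the matching reader.
#'
#' @param x object to write.
#' @param path file path (CSV for tables, JSON for models).
#' @name io
NULL

#' @rdname io
#' @export
writeFeatureMatrix <- function(x, path) {
  stopifnot(is(x, "FeatureMatrix"))
  write.csv(as.data.frame(x@values), path, row.names = FALSE)
  writeSidecar(path, list(type = "FeatureMatrix",
                          frame_interval_ns = x@frameInterval,
                          traj_lengths = x@trajLengths))
  invisible(path)
}

#' @rdname io
#' @export
readFeatureMatrix <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  vals <- as.matrix(read.csv(path, check.names = FALSE))
  new("FeatureMatrix", values = vals,
      frameInterval = meta$frame_interval_ns,
      trajLengths = as.integer(meta$traj_lengths))
}

#' @rdname io
#' @export
writeTransitionMatrix <- function(x, path) {
  stopifnot(is(x, "TransitionMatrix"))
  jsonlite::write_json(
    list(type = "TransitionMatrix", lag = x@lag, lag_unit = x@lagUnit,
         mode = x@mode, matrix = x@matrix,
         counts = if (!is.null(x@counts)) x@counts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
readTransitionMatrix <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TransitionMatrix", matrix = as.matrix(d$matrix), lag = d$lag,
      lagUnit = d$lag_unit, mode = d$mode,
      counts = if (!is.null(d$counts)) as.matrix(d$counts) else NULL)
}

#' @rdname io
#' @export
writeFretTraces <- function(x, path) {
  stopifnot(is(x, "FretTraceSet"))
  rows <- lapply(seq_along(x@traces), function(i) {
    tr <- x@traces[[i]]
    cbind(trace = i, frame = seq_len(nrow(tr)), tr)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  writeSidecar(path, list(type = "FretTraceSet",
                          frame_interval_s = x@frameInterval,
                          state_paths = x@statePaths))
  invisible(path)
}

#' @rdname io
#' @export
readFretTraces <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  d <- read.csv(path)
  traces <- lapply(split(d, d$trace), function(g)
    g[order(g$frame), setdiff(names(g), c("trace", "frame")),
      drop = FALSE])
  names(traces) <- NULL
  traces <- lapply(traces, function(g) { rownames(g) <- NULL; g })
  sp <- meta$state_paths
  if (!is.null(sp)) {
    ## equal-length paths come back as a row-per-trace matrix
    sp <- if (is.matrix(sp))
      lapply(seq_len(nrow(sp)), function(i) as.integer(sp[i, ]))
    else lapply(sp, as.integer)
  }
  new("FretTraceSet", traces = traces, frameInterval = meta$frame_interval_s,
      statePaths = sp)
}

#' @rdname io
#' @export
writeEnergyTable <- function(x, path) {
  stopifnot(is(x, "EnergyTable"))
  write.csv(x@records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readEnergyTable <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  new("EnergyTable", records = d)
}
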