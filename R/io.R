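# CSV dialect: comma separator, mandatory header, '.' decimal point.

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  d <- read.csv(path, check.names = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(sprintf("%s lacks required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  d
}

#' Read / write continuous-photobleaching traces
#'
#' CSV with columns `t_s`, `intensity`.
#'
#' @param path File path.
#' @param trace Data frame to write.
#' @return `read_cp_trace` returns the data frame; `write_cp_trace` the
#'   path, invisibly.
#' @export
read_cp_trace <- function(path) read_checked_csv(path, c("t_s", "intensity"))

#' @rdname read_cp_trace
#' @export
write_cp_trace <- function(trace, path) {
  write.csv(trace[c("t_s", "intensity")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write FCS correlation curves
#'
#' CSV with columns `lag_s`, `G` and optional `sd`.
#'
#' @param path File path.
#' @param curve `fcs_curve` data frame to write.
#' @return The curve (read) or the path (write, invisibly).
#' @export
read_fcs_curve <- function(path) {
  d <- read_checked_csv(path, c("lag_s", "G"))
  structure(d, class = c("fcs_curve", "data.frame"))
}

#' @rdname read_fcs_curve
#' @export
write_fcs_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read / write 3D locus trajectories
#'
#' CSV with columns `telomere_id`, `nucleus_id`, `frame`, `t_s`, `x_um`,
#' `y_um`, `z_um`.
#'
#' @param path File path.
#' @param trajs Trajectory data frame to write.
#' @return The data frame (read) or the path (write, invisibly).
#' @export
read_trajectories <- function(path)
  read_checked_csv(path, c("telomere_id", "frame", "t_s",
                           "x_um", "y_um", "z_um"))

#' @rdname read_trajectories
#' @export
write_trajectories <- function(trajs, path) {
  write.csv(trajs, path, row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth JSON sidecar
#'
#' @param truth List of truth fields from a generator.
#' @param path Output path (conventionally `<dataset>.truth.json`).
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  truth <- rapply(truth, function(x) if (is.matrix(x)) unclass(x) else x,
                  how = "replace")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  jsonlite::fromJSON(path)
}
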