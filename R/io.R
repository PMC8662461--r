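#' Write a trajectory to CSV
#'
#' Columns `time_s,x_m,y_m,phase` plus `valid` for radar-derived tracks.
#'
#' @param traj A `sheep_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(traj, path) {
  d <- data.frame(time_s = traj$time, x_m = traj$x, y_m = traj$y,
                  phase = traj$phase)
  if (!is.null(traj$valid)) d$valid <- traj$valid
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' Expects the header `time_s,x_m,y_m,phase` (the export format of
#' [write_track_csv()] and the input path for externally recorded tracks).
#'
#' @param path CSV file path.
#' @param source Source tag for the resulting trajectory (default
#'   "external").
#' @return A `sheep_trajectory`.
#' @export
read_track_csv <- function(path, source = "external") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_m", "y_m", "phase")
  if (!all(need %in% names(d)))
    stop("track CSV must have columns: ", paste(need, collapse = ", "))
  extra <- if ("valid" %in% names(d)) list(valid = as.logical(d$valid)) else NULL
  trajectory(d$time_s, d$x_m, d$y_m, phase = as.character(d$phase),
             source = source, extra = extra)
}
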