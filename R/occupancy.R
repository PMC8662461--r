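#' Build the occupancy grid of virtual zones
#'
#' Partitions the arena into `grid_partitions[1]` cells along the length and
#' `grid_partitions[2]` across the width: 16 x 5 = 80 zones of
#' 0.4375 m x 0.40 m for the default 7 m x 2 m arena (a lamb-sized cell).
#' Cells are half-open, closed at the far (conspecific) edge; an internal
#' boundary point belongs to the higher-index cell. Indices are 0-based,
#' `(i_length, i_width)`.
#'
#' @param arena An `arena_config`.
#' @return An object of class `arena_grid` with fields `n_length`, `n_width`,
#'   `n_cells`, `cell_length`, `cell_width` and the `arena`.
#' @export
#' @examples
#' g <- build_grid(arena_config())
#' g$n_cells # 80
build_grid <- function(arena = arena_config()) {
  np <- arena$grid_partitions
  if (any(np < 1L)) stop("grid partitions must be positive")
  structure(list(n_length = np[1], n_width = np[2],
                 n_cells = np[1] * np[2],
                 cell_length = arena$length / np[1],
                 cell_width = arena$width / np[2],
                 arena = arena),
            class = "arena_grid")
}

#' @export
print.arena_grid <- function(x, ...) {
  cat(sprintf("Occupancy grid: %d x %d = %d zones of %.4f m x %.2f m\n",
              x$n_length, x$n_width, x$n_cells, x$cell_length, x$cell_width))
  invisible(x)
}

#' Map positions to grid-cell indices
#'
#' @param grid An `arena_grid`.
#' @param x,y Positions in arena coordinates (x centred on the boresight).
#' @return A data.frame with 0-based `i_length`, `i_width` and the linear
#'   0-based `cell` index (`i_length * n_width + i_width`).
#' @export
cell_index <- function(grid, x, y) {
  a <- grid$arena
  xe <- pmin(pmax(x + a$width / 2, 0), a$width)
  ye <- pmin(pmax(y, 0), a$length)
  il <- pmin(floor(ye / grid$cell_length), grid$n_length - 1L)
  iw <- pmin(floor(xe / grid$cell_width), grid$n_width - 1L)
  data.frame(i_length = as.integer(il), i_width = as.integer(iw),
             cell = as.integer(il * grid$n_width + iw))
}

#' Per-cell visit durations
#'
#' A visit is a maximal run of consecutive samples in one grid cell; its
#' duration is the run length divided by the sampling rate. Visits are
#' phase-scoped: a run spanning a phase boundary is split at the boundary.
#'
#' @param traj A `sheep_trajectory` at constant rate.
#' @param grid An `arena_grid` (default: grid of the default arena).
#' @return An object of class `dwell_table`: data.frame `visits` with columns
#'   `cell`, `i_length`, `i_width`, `phase`, `start_time`, `n_samples`,
#'   `duration`, plus the `rate` and `grid`.
#' @export
dwell_times <- function(traj, grid = build_grid(arena_config())) {
  if (nrow(traj) == 0) stop("empty trajectory")
  rate <- traj_rate(traj)
  ci <- cell_index(grid, traj$x, traj$y)
  key <- paste(ci$cell, traj$phase, sep = "|")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  visits <- data.frame(
    cell = ci$cell[starts],
    i_length = ci$i_length[starts],
    i_width = ci$i_width[starts],
    phase = traj$phase[starts],
    start_time = traj$time[starts],
    n_samples = r$lengths,
    duration = r$lengths / rate,
    stringsAsFactors = FALSE)
  structure(list(visits = visits, rate = rate, grid = grid),
            class = "dwell_table")
}

#' Heatmap score: zones occupied longer than a dwell threshold
#'
#' Number of distinct grid zones in which the animal remained for more than
#' `threshold` seconds. By default "remained" means a single continuous visit
#' longer than the threshold (200 ms); `cumulative = TRUE` instead thresholds
#' the total time accumulated per zone.
#'
#' @param dwell A `dwell_table`.
#' @param threshold Dwell threshold in seconds (> 0; default 0.2). The
#'   1-s variant reported for cohort mixed models is `threshold = 1`.
#' @param phase Restrict to one phase label (default: all).
#' @param cumulative Threshold cumulative zone time instead of single visits.
#' @return Integer count in `0..n_cells`.
#' @export
heatmap_score <- function(dwell, threshold = 0.2, phase = NULL,
                          cumulative = FALSE) {
  stopifnot(inherits(dwell, "dwell_table"), threshold > 0)
  v <- dwell$visits
  if (!is.null(phase)) v <- v[v$phase %in% phase, , drop = FALSE]
  if (nrow(v) == 0) return(0L)
  if (cumulative) {
    tot <- tapply(v$duration, v$cell, sum)
    sum(tot > threshold)
  } else {
    length(unique(v$cell[v$duration > threshold]))
  }
}

#' Per-cell total dwell matrix (for heatmap rendering)
#'
#' @param dwell A `dwell_table`.
#' @param phase Optional phase restriction.
#' @return A `n_length` x `n_width` matrix of total seconds per zone.
#' @export
dwell_matrix <- function(dwell, phase = NULL) {
  v <- dwell$visits
  if (!is.null(phase)) v <- v[v$phase %in% phase, , drop = FALSE]
  m <- matrix(0, dwell$grid$n_length, dwell$grid$n_width)
  for (i in seq_len(nrow(v)))
    m[v$i_length[i] + 1L, v$i_width[i] + 1L] <-
      m[v$i_length[i] + 1L, v$i_width[i] + 1L] + v$duration[i]
  m
}

## 1-based virtual-area index along the arena length (1-m areas; boundary
## points belong to the higher-index area, far edge closed)
.area_index <- function(y, arena) {
  ye <- pmin(pmax(y, 0), arena$length)
  pmin(floor(ye) + 1L, arena$n_virtual_areas)
}

#' Time spent in each 1-m virtual area
#'
#' The seven virtual areas tile the arena length (area 1 at the radar /
#' entrance end, area 7 against the grid barrier where the conspecifics
#' stand). Totals sum to the (phase) duration to within one sample period.
#'
#' @param traj A `sheep_trajectory`.
#' @param arena An `arena_config`.
#' @param phase Restrict to one phase label (default: all samples).
#' @return Named numeric vector of seconds per area.
#' @export
area_times <- function(traj, arena = arena_config(), phase = NULL) {
  d <- as.data.frame(traj)
  if (!is.null(phase)) d <- d[d$phase %in% phase, , drop = FALSE]
  a <- .area_index(d$y, arena)
  counts <- tabulate(a, nbins = arena$n_virtual_areas)
  out <- counts / traj_rate(traj)
  names(out) <- paste0("area", seq_len(arena$n_virtual_areas))
  out
}

#' Proximity score: area-weighted dwell time
#'
#' Sum over virtual areas of the time spent there times the area weight.
#' Weights increase towards the conspecific end (default 1..7, 7 at the grid
#' barrier), so a high score indicates high proximity to conspecifics.
#'
#' @param area_times Named vector from [area_times()].
#' @param weights Non-decreasing weights, one per area (default `1:7`).
#' @return The score (weight x seconds).
#' @export
proximity_score <- function(area_times, weights = seq_along(area_times)) {
  if (length(weights) != length(area_times))
    stop("need one weight per virtual area")
  if (is.unsorted(weights))
    stop("weights must be non-decreasing towards the conspecific end")
  sum(weights * area_times)
}

#' Crossing rate: number of virtual-area boundaries crossed
#'
#' Counts sample-to-sample area-index changes; a jump across k boundaries in
#' one step counts k.
#'
#' @inheritParams area_times
#' @return Integer count.
#' @export
crossing_rate <- function(traj, arena = arena_config(), phase = NULL) {
  d <- as.data.frame(traj)
  if (!is.null(phase)) d <- d[d$phase %in% phase, , drop = FALSE]
  a <- .area_index(d$y, arena)
  if (length(a) < 2) return(0L)
  as.integer(sum(abs(diff(a))))
}

#' Infrared beam-crossing events derived from a trajectory
#'
#' Emulates the paired infrared cells placed every metre along the arena: an
#' event is emitted each time the animal's area index changes, one event per
#' boundary crossed (beam b sits at y = b metres, between areas b and b+1),
#' with the crossing time linearly interpolated within the step. By
#' construction the number of events equals [crossing_rate()] exactly.
#'
#' @param traj A `sheep_trajectory`.
#' @param arena An `arena_config`.
#' @return A data.frame with columns `time`, `beam` (1-based boundary index)
#'   and `direction` (+1 towards the conspecifics, -1 towards the entrance).
#' @export
infrared_events <- function(traj, arena = arena_config()) {
  a <- .area_index(traj$y, arena)
  n <- length(a)
  empty <- data.frame(time = numeric(), beam = integer(), direction = integer())
  if (n < 2) return(empty)
  jumps <- which(diff(a) != 0)
  if (length(jumps) == 0) return(empty)
  ev <- vector("list", length(jumps))
  for (k in seq_along(jumps)) {
    i <- jumps[k]
    a0 <- a[i]; a1 <- a[i + 1]
    dirn <- sign(a1 - a0)
    beams <- if (dirn > 0) a0:(a1 - 1L) else (a0 - 1L):a1
    y0 <- traj$y[i]; y1 <- traj$y[i + 1]
    tfrac <- if (abs(y1 - y0) > 0) (beams - y0) / (y1 - y0) else rep(0.5, length(beams))
    tfrac <- pmin(pmax(tfrac, 0), 1)
    ev[[k]] <- data.frame(
      time = traj$time[i] + tfrac * (traj$time[i + 1] - traj$time[i]),
      beam = as.integer(beams),
      direction = as.integer(dirn))
  }
  out <- do.call(rbind, ev)
  out[order(out$time, out$beam), , drop = FALSE]
}
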