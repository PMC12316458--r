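#' Convergence ratio of a migrating cell group
#'
#' Ratio of the cell group's extent along the migration (y) axis at the
#' start of the recording to its extent at the end:
#' \deqn{\mathrm{ratio} = \frac{\max_i y_i(t_0) - \min_i y_i(t_0)}
#'                             {\max_i y_i(t_1) - \min_i y_i(t_1)},}
#' where \eqn{t_0}/\eqn{t_1} are the first/last recorded timepoints.
#' Values above 1 indicate convergence (the group compacts). Extent is the
#' max-min range; the orientation (initial over final) is a package
#' convention chosen so that converging groups score above 1. Cells with no
#' observation at the first or last timepoint are excluded (manual tracks
#' may be ragged); at least two cells must remain at both ends.
#'
#' The ratio only uses y coordinates and is invariant to translating all
#' positions.
#'
#' @param tracks Data frame with columns `track_id`, `t`, `y` (and usually
#'   `x`, ignored here).
#'
#' @return The convergence ratio. If the final extent is exactly zero the
#'   result is `Inf` with attribute `degenerate = TRUE` and a warning.
#' @examples
#' tr <- simulate_dfc_tracks(convergence_strength = 0.004, seed = 1)
#' convergence_ratio(tr)
#' @export
convergence_ratio <- function(tracks) {
  stopifnot(all(c("track_id", "t", "y") %in% names(tracks)))
  if (!nrow(tracks)) stop("empty track set", call. = FALSE)
  t0 <- min(tracks$t)
  t1 <- max(tracks$t)
  if (t1 <= t0) stop("recording spans a single timepoint", call. = FALSE)
  eps <- 1e-9 * max(1, abs(t1))
  at0 <- tracks[abs(tracks$t - t0) < eps, , drop = FALSE]
  at1 <- tracks[abs(tracks$t - t1) < eps, , drop = FALSE]
  both <- intersect(at0$track_id, at1$track_id)
  if (length(both) < 2L) {
    stop("need at least 2 cells observed at both the first and last timepoint",
         call. = FALSE)
  }
  y0 <- at0$y[at0$track_id %in% both]
  y1 <- at1$y[at1$track_id %in% both]
  e0 <- max(y0) - min(y0)
  e1 <- max(y1) - min(y1)
  if (e1 == 0) {
    warning("final extent is zero; returning Inf (complete collapse)")
    return(structure(Inf, degenerate = TRUE))
  }
  e0 / e1
}

#' Mean migration speed of a cell group
#'
#' Per-cell speed is the mean over consecutive steps of displacement
#' divided by step duration; the group speed is the unweighted mean across
#' cells. Units follow the input (um/min for minute-stamped cell tracks).
#' Positional noise inflates the estimate (each step picks up measurement
#' jitter); at zero noise a uniform drift is recovered exactly.
#'
#' @param tracks Data frame with columns `track_id`, `t`, `x`, `y`; each
#'   track needs at least 2 points and strictly increasing times.
#'
#' @return List with `per_cell_speed` (named), `mean_speed`, `n_cells`.
#' @export
migration_speed <- function(tracks) {
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(tracks)))
  if (!nrow(tracks)) stop("empty track set", call. = FALSE)
  pieces <- split(tracks, tracks$track_id)
  speeds <- vapply(pieces, function(tr) {
    if (nrow(tr) < 2L) return(NA_real_)
    tr <- tr[order(tr$t), , drop = FALSE]
    dts <- diff(tr$t)
    if (any(dts <= 0)) stop("track times must be strictly increasing", call. = FALSE)
    mean(sqrt(diff(tr$x)^2 + diff(tr$y)^2) / dts)
  }, numeric(1))
  speeds <- speeds[!is.na(speeds)]
  if (!length(speeds)) stop("no cells with at least 2 observations", call. = FALSE)
  list(per_cell_speed = speeds, mean_speed = mean(speeds), n_cells = length(speeds))
}

#' Migration index along the animal-vegetal axis
#'
#' Position of the cell group along the animal-pole to vegetal-pole axis
#' expressed as a percentage of total embryo length:
#' `100 * position / embryo_length`.
#'
#' @param dfc_position_y Distance migrated from the animal pole, um
#'   (0 <= position <= embryo_length). Vectorised.
#' @param embryo_length Total embryo length along the axis, um (> 0).
#'
#' @return Percentage in \[0, 100\].
#' @examples
#' migration_index(593.2, 1000)
#' @export
migration_index <- function(dfc_position_y, embryo_length) {
  if (length(embryo_length) != 1L || !is.finite(embryo_length) || embryo_length <= 0) {
    stop("`embryo_length` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(dfc_position_y)) || any(dfc_position_y < 0) ||
      any(dfc_position_y > embryo_length)) {
    stop("`dfc_position_y` must lie within [0, embryo_length]", call. = FALSE)
  }
  100 * dfc_position_y / embryo_length
}
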