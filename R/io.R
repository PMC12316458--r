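#' Construct a time-lapse image stack
#'
#' Container for a single-channel 2D time-lapse: an H x W x T array of
#' intensities plus the physical calibration. Pixel indices are 0-based in
#' all coordinate conversions; a spot at pixel (row, col) = (0, 0) has
#' continuous coordinates (x, y) = (0, 0) um, with x along columns
#' (rightward) and y along rows (downward).
#'
#' @param frames Numeric H x W x T array (T >= 2) of intensities.
#' @param pixel_size Pixel size in um (default 0.25).
#' @param frame_interval Frame interval in seconds (default 0.25, 4 Hz).
#'
#' @return Object of class `image_stack`: list with `frames`, `pixel_size`,
#'   `frame_interval`.
#' @export
image_stack <- function(frames, pixel_size = 0.25, frame_interval = 0.25) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be an H x W x T array", call. = FALSE)
  }
  if (dim(frames)[3] < 2L) {
    stop("an image stack needs at least 2 frames", call. = FALSE)
  }
  if (pixel_size <= 0 || frame_interval <= 0) {
    stop("`pixel_size` and `frame_interval` must be positive", call. = FALSE)
  }
  if (any(!is.finite(frames))) stop("`frames` contains non-finite values", call. = FALSE)
  structure(
    list(frames = frames, pixel_size = pixel_size, frame_interval = frame_interval),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d x %d px, %d frames, %.3g um/px, %.3g s/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Read / write a multi-frame TIFF stack
#'
#' `read_stack()` loads a single-channel multi-frame TIFF into an
#' [image_stack()]; `write_stack()` writes one out as 32-bit float TIFF.
#' Physical calibration is not stored in the TIFF and must be supplied.
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval Calibration, see [image_stack()].
#' @return `read_stack()` returns an [image_stack()]; `write_stack()`
#'   returns `path` invisibly.
#' @export
read_stack <- function(path, pixel_size = 0.25, frame_interval = 0.25) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  if (length(imgs) < 2L) {
    stop("stack has fewer than 2 frames; tracking needs a time-lapse", call. = FALSE)
  }
  if (any(vapply(imgs, function(m) length(dim(m)) != 2L, logical(1)))) {
    stop("expected single-channel frames (2D); got multi-channel data", call. = FALSE)
  }
  d1 <- dim(imgs[[1L]])
  if (any(vapply(imgs, function(m) !identical(dim(m), d1), logical(1)))) {
    stop("frames differ in shape; a stack must have constant frame size", call. = FALSE)
  }
  frames <- array(unlist(imgs, use.names = FALSE), dim = c(d1[1], d1[2], length(imgs)))
  image_stack(frames, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' @rdname read_stack
#' @param stack An [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  frames <- lapply(seq_len(d[3]), function(i) stack$frames[, , i])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read / write a track table CSV
#'
#' The interchange format between tracking stages is a CSV with header
#' `track_id,frame,t_seconds,x_um,y_um` (or `t_minutes` with
#' `time_unit = "minutes"`). Internally times are seconds for bead tracks
#' and minutes for cell tracks; `read_track_table()` returns the `t` column
#' in the requested unit's base (seconds when `time_unit = "seconds"`,
#' minutes when `"minutes"`), leaving interpretation to the caller.
#'
#' Writing then reading reproduces the numeric columns to full double
#' precision.
#'
#' @param path CSV path.
#' @param time_unit `"seconds"` or `"minutes"`; selects the expected time
#'   column name.
#' @return `read_track_table()`: data frame with columns `track_id`,
#'   `frame`, `t`, `x`, `y`. `write_track_table()`: `path`, invisibly.
#' @export
read_track_table <- function(path, time_unit = c("seconds", "minutes")) {
  time_unit <- match.arg(time_unit)
  tcol <- paste0("t_", time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", tcol, "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("track table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    track_id = df$track_id,
    frame = as.integer(df$frame),
    t = as.numeric(df[[tcol]]),
    x = as.numeric(df$x_um),
    y = as.numeric(df$y_um)
  )
  if (nrow(out)) {
    key <- paste(out$track_id, out$frame, sep = "\r")
    dup <- anyDuplicated(key)
    if (dup) {
      stop(sprintf("duplicated (track_id, frame) at row %d of %s", dup, path),
           call. = FALSE)
    }
    by_track <- split(seq_len(nrow(out)), out$track_id)
    for (idx in by_track) {
      f <- out$frame[idx]
      if (is.unsorted(f, strictly = TRUE)) {
        bad <- idx[which(diff(f) <= 0)[1] + 1L]
        stop(sprintf("non-increasing frame order within a track at row %d of %s",
                     bad, path), call. = FALSE)
      }
    }
  }
  out
}

#' @rdname read_track_table
#' @param tracks Data frame with columns `track_id`, `frame`, `t`, `x`, `y`.
#' @export
write_track_table <- function(tracks, path, time_unit = c("seconds", "minutes")) {
  time_unit <- match.arg(time_unit)
  stopifnot(all(c("track_id", "frame", "t", "x", "y") %in% names(tracks)))
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  df <- data.frame(
    track_id = tracks$track_id,
    frame = tracks$frame,
    t = fmt(tracks$t),
    x_um = fmt(tracks$x),
    y_um = fmt(tracks$y)
  )
  names(df)[3] <- paste0("t_", time_unit)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype counts CSV into outcome tables
#'
#' Expects a CSV with header `condition,category,count`, one row per
#' (condition, category) cell. Categories are ordered by first appearance
#' and must be identical across conditions.
#'
#' @param path CSV path.
#' @return Named list of [outcome_table()] objects, one per condition in
#'   order of first appearance.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "category", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("counts table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$count < 0)) stop("negative counts in ", path, call. = FALSE)
  cats <- unique(df$category)
  conds <- unique(df$condition)
  out <- lapply(conds, function(cond) {
    sub <- df[df$condition == cond, , drop = FALSE]
    if (!identical(sort(sub$category), sort(cats)) || nrow(sub) != length(cats)) {
      stop(sprintf("condition '%s' does not cover the same categories as the others",
                   cond), call. = FALSE)
    }
    counts <- sub$count[match(cats, sub$category)]
    outcome_table(cond, cats, counts)
  })
  names(out) <- conds
  out
}
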