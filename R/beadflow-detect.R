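#' Detect fluorescent spots in a time-lapse stack
#'
#' Multi-scale blob detection for sub-micron fluorescent beads imaged as
#' diffraction-limited Gaussian spots. Each frame is smoothed at a geometric
#' ladder of Gaussian scales and a normalised difference-of-Gaussians
#' response (a Laplacian-of-Gaussian approximation) is computed; local
#' maxima in (x, y, scale) space are candidate spots. Candidates are kept
#' only if
#' \itemize{
#'   \item the normalised blob response exceeds `response_threshold` robust
#'     standard deviations of the frame's response (rejects noise maxima),
#'   \item the estimated apparent diameter (full width at half maximum of
#'     the best-fitting scale) lies inside `size_range`,
#'   \item the peak raw intensity exceeds the `brightness_quantile` quantile
#'     of the whole stack.
#' }
#' The detection scale ladder deliberately extends beyond `size_range` so
#' that oversized blobs are assigned their true scale and then rejected by
#' the size gate rather than mis-measured at the ladder edge. Spot centres
#' are refined to sub-pixel precision by separable parabolic interpolation
#' of the blob response.
#'
#' @param stack An [image_stack()].
#' @param size_range Apparent spot diameter gate in um, default
#'   `c(0.75, 1.25)`.
#' @param brightness_quantile Whole-stack intensity quantile that a spot's
#'   peak must exceed. The default 0.99 keeps the brightest 1% of
#'   intensities; a permissive literal lower-tail reading (e.g. 1e-4) can be
#'   configured instead.
#' @param response_threshold Blob-response significance gate in robust sds
#'   (default 5).
#'
#' @return Data frame with one row per detection: `frame` (0-based), `x`,
#'   `y` (um, image coordinates: x rightward along columns, y downward
#'   along rows), `diameter` (um), `brightness` (raw peak intensity),
#'   `response` (normalised blob response).
#' @examples
#' tr <- simulate_bead_tracks("diffusive", n_beads = 2, duration = 1, D = 0.1, seed = 1)
#' ren <- render_image_stack(tr, seed = 1)
#' head(detect_spots(ren$stack))
#' @export
detect_spots <- function(stack,
                         size_range = c(0.75, 1.25),
                         brightness_quantile = 0.99,
                         response_threshold = 5) {
  stopifnot(inherits(stack, "image_stack"))
  if (!(size_range[1] > 0 && size_range[1] < size_range[2])) {
    stop("`size_range` must satisfy 0 < min < max", call. = FALSE)
  }
  if (brightness_quantile <= 0 || brightness_quantile >= 1) {
    stop("`brightness_quantile` must lie in (0, 1)", call. = FALSE)
  }
  px <- stack$pixel_size
  fwhm <- 2 * sqrt(2 * log(2)) # diameter = FWHM = 2.355 sigma
  if (size_range[1] / px < 1) {
    warning("smallest gated spot is below one pixel; detection will proceed but may be unreliable")
  }
  # scale ladder (sigma, px) spanning well beyond the size gate
  sig_lo <- 0.6 * size_range[1] / fwhm / px
  sig_hi <- 3.0 * size_range[2] / fwhm / px
  k <- 2^(1 / 3)
  n_sc <- max(4L, ceiling(log(sig_hi / sig_lo) / log(k)) + 1L)
  sigmas <- sig_lo * k^(0:(n_sc - 1L))

  bright_thr <- stats::quantile(stack$frames, brightness_quantile, names = FALSE)
  d <- dim(stack$frames)
  out <- vector("list", d[3])

  for (f in seq_len(d[3])) {
    frame <- stack$frames[, , f]
    blurred <- lapply(sigmas, function(s) .gauss_blur(frame, s))
    # normalised DoG: (G_sigma - G_{k sigma}) / (k - 1) ~ sigma^2 * LoG
    resp <- array(0, dim = c(d[1], d[2], n_sc - 1L))
    for (i in seq_len(n_sc - 1L)) {
      resp[, , i] <- (blurred[[i]] - blurred[[i + 1L]]) / (k - 1)
    }
    mads <- apply(resp, 3L, function(m) stats::mad(m, center = stats::median(m)))
    mads[mads <= 0] <- max(mads, .Machine$double.eps)

    dets <- .scale_space_maxima(resp, sigmas, response_threshold * mads)
    if (nrow(dets) == 0L) { out[[f]] <- NULL; next }
    dets$diameter <- fwhm * dets$sigma_px * px
    dets$brightness <- frame[cbind(dets$row, dets$col)]
    keep <- dets$diameter >= size_range[1] & dets$diameter <= size_range[2] &
      dets$brightness > bright_thr
    dets <- dets[keep, , drop = FALSE]
    if (nrow(dets) == 0L) { out[[f]] <- NULL; next }
    dets <- .merge_close(dets, min_dist_px = size_range[1] / fwhm / px)
    out[[f]] <- data.frame(
      frame = f - 1L,
      x = (dets$col - 1L + dets$dx) * px,
      y = (dets$row - 1L + dets$dy) * px,
      diameter = dets$diameter,
      brightness = dets$brightness,
      response = dets$response
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      diameter = numeric(), brightness = numeric(),
                      response = numeric())
  }
  rownames(res) <- NULL
  res
}

# Separable Gaussian blur with replicate-edge padding via EBImage.
.gauss_blur <- function(img, sigma_px) {
  EBImage::gblur(img, sigma = sigma_px, boundary = "replicate")
}

# Local maxima of the response cube over (row, col, scale) with per-scale
# thresholds; returns sub-pixel offsets from separable parabolic fits.
.scale_space_maxima <- function(resp, sigmas, thresholds) {
  d <- dim(resp)
  hits <- list()
  for (i in seq_len(d[3])) {
    r <- resp[, , i]
    # strict 8-neighbour maxima in-plane (interior pixels only)
    core <- r[2:(d[1] - 1L), 2:(d[2] - 1L)]
    ismax <- core > thresholds[i] &
      core >= r[1:(d[1] - 2L), 2:(d[2] - 1L)] & core >= r[3:d[1], 2:(d[2] - 1L)] &
      core >= r[2:(d[1] - 1L), 1:(d[2] - 2L)] & core >= r[2:(d[1] - 1L), 3:d[2]] &
      core >  r[1:(d[1] - 2L), 1:(d[2] - 2L)] & core >  r[3:d[1], 3:d[2]] &
      core >  r[1:(d[1] - 2L), 3:d[2]] & core >  r[3:d[1], 1:(d[2] - 2L)]
    idx <- which(ismax, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    rows <- idx[, 1L] + 1L
    cols <- idx[, 2L] + 1L
    vals <- r[cbind(rows, cols)]
    # require maximum across adjacent scales at the same pixel
    if (i > 1L) {
      keep <- vals >= resp[, , i - 1L][cbind(rows, cols)]
      rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
    }
    if (i < d[3] && length(rows)) {
      keep <- vals >= resp[, , i + 1L][cbind(rows, cols)]
      rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
    }
    if (!length(rows)) next
    # sub-pixel offsets by 3-point parabola on the in-plane response
    parab <- function(vm, v0, vp) {
      den <- vm - 2 * v0 + vp
      off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (vm - vp) / den, 0)
      pmin(pmax(off, -0.5), 0.5)
    }
    dy <- parab(r[cbind(rows - 1L, cols)], vals, r[cbind(rows + 1L, cols)])
    dx <- parab(r[cbind(rows, cols - 1L)], vals, r[cbind(rows, cols + 1L)])
    # sigma refinement across scales (log-parabola), interior scales only
    s_off <- rep(0, length(rows))
    if (i > 1L && i < d[3]) {
      vm <- resp[, , i - 1L][cbind(rows, cols)]
      vp <- resp[, , i + 1L][cbind(rows, cols)]
      s_off <- parab(vm, vals, vp)
    }
    # the normalised DoG response of a Gaussian spot with sd s peaks at
    # sigma = s / sqrt(k); correct the attribution accordingly
    kk <- sigmas[2] / sigmas[1]
    sigma_px <- sigmas[i] * sqrt(kk) * kk^s_off
    hits[[length(hits) + 1L]] <- data.frame(
      row = rows, col = cols, dx = dx, dy = dy,
      response = vals, sigma_px = sigma_px, scale = i
    )
  }
  if (!length(hits)) {
    return(data.frame(row = integer(), col = integer(), dx = numeric(),
                      dy = numeric(), response = numeric(),
                      sigma_px = numeric(), scale = integer()))
  }
  do.call(rbind, hits)
}

# Collapse detections of the same physical spot surviving at several
# scales: keep the strongest response within min_dist_px.
.merge_close <- function(dets, min_dist_px) {
  if (nrow(dets) <= 1L) return(dets)
  ord <- order(-dets$response)
  dets <- dets[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(dets))
  xs <- dets$col + dets$dx
  ys <- dets$row + dets$dy
  for (i in seq_len(nrow(dets))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(dets)) > i)
    if (!length(later)) break
    dd <- sqrt((xs[later] - xs[i])^2 + (ys[later] - ys[i])^2)
    keep[later[dd < min_dist_px]] <- FALSE
  }
  dets[keep, , drop = FALSE]
}
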