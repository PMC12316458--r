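#' Draw a multinomial phenotype count vector
#'
#' One multinomial draw of `n` outcomes over the given category
#' frequencies, emulating a phenotype-scoring experiment on `n` embryos.
#'
#' @param frequencies Non-negative category probabilities summing to 1.
#' @param n Number of observations (>= 1).
#' @param seed Integer seed; a fixed seed reproduces the draw exactly.
#'
#' @return Integer count vector, same length as `frequencies`.
#' @examples
#' simulate_multinomial_counts(c(0.88, 0.11, 0.01), 120, seed = 1)
#' @export
simulate_multinomial_counts <- function(frequencies, n, seed = 1L) {
  f <- as.numeric(frequencies)
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("`frequencies` must be non-negative", call. = FALSE)
  }
  if (abs(sum(f) - 1) > 1e-8) stop("`frequencies` must sum to 1", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set.seed(seed)
  as.integer(stats::rmultinom(1L, as.integer(n), f)[, 1L])
}

#' Simulate microbead trajectories in an organizer-flow stand-in
#'
#' Generates ground-truth 2D bead tracks in one of three motion regimes:
#' \describe{
#'   \item{directed}{beads advected by a counter-clockwise vortex (rigid
#'     rotation about `center` at each bead's radius) plus residual
#'     diffusion: the stand-in for flow in a functional organizer. Per step
#'     the advection is applied as an exact rotation, then a Gaussian
#'     diffusive step of per-axis variance 2 D dt is added
#'     (Euler-Maruyama splitting with exact drift).}
#'   \item{confined}{Brownian motion restricted to a disc of radius
#'     `confinement_radius` by radial reflection at the boundary: the
#'     stand-in for a collapsed, non-flowing vesicle.}
#'   \item{diffusive}{free Brownian motion.}
#' }
#'
#' Defaults are the study conditions used throughout the package: 4 Hz
#' sampling (dt 0.25 s), 8 s duration so whole tracks sit inside the 1-8 s
#' analysis window, directed tangential speed 0.96 um/s with residual
#' D = 0.02 um^2/s, confined radius 5 um with free-bead
#' D = 1.1 um^2/s (Stokes-Einstein scale for a 0.5 um sphere in a
#' ~0.8 mPa s medium).
#'
#' @param mode One of `"directed"`, `"confined"`, `"diffusive"`.
#' @param n_beads Number of beads.
#' @param duration Track duration in seconds (>= 2 * dt).
#' @param dt Frame interval in seconds (default 0.25, i.e. 4 Hz).
#' @param center Vortex / confinement centre (um), length 2.
#' @param tangential_speed Directed mode: tangential flow speed in um/s,
#'   applied at each bead's own radius (per-bead angular speed
#'   `tangential_speed / r`). Ignored when `angular_speed` is given.
#' @param angular_speed Optional rigid angular speed in rad/s (positive =
#'   counter-clockwise) shared by all beads; overrides `tangential_speed`.
#' @param D Diffusion coefficient in um^2/s; `NULL` picks the per-mode
#'   default (0.02 directed, 1.1 confined/diffusive).
#' @param confinement_radius Disc radius in um for confined mode.
#' @param r_range Directed mode: beads start at radii drawn uniformly in
#'   this range (um). Chosen so the default 200 beads remain optically
#'   resolvable when rendered.
#' @param seed Integer seed.
#'
#' @return A data frame of class `bead_tracks` with columns `track_id`,
#'   `frame` (0-based), `t` (seconds), `x`, `y` (um), carrying the
#'   generating parameters in `attr(, "config")`.
#' @examples
#' tr <- simulate_bead_tracks("directed", n_beads = 5, duration = 2, seed = 1)
#' head(tr)
#' @export
simulate_bead_tracks <- function(mode = c("directed", "confined", "diffusive"),
                                 n_beads = 200L,
                                 duration = 8,
                                 dt = 0.25,
                                 center = c(0, 0),
                                 tangential_speed = 0.96,
                                 angular_speed = NULL,
                                 D = NULL,
                                 confinement_radius = 5,
                                 r_range = c(8, 36),
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (duration < 2 * dt) stop("`duration` must be at least 2 * dt", call. = FALSE)
  if (is.null(D)) D <- if (mode == "directed") 0.02 else 1.1
  if (D < 0) stop("`D` must be non-negative", call. = FALSE)
  if (mode == "confined" && confinement_radius <= 0) {
    stop("`confinement_radius` must be positive", call. = FALSE)
  }
  n_frames <- floor(duration / dt) + 1L
  set.seed(seed)

  x <- matrix(0, nrow = n_frames, ncol = n_beads)
  y <- matrix(0, nrow = n_frames, ncol = n_beads)
  step_sd <- sqrt(2 * D * dt)

  if (mode == "directed") {
    r0 <- stats::runif(n_beads, r_range[1], r_range[2])
    th0 <- stats::runif(n_beads, 0, 2 * pi)
    x[1L, ] <- center[1] + r0 * cos(th0)
    y[1L, ] <- center[2] + r0 * sin(th0)
    omega <- if (is.null(angular_speed)) tangential_speed / r0 else rep_len(angular_speed, n_beads)
    for (i in seq_len(n_frames - 1L)) {
      dx <- x[i, ] - center[1]
      dy <- y[i, ] - center[2]
      ca <- cos(omega * dt); sa <- sin(omega * dt)
      x[i + 1L, ] <- center[1] + ca * dx - sa * dy + stats::rnorm(n_beads, 0, step_sd)
      y[i + 1L, ] <- center[2] + sa * dx + ca * dy + stats::rnorm(n_beads, 0, step_sd)
    }
  } else {
    if (mode == "confined") {
      # uniform start inside the disc
      rr <- confinement_radius * sqrt(stats::runif(n_beads))
      th <- stats::runif(n_beads, 0, 2 * pi)
      x[1L, ] <- center[1] + rr * cos(th)
      y[1L, ] <- center[2] + rr * sin(th)
    } else {
      x[1L, ] <- center[1]
      y[1L, ] <- center[2]
    }
    for (i in seq_len(n_frames - 1L)) {
      xn <- x[i, ] + stats::rnorm(n_beads, 0, step_sd)
      yn <- y[i, ] + stats::rnorm(n_beads, 0, step_sd)
      if (mode == "confined") {
        dx <- xn - center[1]; dy <- yn - center[2]
        r <- sqrt(dx^2 + dy^2)
        out <- r > confinement_radius
        # radial reflection; loop in case a rare step overshoots past 2R
        while (any(out)) {
          rref <- 2 * confinement_radius - r[out]
          rref <- abs(rref)
          scale <- rref / r[out]
          dx[out] <- dx[out] * scale
          dy[out] <- dy[out] * scale
          r <- sqrt(dx^2 + dy^2)
          out <- r > confinement_radius
        }
        xn <- center[1] + dx
        yn <- center[2] + dy
      }
      x[i + 1L, ] <- xn
      y[i + 1L, ] <- yn
    }
  }

  frames <- rep(seq_len(n_frames) - 1L, times = n_beads)
  tracks <- data.frame(
    track_id = rep(seq_len(n_beads), each = n_frames),
    frame = frames,
    t = frames * dt,
    x = as.vector(x),
    y = as.vector(y)
  )
  attr(tracks, "config") <- list(
    mode = mode, n_beads = n_beads, duration = duration, dt = dt,
    center = center, tangential_speed = tangential_speed,
    angular_speed = angular_speed, D = D,
    confinement_radius = confinement_radius, r_range = r_range, seed = seed
  )
  class(tracks) <- c("bead_tracks", "data.frame")
  tracks
}

#' Render bead tracks into a synthetic fluorescence image stack
#'
#' Renders each bead position as an isotropic 2D Gaussian spot (amplitude
#' `peak`, standard deviation `psf_sigma`) on a constant background with
#' additive Gaussian noise, emulating single-plane spinning-disc imaging of
#' sub-micron fluorescent microspheres. SNR is `peak / noise_sd`.
#'
#' Track coordinates are shifted so the whole field of view fits the image
#' (unless `image_size` is given, in which case out-of-field beads are
#' clipped with a warning); the returned ground truth carries the shifted
#' coordinates, directly comparable with detector output.
#'
#' @param tracks Data frame with `track_id`, `frame`, `x`, `y` (um), e.g.
#'   from [simulate_bead_tracks()].
#' @param pixel_size Pixel size in um (default 0.25).
#' @param psf_sigma Gaussian spot sd in um. The default 0.425 gives a
#'   1.0 um full-width-half-maximum spot, inside the 0.75-1.25 um
#'   apparent-size gate used for detection.
#' @param peak Peak spot intensity above background (arbitrary units).
#' @param background Constant background level.
#' @param noise_sd Gaussian noise sd; default `peak / 10` (SNR 10).
#' @param image_size Optional `c(H, W)` in pixels; default sized to the
#'   track bounding box plus a 4 um margin.
#' @param frame_interval Frame interval in seconds stored on the stack.
#' @param seed Integer seed for the noise.
#'
#' @return List with `stack` (an [image_stack()]) and `truth` (the tracks
#'   with coordinates in the image frame, um).
#' @examples
#' tr <- simulate_bead_tracks("diffusive", n_beads = 3, duration = 1, seed = 2)
#' ren <- render_image_stack(tr, seed = 2)
#' dim(ren$stack$frames)
#' @export
render_image_stack <- function(tracks,
                               pixel_size = 0.25,
                               psf_sigma = 0.425,
                               peak = 1,
                               background = 0.1,
                               noise_sd = peak / 10,
                               image_size = NULL,
                               frame_interval = 0.25,
                               seed = 1L) {
  stopifnot(all(c("track_id", "frame", "x", "y") %in% names(tracks)))
  if (pixel_size <= 0 || psf_sigma <= 0) stop("`pixel_size` and `psf_sigma` must be positive", call. = FALSE)
  tr <- as.data.frame(tracks)
  margin <- 4 # um
  if (is.null(image_size)) {
    off <- c(min(tr$x) - margin, min(tr$y) - margin)
    tr$x <- tr$x - off[1]
    tr$y <- tr$y - off[2]
    w_px <- ceiling((max(tr$x) + margin) / pixel_size) + 1L
    h_px <- ceiling((max(tr$y) + margin) / pixel_size) + 1L
  } else {
    h_px <- as.integer(image_size[1]); w_px <- as.integer(image_size[2])
    inside <- tr$x >= 0 & tr$x <= (w_px - 1L) * pixel_size &
      tr$y >= 0 & tr$y <= (h_px - 1L) * pixel_size
    if (!all(inside)) {
      warning(sum(!inside), " bead positions fall outside the field and are clipped")
      tr <- tr[inside, , drop = FALSE]
    }
  }
  n_frames <- max(tr$frame) + 1L
  set.seed(seed)
  frames <- array(background, dim = c(h_px, w_px, n_frames))
  sig_px <- psf_sigma / pixel_size
  halfw <- ceiling(4 * sig_px)
  for (k in seq_len(nrow(tr))) {
    f <- tr$frame[k] + 1L
    cx <- tr$x[k] / pixel_size   # 0-based pixel coordinates
    cy <- tr$y[k] / pixel_size
    c0 <- max(0L, floor(cx) - halfw); c1 <- min(w_px - 1L, ceiling(cx) + halfw)
    r0 <- max(0L, floor(cy) - halfw); r1 <- min(h_px - 1L, ceiling(cy) + halfw)
    if (c1 < c0 || r1 < r0) next
    cols <- c0:c1
    rows <- r0:r1
    gx <- exp(-((cols - cx)^2) / (2 * sig_px^2))
    gy <- exp(-((rows - cy)^2) / (2 * sig_px^2))
    frames[rows + 1L, cols + 1L, f] <-
      frames[rows + 1L, cols + 1L, f] + peak * outer(gy, gx)
  }
  if (noise_sd > 0) {
    frames <- frames + stats::rnorm(length(frames), 0, noise_sd)
  }
  frames[frames < 0] <- 0
  list(
    stack = image_stack(frames, pixel_size = pixel_size, frame_interval = frame_interval),
    truth = tr
  )
}

#' Simulate converging, vegetal-ward cell tracks
#'
#' Emulates collective dorsal-forerunner-cell migration during epiboly: the
#' group centroid drifts toward the vegetal pole (+y) at `drift_speed`
#' while each cell's deviation from the centroid relaxes exponentially at
#' rate `convergence_strength`, so the group's extent shrinks by a factor
#' `exp(convergence_strength * duration)` over the recording (exact at zero
#' noise: the per-step deviation update is the exact exponential decay).
#' Optional additive Gaussian positional noise models measurement error.
#'
#' Defaults emulate a 3 h recording from 50% epiboly at 3 min intervals
#' with a ~100 um cell group drifting at 1 um/min and converging roughly
#' two-fold (`convergence_strength` 0.004 /min).
#'
#' @param n_cells Number of cells.
#' @param drift_speed Centroid drift toward +y, um/min.
#' @param convergence_strength Relaxation rate of deviations from the
#'   centroid, per minute.
#' @param noise_sd Gaussian positional noise sd, um (default 0).
#' @param duration Recording length, minutes.
#' @param dt Sampling interval, minutes.
#' @param init_spread Initial group extent (uniform square side), um.
#' @param seed Integer seed.
#'
#' @return Data frame of class `cell_tracks` with columns `track_id`,
#'   `frame`, `t` (minutes), `x`, `y` (um; +y toward the vegetal pole);
#'   generating parameters in `attr(, "config")`.
#' @examples
#' tr <- simulate_dfc_tracks(n_cells = 5, duration = 30, seed = 3)
#' convergence_ratio(tr)
#' @export
simulate_dfc_tracks <- function(n_cells = 20L,
                                drift_speed = 1,
                                convergence_strength = 0.004,
                                noise_sd = 0,
                                duration = 180,
                                dt = 3,
                                init_spread = 100,
                                seed = 1L) {
  if (any(c(drift_speed, convergence_strength, noise_sd) < 0)) {
    stop("rates and noise must be non-negative", call. = FALSE)
  }
  if (dt <= 0 || duration < dt) stop("need duration >= dt > 0", call. = FALSE)
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  set.seed(seed)
  n_frames <- floor(duration / dt) + 1L
  t_vec <- (seq_len(n_frames) - 1L) * dt
  dev_x0 <- stats::runif(n_cells, -init_spread / 2, init_spread / 2)
  dev_y0 <- stats::runif(n_cells, -init_spread / 2, init_spread / 2)
  dev_x0 <- dev_x0 - mean(dev_x0)
  dev_y0 <- dev_y0 - mean(dev_y0)
  decay <- exp(-convergence_strength * t_vec)
  x <- outer(decay, dev_x0)                       # n_frames x n_cells
  y <- outer(decay, dev_y0) + drift_speed * t_vec # centroid drifts in +y
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise_sd)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  frames <- rep(seq_len(n_frames) - 1L, times = n_cells)
  tracks <- data.frame(
    track_id = rep(seq_len(n_cells), each = n_frames),
    frame = frames,
    t = frames * dt,
    x = as.vector(x),
    y = as.vector(y)
  )
  attr(tracks, "config") <- list(
    n_cells = n_cells, drift_speed = drift_speed,
    convergence_strength = convergence_strength, noise_sd = noise_sd,
    duration = duration, dt = dt, init_spread = init_spread, seed = seed
  )
  class(tracks) <- c("cell_tracks", "data.frame")
  tracks
}
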