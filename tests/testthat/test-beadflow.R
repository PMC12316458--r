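ballistic_track <- function(v = 1, dt = 0.25, n = 21, angle = 0) {
  t <- (seq_len(n) - 1) * dt
  data.frame(track_id = 1L, frame = seq_len(n) - 1L, t = t,
             x = v * t * cos(angle), y = v * t * sin(angle))
}

test_that("time-averaged MSD is exact for ballistic and stationary tracks", {
  tr <- ballistic_track(v = 1)
  cu <- compute_track_msd(tr)
  expect_equal(cu$msd, cu$lag^2, tolerance = 1e-14)
  expect_identical(cu$n_pairs, 21L - seq_len(20L))

  still <- data.frame(track_id = 1, frame = 0:9, t = (0:9) * 0.25, x = 2, y = -1)
  expect_true(all(compute_track_msd(still)$msd == 0))

  expect_identical(nrow(compute_track_msd(still[1, ])), 0L)
})

test_that("MSD is invariant under translation and rotation of coordinates", {
  set.seed(21)
  tr <- data.frame(track_id = 1, frame = 0:30, t = (0:30) * 0.25,
                   x = cumsum(rnorm(31)), y = cumsum(rnorm(31)))
  base <- compute_track_msd(tr)
  shifted <- transform(tr, x = x + 12.3, y = y - 45.6)
  expect_equal(compute_track_msd(shifted)$msd, base$msd, tolerance = 1e-12)
  th <- 0.7
  rotated <- transform(tr, x = cos(th) * x - sin(th) * y,
                       y = sin(th) * x + cos(th) * y)
  expect_equal(compute_track_msd(rotated)$msd, base$msd, tolerance = 1e-12)
})

test_that("gated linking splits far jumps and recovers separated beads", {
  det <- data.frame(frame = 0:19, x = (0:19) * 0.1, y = 0)
  lk <- link_detections(det)
  expect_identical(length(unique(lk$track_id)), 1L)
  expect_identical(nrow(lk), 20L)

  # a 3 um jump exceeds the 2.5 um gate: two single-point tracks
  far <- data.frame(frame = c(0, 1), x = c(0, 3), y = 0)
  expect_identical(length(unique(link_detections(far)$track_id)), 2L)
  # exactly at the gate is also excluded (strict inequality)
  at_gate <- data.frame(frame = c(0, 1), x = c(0, 2.5), y = 0)
  expect_identical(length(unique(link_detections(at_gate)$track_id)), 2L)

  # two beads 10 um apart stepping 0.5 um/frame relink to ground truth
  n <- 15L
  truth <- rbind(
    data.frame(track_id = 1, frame = 0:(n - 1), x = (0:(n - 1)) * 0.5, y = 0),
    data.frame(track_id = 2, frame = 0:(n - 1), x = (0:(n - 1)) * 0.5, y = 10)
  )
  lk2 <- link_detections(truth[order(truth$frame), c("frame", "x", "y")])
  expect_identical(length(unique(lk2$track_id)), 2L)
  for (id in unique(lk2$track_id)) {
    piece <- lk2[lk2$track_id == id, ]
    expect_identical(nrow(piece), n)
    expect_true(all(piece$y == piece$y[1])) # never swaps lanes
  }

  expect_identical(nrow(link_detections(data.frame(frame = integer(),
                                                   x = numeric(), y = numeric()))), 0L)
})

test_that("ensemble MSD averages eligible tracks and enforces the duration window", {
  tr <- ballistic_track(v = 0.7, n = 17) # duration 4 s
  single <- ensemble_msd(tr, frame_interval = 0.25)
  expect_equal(single$msd, compute_track_msd(tr)$msd, tolerance = 1e-14)
  expect_true(all(single$n_pairs == 1L))

  short <- ballistic_track(n = 3)  # 0.5 s
  long <- ballistic_track(n = 41)  # 10 s
  long$track_id <- 2L
  expect_error(ensemble_msd(rbind(short, long), frame_interval = 0.25),
               "duration")

  # a mixed population's curve lies between the pure-population curves
  dir_tr <- simulate_bead_tracks("directed", n_beads = 60, tangential_speed = 1,
                                 D = 0.02, seed = 31)
  con_tr <- simulate_bead_tracks("confined", n_beads = 60, seed = 32)
  con_tr$track_id <- con_tr$track_id + 1000L
  pure_d <- ensemble_msd(dir_tr)
  pure_c <- ensemble_msd(con_tr)
  mixed <- ensemble_msd(rbind(dir_tr, con_tr))
  lo <- pmin(pure_d$msd, pure_c$msd)
  hi <- pmax(pure_d$msd, pure_c$msd)
  expect_true(all(mixed$msd >= lo - 1e-9 & mixed$msd <= hi + 1e-9))
})

test_that("motion classification recovers the generating regime", {
  # exact ballistic curve: directed with v = 1, D ~ 0
  cl <- classify_motion(compute_track_msd(ballistic_track(v = 1)))
  expect_identical(cl$verdict, "directed")
  expect_equal(cl$v, 1, tolerance = 1e-6)
  expect_lt(cl$fits$directed$D, 1e-8)
  expect_gt(cl$alpha, 1.9)

  # exact linear curve: diffusive wins over the nested directed model
  lin <- data.frame(lag = (1:16) * 0.25, msd = 4 * 0.3 * (1:16) * 0.25)
  cl_lin <- classify_motion(lin)
  expect_identical(cl_lin$verdict, "diffusive")
  expect_equal(cl_lin$D, 0.3, tolerance = 1e-6)

  # exact confined curve
  t <- (1:32) * 0.25
  conf <- data.frame(lag = t, msd = 25 * (1 - exp(-t / 3)))
  cl_conf <- classify_motion(conf)
  expect_identical(cl_conf$verdict, "confined")
  expect_equal(cl_conf$L, 5, tolerance = 1e-3)
  expect_equal(cl_conf$tau, 3, tolerance = 1e-2)

  expect_error(classify_motion(data.frame(lag = 1:3, msd = 1:3)), "4 lags")
  expect_error(classify_motion(data.frame(lag = 1:5, msd = c(1, 2, NA, 4, 5))),
               "finite")
})

test_that("mean bead speed is the unweighted per-track average", {
  still <- data.frame(track_id = rep(1:2, each = 5), x = 0, y = 0)
  expect_identical(mean_bead_speed(still)$mean_speed, 0)

  b1 <- ballistic_track(v = 1)
  b2 <- ballistic_track(v = 2, n = 5)
  b2$track_id <- 2L
  fs <- mean_bead_speed(rbind(b1, b2), frame_interval = 0.25)
  expect_equal(fs$mean_speed, 1.5, tolerance = 1e-12) # (1 + 2)/2, length-blind
  expect_identical(fs$n_tracks, 2L)

  lone <- data.frame(track_id = 1, x = 0, y = 0)[1, ]
  expect_error(mean_bead_speed(lone), "length >= 2")
})

test_that("spot detection finds rendered beads, gates size, ignores flat frames", {
  flat <- image_stack(array(0.5, dim = c(64, 64, 2)))
  expect_identical(nrow(detect_spots(flat)), 0L)

  set.seed(77)
  n <- 10L
  pos <- data.frame(track_id = 1:n, frame = 0L,
                    x = runif(n, 5, 55), y = runif(n, 5, 55))
  pos <- rbind(pos, transform(pos, frame = 1L))
  ren <- render_image_stack(pos, image_size = c(260, 260), seed = 77)
  dets <- detect_spots(ren$stack)
  truth0 <- ren$truth[ren$truth$frame == 0L, ]
  d0 <- dets[dets$frame == 0L, ]
  expect_identical(nrow(d0), n)
  for (i in seq_len(n)) {
    err <- min(sqrt((d0$x - truth0$x[i])^2 + (d0$y - truth0$y[i])^2))
    expect_lt(err, 0.25) # within one pixel
  }
  expect_true(all(d0$diameter >= 0.75 & d0$diameter <= 1.25))

  # an oversized (3 um FWHM) blob is excluded by the size gate
  big <- render_image_stack(data.frame(track_id = 99, frame = 0:1, x = 30, y = 50),
                            psf_sigma = 3 / (2 * sqrt(2 * log(2))),
                            image_size = c(260, 260), noise_sd = 0, seed = 1)
  clean <- render_image_stack(pos, image_size = c(260, 260), noise_sd = 0, seed = 1)
  both <- image_stack(clean$stack$frames + big$stack$frames - 0.1)
  d_both <- detect_spots(both)
  near_blob <- sqrt((d_both$x - 30)^2 + (d_both$y - 50)^2) < 2
  expect_identical(sum(near_blob), 0L)
  expect_identical(sum(d_both$frame == 0L), n)
})
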