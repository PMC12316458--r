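test_that("multinomial table generator is exact, bounded and reproducible", {
  expect_identical(simulate_multinomial_counts(c(1, 0, 0), 50, seed = 1),
                   c(50L, 0L, 0L))
  k1 <- simulate_multinomial_counts(c(0.5, 0.5), 1e5, seed = 9)
  k2 <- simulate_multinomial_counts(c(0.5, 0.5), 1e5, seed = 9)
  expect_identical(k1, k2)
  expect_identical(sum(k1), 100000L)
  # binomial sd bound: within 4 * sqrt(n p (1-p)) of the mean
  expect_lt(abs(k1[1] - 50000), 4 * sqrt(1e5 * 0.25))

  expect_error(simulate_multinomial_counts(c(0.7, -0.3, 0.6), 10), "non-negative")
})

test_that("noise-free vortex advection traces exact circles at omega * r speed", {
  tr <- simulate_bead_tracks("directed", n_beads = 8, duration = 4, D = 0,
                             tangential_speed = 1, seed = 4)
  for (id in unique(tr$track_id)) {
    piece <- tr[tr$track_id == id, ]
    r <- sqrt(piece$x^2 + piece$y^2)
    expect_lt(diff(range(r)), 1e-9) # constant radius: exact circle
    sp <- mean_bead_speed(piece, frame_interval = 0.25)$per_track_speed
    omega <- 1 / r[1]
    chord_speed <- 2 * r[1] * sin(omega * 0.25 / 2) / 0.25
    expect_equal(unname(sp), chord_speed, tolerance = 1e-9)
    expect_equal(unname(sp), 1, tolerance = 1e-3) # chord ~ arc at small angles
  }
})

test_that("confined ensemble MSD plateaus at the disc asymptote", {
  # long tracks so lags reach well past the equilibration time
  tr <- simulate_bead_tracks("confined", n_beads = 300, duration = 40,
                             confinement_radius = 5, seed = 14)
  cu <- ensemble_msd(tr, min_duration = 1, max_duration = 40, max_lag = 40)
  # asymptote for a uniform disc of radius R: E|r1 - r2|^2 = R^2
  tail_msd <- mean(cu$msd[cu$lag >= 20 & cu$lag <= 35])
  expect_lt(abs(tail_msd - 25) / 25, 0.2)
  # long-lag log-log slope is far below diffusive
  tail <- cu[cu$lag >= 10 & cu$lag <= 35, ]
  alpha_tail <- unname(coef(lm(log(msd) ~ log(lag), tail))[2])
  expect_lt(alpha_tail, 0.5)
  # no bead ever leaves the disc
  expect_true(all(tr$x^2 + tr$y^2 <= 25 + 1e-9))
})

test_that("free diffusion recovers its coefficient from the MSD slope", {
  tr <- simulate_bead_tracks("diffusive", n_beads = 500, D = 0.5, seed = 6)
  cu <- ensemble_msd(tr)
  slope <- unname(coef(lm(msd ~ 0 + lag, cu[1:5, ]))[1])
  expect_lt(abs(slope - 4 * 0.5) / (4 * 0.5), 0.1)
})

test_that("directed and confined ensembles separate in the log-log exponent", {
  dir_cu <- ensemble_msd(simulate_bead_tracks("directed", n_beads = 200,
                                              tangential_speed = 1, D = 0.02,
                                              seed = 8))
  expect_gt(classify_motion(dir_cu)$alpha, 1.5)
  con_tr <- simulate_bead_tracks("confined", n_beads = 200, duration = 30, seed = 8)
  con_cu <- ensemble_msd(con_tr, max_duration = 30, max_lag = 30)
  tail <- con_cu[con_cu$lag >= 10, ]
  expect_lt(unname(coef(lm(log(msd) ~ log(lag), tail))[2]), 0.5)
})

test_that("rendering places spots at ground truth and is seed-stable", {
  still <- data.frame(track_id = 1, frame = 0:1, x = 5.0, y = 7.5)
  ren <- render_image_stack(still, image_size = c(64, 64), noise_sd = 0, seed = 1)
  for (f in 1:2) {
    idx <- which(ren$stack$frames[, , f] == max(ren$stack$frames[, , f]),
                 arr.ind = TRUE)
    # 0-based pixel coords times pixel size recover the position
    expect_equal(as.numeric(idx[1, 2] - 1) * 0.25, ren$truth$x[1], tolerance = 0.25)
    expect_equal(as.numeric(idx[1, 1] - 1) * 0.25, ren$truth$y[1], tolerance = 0.25)
  }

  tr <- simulate_bead_tracks("diffusive", n_beads = 4, duration = 1, seed = 2)
  r1 <- render_image_stack(tr, seed = 5)
  r2 <- render_image_stack(tr, seed = 5)
  expect_identical(r1$stack$frames, r2$stack$frames)

  expect_warning(
    render_image_stack(data.frame(track_id = 1, frame = 0:2, x = c(2, 500, 2), y = 2),
                       image_size = c(40, 40), seed = 1),
    "clipped")
})

test_that("noise-only stacks yield at most one false positive per 100 frames", {
  set.seed(55)
  noise <- array(rnorm(160 * 160 * 100, mean = 0.1, sd = 0.1),
                 dim = c(160, 160, 100))
  noise[noise < 0] <- 0
  fp <- detect_spots(image_stack(noise))
  expect_lte(nrow(fp), 1L)
})

test_that("cell-track generator has the closed-form convergence and drift", {
  tr <- simulate_dfc_tracks(n_cells = 15, drift_speed = 1, convergence_strength = 0,
                            noise_sd = 0, seed = 10)
  expect_equal(convergence_ratio(tr), 1, tolerance = 1e-12)
  expect_equal(migration_speed(tr)$mean_speed, 1, tolerance = 1e-12)

  cc <- 0.004; dur <- 180
  tr2 <- simulate_dfc_tracks(n_cells = 20, convergence_strength = cc,
                             noise_sd = 0, duration = dur, seed = 11)
  expect_lt(abs(convergence_ratio(tr2) - exp(cc * dur)) / exp(cc * dur), 0.1)

  expect_identical(simulate_dfc_tracks(seed = 3), simulate_dfc_tracks(seed = 3))
})
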