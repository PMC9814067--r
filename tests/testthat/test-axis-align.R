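test_that("tilt estimation from feature points handles canonical cases", {
  # flat horizontal track: both tilts zero
  est <- estimate_tilt(c(-30, 0), c(30, 0), c(0, 0), c(0, 0))
  expect_equal(est$theta_Xt_hat, 0)
  expect_equal(est$theta_Zt_hat, 0)
  # pure opening: theta_Zt = asin(chord / major)
  est2 <- estimate_tilt(c(-30, 0), c(30, 0), c(0, -30 * sin(pi / 18)),
                        c(0, 30 * sin(pi / 18)))
  expect_equal(est2$theta_Zt_hat, 10, tolerance = 1e-9)
  expect_error(estimate_tilt(c(1, 1), c(1, 1), c(0, 0), c(0, 0)),
               "degenerate")
})

test_that("simulated scans recover each 14.01-degree tilt to within 0.3 degrees", {
  run_estimate <- function(theta_Xt, theta_Zt) {
    bl <- small_axis_beamline(theta_Xt = theta_Xt, theta_Zt = theta_Zt)
    track <- track_particle(acquire_scan(bl, seq(0, 355, 5)), 1)
    m <- fit_ellipse(track)
    fp <- feature_points(m)
    estimate_tilt(c(fp$x[1], fp$y[1]), c(fp$x[2], fp$y[2]),
                  c(fp$x[3], fp$y[3]), c(fp$x[4], fp$y[4]),
                  sign_Zt = tomoalign:::orbit_zt_sign(track))
  }
  ez <- run_estimate(0, 14.01)
  expect_equal(ez$theta_Zt_hat, 14.01, tolerance = 0.3)
  expect_lt(abs(ez$theta_Xt_hat), 0.3)
  ex <- run_estimate(14.01, 0)
  expect_equal(ex$theta_Xt_hat, 14.01, tolerance = 0.3)
  expect_lt(abs(ex$theta_Zt_hat), 0.3)
})

test_that("coarse tilt recovery holds over the whole tilt grid", {
  grid <- c(2, 5, 10, 14.01)
  for (tx in grid) {
    for (tz in grid) {
      bl <- small_axis_beamline(theta_Xt = tx, theta_Zt = tz)
      rep <- coarse_align_axis(bl, 1, angles = seq(0, 355, 5))
      expect_lt(abs(rep$estimate$theta_Xt_hat - tx), 0.5)
      expect_lt(abs(rep$estimate$theta_Zt_hat - tz), 0.5)
    }
  }
  # with default jitter the estimates stay within 1.5 degrees
  bl <- small_axis_beamline(theta_Xt = 10, theta_Zt = 10, jitter_sd = 0.05)
  rep <- coarse_align_axis(bl, 1, angles = seq(0, 355, 5))
  expect_lt(abs(rep$estimate$theta_Xt_hat - 10), 1.5)
  expect_lt(abs(rep$estimate$theta_Zt_hat - 10), 1.5)
})

test_that("a negative out-of-plane tilt is corrected with the right sign", {
  bl <- small_axis_beamline(theta_Xt = 5, theta_Zt = -8)
  rep <- coarse_align_axis(bl, 1)
  expect_lt(abs(rep$residual_tilts$theta_Zt), 1)
  expect_lt(abs(rep$residual_tilts$theta_Xt), 0.5)
})

test_that("one coarse pass collapses a (14.01, 14.01) misalignment", {
  bl <- small_axis_beamline(theta_Xt = 14.01, theta_Zt = 14.01)
  rep <- coarse_align_axis(bl, 1)
  expect_lt(abs(rep$residual_tilts$theta_Zt), 1)
  expect_lt(abs(rep$residual_tilts$theta_Xt), 0.5)
  expect_lt(rep$fitness_after, rep$fitness_before)
})

test_that("an already aligned axis receives near-zero corrections", {
  bl <- small_axis_beamline(jitter_sd = 0.05)
  rep <- coarse_align_axis(bl, 1)
  expect_lt(max(abs(rep$motor_commands$value)), 0.2)
})

test_that("a fiducial within ~2 px of the axis still allows coarse correction", {
  # orbit radius ~2.06 px: particle two voxels off-axis
  bl <- small_axis_beamline(theta_Xt = 14.01, theta_Zt = 14.01,
                            jitter_sd = 0.01, pos = c(34.5, 42.5, 32.5))
  rep <- coarse_align_axis(bl, 1, angles = seq(0, 355, 5))
  expect_lt(abs(rep$residual_tilts$theta_Xt), 14.01)
  expect_lt(abs(rep$residual_tilts$theta_Zt), 14.01)
  expect_lt(rep$fitness_after, rep$fitness_before)
})

test_that("axis fitness is the vertical peak-to-peak trajectory extent", {
  flat <- tibble::tibble(angle = 0:9 * 36, u = 1:10, v = rep(4, 10),
                         in_fov = TRUE)
  expect_equal(axis_fitness(flat), 0)
  ell <- ellipse_pts(c(50, 50), 20, 5, 0, seq(0, 359))
  ell$in_fov <- TRUE
  expect_equal(axis_fitness(ell), 10, tolerance = 1e-6)
  line <- tibble::tibble(u = seq(0, 100, length.out = 50))
  line$v <- line$u * tan(10 * pi / 180)
  line$in_fov <- TRUE
  expect_equal(axis_fitness(line), 100 * tan(10 * pi / 180),
               tolerance = 1e-9)
})

test_that("GA fine alignment drives both tilts below 0.1 degrees", {
  bl <- small_axis_beamline(theta_Xt = 14.01, theta_Zt = 14.01,
                            jitter_sd = 0.05, seed = 5)
  coarse_align_axis(bl, 1)
  rep <- fine_align_axis(bl, 1,
                         ga = ga_config(bounds = list(c(0, 1), c(0, 1)),
                                        pop_size = 20, n_generations = 15,
                                        rng_seed = 7),
                         angles = seq(0, 345, 15))
  expect_lt(abs(bl$state$theta_Xt), 0.1)
  expect_lt(abs(bl$state$theta_Zt), 0.1)
  expect_true(all(diff(rep$history$best_fitness) <= 1e-12))
})

test_that("a zero search window leaves the motors where they started", {
  bl <- small_axis_beamline(theta_Xt = 1, theta_Zt = -1, jitter_sd = 0)
  before <- c(bl$state$theta_Xt, bl$state$theta_Zt)
  rep <- fine_align_axis(bl, 1,
                         ga = ga_config(bounds = list(c(0, 1), c(0, 1)),
                                        pop_size = 6, n_generations = 2,
                                        rng_seed = 1),
                         angles = seq(0, 270, 90), window = 0)
  expect_equal(c(bl$state$theta_Xt, bl$state$theta_Zt), before)
})

test_that("a larger population does no worse than the standard mode", {
  diffs <- numeric(3)
  for (i in 1:3) {
    run_mode <- function(pop) {
      bl <- small_axis_beamline(theta_Xt = 1.2, theta_Zt = -0.8,
                                jitter_sd = 0.05, seed = 30 + i)
      rep <- fine_align_axis(bl, 1,
                             ga = ga_config(bounds = list(c(0, 1), c(0, 1)),
                                            pop_size = pop,
                                            n_generations = 6,
                                            rng_seed = 50 + i),
                             angles = seq(0, 330, 30), window = 3)
      rep$best_fitness
    }
    diffs[i] <- run_mode(30) - run_mode(20)
  }
  expect_lte(median(diffs), 0)
})

test_that("coarse + fine is a contraction of the trajectory fitness", {
  withr::with_seed(13, {
    for (i in 1:4) {
      tx <- runif(1, -20, 20); tz <- runif(1, -20, 20)
      bl <- small_axis_beamline(theta_Xt = tx, theta_Zt = tz,
                                jitter_sd = 0.05, seed = 60 + i)
      initial <- axis_fitness(
        track_particle(acquire_scan(bl, seq(0, 330, 30)), 1))
      coarse_align_axis(bl, 1, angles = seq(0, 330, 30))
      rep <- fine_align_axis(bl, 1,
                             ga = ga_config(bounds = list(c(0, 1), c(0, 1)),
                                            pop_size = 10,
                                            n_generations = 5,
                                            rng_seed = 70 + i),
                             angles = seq(0, 330, 30))
      final <- axis_fitness(
        track_particle(acquire_scan(bl, seq(0, 330, 30)), 1))
      expect_lt(final, initial)
    }
  })
})
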