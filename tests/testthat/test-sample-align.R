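test_that("sample centering is symmetric, equivariant and FoV-aware", {
  vol <- make_sphere_volume(48, 12)
  det <- detector_geometry(256, 64)
  img <- project(vol, misalignment_state(), det, 0)
  got <- sample_center(img)
  expect_equal(got$u, det$u_c, tolerance = 0.1)
  img10 <- project(vol, misalignment_state(offset_x = 10), det, 0)
  expect_equal(sample_center(img10)$u, got$u + 10, tolerance = 0.1)
  blank <- sample_center(matrix(0, 8, 8))
  expect_false(blank$in_fov)
  # truncation flag when the sample touches the detector edge
  img_edge <- project(vol, misalignment_state(offset_x = 125), det, 0)
  expect_true(sample_center(img_edge)$truncated)
})

test_that("projected displacement follows the cos/sin forward model", {
  expect_equal(projected_displacement(10, 0, 0), 10)
  expect_equal(projected_displacement(10, 0, 90), 0, tolerance = 1e-12)
  expect_equal(projected_displacement(159, 104, 60),
               159 * cos(pi / 3) + 104 * sin(pi / 3), tolerance = 1e-12)
  expect_equal(round(projected_displacement(159, 104, 60), 2), 169.57)
})

test_that("offset solve inverts the forward model exactly", {
  expect_equal(as.numeric(unlist(solve_offsets(0, 90, 10))), c(10, 0))
  # paper-scale truth (159, 104): omega2 is the root of d(omega) = 0
  omega2 <- 180 / pi * atan2(159, -104)
  sol <- solve_offsets(0, omega2, 159)
  expect_equal(sol$offset_x_hat, 159, tolerance = 1e-9)
  expect_equal(sol$offset_z_hat, 104, tolerance = 1e-9)
  expect_equal(as.numeric(unlist(solve_offsets(20, 130, 0))), c(0, 0))
  expect_error(solve_offsets(45, 45, 10), "degenerate")
})

test_that("solve_offsets agrees with a least-squares fit of d(omega)", {
  withr::with_seed(8, {
    for (i in 1:10) {
      ox <- runif(1, -80, 80); oz <- runif(1, -80, 80)
      omega1 <- runif(1, 0, 60)
      # noiseless displacement observations over many angles
      om <- seq(0, 180, by = 5)
      d <- projected_displacement(ox, oz, om)
      fit <- lm(d ~ 0 + cos(om * pi / 180) + sin(om * pi / 180))
      ls <- unname(coef(fit))
      omega2 <- 180 / pi * atan2(ox, -oz)
      if (omega2 < 0) omega2 <- omega2 + 180
      sol <- solve_offsets(omega1,  omega2,
                           projected_displacement(ox, oz, omega1))
      expect_equal(sol$offset_x_hat, ls[1], tolerance = 1e-9)
      expect_equal(sol$offset_z_hat, ls[2], tolerance = 1e-9)
    }
  })
})

test_that("reference angles are found and consistent with the forward model", {
  bl <- small_blob_beamline(offset_x = 50, offset_z = 35)
  ref <- find_reference_angles(bl, step = 2)
  expect_true(ref$omega1 >= 0 && ref$omega1 <= 180)
  # omega2 is where the projected displacement vanishes
  expect_lt(abs(projected_displacement(50, 35, ref$omega2)), 2)
  expect_equal(ref$distance_omega1,
               projected_displacement(50, 35, ref$omega1), tolerance = 0.5)
  sol <- solve_offsets(ref)
  expect_equal(sol$offset_x_hat, 50, tolerance = 1)
  expect_equal(sol$offset_z_hat, 35, tolerance = 1)
})

test_that("a sample out of FoV at 0 degrees reports omega1 past the re-entry angle", {
  bl <- small_blob_beamline(offset_x = 55, offset_z = 20)
  ref <- find_reference_angles(bl, step = 2)
  scan0 <- ref$scan[ref$scan$angle == 0, ]
  expect_true(scan0$truncated)
  expect_gt(ref$omega1, 0)
  at1 <- ref$scan[ref$scan$angle == ref$omega1, ]
  expect_false(at1$truncated)
})

test_that("an already centered sample solves to near-zero offsets", {
  bl <- small_blob_beamline()
  ref <- find_reference_angles(bl, step = 2)
  expect_lt(abs(ref$distance_omega1), 0.5)
  sol <- solve_offsets(ref)
  expect_lt(abs(sol$offset_x_hat), 0.5)
  expect_lt(abs(sol$offset_z_hat), 0.5)
  rep <- coarse_align_sample(bl)
  expect_lt(max(abs(rep$motor_commands$value)), 0.5)
})

test_that("coarse alignment pulls large offsets to a few pixels", {
  bl <- small_blob_beamline(offset_x = 50, offset_z = 35)
  rep <- coarse_align_sample(bl)
  expect_lt(abs(rep$residual_offsets$offset_x), 3)
  expect_lt(abs(rep$residual_offsets$offset_z), 3)
  expect_true(all(c("omega1", "omega2", "distance_omega1") %in%
                  names(rep$reference)))
})

test_that("sample fitness is the opposing-projection center difference sum", {
  centers <- tibble::tibble(angle = c(0, 90, 180, 270),
                            u = c(130.5, 127.5, 124.5, 127.5))
  expect_equal(sample_fitness(centers), 6)  # |130.5-124.5| + 0
  centered <- tibble::tibble(angle = c(0, 90, 180, 270), u = rep(127.5, 4))
  expect_equal(sample_fitness(centered), 0)
  # pure offsets: fitness = 2|x| + 2|z| under the forward model
  ox <- 3; oz <- -2
  u <- 127.5 + projected_displacement(ox, oz, c(0, 90, 180, 270))
  expect_equal(sample_fitness(tibble::tibble(angle = c(0, 90, 180, 270),
                                             u = u)),
               2 * abs(ox) + 2 * abs(oz), tolerance = 1e-9)
  expect_error(sample_fitness(centers[1:3, ]), "missing sample center")
})

test_that("GA fine alignment reaches sub-pixel residuals from a coarse start", {
  bl <- small_blob_beamline(offset_x = 2, offset_z = 3)
  bl$stages_done <- "sample_coarse"
  rep <- fine_align_sample(bl,
                           ga = ga_config(bounds = list(c(0, 1), c(0, 1)),
                                          pop_size = 20, n_generations = 15,
                                          rng_seed = 4))
  expect_lt(abs(bl$state$offset_x), 1)
  expect_lt(abs(bl$state$offset_z), 1)
  expect_true(all(diff(rep$history$best_fitness) <= 1e-12))
})

test_that("zero window and repeated seeds give reproducible fine alignment", {
  bl <- small_blob_beamline(offset_x = 1, offset_z = -1)
  before <- c(bl$state$offset_x, bl$state$offset_z)
  fine_align_sample(bl, ga = ga_config(bounds = list(c(0, 1), c(0, 1)),
                                       pop_size = 5, n_generations = 2,
                                       rng_seed = 2), window = 0)
  expect_equal(c(bl$state$offset_x, bl$state$offset_z), before)

  run_once <- function() {
    b <- small_blob_beamline(offset_x = 2, offset_z = 1)
    r <- fine_align_sample(b, ga = ga_config(bounds = list(c(0, 1), c(0, 1)),
                                             pop_size = 8,
                                             n_generations = 4,
                                             rng_seed = 31))
    list(state = c(b$state$offset_x, b$state$offset_z),
         history = r$history)
  }
  r1 <- run_once(); r2 <- run_once()
  expect_identical(r1$state, r2$state)
  expect_identical(r1$history, r2$history)
})

test_that("caching keeps acquisitions at four projections per unique position", {
  bl <- small_blob_beamline(offset_x = 2, offset_z = 2)
  n0 <- bl$n_projections
  rep <- fine_align_sample(bl,
                           ga = ga_config(bounds = list(c(0, 1), c(0, 1)),
                                          pop_size = 12, n_generations = 10,
                                          rng_seed = 6))
  acquired <- bl$n_projections - n0
  # 4 per unique evaluation plus the final report scan
  expect_lte(acquired, 4 * (rep$evaluations + 1))
  expect_lt(acquired, 4 * 12 * 11)
  expect_gt(rep$cache_hits, 0)
})
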