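test_that("particle extraction returns intensity-weighted sub-pixel centroids", {
  img <- matrix(0, 40, 40)
  img[21, 11] <- 5            # v = 20, u = 10 (0-based)
  got <- extract_particle(img, 1)
  expect_equal(c(got$u, got$v), c(10, 20))

  img2 <- matrix(0, 40, 40)
  img2[21, 11] <- 3; img2[21, 13] <- 3
  got2 <- extract_particle(img2, 1)
  expect_equal(c(got2$u, got2$v), c(11, 20))

  blank <- extract_particle(matrix(0, 8, 8), 1)
  expect_false(blank$in_fov)
  expect_error(extract_particle(img, -1), "positive")
})

test_that("centroid extraction is translation-equivariant", {
  set.seed(42)
  img <- matrix(0, 64, 64)
  img[20:24, 30:34] <- matrix(runif(25, 1, 2), 5, 5)
  base <- extract_particle(img, 0.5)
  for (shift in list(c(3, 5), c(-4, 2))) {
    moved <- matrix(0, 64, 64)
    moved[20:24 + shift[2], 30:34 + shift[1]] <- img[20:24, 30:34]
    got <- extract_particle(moved, 0.5)
    expect_equal(got$u, base$u + shift[1])
    expect_equal(got$v, base$v + shift[2])
  }
})

test_that("tracking produces one row per angle and closes for a tilted orbit", {
  bl <- small_axis_beamline(theta_Zt = 10)
  angles <- seq(0, 360, by = 5)     # full turn including the repeat at 360
  track <- track_particle(acquire_scan(bl, angles), 1)
  expect_equal(nrow(track), length(angles))
  first <- track[1, ]; last <- track[nrow(track), ]
  expect_lt(sqrt((first$u - last$u)^2 + (first$v - last$v)^2), 1)
})

test_that("tracking a blank scan is an explicit error", {
  vol <- new_volume(array(0, c(8, 8, 8)) + 0)
  bl <- virtual_beamline(vol, detector_geometry(16, 16),
                         misalignment_state(), jitter_sd = 0)
  expect_error(track_particle(acquire_scan(bl, c(0, 90, 180, 270)), 1),
               "no trajectory")
})

test_that("the constrained conic fit recovers exact ellipse parameters", {
  pts <- ellipse_pts(c(100, 50), 40, 10, 0, seq(0, 359))
  m <- fit_ellipse(pts)
  expect_equal(m$center, c(100, 50), tolerance = 1e-6)
  expect_equal(m$a, 40, tolerance = 1e-6)
  expect_equal(m$b, 10, tolerance = 1e-6)
  expect_lt(abs(m$phi_deg), 1e-6)
})

test_that("random ellipses round-trip through the fit to < 1e-4 relative error", {
  withr::with_seed(99, {
    for (i in 1:100) {
      a <- runif(1, 10, 60)
      b <- runif(1, 1, a / 2)         # a >= 2b > 0
      phi <- runif(1, -85, 85)
      ctr <- runif(2, -50, 150)
      pts <- ellipse_pts(ctr, a, b, phi, seq(0, 350, by = 10))
      m <- fit_ellipse(pts)
      expect_lt(max(abs(m$center - ctr)) / a, 1e-4)
      expect_lt(abs(m$a - a) / a, 1e-4)
      expect_lt(abs(m$b - b) / a, 1e-4)
      expect_lt(abs(m$phi_deg - phi) / 90, 1e-4)
    }
  })
})

test_that("degenerate tracks fall back to a zero-minor-axis line model", {
  flat <- tibble::tibble(u = seq(10, 90, length.out = 20), v = rep(25, 20))
  m <- fit_ellipse(flat)
  expect_true(m$degenerate)
  expect_equal(m$b, 0)
  expect_equal(m$phi_deg, 0)

  sloped <- tibble::tibble(u = seq(0, 50, length.out = 30),
                           v = 5 + seq(0, 50, length.out = 30) * tan(pi / 9))
  m2 <- fit_ellipse(sloped)
  expect_true(m2$degenerate)
  expect_equal(m2$phi_deg, 20, tolerance = 1e-6)

  four <- tibble::tibble(u = c(0, 1, 2, 3), v = c(0, 1, 0, 1))
  expect_error(fit_ellipse(four), "at least 5")
})

test_that("feature points sit on the conic and handle canonical cases", {
  m <- tomoalign:::new_ellipse_model(c(0, 0), 2, 1, 0, n = 0, rss = 0)
  fp <- feature_points(m)
  expect_equal(fp$x, c(-2, 2, 0, 0))
  expect_equal(fp$y, c(0, 0, -1, 1))

  # vertical major axis: P3/P4 are the two intersection roots at x = 0
  mv <- tomoalign:::new_ellipse_model(c(0, 0), 2, 1, 90, n = 0, rss = 0)
  fpv <- feature_points(mv)
  expect_equal(fpv$x[1:2], c(0, 0), tolerance = 1e-9)
  expect_equal(sort(fpv$y[1:2]), c(-2, 2), tolerance = 1e-9)
  expect_equal(sort(fpv$y[3:4]), c(-2, 2), tolerance = 1e-6)

  # line model: P3 = P4 = center
  ml <- tomoalign:::new_ellipse_model(c(5, 7), 10, 0, 15, n = 0, rss = 0,
                                      degenerate = TRUE)
  fpl <- feature_points(ml)
  expect_equal(fpl$x[3:4], c(5, 5))
  expect_equal(fpl$y[3:4], c(7, 7))

  # property: P1..P4 satisfy the conic equation of their model
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- runif(1, 5, 40); b <- runif(1, 1, a)
      mm <- tomoalign:::new_ellipse_model(runif(2, -20, 20), a, b,
                                          runif(1, -89, 89), n = 0, rss = 0)
      fpp <- feature_points(mm)
      k <- mm$conic
      res <- k[1] * fpp$x^2 + k[2] * fpp$x * fpp$y + k[3] * fpp$y^2 +
        k[4] * fpp$x + k[5] * fpp$y + k[6]
      expect_lt(max(abs(res)), 1e-6)
    }
  })
})

test_that("tidy and glance summarise a fitted ellipse", {
  pts <- ellipse_pts(c(10, 20), 30, 12, 25, seq(0, 350, 10))
  m <- fit_ellipse(pts)
  td <- tidy(m)
  expect_equal(td$term, c("u0", "v0", "a", "b", "phi_deg"))
  gl <- glance(m)
  expect_equal(gl$a, 30, tolerance = 1e-6)
  expect_false(gl$degenerate)
})
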