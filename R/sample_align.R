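#' Horizontal center of the sample in a projection image
#'
#' The sample center is the intensity-weighted horizontal centroid of all
#' pixels above a background threshold. When the above-threshold mask
#' touches the detector edge the sample is truncated by the field of view
#' and the centroid of the visible part is returned with
#' `truncated = TRUE`.
#'
#' @param image `nv x nu` numeric matrix.
#' @param threshold background threshold; defaults to 0.5% of the image
#'   maximum.
#' @return One-row tibble with `u`, `v` (0-based pixel coordinates, `NA`
#'   when the image is empty), `in_fov` and `truncated`.
#' @export
sample_center <- function(image, threshold = NULL) {
  if (is.null(threshold)) threshold <- 0.005 * max(image)
  sel <- which(image > threshold)
  if (length(sel) == 0L || max(image) <= 0)
    return(tibble(u = NA_real_, v = NA_real_, in_fov = FALSE,
                  truncated = FALSE))
  w <- image[sel]
  ai <- arrayInd(sel, dim(image))
  truncated <- any(ai[, 2] == 1L) || any(ai[, 2] == ncol(image)) ||
    any(ai[, 1] == 1L) || any(ai[, 1] == nrow(image))
  tibble(u = sum((ai[, 2] - 1) * w) / sum(w),
         v = sum((ai[, 1] - 1) * w) / sum(w),
         in_fov = TRUE, truncated = truncated)
}

#' Horizontal displacement of an offset sample at a projection angle
#'
#' The forward model of the coarse solve: an in-plane sample offset
#' `(offset_x, offset_z)` displaces the projected sample center
#' horizontally by `d(omega) = offset_x * cos(omega) + offset_z *
#' sin(omega)` pixels.
#'
#' @param offset_x,offset_z sample offsets in pixels.
#' @param omega projection angle in degrees (vectorised).
#' @return Displacement in pixels.
#' @export
projected_displacement <- function(offset_x, offset_z, omega) {
  stopifnot(all(is.finite(c(offset_x, offset_z, omega))))
  offset_x * cos(deg2rad(omega)) + offset_z * sin(deg2rad(omega))
}

#' Find the reference angles for the coarse sample solve
#'
#' Scans 0-180 degrees at the coarse step and extracts the two reference
#' observations: `omega1`, the first angle at which the sample is entirely
#' inside the field of view (no above-threshold pixel touching the detector
#' edge), and `omega2`, the angle (linearly interpolated between scan
#' samples) at which the sample center crosses the detector center.
#' `distance_omega1` is the signed horizontal distance between sample
#' center and detector center at `omega1`.
#'
#' @param bl a [virtual_beamline()].
#' @param step coarse scan step in degrees.
#' @param threshold background threshold for [sample_center()].
#' @return A list of class `offset_solve` with `omega1`, `omega2`,
#'   `distance_omega1` and the per-angle `scan` tibble.
#' @export
find_reference_angles <- function(bl, step = 2, threshold = NULL) {
  stopifnot(inherits(bl, "virtual_beamline"))
  angles <- seq(0, 180, by = step)
  stack <- acquire_scan(bl, angles)
  scan <- purrr::map2_dfr(stack$images, angles, function(img, a)
    dplyr::mutate(sample_center(img, threshold), angle = a, .before = 1))
  if (!any(scan$in_fov))
    stop_bad("sample not visible at any projection angle", "sample_error")
  full <- scan$in_fov & !scan$truncated
  if (!any(full))
    stop_bad(paste("sample never fully inside the field of view between 0",
                   "and 180 degrees; move the sample manually (set-motor)",
                   "before coarse alignment"), "sample_error")
  i1 <- which(full)[1]
  omega1 <- scan$angle[i1]
  u_c <- bl$det$u_c
  distance_omega1 <- scan$u[i1] - u_c
  # center crossing of the detector center, among measurable frames
  d <- scan$u - u_c
  omega2 <- NA_real_
  meas <- which(scan$in_fov)
  for (j in seq_along(meas)[-1]) {
    a <- meas[j - 1]; b <- meas[j]
    if (b - a == 1L && is.finite(d[a]) && is.finite(d[b]) &&
        d[a] * d[b] <= 0 && d[a] != d[b]) {
      frac <- d[a] / (d[a] - d[b])
      omega2 <- scan$angle[a] + frac * (scan$angle[b] - scan$angle[a])
      break
    }
  }
  if (!is.finite(omega2)) {
    if (abs(distance_omega1) < 0.5) {
      omega2 <- omega1 + 90   # already centered; any non-singular pair
    } else {
      omega2 <- scan$angle[which.min(abs(d))]
    }
  }
  structure(list(omega1 = omega1, omega2 = omega2,
                 distance_omega1 = distance_omega1, scan = scan),
            class = "offset_solve")
}

#' @export
print.offset_solve <- function(x, ...) {
  cat(sprintf("<offset_solve> omega1 = %g deg, omega2 = %g deg, distance_omega1 = %.3f px\n",
              x$omega1, x$omega2, x$distance_omega1))
  invisible(x)
}

#' Solve the in-plane sample offsets from the reference angles
#'
#' Inverts the forward model at the two reference observations
#' `d(omega1) = distance_omega1` and `d(omega2) = 0`:
#' `offset_x = distance_omega1 * sin(omega2) / sin(omega2 - omega1)` and
#' `offset_z = -distance_omega1 * cos(omega2) / sin(omega2 - omega1)`.
#'
#' @param omega1,omega2 reference angles in degrees (or an `offset_solve`
#'   as the first argument).
#' @param distance_omega1 signed center distance at `omega1`, pixels.
#' @return A tibble with `offset_x_hat` and `offset_z_hat` in pixels.
#' @export
solve_offsets <- function(omega1, omega2 = NULL, distance_omega1 = NULL) {
  if (inherits(omega1, "offset_solve")) {
    ref <- omega1
    omega1 <- ref$omega1; omega2 <- ref$omega2
    distance_omega1 <- ref$distance_omega1
  }
  s <- sin(deg2rad(omega2 - omega1))
  if (abs(s) < 1e-9)
    stop_bad("reference angles degenerate: omega1 and omega2 coincide",
             "sample_error")
  tibble(
    offset_x_hat = distance_omega1 * sin(deg2rad(omega2)) / s,
    offset_z_hat = -distance_omega1 * cos(deg2rad(omega2)) / s)
}

cardinal_centers <- function(bl, threshold = NULL) {
  stack <- acquire_scan(bl, c(0, 90, 180, 270))
  purrr::map2_dfr(stack$images, stack$angles, function(img, a)
    dplyr::mutate(sample_center(img, threshold), angle = a, .before = 1))
}

#' Coarse sample alignment
#'
#' Runs [find_reference_angles()] and [solve_offsets()], then commands
#' motors x and z by the negated offset estimates. The report records the
#' sample centers at 0/90/180/270 degrees before committing to the fine
#' stage.
#'
#' @param bl a [virtual_beamline()].
#' @param step coarse scan step in degrees.
#' @param threshold background threshold for [sample_center()].
#' @return An `alignment_report` with the solve, motor commands and
#'   residual cardinal-angle centers.
#' @export
coarse_align_sample <- function(bl, step = 2, threshold = NULL) {
  stopifnot(inherits(bl, "virtual_beamline"))
  ref <- find_reference_angles(bl, step = step, threshold = threshold)
  sol <- solve_offsets(ref)
  x_cmd <- bl$state$offset_x - sol$offset_x_hat
  z_cmd <- bl$state$offset_z - sol$offset_z_hat
  beamline_move(bl, "x", x_cmd)
  beamline_move(bl, "z", z_cmd)
  centers <- cardinal_centers(bl, threshold)
  bl$stages_done <- union(bl$stages_done, "sample_coarse")
  structure(list(
    stage = "sample_coarse",
    reference = ref[c("omega1", "omega2", "distance_omega1")],
    solve = sol,
    motor_commands = tibble(motor = c("x", "z"), value = c(x_cmd, z_cmd)),
    cardinal_centers = centers,
    residual_offsets = tibble(offset_x = bl$state$offset_x,
                              offset_z = bl$state$offset_z),
    evaluations = NA_integer_,
    n_projections = bl$n_projections),
    class = "alignment_report")
}

#' Opposing-projection fitness for the sample GA
#'
#' The fitness of a candidate sample position is the sum of the difference
#' between the sample center at 90 and 270 degrees and the difference
#' between the sample center at 0 and 180 degrees:
#' `|u(0) - u(180)| + |u(90) - u(270)|`. Under the forward model this
#' equals `2 |offset_x| + 2 |offset_z|`, so it is zero exactly when the
#' sample sits on the rotation axis.
#'
#' @param centers tibble with columns `angle` and `u` containing the four
#'   cardinal angles 0, 90, 180, 270.
#' @return Non-negative scalar, in pixels; `Inf` if any center is missing.
#' @export
sample_fitness <- function(centers) {
  u_at <- function(a) {
    i <- which(centers$angle == a)
    if (length(i) != 1L)
      stop_bad(sprintf("missing sample center at %g degrees", a),
               "sample_error")
    centers$u[i]
  }
  u0 <- u_at(0); u90 <- u_at(90); u180 <- u_at(180); u270 <- u_at(270)
  if (!all(is.finite(c(u0, u90, u180, u270)))) return(Inf)
  abs(u0 - u180) + abs(u90 - u270)
}

#' Fine sample alignment by genetic algorithm
#'
#' Optimises the absolute positions of motors x and z inside a
#' `+/- window` box around the coarsely aligned position. Each candidate
#' acquires the four cardinal projections (0/90/180/270 degrees) and is
#' scored by [sample_fitness()]; images for previously visited motor
#' positions are reused through the evaluation cache rather than
#' re-acquired. The best individual's move is committed.
#'
#' @param bl a [virtual_beamline()], already coarse-aligned.
#' @param ga a [ga_config()]; its `bounds` are overridden by the window.
#' @param threshold background threshold for [sample_center()].
#' @param window half-width of the search box in pixels on each motor.
#' @return An `alignment_report` with GA history, evaluation counts,
#'   cardinal centers and residual offset readbacks.
#' @export
fine_align_sample <- function(bl, ga = ga_config(bounds = NULL),
                              threshold = NULL, window = 8) {
  stopifnot(inherits(bl, "virtual_beamline"))
  x0 <- bl$state$offset_x
  z0 <- bl$state$offset_z
  cfg <- ga
  cfg$bounds <- list(x = c(x0 - window, x0 + window),
                     z = c(z0 - window, z0 + window))
  fitness <- function(pos) {
    beamline_move(bl, "x", pos[1])
    beamline_move(bl, "z", pos[2])
    sample_fitness(cardinal_centers(bl, threshold))
  }
  res <- ga_evolve(fitness, cfg, initial = list(c(x0, z0)))
  beamline_move(bl, "x", res$best$values[1])
  beamline_move(bl, "z", res$best$values[2])
  bl$stages_done <- union(bl$stages_done, "sample_fine")
  structure(list(
    stage = "sample_fine",
    motor_commands = tibble(motor = c("x", "z"), value = res$best$values),
    ga = res,
    history = res$history,
    best_fitness = res$best$fitness,
    evaluations = res$n_evaluations,
    cache_hits = res$cache_hits,
    cardinal_centers = cardinal_centers(bl, threshold),
    residual_offsets = tibble(offset_x = bl$state$offset_x,
                              offset_z = bl$state$offset_z),
    n_projections = bl$n_projections),
    class = "alignment_report")
}
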