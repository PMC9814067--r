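#' Estimate the rotation-axis tilt from the ellipse feature points
#'
#' A fiducial circling the rotation axis at radius `r` projects onto the
#' detector as an ellipse with semi-major axis `r`, semi-minor axis
#' `r * sin(theta_Zt)` and major-axis inclination `theta_Xt`. The in-plane
#' tilt is therefore the inclination of the major-axis segment P1->P2 and
#' the out-of-plane tilt the arcsine of the vertical center chord |y4 - y3|
#' over the major-axis length |P2 - P1|. The chord ratio is unsigned, so
#' the sign of `theta_Zt_hat` must come from the orbit's sense of traversal
#' (see [coarse_align_axis()]); this function reports it with the sign of
#' `sign_Zt`.
#'
#' @param p1,p2 major-axis vertices `(x, y)`; `p2` in the +major direction.
#' @param p3,p4 the two ellipse points at the x-coordinate of the ellipse
#'   center.
#' @param sign_Zt sign (+1/-1) to attach to the out-of-plane estimate.
#' @return A tibble with `theta_Xt_hat` and `theta_Zt_hat` in degrees.
#' @export
estimate_tilt <- function(p1, p2, p3, p4, sign_Zt = 1) {
  major <- sqrt(sum((p2 - p1)^2))
  if (major <= .Machine$double.eps)
    stop_bad("degenerate feature points: P1 and P2 coincide", "axis_error")
  theta_Xt <- rad2deg(atan2(p2[2] - p1[2], p2[1] - p1[1]))
  ratio <- min(abs(p4[2] - p3[2]) / major, 1)
  theta_Zt <- sign(sign_Zt) * rad2deg(asin(ratio))
  tibble(theta_Xt_hat = theta_Xt, theta_Zt_hat = theta_Zt)
}

# Sign of theta_Zt from the orbit's sense of traversal: regress u(angle)
# and v(angle) on first harmonics; the determinant of the 2x2 harmonic
# coefficient matrix equals r^2 sin(theta_Zt) up to a positive factor and
# is invariant to the (unknown) particle phase.
orbit_zt_sign <- function(track) {
  df <- track[track$in_fov, ]
  th <- deg2rad(df$angle)
  X <- cbind(1, cos(th), sin(th))
  cu <- stats::lm.fit(X, df$u)$coefficients
  cv <- stats::lm.fit(X, df$v)$coefficients
  d <- unname(cu[2] * cv[3] - cu[3] * cv[2])
  if (!is.finite(d) || d == 0) 1 else sign(d)
}

#' Trajectory-flatness fitness for the axis GA
#'
#' The ideal trajectory of the fiducial over a full turn is a horizontal
#' straight line; this fitness is the vertical peak-to-peak extent of the
#' track in pixels, which is zero exactly at that ideal and grows with both
#' tilt modes.
#'
#' @param track a `particle_track` (in-FoV points are used).
#' @return Non-negative scalar, in pixels.
#' @export
axis_fitness <- function(track) {
  v <- track$v[track$in_fov]
  if (length(v) == 0L) return(Inf)
  max(v) - min(v)
}

#' Coarse rotation-axis alignment
#'
#' Runs one full-turn scan, tracks the fiducial, fits the trajectory
#' ellipse, estimates the two tilt angles from the feature points P1-P4 and
#' commands the correction `nu <- nu - theta_Xt_hat`,
#' `mu <- mu - theta_Zt_hat`. A second scan records the corrected
#' trajectory.
#'
#' @param bl a [virtual_beamline()] holding a fiducial-bearing specimen.
#' @param threshold grayscale threshold isolating the fiducial.
#' @param angles full-turn scan angles in degrees.
#' @return A list of class `alignment_report` with the tilt estimate, the
#'   motor commands, before/after tracks and fitness, and residual tilt
#'   readbacks.
#' @export
coarse_align_axis <- function(bl, threshold,
                              angles = seq(0, 355, by = 5)) {
  stopifnot(inherits(bl, "virtual_beamline"))
  stack <- acquire_scan(bl, angles)
  track_before <- track_particle(stack, threshold)
  model <- fit_ellipse(track_before)
  fp <- feature_points(model)
  pts <- setNames(lapply(seq_len(4), function(i) c(fp$x[i], fp$y[i])),
                  fp$point)
  est <- estimate_tilt(pts$P1, pts$P2, pts$P3, pts$P4,
                       sign_Zt = orbit_zt_sign(track_before))
  nu_cmd <- bl$state$theta_Xt - est$theta_Xt_hat
  mu_cmd <- bl$state$theta_Zt - est$theta_Zt_hat
  beamline_move(bl, "nu", nu_cmd)
  beamline_move(bl, "mu", mu_cmd)
  track_after <- track_particle(acquire_scan(bl, angles), threshold)
  bl$stages_done <- union(bl$stages_done, "axis_coarse")
  structure(list(
    stage = "axis_coarse",
    estimate = est,
    ellipse = model,
    feature_points = fp,
    motor_commands = tibble(motor = c("nu", "mu"),
                            value = c(nu_cmd, mu_cmd)),
    track_before = track_before,
    track_after = track_after,
    fitness_before = axis_fitness(track_before),
    fitness_after = axis_fitness(track_after),
    residual_tilts = tibble(theta_Xt = bl$state$theta_Xt,
                            theta_Zt = bl$state$theta_Zt),
    evaluations = NA_integer_,
    n_projections = bl$n_projections),
    class = "alignment_report")
}

#' Fine rotation-axis alignment by genetic algorithm
#'
#' Optimises the absolute positions of motors mu and nu inside a
#' `+/- window` box around the coarsely aligned position. Each candidate is
#' evaluated by acquiring a scan and scoring [axis_fitness()] on the
#' fiducial track; repeated candidate positions are served from the GA's
#' evaluation cache without new acquisitions. The best individual is
#' committed to the motors.
#'
#' @param bl a [virtual_beamline()], already coarse-aligned.
#' @param threshold grayscale threshold isolating the fiducial.
#' @param ga a [ga_config()]; its `bounds` are overridden by the window
#'   around the current motor positions.
#' @param angles scan angles used for each fitness evaluation.
#' @param window half-width of the search box in degrees on each motor.
#' @return An `alignment_report` with the GA history (best fitness per
#'   generation is non-increasing under elitism), evaluation counts and
#'   final tilt readbacks.
#' @export
fine_align_axis <- function(bl, threshold, ga = ga_config(bounds = NULL),
                            angles = seq(0, 345, by = 15), window = 3) {
  stopifnot(inherits(bl, "virtual_beamline"))
  mu0 <- bl$state$theta_Zt
  nu0 <- bl$state$theta_Xt
  cfg <- ga
  cfg$bounds <- list(mu = c(mu0 - window, mu0 + window),
                     nu = c(nu0 - window, nu0 + window))
  fitness <- function(pos) {
    beamline_move(bl, "mu", pos[1])
    beamline_move(bl, "nu", pos[2])
    track <- track_particle(acquire_scan(bl, angles), threshold)
    axis_fitness(track)
  }
  res <- ga_evolve(fitness, cfg, initial = list(c(mu0, nu0)))
  beamline_move(bl, "mu", res$best$values[1])
  beamline_move(bl, "nu", res$best$values[2])
  bl$stages_done <- union(bl$stages_done, "axis_fine")
  structure(list(
    stage = "axis_fine",
    motor_commands = tibble(motor = c("mu", "nu"),
                            value = res$best$values),
    ga = res,
    history = res$history,
    best_fitness = res$best$fitness,
    evaluations = res$n_evaluations,
    cache_hits = res$cache_hits,
    residual_tilts = tibble(theta_Xt = bl$state$theta_Xt,
                            theta_Zt = bl$state$theta_Zt),
    n_projections = bl$n_projections),
    class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> stage %s\n", x$stage))
  if (!is.null(x$residual_tilts))
    cat(sprintf("  residual tilts: theta_Xt = %.4g deg, theta_Zt = %.4g deg\n",
                x$residual_tilts$theta_Xt, x$residual_tilts$theta_Zt))
  if (!is.null(x$residual_offsets))
    cat(sprintf("  residual offsets: x = %.4g px, z = %.4g px\n",
                x$residual_offsets$offset_x, x$residual_offsets$offset_z))
  if (!is.null(x$best_fitness))
    cat(sprintf("  best fitness %.6g after %d evaluations\n",
                x$best_fitness, x$evaluations))
  invisible(x)
}
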