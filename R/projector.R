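#' Detector geometry
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner,
#' `u` horizontal and `v` vertical; pixel centers sit at integer
#' coordinates.
#'
#' @param nu,nv detector width and height in pixels (>= 2).
#' @param u_c,v_c detector center in pixel coordinates; defaults to the
#'   geometric center `(n - 1) / 2`.
#' @return A list of class `detector_geometry`.
#' @export
detector_geometry <- function(nu, nv, u_c = (nu - 1) / 2,
                              v_c = (nv - 1) / 2) {
  nu <- as.integer(nu); nv <- as.integer(nv)
  if (nu < 2L || nv < 2L)
    stop_bad("detector must be at least 2 x 2 pixels", "geometry_error")
  if (u_c < 0 || u_c >= nu || v_c < 0 || v_c >= nv)
    stop_bad("detector center must lie inside the detector", "geometry_error")
  structure(list(nu = nu, nv = nv, u_c = u_c, v_c = v_c),
            class = "detector_geometry")
}

#' Misalignment state of the virtual sample stage
#'
#' The four virtual-motor error terms: two rotation-axis tilt angles and two
#' in-plane sample offsets. `theta_Xt` is the in-detector-plane tilt of the
#' rotation axis (axis leaning sideways within the detector plane, corrected
#' by motor nu); `theta_Zt` is the out-of-plane tilt toward/away from the
#' beam (corrected by motor mu). `offset_x` displaces the sample
#' perpendicular to the beam, `offset_z` along the beam, both in detector
#' pixels and applied in the rotating sample frame.
#'
#' @param theta_Xt,theta_Zt tilt angles in degrees, `|tilt| < 90`.
#' @param offset_x,offset_z sample offsets in pixels.
#' @return A list of class `misalignment_state`.
#' @export
misalignment_state <- function(theta_Xt = 0, theta_Zt = 0,
                               offset_x = 0, offset_z = 0) {
  vals <- c(theta_Xt, theta_Zt, offset_x, offset_z)
  if (!all(is.finite(vals)))
    stop_bad("all misalignment terms must be finite", "state_error")
  if (abs(theta_Xt) >= 90 || abs(theta_Zt) >= 90)
    stop_bad("tilt angles must satisfy |tilt| < 90 degrees", "state_error")
  structure(list(theta_Xt = unname(theta_Xt), theta_Zt = unname(theta_Zt),
                 offset_x = unname(offset_x), offset_z = unname(offset_z)),
            class = "misalignment_state")
}

#' @export
print.misalignment_state <- function(x, ...) {
  cat(sprintf(
    "<misalignment_state> theta_Xt = %.4g deg, theta_Zt = %.4g deg, offset_x = %.4g px, offset_z = %.4g px\n",
    x$theta_Xt, x$theta_Zt, x$offset_x, x$offset_z))
  invisible(x)
}

#' Command a virtual motor to an absolute position
#'
#' Motor `mu` sets the out-of-plane tilt `theta_Zt`, motor `nu` the in-plane
#' tilt `theta_Xt`; motors `x` and `z` set the sample offsets. Moves are
#' absolute-position commands.
#'
#' @param state a [misalignment_state()].
#' @param motor one of `"mu"`, `"nu"`, `"x"`, `"z"`.
#' @param value target position (degrees for tilts, pixels for offsets).
#' @return The updated [misalignment_state()].
#' @export
move_motor <- function(state, motor, value) {
  stopifnot(inherits(state, "misalignment_state"))
  if (!is.finite(value))
    stop_bad("motor target must be finite", "motor_error")
  switch(motor,
    mu = misalignment_state(state$theta_Xt, value,
                            state$offset_x, state$offset_z),
    nu = misalignment_state(value, state$theta_Zt,
                            state$offset_x, state$offset_z),
    x  = misalignment_state(state$theta_Xt, state$theta_Zt,
                            value, state$offset_z),
    z  = misalignment_state(state$theta_Xt, state$theta_Zt,
                            state$offset_x, value),
    stop_bad(sprintf("unknown motor '%s' (use mu, nu, x or z)", motor),
             "motor_error"))
}

rot_y <- function(th) {
  c <- cos(th); s <- sin(th)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
}
rot_x <- function(th) {
  c <- cos(th); s <- sin(th)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}
rot_z <- function(th) {
  c <- cos(th); s <- sin(th)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Full rigid transform from sample frame (relative to the rotation-axis
# pivot) to lab frame: rotate by `angle` about the nominal vertical axis,
# then tilt the whole assembly by (theta_Xt about the beam-facing z-axis,
# theta_Zt about the horizontal x-axis). Beam runs along lab +z; the
# detector reads u = lab x, v = lab y.
alignment_rotation <- function(theta_Xt_deg, theta_Zt_deg, angle_deg) {
  rot_z(deg2rad(theta_Xt_deg)) %*% rot_x(deg2rad(theta_Zt_deg)) %*%
    rot_y(deg2rad(angle_deg))
}

# Sparse representation of a volume: coordinates of nonzero voxels relative
# to the rotation-axis pivot (volume center), and their values scaled by
# voxel size (so splatting approximates line integrals).
volume_points <- function(volume) {
  vox <- volume$voxels
  idx <- which(vox != 0)
  if (length(idx) == 0L)
    return(list(pts = matrix(numeric(0), 0, 3), val = numeric(0)))
  d <- dim(vox)
  ai <- arrayInd(idx, d)
  ctr <- (d + 1) / 2
  pts <- sweep(ai, 2, ctr) * volume$voxel_size
  list(pts = pts, val = vox[idx] * volume$voxel_size)
}

project_points <- function(pp, state, det, angle, jitter = c(0, 0)) {
  R <- alignment_rotation(state$theta_Xt + jitter[1],
                          state$theta_Zt + jitter[2], angle)
  off <- R %*% c(state$offset_x, 0, state$offset_z)
  splat_project(pp$pts, pp$val, R,
                det$u_c + off[1], det$v_c + off[2], det$nu, det$nv)
}

#' Render one parallel-beam projection image
#'
#' Computes the parallel-beam line integrals of the volume after applying
#' the sample offsets in the rotating sample frame, rotating by `angle`
#' about the rotation axis, and tilting the axis by
#' `(theta_Xt, theta_Zt)`. Angles are in degrees, counter-clockwise viewed
#' from the top; at angle 0 the beam axis is the volume's third axis and
#' `u` increases with the volume's first axis. Mass projecting outside the
#' detector is clipped (field-of-view truncation).
#'
#' @param volume a [new_volume()].
#' @param state a [misalignment_state()].
#' @param det a [detector_geometry()].
#' @param angle projection angle in degrees.
#' @param jitter optional per-projection tilt perturbation
#'   `c(d_theta_Xt, d_theta_Zt)` in degrees.
#' @return An `nv x nu` numeric matrix (row = v, column = u).
#' @export
project <- function(volume, state, det, angle, jitter = c(0, 0)) {
  stopifnot(inherits(volume, "tomo_volume"),
            inherits(state, "misalignment_state"),
            inherits(det, "detector_geometry"))
  if (!is.finite(angle))
    stop_bad("projection angle must be finite", "projector_error")
  project_points(volume_points(volume), state, det, angle, jitter)
}

new_projection_stack <- function(angles, images, det) {
  structure(list(angles = angles, images = images, det = det),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("<projection_stack> %d projections, %d x %d px, angles [%g, %g] deg\n",
              length(x$angles), x$det$nv, x$det$nu,
              min(x$angles), max(x$angles)))
  invisible(x)
}

#' @export
length.projection_stack <- function(x) length(x$angles)
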