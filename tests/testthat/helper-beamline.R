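# Shared fixtures and independent oracles, built in code at test time.

# Closed-form rigid-transform + orthographic-projection oracle for a single
# point mass, written out explicitly (independent of the splat projector).
# p_rel: point coordinates relative to the rotation-axis pivot, sample frame.
oracle_project_point <- function(p_rel, state, det, angle_deg) {
  d2r <- pi / 180
  p <- p_rel + c(state$offset_x, 0, state$offset_z)
  a <- angle_deg * d2r
  p <- c(p[1] * cos(a) + p[3] * sin(a), p[2],
         -p[1] * sin(a) + p[3] * cos(a))
  b <- state$theta_Zt * d2r
  p <- c(p[1], p[2] * cos(b) - p[3] * sin(b), p[2] * sin(b) + p[3] * cos(b))
  g <- state$theta_Xt * d2r
  p <- c(p[1] * cos(g) - p[2] * sin(g), p[1] * sin(g) + p[2] * cos(g), p[3])
  c(u = det$u_c + p[1], v = det$v_c + p[2])
}

# volume with a single nonzero voxel (a true point mass for the oracle)
make_point_volume <- function(grid_shape, pos, value = 50) {
  vox <- array(0, dim = grid_shape)
  vox[pos[1], pos[2], pos[3]] <- value
  new_volume(vox)
}

# exact points on an ellipse, detector convention
ellipse_pts <- function(center, a, b, phi_deg, t_deg) {
  t <- t_deg * pi / 180
  phi <- phi_deg * pi / 180
  x <- center[1] + a * cos(t) * cos(phi) - b * sin(t) * sin(phi)
  y <- center[2] + a * cos(t) * sin(phi) + b * sin(t) * cos(phi)
  tibble::tibble(u = x, v = y)
}

# a centered solid sphere volume
make_sphere_volume <- function(n, radius, value = 1) {
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  vox <- array(0, dim = c(n, n, n))
  sel <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= radius^2
  vox[cbind(g$x, g$y, g$z)[sel, , drop = FALSE]] <- value
  new_volume(vox)
}

# small fiducial beamline used across axis-alignment tests: particle on a
# 64^3 grid, orbit radius ~20 px horizontally, 10 px above the pivot plane
small_axis_beamline <- function(theta_Xt = 0, theta_Zt = 0,
                                jitter_sd = 0, seed = 7,
                                pos = c(52.5, 42.5, 32.5)) {
  vol <- make_point_volume(c(64, 64, 64), round(pos))
  virtual_beamline(vol, detector_geometry(160, 160),
                   misalignment_state(theta_Xt = theta_Xt,
                                      theta_Zt = theta_Zt),
                   jitter_sd = jitter_sd, seed = seed)
}

# small blob beamline for sample-alignment tests
small_blob_beamline <- function(offset_x = 0, offset_z = 0, seed = 11,
                                grid = 48, det = detector_geometry(128, 64),
                                jitter_sd = 0.05, blob_seed = 3) {
  vol <- make_blob_phantom(phantom_spec("blob_with_particle",
                                        rep(grid, 3), rng_seed = blob_seed))
  virtual_beamline(vol, det,
                   misalignment_state(offset_x = offset_x,
                                      offset_z = offset_z),
                   jitter_sd = jitter_sd, seed = seed)
}
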