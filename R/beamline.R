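#' Create a virtual tomography beamline
#'
#' The virtual beamline bundles a specimen volume, a detector, the current
#' misalignment state and an optional per-projection rotation-axis jitter.
#' It exposes the same surface a real instrument would: motor moves,
#' projection acquisition, position readback, plus an acquisition counter
#' used to audit how many projections an alignment strategy costs.
#'
#' Jitter emulates rotation-stage noise: at each projection angle a
#' zero-mean perturbation (standard deviation `jitter_sd` degrees) is added
#' to both tilt angles. The perturbation is a deterministic, seeded function
#' of the angle, so re-acquiring the same angle reproduces the same image.
#'
#' @param volume a [new_volume()] specimen.
#' @param det a [detector_geometry()].
#' @param state initial [misalignment_state()].
#' @param jitter_sd per-projection axis jitter, standard deviation in
#'   degrees (0 disables jitter).
#' @param seed integer seed for the jitter stream.
#' @return An environment of class `virtual_beamline`.
#' @export
virtual_beamline <- function(volume, det, state = misalignment_state(),
                             jitter_sd = 0.05, seed = 1L) {
  stopifnot(inherits(volume, "tomo_volume"),
            inherits(det, "detector_geometry"),
            inherits(state, "misalignment_state"))
  bl <- new.env(parent = emptyenv())
  bl$volume <- volume
  bl$points <- volume_points(volume)
  bl$det <- det
  bl$state <- state
  bl$jitter_sd <- jitter_sd
  bl$seed <- as.integer(seed) %% 100003L
  bl$n_projections <- 0L
  bl$n_scans <- 0L
  bl$stages_done <- character(0)
  class(bl) <- "virtual_beamline"
  bl
}

#' @export
print.virtual_beamline <- function(x, ...) {
  cat("<virtual_beamline>\n")
  print(x$state)
  cat(sprintf("  detector %d x %d px, jitter_sd = %g deg, %d projections acquired\n",
              x$det$nv, x$det$nu, x$jitter_sd, x$n_projections))
  invisible(x)
}

# Deterministic per-angle jitter: a seeded hash of the angle mapped through
# the normal quantile function. Identical (seed, angle) pairs always give
# the identical perturbation.
angle_jitter <- function(angles, sd, seed, channel) {
  if (sd <= 0) return(rep(0, length(angles)))
  h <- sin((angles + 0.12345) * (12.9898 + 7.13 * channel) +
             seed * 0.6180339887) * 43758.5453
  u <- h - floor(h)
  u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
  sd * stats::qnorm(u)
}

#' Acquire a projection scan on the virtual beamline
#'
#' Renders one projection per angle under the beamline's current
#' misalignment state (with its per-angle jitter) and increments the
#' acquisition counter by the number of projections rendered. Rendering is
#' stateless: repeating the same call yields an identical stack.
#'
#' @param bl a [virtual_beamline()].
#' @param angles projection angles in degrees (at least one; alignment
#'   scans use at least 4).
#' @return A `projection_stack`: angle-ordered list of detector images.
#' @export
acquire_scan <- function(bl, angles) {
  stopifnot(inherits(bl, "virtual_beamline"))
  if (length(angles) < 1L)
    stop_bad("at least one projection angle is required", "scan_error")
  if (!all(is.finite(angles)))
    stop_bad("projection angles must be finite", "scan_error")
  jx <- angle_jitter(angles, bl$jitter_sd, bl$seed, channel = 1)
  jz <- angle_jitter(angles, bl$jitter_sd, bl$seed, channel = 2)
  images <- lapply(seq_along(angles), function(i)
    project_points(bl$points, bl$state, bl$det, angles[i],
                   jitter = c(jx[i], jz[i])))
  bl$n_projections <- bl$n_projections + length(angles)
  bl$n_scans <- bl$n_scans + 1L
  new_projection_stack(angles, images, bl$det)
}

#' Move a beamline motor (absolute position)
#'
#' @param bl a [virtual_beamline()].
#' @param motor one of `"mu"`, `"nu"`, `"x"`, `"z"` (see [move_motor()]).
#' @param value absolute target position.
#' @return The beamline, invisibly.
#' @export
beamline_move <- function(bl, motor, value) {
  stopifnot(inherits(bl, "virtual_beamline"))
  bl$state <- move_motor(bl$state, motor, value)
  invisible(bl)
}

#' Read back the beamline motor positions
#'
#' @param bl a [virtual_beamline()].
#' @return The current [misalignment_state()].
#' @export
beamline_state <- function(bl) {
  stopifnot(inherits(bl, "virtual_beamline"))
  bl$state
}
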