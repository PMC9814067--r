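#' Locate the fiducial particle in one projection image
#'
#' The strongly absorbing particle is isolated with a grayscale threshold
#' and located by the intensity-weighted centroid of all pixels above it,
#' giving sub-pixel detector coordinates.
#'
#' @param image `nv x nu` numeric matrix (row = v, column = u).
#' @param threshold grayscale threshold (> 0); pixels strictly above it
#'   belong to the particle.
#' @return A one-row tibble with columns `u`, `v` (0-based pixel
#'   coordinates) and `in_fov`; `u`, `v` are `NA` when no pixel exceeds the
#'   threshold (particle out of the field of view).
#' @export
extract_particle <- function(image, threshold) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop_bad("`threshold` must be a positive number", "trajectory_error")
  sel <- which(image > threshold)
  if (length(sel) == 0L)
    return(tibble(u = NA_real_, v = NA_real_, in_fov = FALSE))
  w <- image[sel]
  ai <- arrayInd(sel, dim(image))
  tibble(u = sum((ai[, 2] - 1) * w) / sum(w),
         v = sum((ai[, 1] - 1) * w) / sum(w),
         in_fov = TRUE)
}

#' Track the fiducial particle across a scan
#'
#' @param stack a `projection_stack`.
#' @param threshold grayscale threshold passed to [extract_particle()].
#' @return A particle track: tibble with one row per scan angle and columns
#'   `angle`, `u`, `v`, `in_fov`, of class `particle_track`.
#' @export
track_particle <- function(stack, threshold) {
  stopifnot(inherits(stack, "projection_stack"))
  rows <- purrr::map2_dfr(stack$images, stack$angles, function(img, a) {
    dplyr::mutate(extract_particle(img, threshold), angle = a,
                  .before = 1)
  })
  if (!any(rows$in_fov))
    stop_bad("no trajectory: the particle is out of the field of view in every frame",
             "trajectory_error")
  class(rows) <- c("particle_track", class(rows))
  rows
}

# conic coefficients (A,B,C,D,E,F) of the ellipse with the given geometry
conic_from_params <- function(center, a, b, phi_deg) {
  c0 <- cos(deg2rad(phi_deg)); s0 <- sin(deg2rad(phi_deg))
  A <- (c0 / a)^2 + (s0 / b)^2
  B <- 2 * c0 * s0 * (1 / a^2 - 1 / b^2)
  C <- (s0 / a)^2 + (c0 / b)^2
  x0 <- center[1]; y0 <- center[2]
  D <- -2 * A * x0 - B * y0
  E <- -B * x0 - 2 * C * y0
  F <- A * x0^2 + B * x0 * y0 + C * y0^2 - 1
  c(A = unname(A), B = unname(B), C = unname(C),
    D = unname(D), E = unname(E), F = unname(F))
}

new_ellipse_model <- function(center, a, b, phi_deg, n, rss,
                              degenerate = FALSE) {
  conic <- if (degenerate) NULL else conic_from_params(center, a, b, phi_deg)
  structure(list(center = unname(center), a = unname(a), b = unname(b),
                 phi_deg = unname(phi_deg), conic = conic, n = n,
                 rss = rss, degenerate = degenerate),
            class = "ellipse_model")
}

#' @export
print.ellipse_model <- function(x, ...) {
  cat(sprintf(
    "<ellipse_model> center (%.3f, %.3f), a = %.3f, b = %.3f, phi = %.3f deg%s\n",
    x$center[1], x$center[2], x$a, x$b, x$phi_deg,
    if (x$degenerate) " [degenerate line]" else ""))
  invisible(x)
}

#' Fit an ellipse to a particle track
#'
#' Direct algebraic least-squares conic fit constrained to an ellipse
#' (Fitzgibbon-style, in the numerically stabilised Halir-Flusser form),
#' applied to the in-FoV track points. Tracks that are collinear within
#' tolerance (smallest singular value of the centered points below
#' `eps_line` times the largest) are returned as a zero-minor-axis model
#' (`b = 0`, orientation = line slope) rather than as an error.
#'
#' @param track a `particle_track`, or any data frame with numeric columns
#'   `u` and `v` (an `in_fov` column, when present, filters the points).
#' @param eps_line relative collinearity tolerance.
#' @return An `ellipse_model`: center `(u0, v0)`, semi-axes `a >= b >= 0`
#'   and major-axis orientation `phi_deg` in `(-90, 90]`.
#' @export
fit_ellipse <- function(track, eps_line = 5e-3) {
  df <- as.data.frame(track)
  if ("in_fov" %in% names(df)) df <- df[df$in_fov, , drop = FALSE]
  x <- df$u; y <- df$v
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L)
    stop_bad("at least 5 usable track points are required to fit an ellipse",
             "trajectory_error")
  mx <- mean(x); my <- mean(y)
  P <- cbind(x - mx, y - my)
  sv <- svd(P, nu = 0)
  if (sv$d[2] <= eps_line * sv$d[1]) {
    dir <- sv$v[, 1]
    if (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)) dir <- -dir
    t <- P %*% dir
    a <- (max(t) - min(t)) / 2
    ctr <- c(mx, my) + as.numeric((max(t) + min(t)) / 2) * dir
    phi <- rad2deg(atan2(dir[2], dir[1]))
    rss <- mean((P %*% sv$v[, 2])^2)
    return(new_ellipse_model(ctr, a, 0, phi, n, rss, degenerate = TRUE))
  }
  s <- mean(sqrt(rowSums(P^2)))
  xs <- P[, 1] / s; ys <- P[, 2] / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M2)
  V <- Re(eg$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0L)
    stop_bad("constrained conic fit did not yield an ellipse", "trajectory_error")
  a1 <- V[, k[1]]
  conic_s <- c(a1, as.numeric(T %*% a1))
  geo <- conic_to_params(conic_s)
  ctr <- c(mx, my) + s * geo$center
  resid <- cbind(D1, D2) %*% conic_s / sqrt(sum(conic_s^2))
  new_ellipse_model(ctr, s * geo$a, s * geo$b, geo$phi_deg, n,
                    mean(resid^2))
}

# conic (A,B,C,D,E,F) -> center, semi-axes (a >= b), orientation in
# (-90, 90] degrees
conic_to_params <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop_bad("conic is not an ellipse", "trajectory_error")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  Fc <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  eg <- eigen(Q, symmetric = TRUE)
  ax <- sqrt(pmax(-Fc / eg$values, 0))   # semi-axis along each eigenvector
  i_maj <- which.max(ax)
  vmaj <- eg$vectors[, i_maj]
  if (vmaj[1] < 0 || (vmaj[1] == 0 && vmaj[2] < 0)) vmaj <- -vmaj
  phi <- rad2deg(atan2(vmaj[2], vmaj[1]))
  if (phi <= -90) phi <- phi + 180
  if (phi > 90) phi <- phi - 180
  list(center = c(x0, y0), a = max(ax), b = min(ax), phi_deg = phi)
}

#' Feature points P1-P4 of a fitted ellipse
#'
#' `P1`, `P2` are the vertices of the major axis (`P2` in the +major
#' direction, so the segment P1->P2 has the major-axis inclination). `P3`,
#' `P4` are the two ellipse points sharing the x-coordinate of the
#' minor-axis midpoint (the ellipse center), `P3` below `P4`. For a
#' degenerate line model (`b = 0`), `P3 = P4 = center`.
#'
#' @param model an `ellipse_model`.
#' @return A tibble with columns `point` (`"P1"`..`"P4"`), `x`, `y`.
#' @export
feature_points <- function(model) {
  stopifnot(inherits(model, "ellipse_model"))
  dirm <- c(cos(deg2rad(model$phi_deg)), sin(deg2rad(model$phi_deg)))
  P1 <- model$center - model$a * dirm
  P2 <- model$center + model$a * dirm
  if (model$degenerate || model$b <= 0) {
    P3 <- P4 <- model$center
  } else {
    k <- model$conic
    x0 <- model$center[1]
    qa <- k[3]
    qb <- k[2] * x0 + k[5]
    qc <- k[1] * x0^2 + k[4] * x0 + k[6]
    disc <- max(qb^2 - 4 * qa * qc, 0)
    roots <- sort((-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
    P3 <- c(x0, roots[1])
    P4 <- c(x0, roots[2])
  }
  tibble(point = c("P1", "P2", "P3", "P4"),
         x = c(P1[1], P2[1], P3[1], P4[1]),
         y = c(P1[2], P2[2], P3[2], P4[2]))
}

#' @export
tidy.ellipse_model <- function(x, ...) {
  tibble(term = c("u0", "v0", "a", "b", "phi_deg"),
         estimate = c(x$center[1], x$center[2], x$a, x$b, x$phi_deg))
}

#' @export
glance.ellipse_model <- function(x, ...) {
  tibble(u0 = x$center[1], v0 = x$center[2], a = x$a, b = x$b,
         phi_deg = x$phi_deg, degenerate = x$degenerate, n = x$n,
         rss = x$rss)
}
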