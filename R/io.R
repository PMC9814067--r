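#' Write / read a projection stack as multi-page TIFF
#'
#' Images are stored as 32-bit float TIFF pages rescaled to `[0, 1]`; the
#' scale factor, detector geometry and angle list live in a JSON sidecar
#' (`<prefix>_meta.json`) and a CSV angle table (`<prefix>_angles.csv`), so
#' the round trip is lossless within float32 precision.
#'
#' @param stack a `projection_stack`.
#' @param prefix file path prefix (without extension).
#' @return `write_projection_stack` returns the prefix invisibly;
#'   `read_projection_stack` returns the `projection_stack`.
#' @export
write_projection_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "projection_stack"))
  scale <- max(vapply(stack$images, max, numeric(1)), .Machine$double.eps)
  tiff::writeTIFF(lapply(stack$images, function(m) m / scale),
                  paste0(prefix, ".tif"), bits.per.sample = 32L)
  readr::write_csv(tibble(angle_deg = stack$angles),
                   paste0(prefix, "_angles.csv"), progress = FALSE)
  jsonlite::write_json(
    list(scale = scale, nu = stack$det$nu, nv = stack$det$nv,
         u_c = stack$det$u_c, v_c = stack$det$v_c),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_projection_stack
#' @export
read_projection_stack <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(meta_path))
    stop_bad(sprintf("missing stack metadata file '%s'", meta_path),
             "io_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("scale", "nu", "nv", "u_c", "v_c"))
    if (is.null(meta[[f]]))
      stop_bad(sprintf("stack metadata is missing field '%s'", f),
               "io_error")
  angles <- read_angles_csv(paste0(prefix, "_angles.csv"))
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(angles))
    stop_bad("angle list and TIFF page count disagree", "io_error")
  images <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * meta$scale
  })
  det <- detector_geometry(meta$nu, meta$nv, meta$u_c, meta$v_c)
  new_projection_stack(angles, images, det)
}

read_angles_csv <- function(path) {
  if (!file.exists(path))
    stop_bad(sprintf("missing angle file '%s'", path), "io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"angle_deg" %in% names(df))
    stop_bad("angle CSV is missing column 'angle_deg'", "io_error")
  df$angle_deg
}

#' Write / read a volume as a multi-page TIFF stack
#'
#' One float32 page per slice along the third axis, rescaled to `[0, 1]`
#' with the scale factor and voxel size in a JSON sidecar.
#'
#' @param volume a [new_volume()].
#' @param prefix file path prefix (without extension).
#' @return `write_volume_tiff` returns the prefix invisibly;
#'   `read_volume_tiff` returns the volume.
#' @export
write_volume_tiff <- function(volume, prefix) {
  stopifnot(inherits(volume, "tomo_volume"))
  vox <- volume$voxels
  scale <- max(max(vox), .Machine$double.eps)
  pages <- lapply(seq_len(dim(vox)[3]), function(k) vox[, , k] / scale)
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = scale, dims = dim(vox), voxel_size = volume$voxel_size),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(meta_path))
    stop_bad(sprintf("missing volume metadata file '%s'", meta_path),
             "io_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("scale", "dims", "voxel_size"))
    if (is.null(meta[[f]]))
      stop_bad(sprintf("volume metadata is missing field '%s'", f),
               "io_error")
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$dims[3])
    stop_bad("volume metadata dims and TIFF page count disagree", "io_error")
  vox <- array(0, dim = meta$dims)
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    vox[, , k] <- p * meta$scale
  }
  new_volume(vox, meta$voxel_size)
}

#' Write / read a particle track as CSV
#'
#' Columns: `angle_deg`, `u_px`, `v_px`, `in_fov`.
#'
#' @param track a `particle_track` (tibble with `angle`, `u`, `v`,
#'   `in_fov`).
#' @param path CSV file path.
#' @return `write_track_csv` returns the path invisibly; `read_track_csv`
#'   returns the `particle_track` tibble.
#' @export
write_track_csv <- function(track, path) {
  df <- tibble(angle_deg = track$angle, u_px = track$u, v_px = track$v,
               in_fov = track$in_fov)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  if (!file.exists(path))
    stop_bad(sprintf("missing track file '%s'", path), "io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("angle_deg", "u_px", "v_px", "in_fov"))
    if (!col %in% names(df))
      stop_bad(sprintf("track CSV is missing column '%s'", col), "io_error")
  out <- tibble(angle = df$angle_deg, u = df$u_px, v = df$v_px,
                in_fov = as.logical(df$in_fov))
  class(out) <- c("particle_track", class(out))
  out
}

report_to_list <- function(report) {
  keep <- setdiff(names(report), c("ga", "ellipse"))
  out <- lapply(report[keep], function(x) {
    if (inherits(x, "data.frame")) as.data.frame(x) else x
  })
  out
}

#' Write / read an alignment report as JSON
#'
#' Serialises the stage name, motor commands, per-generation GA history,
#' evaluation and acquisition counts, and residual readbacks.
#'
#' @param report an `alignment_report` (or plain list).
#' @param path JSON file path.
#' @return `write_report_json` returns the path invisibly;
#'   `read_report_json` returns the parsed list.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  if (!file.exists(path))
    stop_bad(sprintf("missing report file '%s'", path), "io_error")
  out <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_bad(sprintf("malformed report JSON '%s': %s",
                                     path, conditionMessage(e)), "io_error"))
  if (is.null(out$stage))
    stop_bad("report JSON is missing field 'stage'", "io_error")
  out
}
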