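#' Build a pipeline run configuration
#'
#' Bundles everything one alignment run needs: the phantom spec, detector
#' geometry, initial misalignment, jitter, thresholds, scan steps, the GA
#' settings per fine stage and a global seed. All fields have working
#' defaults for the walnut-like blob scenario.
#'
#' @param phantom list of arguments for [phantom_spec()].
#' @param detector list with `nu`, `nv` (and optional `u_c`, `v_c`).
#' @param initial list of [misalignment_state()] arguments: the injected
#'   misalignment the run starts from.
#' @param jitter_sd per-projection axis jitter, degrees.
#' @param seed global integer seed (drives phantom, jitter and the GA).
#' @param particle_threshold grayscale threshold for fiducial tracking;
#'   `NULL` chooses half the maximum of the first scan frame.
#' @param sample_threshold background threshold for sample centering
#'   (`NULL` = 0.5% of each image maximum).
#' @param axis_scan_step,axis_fine_step full-turn scan steps (degrees) for
#'   the coarse and fine axis stages.
#' @param sample_scan_step coarse sample scan step over 0-180 degrees.
#' @param axis_window,sample_window GA search half-windows (degrees,
#'   pixels).
#' @param ga list of [ga_config()] overrides shared by both fine stages
#'   (e.g. `pop_size`, `n_generations`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(phantom = list(kind = "blob_with_particle",
                                      grid_shape = c(96, 96, 96)),
                       detector = list(nu = 256, nv = 96),
                       initial = list(),
                       jitter_sd = 0.05,
                       seed = 1L,
                       particle_threshold = NULL,
                       sample_threshold = NULL,
                       axis_scan_step = 5,
                       axis_fine_step = 15,
                       sample_scan_step = 2,
                       axis_window = 3,
                       sample_window = 8,
                       ga = list()) {
  cfg <- list(phantom = phantom, detector = detector, initial = initial,
              jitter_sd = jitter_sd, seed = as.integer(seed),
              particle_threshold = particle_threshold,
              sample_threshold = sample_threshold,
              axis_scan_step = axis_scan_step,
              axis_fine_step = axis_fine_step,
              sample_scan_step = sample_scan_step,
              axis_window = axis_window, sample_window = sample_window,
              ga = ga)
  # validate the sub-configs eagerly
  do.call(phantom_spec, c(phantom, list(rng_seed = cfg$seed)))
  do.call(detector_geometry, detector)
  do.call(misalignment_state, initial)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_bad(sprintf("missing config file '%s'", path), "io_error")
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(run_config)))
  if (length(bad))
    stop_bad(sprintf("unknown config field(s): %s",
                     paste(bad, collapse = ", ")), "io_error")
  do.call(run_config, raw)
}

pipeline_stages <- c("axis_coarse", "axis_fine", "sample_coarse",
                     "sample_fine")

check_stage_order <- function(stages) {
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad))
    stop_bad(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
             "pipeline_error")
  pos <- match(stages, pipeline_stages)
  if (is.unsorted(pos, strictly = TRUE))
    stop_bad("stages must respect the order axis before sample, coarse before fine",
             "pipeline_error")
  if ("axis_fine" %in% stages && !"axis_coarse" %in% stages)
    stop_bad("axis_fine requires a prior axis_coarse stage", "pipeline_error")
  if ("sample_fine" %in% stages && !"sample_coarse" %in% stages)
    stop_bad("sample_fine requires a prior sample_coarse stage",
             "pipeline_error")
  stages[order(pos)]
}

#' Set up the virtual beamline described by a run configuration
#'
#' @param config a [run_config()].
#' @return A [virtual_beamline()] holding the generated phantom, the
#'   configured detector and the injected initial misalignment.
#' @export
build_beamline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- do.call(phantom_spec,
                  c(config$phantom, list(rng_seed = config$seed)))
  volume <- switch(spec$kind,
                   particle_only = make_particle_phantom(spec),
                   make_blob_phantom(spec))
  det <- do.call(detector_geometry, config$detector)
  state <- do.call(misalignment_state, config$initial)
  virtual_beamline(volume, det, state, jitter_sd = config$jitter_sd,
                   seed = config$seed)
}

#' Run the alignment pipeline
#'
#' Executes the requested stages, in order, against the configured virtual
#' beamline. When `out_dir` is given, each stage writes a JSON report
#' (motor commands, fitness history, residuals, acquisition counts), the
#' axis stages write their particle tracks as CSV, and the run config is
#' persisted as YAML so the run is reproducible from its outputs.
#'
#' @param config a [run_config()].
#' @param stages subset of `"axis_coarse"`, `"axis_fine"`,
#'   `"sample_coarse"`, `"sample_fine"`; order is enforced (axis before
#'   sample, coarse before fine).
#' @param out_dir optional output directory (created if needed).
#' @param bl optional existing [virtual_beamline()] to run against (used to
#'   continue a previous run); defaults to [build_beamline()] on `config`.
#' @return A list with `reports` (one `alignment_report` per stage),
#'   `beamline`, and `files` (paths written).
#' @export
run_pipeline <- function(config, stages = pipeline_stages, out_dir = NULL,
                         bl = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- check_stage_order(stages)
  if (is.null(bl)) bl <- build_beamline(config)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(out_dir, "run_config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    files <- c(files, cfg_path)
  }
  pthr <- config$particle_threshold
  if (is.null(pthr) && any(grepl("^axis", stages))) {
    # half the peak of one probe frame isolates the fiducial
    probe <- project(bl$volume, bl$state, bl$det, 0)
    pthr <- max(probe) / 2
  }
  ga_base <- function(seed_offset) {
    do.call(ga_config, modifyList(
      list(bounds = list(c(0, 1), c(0, 1)),
           rng_seed = config$seed + seed_offset),
      config$ga))
  }
  reports <- list()
  for (st in stages) {
    rep <- switch(st,
      axis_coarse = coarse_align_axis(
        bl, pthr, angles = seq(0, 360 - config$axis_scan_step,
                               by = config$axis_scan_step)),
      axis_fine = fine_align_axis(
        bl, pthr, ga = ga_base(101L),
        angles = seq(0, 360 - config$axis_fine_step,
                     by = config$axis_fine_step),
        window = config$axis_window),
      sample_coarse = coarse_align_sample(
        bl, step = config$sample_scan_step,
        threshold = config$sample_threshold),
      sample_fine = fine_align_sample(
        bl, ga = ga_base(202L), threshold = config$sample_threshold,
        window = config$sample_window))
    reports[[st]] <- rep
    if (!is.null(out_dir)) {
      jp <- file.path(out_dir, paste0(st, "_report.json"))
      write_report_json(rep, jp)
      files <- c(files, jp)
      if (st == "axis_coarse") {
        for (w in c("track_before", "track_after")) {
          tp <- file.path(out_dir, paste0(st, "_", w, ".csv"))
          write_track_csv(rep[[w]], tp)
          files <- c(files, tp)
        }
      }
    }
  }
  list(reports = reports, beamline = bl, files = files)
}
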