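#' Full pipeline configuration
#'
#' Bundles the phantom, acquisition, reconstruction and analysis settings
#' with an output directory and a single master seed that feeds every
#' stochastic stage through named sub-streams ([seed_substream()]).
#'
#' The default is a small demonstration setup: a 32^3 grid with an
#' ellipsoidal ventricle-like blob and one tube, full sampling, zero-fill
#' reconstruction.
#'
#' @param phantom a [phantom_spec()] or a plain list of its arguments
#'   (structures as lists of [csf_structure()] arguments), as produced by
#'   YAML deserialization.
#' @param acquisition an [acquisition_config()] or argument list.
#' @param recon a [recon_config()] or argument list.
#' @param analysis list: `forces` (subset of cardiac/respiratory/random),
#'   `mask` ([mask_config()] or list), `use_truth_peaks` flag,
#'   `vessel_structure` (structure index for rim profiles, or 0 to skip).
#' @param outputs output directory.
#' @param seed master integer seed.
#' @param n_repeats passes over the sampling pattern per subscan.
#' @param duration physiological trace duration, s; default covers the
#'   schedule.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = NULL, acquisition = NULL, recon = NULL,
                            analysis = NULL, outputs = tempfile("csfpipe"),
                            seed = 1L, n_repeats = 1L, duration = NULL) {
  as_spec <- function(x, ctor) {
    if (is.null(x)) return(ctor())
    if (inherits(x, c("phantom_spec", "acquisition_config", "recon_config"))) return(x)
    do.call(ctor, x)
  }
  if (is.null(phantom)) {
    phantom <- demo_phantom_spec(seed)
  } else if (!inherits(phantom, "phantom_spec")) {
    phantom$structures <- lapply(phantom$structures, function(st) {
      if (inherits(st, "csf_structure")) st else do.call(csf_structure, st)
    })
    phantom <- do.call(phantom_spec, phantom)
  }
  if (is.null(acquisition)) {
    acquisition <- acquisition_config(grid = phantom$grid_shape[2:3],
                                      acs_size = min(9L, min(phantom$grid_shape[2:3])),
                                      accel_target = 1, tse_factor = 64L,
                                      seed = seed)
  } else {
    acquisition <- as_spec(acquisition, acquisition_config)
  }
  recon <- as_spec(recon, recon_config)
  analysis <- utils::modifyList(
    list(forces = c("cardiac", "random"), mask = mask_config(),
         use_truth_peaks = FALSE, vessel_structure = 0L),
    analysis %||% list())
  if (!inherits(analysis$mask, "mask_config")) {
    analysis$mask <- do.call(mask_config, analysis$mask)
  }
  structure(list(phantom = phantom, acquisition = acquisition, recon = recon,
                 analysis = analysis, outputs = outputs,
                 seed = as.integer(seed), n_repeats = as.integer(n_repeats),
                 duration = duration),
            class = "pipeline_config")
}

## small two-structure demonstration phantom
demo_phantom_spec <- function(seed = 1L) {
  phantom_spec(
    grid_shape = c(32L, 32L, 32L), voxel_size = 0.45,
    structures = list(
      csf_structure("ellipsoid", center = c(4.5, 4.5, 6.3),
                    axes = c(2.7, 2.7, 3.6), base_mobility = 0.025,
                    cardiac_amp = 0.084, resp_amp = 0.025),
      csf_structure("tube", p1 = c(9, 9, 2.25), p2 = c(9, 9, 11.7),
                    radius = 1.35, base_mobility = 0.041, fa = 0.7,
                    cardiac_amp = 0.032, resp_amp = 0.012)),
    csf_signal = 1000, seed = seed)
}

stage_file <- function(cfg, name) file.path(cfg$outputs, name)

require_artifact <- function(cfg, name, stage) {
  p <- stage_file(cfg, name)
  if (!file.exists(p)) {
    stop(sprintf("missing upstream artifact '%s': run the '%s' stage first",
                 name, stage), call. = FALSE)
  }
  p
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  cfg$outputs <- NULL  # hash the scientific settings, not the artifact path
  writeLines(jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE,
                              digits = 12, null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run one stage of the simulation / analysis pipeline
#'
#' Stage order mirrors the measurement chain: `simulate` (phantom, traces,
#' pattern, seven encoded subscans) -> `bin` (retrospective phase binning
#' per driving force) -> `recon` (per-phase and static reconstructions) ->
#' `fit` (per-phase tensor fits) -> `phasecycle` (percent-change profiles,
#' sine fits, ROI summaries) -> `roi` (CSF mask, ROI statistics, optional
#' rim profiles) -> `report` (JSON summary). Each stage reads the previous
#' stage's artifacts from `cfg$outputs` and fails with a dependency error
#' if they are absent. A fixed master seed yields byte-identical reports.
#'
#' @param cfg a [pipeline_config()].
#' @param command one of `simulate`, `bin`, `recon`, `fit`, `phasecycle`,
#'   `roi`, `report`, or `all`.
#' @return invisibly, the path(s) of the artifacts written.
#' @export
run_pipeline <- function(cfg, command = c("all", "simulate", "bin", "recon",
                                          "fit", "phasecycle", "roi", "report")) {
  command <- match.arg(command)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outputs, showWarnings = FALSE, recursive = TRUE)
  stages <- if (command == "all") {
    c("simulate", "bin", "recon", "fit", "phasecycle", "roi", "report")
  } else command
  out <- character(0)
  for (st in stages) {
    out <- c(out, switch(st,
      simulate = stage_simulate(cfg),
      bin = stage_bin(cfg),
      recon = stage_recon(cfg),
      fit = stage_fit(cfg),
      phasecycle = stage_phasecycle(cfg),
      roi = stage_roi(cfg),
      report = stage_report(cfg)))
  }
  invisible(out)
}

stage_simulate <- function(cfg) {
  truth <- make_phantom(cfg$phantom)
  pattern <- make_pattern(cfg$acquisition)
  sched0 <- make_shot_schedule(pattern, cfg$acquisition, n_repeats = cfg$n_repeats)
  per_sub <- length(sched0$shots) * cfg$acquisition$TR
  duration <- cfg$duration %||% (7 * per_sub + 10)
  traces <- make_physio_traces(duration, seed = seed_substream(cfg$seed, "physio"))
  data <- simulate_acquisition(truth, traces, pattern, cfg$acquisition,
                               n_repeats = cfg$n_repeats)
  vx <- cfg$phantom$voxel_size
  write_tensor_volume(truth$tensor0, stage_file(cfg, "truth_tensor.nii.gz"), vx)
  write_volume(truth$signal, stage_file(cfg, "truth_signal.nii.gz"), vx)
  write_trace_tsv(traces$time, traces$cardiac, stage_file(cfg, "trace_cardiac.tsv"))
  write_trace_tsv(traces$time, traces$respiratory,
                  stage_file(cfg, "trace_respiratory.tsv"))
  write_profile_tsv(sched0, stage_file(cfg, "profiles.tsv"))
  saveRDS(list(truth = truth, traces = traces, pattern = pattern, data = data),
          stage_file(cfg, "encoded.rds"))
  writeLines(jsonlite::toJSON(list(
    dims = data$dims, grid = data$grid, n_subscans = 7,
    subscan_order = c("reference", paste0("dir", 1:6)),
    directions = data$directions, b_value = data$b_value,
    container = "encoded.rds (R serialization)",
    config_hash = config_hash(cfg)), auto_unbox = TRUE, digits = 12, pretty = TRUE),
    stage_file(cfg, "encoded.json"))
  stage_file(cfg, "encoded.rds")
}

stage_bin <- function(cfg) {
  enc <- readRDS(require_artifact(cfg, "encoded.rds", "simulate"))
  res <- lapply(cfg$analysis$forces, function(f) {
    bin_acquisition(enc$data, enc$traces, f,
                    seed = seed_substream(cfg$seed, "random_binning"),
                    use_truth_peaks = isTRUE(cfg$analysis$use_truth_peaks))
  })
  names(res) <- cfg$analysis$forces
  saveRDS(res, stage_file(cfg, "binned.rds"))
  stage_file(cfg, "binned.rds")
}

stage_recon <- function(cfg) {
  enc <- readRDS(require_artifact(cfg, "encoded.rds", "simulate"))
  binned <- readRDS(require_artifact(cfg, "binned.rds", "bin"))
  series <- lapply(binned, reconstruct_series, cfg = cfg$recon)
  static <- array(0, c(enc$data$dims, 7))
  for (s in 1:7) static[, , , s] <- reconstruct_static(enc$data$subscans[[s]])
  saveRDS(list(series = series, static = static), stage_file(cfg, "recon.rds"))
  write_volume(static[, , , 1], stage_file(cfg, "static_reference.nii.gz"),
               cfg$phantom$voxel_size)
  stage_file(cfg, "recon.rds")
}

stage_fit <- function(cfg) {
  rec <- readRDS(require_artifact(cfg, "recon.rds", "recon"))
  b <- cfg$acquisition$b_value
  thr <- cfg$analysis$mask$csf_threshold
  fit_static <- fit_tensor(rec$static, b = b, s0_threshold = thr)
  per_force <- lapply(rec$series, function(ser) {
    lapply(1:6, function(p) fit_tensor(ser[, , , , p], b = b, s0_threshold = thr))
  })
  saveRDS(list(static = fit_static, per_force = per_force),
          stage_file(cfg, "tensors.rds"))
  vx <- cfg$phantom$voxel_size
  write_volume(fit_static$mobility, stage_file(cfg, "mobility_static.nii.gz"), vx)
  write_volume(fit_static$fa, stage_file(cfg, "fa_static.nii.gz"), vx)
  stage_file(cfg, "tensors.rds")
}

stage_phasecycle <- function(cfg) {
  fits <- readRDS(require_artifact(cfg, "tensors.rds", "fit"))
  res <- lapply(fits$per_force, function(phases) {
    d3 <- dim(phases[[1]]$mobility)
    maps <- array(0, c(d3, 6))
    valid <- array(TRUE, d3)
    for (p in 1:6) {
      maps[, , , p] <- phases[[p]]$mobility
      valid <- valid & phases[[p]]$valid
    }
    pcres <- percent_change(maps, valid)
    sf <- sine_fit(pcres$pc)
    list(pc = pcres, sine = sf)
  })
  saveRDS(res, stage_file(cfg, "phasecycle.rds"))
  stage_file(cfg, "phasecycle.rds")
}

stage_roi <- function(cfg) {
  enc <- readRDS(require_artifact(cfg, "encoded.rds", "simulate"))
  rec <- readRDS(require_artifact(cfg, "recon.rds", "recon"))
  fits <- readRDS(require_artifact(cfg, "tensors.rds", "fit"))
  pc <- readRDS(require_artifact(cfg, "phasecycle.rds", "phasecycle"))
  change_vols <- lapply(pc, function(f) {
    apply(abs(f$pc$pc), 1:3, max)
  })
  mask <- csf_mask(rec$static[, , , 1], change_vols, cfg$analysis$mask)
  rois <- lapply(enc$truth$structure_masks, function(m) m & mask)
  roi_summaries <- lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    if (!any(roi)) return(list(n_voxels = 0))
    stats_mob <- roi_stats(fits$static$mobility, roi)
    stats_fa <- roi_stats(fits$static$fa, roi)
    per_force <- lapply(pc, function(f) {
      s <- phase_summaries(f$pc$pc, f$sine, roi & f$pc$valid)
      s$realigned_mean <- as.numeric(s$realigned_mean)
      s
    })
    list(structure = i, n_voxels = sum(roi),
         mobility = stats_mob, fa = stats_fa, per_force = per_force)
  })
  rims <- NULL
  vs <- cfg$analysis$vessel_structure
  if (vs >= 1 && vs <= length(rois) && any(enc$truth$structure_masks[[vs]])) {
    rims <- dilation_rims(enc$truth$structure_masks[[vs]],
                          cfg$phantom$voxel_size,
                          csf = mask,
                          mobility = fits$static$mobility,
                          fa = fits$static$fa,
                          step = max(0.17, cfg$phantom$voxel_size))
    attr(rims, "rim_index") <- NULL
  }
  saveRDS(list(mask = mask, rois = rois, roi_summaries = roi_summaries,
               rims = rims), stage_file(cfg, "roi.rds"))
  stage_file(cfg, "roi.rds")
}

stage_report <- function(cfg) {
  roi <- readRDS(require_artifact(cfg, "roi.rds", "roi"))
  pc <- readRDS(require_artifact(cfg, "phasecycle.rds", "phasecycle"))
  tests <- NULL
  if (all(c("cardiac", "random") %in% names(pc))) {
    ## paired voxel-wise comparison of gated amplitudes, cardiac vs random
    sel <- which(roi$mask & pc$cardiac$pc$valid & pc$random$pc$valid)
    if (length(sel) >= 3) {
      sel <- sel[seq_len(min(length(sel), 2000))]
      tests <- nonparam_tests(list(as.numeric(pc$cardiac$sine$gated_amplitude)[sel],
                                   as.numeric(pc$random$sine$gated_amplitude)[sel]),
                              design = "paired_two")
    }
  }
  report <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    n_csf_voxels = sum(roi$mask),
    rois = roi$roi_summaries,
    rim_profile = roi$rims,
    tests = tests)
  path <- stage_file(cfg, "report.json")
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = 12,
                              pretty = TRUE, dataframe = "columns",
                              null = "null", force = TRUE), path)
  path
}
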