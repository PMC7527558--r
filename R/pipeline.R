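#' Default pipeline run configuration
#'
#' Builds the configuration driving [run_pipeline()]: the study-protocol
#' constants (calibration anchors 133/9, -223 HU threshold, 4 phase bins,
#' 220 degrees / 0.9 degrees / 9 projections / 55 ms acquisition, 150
#' breaths/min) plus desk-scale simulation sizes. The imaging arm renders
#' one representative animal per group at weeks 0, 1, 5 and 15 (four
#' breathing phases each) on a reduced grid; the full cohort is simulated at
#' the table level with the study cohort sizes. All randomness flows from
#' `seed` via named sub-streams.
#'
#' @param seed Integer root seed.
#' @param out_dir Output directory for all stage files.
#' @return A nested configuration list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("silicoct_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    threshold = -223,
    n_bins = 4L,
    phantom = list(grid_shape = c(64L, 64L, 64L), voxel_size = 0.3,
                   water_gs = 133, air_gs = 9, noise_sd = 2),
    respiratory = list(rate = 150, tidal_fraction = 0.4, phase_origin = 0),
    acquisition = list(total_angle = 220, angle_increment = 0.9,
                       projections_per_view = 9, exposure = 55),
    imaging = list(weeks = c(0, 1, 5, 15),
                   silica_lesion_fraction = 0.15, lesion_count = 24L,
                   lung_hu = -500, lesion_hu = 30),
    design = list(), trajectory = list(), endpoint = list(),
    correlation_pairs = data.frame(
      x = c("aerated_ml", "total_ml", "non_aerated_ml", "non_aerated_ml",
            "non_aerated_ml", "non_aerated_ml"),
      y = c("ic_ml", "eta", "tiffeneau", "bal_protein_mg_ml",
            "serum_spd_ng_ml", "oh_proline_ug"),
      m = 6)
  )
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to [default_run_config()] values; `seed` is
#' mandatory in the file.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set `seed`", call. = FALSE)
  cfg <- default_run_config(seed = y$seed)
  for (nm in setdiff(names(y), "seed")) {
    if (is.list(cfg[[nm]]) && is.list(y[[nm]])) {
      cfg[[nm]][names(y[[nm]])] <- y[[nm]]
    } else {
      cfg[[nm]] <- y[[nm]]
    }
  }
  cfg
}

cfg_paths <- function(config) {
  d <- config$out_dir
  list(dir = d, volumes = file.path(d, "volumes"),
       events = file.path(d, "events.csv"),
       study = file.path(d, "study.csv"),
       mapping = file.path(d, "mapping.json"),
       binning = file.path(d, "binning.csv"),
       gating = file.path(d, "gating.json"),
       imaging = file.path(d, "imaging_biomarkers.csv"),
       correlations = file.path(d, "correlations.csv"),
       trajectory = file.path(d, "trajectory_summary.csv"),
       model = file.path(d, "model_report.json"),
       provenance = file.path(d, "provenance.json"),
       log = file.path(d, "log.txt"))
}

log_line <- function(config, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  cat(msg, "\n", sep = "", file = cfg_paths(config)$log, append = TRUE)
  message(msg)
}

cfg_resp <- function(config) do.call(respiratory_model, config$respiratory)

cfg_design <- function(config) {
  do.call(study_design, c(config$design,
                          if (is.null(config$design$seed))
                            list(seed = stream_seed(config$seed, "study"))))
}

imaging_scan_name <- function(group, week, phase_bin) {
  sprintf("%s_w%02d_phase%d", group, week, phase_bin)
}

#' Pipeline stage: simulate
#'
#' Generates every pipeline input: the calibration phantom, the
#' imaging-arm thorax volumes across the four breathing phases, the
#' list-mode projection stream and the full simulated study table.
#'
#' @param config Configuration from [default_run_config()] or
#'   [read_run_config()].
#' @return Invisibly, the list of files written.
#' @export
stage_simulate <- function(config) {
  p <- cfg_paths(config)
  dir.create(p$volumes, recursive = TRUE, showWarnings = FALSE)
  resp <- cfg_resp(config)
  traj <- do.call(trajectory_model, config$trajectory)

  pspec <- phantom_spec(grid_shape = config$phantom$grid_shape,
                        voxel_size = config$phantom$voxel_size,
                        water_gs = config$phantom$water_gs,
                        air_gs = config$phantom$air_gs,
                        noise_sd = config$phantom$noise_sd,
                        seed = stream_seed(config$seed, "phantom"))
  cal <- make_calibration_phantom(pspec)
  write_volume(cal$volume, file.path(p$volumes, "calibration.nii.gz"),
               pspec$voxel_size)
  write_volume(cal$labels, file.path(p$volumes, "calibration_labels.nii.gz"),
               pspec$voxel_size)
  log_line(config, "simulate: calibration phantom (%s grid)",
           paste(pspec$grid_shape, collapse = "x"))

  hu_map <- fit_hu_mapping(config$phantom$water_gs, config$phantom$air_gs)
  centers <- phase_bin_centers(config$n_bins)
  for (group in c("control", "silica")) {
    for (wk in config$imaging$weeks) {
      traj_w <- expected_trajectory(traj, wk, group)
      lf <- if (group == "silica" && wk > 0)
        config$imaging$silica_lesion_fraction else 0
      tsp <- thorax_spec(
        lung_volume_mL = traj_w$total_ml, lesion_fraction = lf,
        lesion_count = config$imaging$lesion_count,
        lung_hu = config$imaging$lung_hu,
        lesion_hu = config$imaging$lesion_hu,
        seed = stream_seed(config$seed, paste0("thorax_", group, wk)))
      thorax <- make_thorax_phantom(pspec, tsp, hu_map)
      series <- breathing_series(thorax, resp, centers)
      for (k in seq_along(series)) {
        stem <- imaging_scan_name(group, wk, k - 1L)
        write_volume(series[[k]]$volume,
                     file.path(p$volumes, paste0(stem, ".nii.gz")),
                     pspec$voxel_size)
        write_volume(series[[k]]$labels,
                     file.path(p$volumes, paste0(stem, "_labels.nii.gz")),
                     pspec$voxel_size)
      }
      log_line(config, "simulate: thorax %s week %d (%d phases)", group, wk,
               length(series))
    }
  }

  acq <- do.call(acquisition_spec, config$acquisition)
  write_events(make_listmode_stream(acq, resp), p$events)

  design <- cfg_design(config)
  endp <- do.call(endpoint_model, config$endpoint)
  write_study_table(simulate_study(design, traj, endp), p$study)
  log_line(config, "simulate: study table (%d control + %d silica endpoint animals)",
           sum(design$n_control), sum(design$n_silica))
  invisible(p)
}

#' Pipeline stage: calibrate
#'
#' Fits the grayscale-to-HU mapping from the calibration phantom scan
#' (histogram modes of the water and air VOIs) and serializes it as JSON.
#'
#' @inheritParams stage_simulate
#' @return The fitted `hu_mapping`, invisibly.
#' @export
stage_calibrate <- function(config) {
  p <- cfg_paths(config)
  vol_path <- file.path(p$volumes, "calibration.nii.gz")
  lab_path <- file.path(p$volumes, "calibration_labels.nii.gz")
  for (f in c(vol_path, lab_path)) {
    if (!file.exists(f)) {
      stop("calibration stage: phantom file not found: ", f, call. = FALSE)
    }
  }
  m <- calibrate_from_phantom(read_volume(vol_path), read_volume(lab_path))
  write_hu_mapping(m, p$mapping)
  log_line(config, "calibrate: water gs %g -> 0 HU, air gs %g -> -1000 HU (slope %.4f)",
           m$water_gs, m$air_gs, m$slope)
  invisible(m)
}

#' Pipeline stage: gate
#'
#' Retrospectively sorts the list-mode events into phase bins and selects
#' the end-expiration bin.
#'
#' @inheritParams stage_simulate
#' @return The `phase_binning`, invisibly.
#' @export
stage_gate <- function(config) {
  p <- cfg_paths(config)
  if (!file.exists(p$events)) {
    stop("gating stage: event file not found: ", p$events, call. = FALSE)
  }
  resp <- cfg_resp(config)
  binning <- assign_bins(read_events(p$events), resp, config$n_bins)
  write_binning(binning, p$binning)
  sel <- select_end_expiration(binning, resp)
  jsonlite::write_json(list(n_bins = binning$n_bins, selected_bin = sel,
                            bin_sizes = binning$bin_sizes),
                       p$gating, auto_unbox = TRUE, digits = NA)
  log_line(config, "gate: %d events -> bins [%s], end-expiration bin %d",
           nrow(binning$assignment),
           paste(binning$bin_sizes, collapse = ", "), sel)
  invisible(binning)
}

#' Pipeline stage: quantify
#'
#' For each imaging-arm scan, picks the end-expiration phase volume, applies
#' the fitted HU mapping, builds the lung VOI from the labels (excluding
#' heart/vessels) and extracts the four biomarkers.
#'
#' @inheritParams stage_simulate
#' @return The imaging biomarker table, invisibly.
#' @export
stage_quantify <- function(config) {
  p <- cfg_paths(config)
  for (f in c(p$mapping, p$gating)) {
    if (!file.exists(f)) {
      stop("quantify stage: required input not found: ", f, call. = FALSE)
    }
  }
  m <- read_hu_mapping(p$mapping)
  sel <- jsonlite::read_json(p$gating)$selected_bin
  records <- list()
  for (group in c("control", "silica")) {
    for (wk in config$imaging$weeks) {
      stem <- imaging_scan_name(group, wk, sel)
      vol_path <- file.path(p$volumes, paste0(stem, ".nii.gz"))
      if (!file.exists(vol_path)) {
        stop("quantify stage: volume not found: ", vol_path, call. = FALSE)
      }
      gs <- read_volume(vol_path)
      labels <- read_volume(file.path(p$volumes,
                                      paste0(stem, "_labels.nii.gz")))
      calib <- apply_hu_mapping(gs, m, attr(gs, "voxel_size"))
      voi <- voi_from_labels(labels)
      b <- extract_biomarkers(calib, voi, config$threshold)
      records[[length(records) + 1]] <-
        list(animal = paste0("imaging_", group), group = group, week = wk,
             biomarkers = b)
    }
  }
  tab <- longitudinal_table(records)
  readr::write_csv(tab, p$imaging)
  log_line(config, "quantify: %d scans quantified at threshold %g HU",
           nrow(tab), config$threshold)
  invisible(tab)
}

#' Pipeline stage: analyze
#'
#' Derives the physiology indices, computes group/week trajectory summaries
#' of the four biomarkers, the imaging-endpoint Pearson correlations
#' (silica animals, Sidak-adjusted) and the delegated longitudinal
#' mixed-model interaction test.
#'
#' @inheritParams stage_simulate
#' @return List with `correlations`, `trajectory`, `model_p`, invisibly.
#' @export
stage_analyze <- function(config) {
  p <- cfg_paths(config)
  if (!file.exists(p$study)) {
    stop("analyze stage: study table not found: ", p$study, call. = FALSE)
  }
  study <- derive_indices(read_study_table(p$study))
  cors <- correlation_table(study, config$correlation_pairs)
  readr::write_csv(cors, p$correlations)

  traj <- dplyr::bind_rows(lapply(
    c("mean_lung_density_hu", "aerated_ml", "non_aerated_ml", "total_ml"),
    function(v) dplyr::mutate(group_summaries(study, v), biomarker = v,
                              .before = 1)))
  readr::write_csv(traj, p$trajectory)

  fit <- fit_longitudinal_model(study, "non_aerated_ml")
  jsonlite::write_json(list(response = "non_aerated_ml",
                            interaction_p = fit$interaction_p),
                       p$model, auto_unbox = TRUE, digits = NA)
  log_line(config, "analyze: %d correlations; interaction p = %.3g",
           nrow(cors), fit$interaction_p)
  invisible(list(correlations = cors, trajectory = traj,
                 model_p = fit$interaction_p))
}

#' Run the full pipeline
#'
#' Executes simulate, calibrate, gate, quantify and analyze in order,
#' logging each stage and writing a provenance record (seed, config digest,
#' package version). Re-running with the same configuration is
#' bit-identical for all CSV outputs. Any stage failure aborts with the
#' stage name and the offending input path in the message.
#'
#' @inheritParams stage_simulate
#' @return List of stage outputs, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  p <- cfg_paths(config)
  dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(p$log)) unlink(p$log)
  stages <- list(simulate = stage_simulate, calibrate = stage_calibrate,
                 gate = stage_gate, quantify = stage_quantify,
                 analyze = stage_analyze)
  out <- list()
  for (nm in names(stages)) {
    out[[nm]] <- tryCatch(stages[[nm]](config), error = function(e) {
      stop(sprintf("pipeline aborted in stage '%s': %s", nm,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  tmp <- tempfile()
  saveRDS(config[setdiff(names(config), "out_dir")], tmp)
  digest <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(seed = config$seed, config_md5 = digest,
         package_version = as.character(utils::packageVersion("silicoct")),
         threshold_hu = config$threshold, n_bins = config$n_bins),
    p$provenance, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
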