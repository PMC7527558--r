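#' Simulate a longitudinal silica-vs-saline study cohort
#'
#' Generates the long-format study table the quantification pipeline would
#' produce from a full in-vivo study: one row per animal and scan week, with
#' the four scan-derived biomarkers (ground truth plus measurement noise)
#' at every scan, and the terminal readouts (lung function raw parameters,
#' BAL cellularity and protein, serum SP-D, hydroxyproline, analyte panel)
#' only in each animal's sacrifice-week row. Per-animal records end at
#' sacrifice (monotone missingness); scanned-only extras run the full
#' schedule. All draws are reproducible from `design$seed` via named
#' sub-streams.
#'
#' Derived indices (eta, Tiffeneau) are deliberately not emitted: the raw
#' parameters G, H, FEV_0.1 and FVC are, and [derive_indices()] computes the
#' indices downstream, as in the real analysis chain.
#'
#' @param design A [study_design()].
#' @param traj A [trajectory_model()].
#' @param endp An [endpoint_model()].
#' @return Tibble; one row per animal x scanned week. Endpoint columns are
#'   `NA` outside sacrifice rows. Ground-truth columns carry the `_true`
#'   suffix.
#' @export
simulate_study <- function(design = study_design(),
                           traj = trajectory_model(),
                           endp = endpoint_model()) {
  stopifnot(inherits(design, "study_design"),
            inherits(traj, "trajectory_model"),
            inherits(endp, "endpoint_model"))

  ew <- design$endpoint_weeks
  animals <- tibble::tibble(
    group = c(rep("control", sum(design$n_control) + design$extra_control),
              rep("silica", sum(design$n_silica) + design$extra_silica)),
    endpoint_week = c(rep(ew, design$n_control),
                      rep(NA_real_, design$extra_control),
                      rep(ew, design$n_silica),
                      rep(NA_real_, design$extra_silica))
  )
  animals$animal_id <- paste0(ifelse(animals$group == "control", "C", "S"),
                              sprintf("%02d", stats::ave(
                                seq_len(nrow(animals)), animals$group,
                                FUN = seq_along)))

  set.seed(stream_seed(design$seed, "animals"))
  animals$severity <- pmax(stats::rnorm(nrow(animals), 1, traj$sd_severity),
                           0.2)
  animals$b_ae <- stats::rnorm(nrow(animals), 0, traj$sd_baseline)
  animals$b_na <- stats::rnorm(nrow(animals), 0, traj$sd_baseline)

  rows <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    last <- animals$endpoint_week[i]
    wk <- design$scan_weeks[is.na(last) | design$scan_weeks <= last]
    data.frame(idx = i, week = wk)
  }))
  tab <- tibble::tibble(
    animal_id = animals$animal_id[rows$idx],
    group = animals$group[rows$idx],
    endpoint_week = animals$endpoint_week[rows$idx],
    week = rows$week
  )
  sev <- animals$severity[rows$idx]
  dis <- as.numeric(tab$group == "silica")

  ae_true <- traj$base_aerated * (1 + traj$drift_aerated * tab$week) +
    animals$b_ae[rows$idx] + dis * sev * ae_profile(traj, tab$week)
  na_true <- traj$base_non_aerated * (1 + traj$drift_non_aerated * tab$week) +
    animals$b_na[rows$idx] + dis * sev * na_profile(traj, tab$week)

  set.seed(stream_seed(design$seed, "measure"))
  ae <- ae_true + stats::rnorm(nrow(tab), 0, traj$meas_sd)
  na <- na_true + stats::rnorm(nrow(tab), 0, traj$meas_sd)
  mld <- (ae * traj$hu_aerated + na * traj$hu_non_aerated) / (ae + na) +
    stats::rnorm(nrow(tab), 0, traj$mld_noise_sd)

  tab$mean_lung_density_hu <- mld
  tab$aerated_ml <- ae
  tab$non_aerated_ml <- na
  tab$total_ml <- ae + na
  tab$aerated_true_ml <- ae_true
  tab$non_aerated_true_ml <- na_true

  # terminal readouts at sacrifice rows only
  is_end <- !is.na(tab$endpoint_week) & tab$week == tab$endpoint_week
  n_end <- sum(is_end)
  moments <- lapply(
    stats::setNames(nm = c("aerated_ml", "non_aerated_ml", "total_ml")),
    function(v) silica_pooled_moments(traj, design, v))

  set.seed(stream_seed(design$seed, "endpoints"))
  for (nm in names(endp$links)) {
    l <- endp$links[[nm]]
    zx <- (tab[[l$x]][is_end] - moments[[l$x]]$mean) / moments[[l$x]]$sd
    eps <- stats::rnorm(n_end)
    y <- l$mean + l$sd * (l$target_r * zx + sqrt(1 - l$target_r^2) * eps)
    col <- rep(NA_real_, nrow(tab))
    col[is_end] <- pmin(pmax(y, l$lo), l$hi)
    tab[[nm]] <- col
  }

  # raw lung-function parameters carrying the derived-index links
  h_v <- rep(NA_real_, nrow(tab)); fvc_v <- h_v; rn_v <- h_v; pef_v <- h_v
  h_v[is_end] <- stats::rnorm(n_end, 20, 2)
  fvc_v[is_end] <- stats::rnorm(n_end, 1.25, 0.12)
  rn_v[is_end] <- stats::rnorm(n_end, 0.32, 0.04)
  pef_v[is_end] <- stats::rnorm(n_end, 32, 4)
  tab$h_cmh2o_ml <- h_v
  tab$g_cmh2o_ml <- tab$eta * h_v
  tab$fvc_ml <- fvc_v
  tab$fev01_ml <- tab$tiffeneau * fvc_v
  tab$rn_cmh2o_s_ml <- rn_v
  tab$pef_ml_s <- pef_v
  tab$eta <- NULL
  tab$tiffeneau <- NULL

  # BAL differential: score cells_scored cells per sacrificed animal
  p_true <- ifelse(tab$group[is_end] == "silica",
                   endp$neutrophil_silica[as.character(tab$week[is_end])],
                   endp$neutrophil_control)
  p_i <- pmin(pmax(p_true + stats::rnorm(n_end, 0, endp$neutrophil_sd),
                   0.001), 0.95)
  counts <- stats::rbinom(n_end, endp$cells_scored, p_i)
  neut <- rep(NA_real_, nrow(tab))
  neut[is_end] <- 100 * counts / endp$cells_scored
  tab$neutrophil_pct <- neut

  tab
}

#' Write/read a study table as CSV
#'
#' Long-format CSV, one row per animal x week; missing endpoint cells are
#' written empty.
#'
#' @param table Study table tibble.
#' @param path File path.
#' @return `write_study_table` returns `path` invisibly; `read_study_table`
#'   the tibble.
#' @export
write_study_table <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(animal_id = "c", group = "c",
                                          .default = "d"))
}
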