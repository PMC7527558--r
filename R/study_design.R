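#' Longitudinal study design
#'
#' Encodes the scan schedule and the cross-sectional sacrifice scheme: scans
#' at baseline, weekly through week 5, then every two weeks through week 15;
#' at weeks 1, 5, 9 and 15 a cohort of each group is sacrificed for endpoint
#' readouts. The study cohorts are 6/6, 6/10, 6/8 and 6/8 (control/silica)
#' at the four endpoints, so 24 control and 32 silica endpoint animals in
#' total. `extra_control`/`extra_silica` add scanned-only animals that are
#' never sacrificed (the published baseline silica headcount exceeds the
#' endpoint cohort sum by two; extras cover such animals without guessing
#' their fate).
#'
#' @param scan_weeks Ordered scan timepoints in weeks (baseline = 0).
#' @param endpoint_weeks Sacrifice weeks; must be a subset of `scan_weeks`.
#' @param n_control,n_silica Animals sacrificed per endpoint week.
#' @param extra_control,extra_silica Scanned-only animals per group.
#' @param seed Integer root seed for the simulated cohort.
#' @return A `study_design` list.
#' @export
study_design <- function(scan_weeks = c(0:5, 7, 9, 11, 13, 15),
                         endpoint_weeks = c(1, 5, 9, 15),
                         n_control = c(6, 6, 6, 6),
                         n_silica = c(6, 10, 8, 8),
                         extra_control = 0, extra_silica = 0,
                         seed = 1L) {
  stopifnot(length(n_control) == length(endpoint_weeks),
            length(n_silica) == length(endpoint_weeks),
            all(n_control >= 0), all(n_silica >= 0),
            extra_control >= 0, extra_silica >= 0)
  if (!all(endpoint_weeks %in% scan_weeks)) {
    stop("endpoint_weeks must be a subset of scan_weeks", call. = FALSE)
  }
  if (is.unsorted(scan_weeks, strictly = TRUE)) {
    stop("scan_weeks must be strictly increasing", call. = FALSE)
  }
  structure(list(scan_weeks = scan_weeks, endpoint_weeks = endpoint_weeks,
                 n_control = as.integer(n_control),
                 n_silica = as.integer(n_silica),
                 extra_control = as.integer(extra_control),
                 extra_silica = as.integer(extra_silica),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Parametric biomarker trajectories
#'
#' Ground-truth group trajectories of the scan-derived biomarkers. The
#' silica non-aerated lung volume peaks at week 1 and relaxes to a stable
#' elevated plateau; the aerated volume dips transiently at week 1 and then
#' rises above baseline; the total volume increases progressively; controls
#' drift only slightly with aging. Disease deviations are scaled per animal
#' by a severity factor (between-animal SD `sd_severity`), each animal
#' carries a small baseline intercept (`sd_baseline`, mL) and every scan
#' adds measurement noise (`meas_sd`, mL). Volume units are mL, weeks are
#' weeks; defaults are plausible mouse-scale values chosen once for the
#' study conditions.
#'
#' @param base_aerated,base_non_aerated Baseline compartment volumes (mL).
#' @param drift_aerated,drift_non_aerated Relative aging drift per week.
#' @param na_effect Week-1 peak increase of non-aerated volume (mL, silica).
#' @param na_plateau Plateau fraction of the week-1 peak retained late.
#' @param tau_na Decay constant (weeks) of the peak-to-plateau relaxation.
#' @param ae_dip Week-1 transient aerated-volume drop (mL, silica).
#' @param tau_dip Decay constant (weeks) of the dip.
#' @param ae_overshoot Late aerated-volume overshoot amplitude (mL, silica).
#' @param tau_overshoot Rise constant (weeks) of the overshoot.
#' @param sd_severity Between-animal SD of the severity factor (mean 1).
#' @param sd_baseline Between-animal SD of per-compartment baselines (mL).
#' @param meas_sd Per-scan measurement noise SD on each volume (mL).
#' @param hu_aerated,hu_non_aerated Effective densities (HU) of the two
#'   classes used to synthesize mean lung density.
#' @param mld_noise_sd Measurement noise on mean lung density (HU).
#' @return A `trajectory_model` list.
#' @export
trajectory_model <- function(base_aerated = 0.42, base_non_aerated = 0.20,
                             drift_aerated = 0.002,
                             drift_non_aerated = 0.001,
                             na_effect = 0.18, na_plateau = 0.85,
                             tau_na = 2,
                             ae_dip = 0.08, tau_dip = 2,
                             ae_overshoot = 0.10, tau_overshoot = 6,
                             sd_severity = 0.25, sd_baseline = 0.02,
                             meas_sd = 0.01,
                             hu_aerated = -480, hu_non_aerated = -60,
                             mld_noise_sd = 10) {
  stopifnot(base_aerated > 0, base_non_aerated > 0, na_effect >= 0,
            na_plateau > 0, na_plateau <= 1, sd_severity >= 0,
            sd_baseline >= 0, meas_sd >= 0)
  structure(as.list(environment()), class = "trajectory_model")
}

# disease deviation profiles (multiply by per-animal severity); 0 at week 0
na_profile <- function(traj, week) {
  ifelse(week <= 0, 0,
         traj$na_effect *
           (traj$na_plateau +
              (1 - traj$na_plateau) * exp(-(pmax(week, 1) - 1) / traj$tau_na)))
}

ae_profile <- function(traj, week) {
  ifelse(week <= 0, 0,
         -traj$ae_dip * exp(-(pmax(week, 1) - 1) / traj$tau_dip) +
           traj$ae_overshoot * (1 - exp(-week / traj$tau_overshoot)))
}

#' Expected biomarker trajectory
#'
#' Population-mean curves (severity = 1, no noise) of the aerated,
#' non-aerated and total lung volume for a group.
#'
#' @param traj A [trajectory_model()].
#' @param week Numeric week(s).
#' @param group `"control"` or `"silica"`.
#' @return Tibble with `week`, `aerated_ml`, `non_aerated_ml`, `total_ml`.
#' @export
expected_trajectory <- function(traj, week, group = c("silica", "control")) {
  group <- match.arg(group)
  dis <- as.numeric(group == "silica")
  ae <- traj$base_aerated * (1 + traj$drift_aerated * week) +
    dis * ae_profile(traj, week)
  na <- traj$base_non_aerated * (1 + traj$drift_non_aerated * week) +
    dis * na_profile(traj, week)
  tibble::tibble(week = week, aerated_ml = ae, non_aerated_ml = na,
                 total_ml = ae + na)
}

# pooled mean/SD of a measured biomarker across silica endpoint animals
# (mixture over endpoint weeks weighted by cohort size); used to standardize
# the endpoint links so sample correlations converge to their targets
silica_pooled_moments <- function(traj, design,
                                  var = c("non_aerated_ml", "aerated_ml",
                                          "total_ml")) {
  var <- match.arg(var)
  w <- design$endpoint_weeks
  p <- design$n_silica / sum(design$n_silica)
  mu <- expected_trajectory(traj, w, "silica")[[var]]
  dev <- switch(var,
    non_aerated_ml = na_profile(traj, w),
    aerated_ml = ae_profile(traj, w),
    total_ml = na_profile(traj, w) + ae_profile(traj, w))
  n_ind <- if (var == "total_ml") 2 else 1  # independent noise terms summed
  v <- (dev * traj$sd_severity)^2 +
    n_ind * (traj$sd_baseline^2 + traj$meas_sd^2)
  m <- sum(p * mu)
  list(mean = m, sd = sqrt(sum(p * (v + mu^2)) - m^2))
}

#' Endpoint readout model
#'
#' Links each terminal readout to a measured imaging biomarker through a
#' standardized linear-plus-noise model calibrated so that, across silica
#' endpoint animals pooled over cohorts, the Pearson correlation converges
#' to `target_r`. Default targets are the reported imaging-endpoint
#' coefficients: aerated volume vs inspiratory capacity 0.6612, total volume
#' vs tissue hysteresivity 0.4027, non-aerated volume vs Tiffeneau index
#' -0.7764 (inverse relationship; the magnitude is the reported value),
#' non-aerated vs BAL protein 0.5557, vs serum SP-D 0.8445 and vs
#' hydroxyproline 0.4187. The forced-oscillation and forced-expiration raw
#' parameters are emitted so that the derived indices (eta = G/H, Tiffeneau
#' = FEV_0.1/FVC) carry the links. BAL differential counts score 200 cells
#' per animal; the silica neutrophil fraction decays from its week-1 peak to
#' 20% at week 15.
#'
#' @param links Named list of link specs (`x`, `target_r`, `mean`, `sd`,
#'   `lo`, `hi`); see defaults.
#' @param neutrophil_silica Named vector of true silica neutrophil fractions
#'   by endpoint week.
#' @param neutrophil_control Control neutrophil fraction.
#' @param neutrophil_sd Between-animal SD of the neutrophil fraction.
#' @param cells_scored Cells scored per differential count.
#' @return An `endpoint_model` list.
#' @export
endpoint_model <- function(links = NULL,
                           neutrophil_silica = c(`1` = 0.45, `5` = 0.30,
                                                 `9` = 0.24, `15` = 0.20),
                           neutrophil_control = 0.015,
                           neutrophil_sd = 0.04,
                           cells_scored = 200L) {
  default_links <- list(
    ic_ml = list(x = "aerated_ml", target_r = 0.6612,
                 mean = 0.95, sd = 0.12, lo = 0.2, hi = Inf),
    eta = list(x = "total_ml", target_r = 0.4027,
               mean = 0.17, sd = 0.025, lo = 0.02, hi = Inf),
    tiffeneau = list(x = "non_aerated_ml", target_r = -0.7764,
                     mean = 0.78, sd = 0.07, lo = 0.05, hi = 0.99),
    bal_protein_mg_ml = list(x = "non_aerated_ml", target_r = 0.5557,
                             mean = 0.45, sd = 0.18, lo = 0.02, hi = Inf),
    serum_spd_ng_ml = list(x = "non_aerated_ml", target_r = 0.8445,
                           mean = 60, sd = 25, lo = 1, hi = Inf),
    oh_proline_ug = list(x = "non_aerated_ml", target_r = 0.4187,
                         mean = 180, sd = 50, lo = 10, hi = Inf),
    bal_total_cells_k = list(x = "non_aerated_ml", target_r = 0.6,
                             mean = 400, sd = 150, lo = 20, hi = Inf),
    il13_pg_ml = list(x = "non_aerated_ml", target_r = 0.6,
                      mean = 45, sd = 20, lo = 0.5, hi = Inf),
    mcp1_pg_ml = list(x = "non_aerated_ml", target_r = 0.6,
                      mean = 80, sd = 35, lo = 0.5, hi = Inf),
    mip2_pg_ml = list(x = "non_aerated_ml", target_r = 0.6,
                      mean = 50, sd = 22, lo = 0.5, hi = Inf),
    tnfa_pg_ml = list(x = "non_aerated_ml", target_r = 0.6,
                      mean = 25, sd = 11, lo = 0.5, hi = Inf)
  )
  if (!is.null(links)) default_links[names(links)] <- links
  for (l in default_links) {
    stopifnot(abs(l$target_r) < 1, l$sd >= 0)
  }
  stopifnot(all(neutrophil_silica > 0 & neutrophil_silica < 1),
            neutrophil_control > 0, neutrophil_control < 1,
            neutrophil_sd >= 0, cells_scored >= 1)
  structure(list(links = default_links,
                 neutrophil_silica = neutrophil_silica,
                 neutrophil_control = neutrophil_control,
                 neutrophil_sd = neutrophil_sd,
                 cells_scored = as.integer(cells_scored)),
            class = "endpoint_model")
}
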