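#' Respiratory model for gating and simulation
#'
#' Periodic breathing model used both to drive the synthetic thorax through
#' its cycle and to assign projection timestamps to phases. The aerated lung
#' volume follows `v(phi) = V_ee * (1 + tidal_fraction * sin^2(pi * phi))`,
#' with phase 0 at end-expiration (unique volume minimum). The ventilation
#' protocol runs at 150 breaths/min with a tidal volume of 10 mL/kg; for a
#' ~25 g mouse with ~0.6 mL end-expiratory lung volume that motivates the
#' default `tidal_fraction` of 0.4.
#'
#' @param rate Breathing rate in breaths per minute (> 0).
#' @param tidal_fraction Tidal volume as a fraction of the end-expiratory
#'   lung volume (>= 0).
#' @param phase_origin Time of an end-expiration instant, in ms.
#' @return A `respiratory_model` list.
#' @export
respiratory_model <- function(rate = 150, tidal_fraction = 0.4,
                              phase_origin = 0) {
  stopifnot(rate > 0, tidal_fraction >= 0)
  structure(list(rate = rate, tidal_fraction = tidal_fraction,
                 phase_origin = phase_origin),
            class = "respiratory_model")
}

#' Acquisition protocol for list-mode scanning
#'
#' The scan protocol acquires projections in list mode: views at fixed
#' angular increments over a total rotation, several projections per view,
#' each with a fixed exposure. The study protocol is 0.9 degree increments
#' over 220 degrees, 9 projections per view, 55 ms exposure.
#'
#' @param total_angle Total rotation in degrees.
#' @param angle_increment Angular step between views in degrees.
#' @param projections_per_view Projections acquired at each view.
#' @param exposure Exposure time per projection in ms.
#' @return An `acquisition_spec` list.
#' @export
acquisition_spec <- function(total_angle = 220, angle_increment = 0.9,
                             projections_per_view = 9, exposure = 55) {
  stopifnot(total_angle > 0, angle_increment > 0, projections_per_view >= 1,
            exposure > 0)
  if (total_angle / angle_increment < 1) {
    stop("total_angle/angle_increment must be >= 1", call. = FALSE)
  }
  structure(list(total_angle = total_angle, angle_increment = angle_increment,
                 projections_per_view = as.integer(projections_per_view),
                 exposure = exposure),
            class = "acquisition_spec")
}

#' Simulate a list-mode projection event stream
#'
#' Emits the timestamped projection events of one scan: views at
#' `angle_increment` steps (view count `floor(total/increment) + 1`,
#' including both ends), `projections_per_view` consecutive events per view,
#' event k starting at `k * exposure` ms. Each event also carries its true
#' respiratory phase (of the exposure midpoint) for test oracles; the gating
#' stage never reads it.
#'
#' @param acq An [acquisition_spec()].
#' @param resp A [respiratory_model()] supplying the true phase column.
#' @return Tibble with columns `event_id`, `view_index`, `angle_deg`,
#'   `t_start_ms`, `t_end_ms`, `true_phase`.
#' @export
make_listmode_stream <- function(acq = acquisition_spec(),
                                 resp = respiratory_model()) {
  stopifnot(inherits(acq, "acquisition_spec"),
            inherits(resp, "respiratory_model"))
  n_views <- floor(acq$total_angle / acq$angle_increment) + 1
  n_events <- n_views * acq$projections_per_view
  event_id <- seq_len(n_events) - 1L
  view_index <- event_id %/% acq$projections_per_view
  t_start <- event_id * acq$exposure
  t_end <- t_start + acq$exposure
  tibble::tibble(
    event_id = event_id,
    view_index = as.integer(view_index),
    angle_deg = view_index * acq$angle_increment,
    t_start_ms = t_start,
    t_end_ms = t_end,
    true_phase = phase_of((t_start + t_end) / 2, resp)
  )
}
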