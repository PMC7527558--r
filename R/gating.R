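#' Respiratory phase of a timestamp
#'
#' Maps a time to its fraction of the breathing cycle:
#' `phi = ((t - phase_origin) mod T) / T` with period `T = 60000 / rate` ms.
#' Phase 0 is end-expiration.
#'
#' @param t Time(s) in ms.
#' @param resp A [respiratory_model()].
#' @return Phase fraction(s) in `[0, 1)`.
#' @export
phase_of <- function(t, resp) {
  stopifnot(inherits(resp, "respiratory_model"), resp$rate > 0)
  period <- 60000 / resp$rate
  ((t - resp$phase_origin) %% period) / period
}

# centered bin index for a phase: bin k covers [(k - 1/2)/n, (k + 1/2)/n) mod 1
phase_bin_index <- function(phi, n_bins) {
  as.integer(floor(phi * n_bins + 0.5) %% n_bins)
}

#' Bin centers of the centered phase-binning convention
#'
#' @param n_bins Number of bins.
#' @return Numeric vector of bin-center phases `k / n_bins`.
#' @export
phase_bin_centers <- function(n_bins) (seq_len(n_bins) - 1) / n_bins

#' Retrospectively sort list-mode events into respiratory-phase bins
#'
#' Time-based sorting of projection events: each event is assigned by the
#' respiratory phase of its exposure midpoint `(t_start + t_end) / 2` to one
#' of `n_bins` half-open bins centered on the phases `k / n_bins` (bin k
#' covers `[(k - 1/2)/n, (k + 1/2)/n)` modulo 1). Centering the bins on
#' quarter phases makes end-expiration a bin center rather than a bin edge.
#' With the default four bins this reproduces the four-phase (4D) sorting of
#' the acquisition protocol.
#'
#' @param events Event table from [make_listmode_stream()] (or any table
#'   with `event_id`, `t_start_ms`, `t_end_ms`).
#' @param resp A [respiratory_model()].
#' @param n_bins Number of phase bins (default 4).
#' @return A `phase_binning`: list with `n_bins`, `assignment` (tibble
#'   `event_id`, `phase`, `bin`), and `bin_sizes`.
#' @export
assign_bins <- function(events, resp, n_bins = 4) {
  stopifnot(n_bins >= 1)
  if (nrow(events) == 0) stop("empty event table", call. = FALSE)
  req <- c("event_id", "t_start_ms", "t_end_ms")
  if (!all(req %in% names(events))) {
    stop("events must have columns event_id, t_start_ms, t_end_ms",
         call. = FALSE)
  }
  phi <- phase_of((events$t_start_ms + events$t_end_ms) / 2, resp)
  bin <- phase_bin_index(phi, n_bins)
  assignment <- tibble::tibble(event_id = events$event_id, phase = phi,
                               bin = bin)
  sizes <- tabulate(bin + 1L, nbins = n_bins)
  structure(list(n_bins = as.integer(n_bins), assignment = assignment,
                 bin_sizes = sizes),
            class = "phase_binning")
}

#' @export
print.phase_binning <- function(x, ...) {
  cat(sprintf("<phase_binning> %d events in %d bins: %s\n",
              nrow(x$assignment), x$n_bins,
              paste(x$bin_sizes, collapse = ", ")))
  invisible(x)
}

#' Select the end-expiration phase bin
#'
#' Returns the bin whose center phase is nearest 0 (circular distance),
#' i.e. the bin over which the breathing waveform's mean lung volume is
#' minimal; ties break toward the lower index. Under the centered-bin
#' convention this is bin 0. The reported biomarkers are computed on this
#' bin's reconstruction.
#'
#' @param binning A `phase_binning` from [assign_bins()].
#' @param resp A [respiratory_model()] (waveform convention; the centered
#'   waveform has its minimum at phase 0).
#' @return Integer bin index.
#' @export
select_end_expiration <- function(binning, resp = respiratory_model()) {
  stopifnot(inherits(binning, "phase_binning"), binning$n_bins >= 2)
  centers <- phase_bin_centers(binning$n_bins)
  d <- pmin(centers, 1 - centers)  # circular distance to phase 0
  as.integer(which.min(d) - 1L)    # which.min takes the first = lowest index
}

#' Pick the end-expiration volume from per-phase reconstructions
#'
#' Joins the generator's per-phase volumes to the gating result and returns
#' the volume of the selected end-expiration bin. Volumes are matched by
#' their `bin` label when present, so input order does not matter; otherwise
#' positional order `0..n_bins-1` is assumed.
#'
#' @param phase_volumes List of volumes (one per bin), each optionally
#'   carrying a `bin` element/attribute.
#' @param binning A `phase_binning`.
#' @param resp A [respiratory_model()].
#' @return The selected volume.
#' @export
per_bin_volumes <- function(phase_volumes, binning,
                            resp = respiratory_model()) {
  stopifnot(inherits(binning, "phase_binning"))
  if (length(phase_volumes) != binning$n_bins) {
    stop("consistency error: need exactly one volume per bin", call. = FALSE)
  }
  if (binning$n_bins == 1) return(phase_volumes[[1]])
  sel <- select_end_expiration(binning, resp)
  bins <- vapply(phase_volumes, function(v) {
    b <- if (!is.null(v$bin)) v$bin else attr(v, "bin")
    if (is.null(b)) NA_integer_ else as.integer(b)
  }, integer(1))
  if (anyNA(bins)) bins <- seq_along(phase_volumes) - 1L
  if (anyDuplicated(bins) || !all(sort(bins) == seq_along(bins) - 1L)) {
    stop("consistency error: bin labels must be a permutation of 0..n_bins-1",
         call. = FALSE)
  }
  phase_volumes[[which(bins == sel)]]
}

#' Write/read a phase binning as CSV
#'
#' @param binning A `phase_binning`.
#' @param path File path.
#' @return `write_binning` returns `path` invisibly; `read_binning` a tibble.
#' @export
write_binning <- function(binning, path) {
  readr::write_csv(binning$assignment, path)
  invisible(path)
}

#' @rdname write_binning
#' @export
read_binning <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
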