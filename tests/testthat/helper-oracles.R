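# independent brute-force oracles used across tests

# most frequent value by explicit counting; ties broken toward the lower value
brute_mode <- function(values) {
  uu <- sort(unique(values))
  counts <- vapply(uu, function(u) sum(values == u), numeric(1))
  uu[which.max(counts)]
}

# per-event loop: recompute the phase and scan the centered bin intervals
brute_assign <- function(events, resp, n_bins) {
  period <- 60000 / resp$rate
  vapply(seq_len(nrow(events)), function(i) {
    tm <- (events$t_start_ms[i] + events$t_end_ms[i]) / 2
    phi <- ((tm - resp$phase_origin) %% period) / period
    for (k in 0:(n_bins - 1)) {
      lo <- (k - 0.5) / n_bins
      hi <- (k + 0.5) / n_bins
      in_bin <- if (lo < 0) (phi >= lo %% 1 || phi < hi) else
        (phi >= lo && phi < hi)
      if (in_bin) return(k)
    }
    stop("unassigned event")
  }, numeric(1))
}

# small desk-scale specs shared by phantom tests
small_pspec <- function(noise_sd = 0, seed = 1, grid = 48, voxel = 0.3) {
  phantom_spec(grid_shape = rep(grid, 3), voxel_size = voxel,
               noise_sd = noise_sd, seed = seed)
}
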