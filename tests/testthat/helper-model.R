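# Shared fixtures, built in code and cached per test run.

# small head model for fast unit tests
small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sens <- make_standard_montage(16)
      src <- make_grid_source_space(0.035, 0.08)
      lf <- make_spherical_leadfield(sens, src)
      cache <<- list(sens = sens, src = src, lf = lf,
                     atlas = assign_regions(src))
    }
    cache
  }
})

# the 32-channel / ~200-voxel model the localization and recovery
# properties are stated for
acc_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sens <- make_standard_montage(32)
      src <- make_grid_source_space(0.022, 0.08)
      lf <- make_spherical_leadfield(sens, src)
      cache <<- list(sens = sens, src = src, lf = lf,
                     atlas = assign_regions(src))
    }
    cache
  }
})

# deterministic choice of the region hosting the simulated P300 source:
# whatever region owns the voxel nearest a right-parietal point
pick_source_region <- function(model, target = c(0.03, -0.03, 0.05)) {
  vox <- which.min(colSums((t(model$src$positions) - target)^2))
  model$atlas$region_of_voxel[vox]
}

# wrap a bare data matrix as an eeg_recording for preprocessing tests
as_recording <- function(data, srate, events, sensors = NULL,
                         meta = subject_meta("test")) {
  if (is.null(sensors)) {
    sensors <- make_standard_montage(max(nrow(data), 8L))
    sensors$labels <- sensors$labels[seq_len(nrow(data))]
    sensors$positions <- sensors$positions[seq_len(nrow(data)), , drop = FALSE]
  }
  structure(list(data = data, srate = srate, events = events,
                 sensors = sensors, meta = meta),
            class = "eeg_recording")
}

# region_activity with prescribed traces, for the iota unit tests
make_activity <- function(traces, bin_width = 0.005, t0 = 0,
                          condition = "TGT") {
  I <- do.call(rbind, traces)
  rownames(I) <- names(traces)
  structure(
    list(regions = names(traces), I = I,
         bin_times = t0 + bin_width * (seq_len(ncol(I)) - 1L),
         bin_width = bin_width, condition = condition),
    class = "region_activity")
}
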