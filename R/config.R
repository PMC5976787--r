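#' Default pipeline configuration
#'
#' Returns the configuration used by [run_pipeline()] and the command-line
#' driver. The defaults encode the oddball protocol (four series of 100
#' stimuli, 20% targets, 500 ms display), the 256-channel dense-array
#' montage, the 5 ms Brodmann-area binning grid, and the charge-integration
#' window \eqn{[t_1, t_2] = [280, 600]} ms after stimulus onset.
#'
#' @param ... named overrides for individual entries.
#' @return A named list of configuration values:
#' \describe{
#'   \item{n_channels}{montage size (default 256).}
#'   \item{srate}{sampling rate in Hz for simulation (default 500).}
#'   \item{n_series, series_len, target_frac}{stimulus schedule: 4 series of
#'     100 stimuli, 20% targets; the first series is a test series excluded
#'     from analysis.}
#'   \item{stimulus_duration, isi}{stimulus display time 0.5 s and
#'     inter-stimulus interval 1.5 s.}
#'   \item{window, baseline}{epoch limits (-0.2, 0.8) s and baseline
#'     interval (-0.2, 0) s relative to stimulus onset.}
#'   \item{bandpass}{zero-phase band-pass edges in Hz, `NULL` to disable.}
#'   \item{ptp_threshold, flat_threshold}{epoch rejection thresholds in uV.}
#'   \item{bin_width}{region-activity bin width in seconds (default 0.005).}
#'   \item{t1, t2}{charge-integration window in seconds (0.280, 0.600).}
#'   \item{region_statistic}{voxel-to-region reduction: mean, max or sum.}
#'   \item{tolerance, max_report}{most-active-region reporting: regions
#'     within 5% of the top charge are co-reported, at most 2.}
#'   \item{alpha, snr}{inverse regularization ("auto" scales by assumed
#'     signal-to-noise ratio, default 3).}
#'   \item{conductivity, sensor_radius, source_radius}{spherical head model:
#'     0.33 S/m, 9 cm sensor sphere, 8 cm source sphere.}
#' }
#' @examples
#' cfg <- default_config()
#' cfg$bin_width            # 0.005 s
#' c(cfg$t1, cfg$t2)        # 0.28 0.60 s
#' @export
default_config <- function(...) {
  cfg <- list(
    n_channels = 256L,
    srate = 500,
    n_series = 4L,
    series_len = 100L,
    target_frac = 0.2,
    stimulus_duration = 0.5,
    isi = 1.5,
    window = c(-0.2, 0.8),
    baseline = c(-0.2, 0),
    bandpass = c(0.5, 40),
    ptp_threshold = 150,
    flat_threshold = 0.1,
    bin_width = 0.005,
    t1 = 0.280,
    t2 = 0.600,
    region_statistic = "mean",
    tolerance = 0.05,
    max_report = 2L,
    alpha = "auto",
    snr = 3,
    conductivity = 0.33,
    sensor_radius = 0.09,
    source_radius = 0.08
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop_invalid("config overrides must be named")
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop_invalid("unknown config entries: %s", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  cfg
}
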