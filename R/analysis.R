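# Region-level analysis: aggregate standardized source amplitudes to
# Brodmann-area time courses on a 5 ms grid, rank the most active areas by
# integrated charge, and compute iota — the charge
#   iota = q(BA, tau) = integral_{tau+t1}^{tau+t2} I(BA, tau, t) dt
# over the window t1 = 280 ms, t2 = 600 ms after stimulus onset tau, the
# standard interval in which the P300 deflection is observed.

#' Aggregate a source estimate to region time courses
#'
#' Reduces voxel-level standardized current amplitudes to one time course
#' per reported region: first the chosen statistic over the region's member
#' voxels, then the mean over the samples of each bin. Region labels pass
#' through the atlas merge map, so BA1/BA2/BA3 report jointly as S1.
#'
#' @param stc a `source_estimate`.
#' @param atlas a `ba_atlas` over the same source space.
#' @param bin_width bin width in seconds (default 0.005, the 5 ms grid);
#'   must be at least one sample.
#' @param statistic voxel reduction: "mean" (default), "max" or "sum".
#' @return Object of class `region_activity`: `regions` (ordered labels
#'   after merging), `I` (region x bin matrix of current amplitude, model
#'   units), `bin_times` (bin start times, seconds relative to onset),
#'   `bin_width`, `condition`.
#' @export
aggregate_to_regions <- function(stc, atlas, bin_width = 0.005,
                                 statistic = c("mean", "max", "sum")) {
  stopifnot(inherits(stc, "source_estimate"), inherits(atlas, "ba_atlas"))
  statistic <- match.arg(statistic)
  if (length(atlas$region_of_voxel) != stc$n_voxels) {
    stop_invalid("atlas covers %d voxels, source estimate has %d",
                 length(atlas$region_of_voxel), stc$n_voxels)
  }
  if (!is.na(stc$srate) && bin_width < 1 / stc$srate - 1e-12) {
    stop_invalid("bin_width must be at least one sample (1/srate)")
  }
  labels <- atlas$merge_map(atlas$region_of_voxel)
  regions <- sort(unique(labels))
  reduce <- switch(statistic, mean = colMeans,
                   max = function(m) apply(m, 2, max), sum = colSums)
  region_trace <- t(vapply(regions, function(rg) {
    reduce(stc$magnitude[labels == rg, , drop = FALSE])
  }, numeric(ncol(stc$magnitude))))

  t0 <- stc$times[1]
  bin_idx <- floor((stc$times - t0) / bin_width + 1e-9)
  n_bins <- max(bin_idx) + 1L
  I <- t(apply(region_trace, 1, function(tr) {
    as.numeric(tapply(tr, bin_idx, mean))
  }))
  rownames(I) <- regions
  structure(
    list(regions = regions, I = I,
         bin_times = t0 + bin_width * (seq_len(n_bins) - 1L),
         bin_width = bin_width, condition = stc$condition),
    class = "region_activity"
  )
}

#' @export
print.region_activity <- function(x, ...) {
  cat(sprintf("<region_activity> %d regions x %d bins of %g ms (%s)\n",
              length(x$regions), ncol(x$I), 1000 * x$bin_width,
              ifelse(is.na(x$condition), "unlabeled", x$condition)))
  invisible(x)
}

#' Charge through a region: the iota observable
#'
#' Integrates the region's binned current amplitude over the window
#' `[t1, t2]` by the trapezoidal rule on bin centers, with linear
#' interpolation where a window edge falls between centers. With the
#' defaults this is the electric charge that flowed through the region
#' between 280 and 600 ms after stimulus onset, in (model current
#' units) x seconds.
#'
#' @param activity a `region_activity`.
#' @param region region label present in `activity$regions`.
#' @param t1,t2 integration limits in seconds relative to stimulus onset
#'   (defaults 0.280 and 0.600); `[t1, t2]` must lie within the covered
#'   bin-center range.
#' @return Object of class `iota_result`: `region`, `condition`, `iota`,
#'   `t1`, `t2`.
#' @examples
#' # a constant unit current integrates to the window width, 0.32
#' act <- structure(list(
#'     regions = "R9", I = matrix(1, 1, 200, dimnames = list("R9")),
#'     bin_times = seq(0, by = 0.005, length.out = 200),
#'     bin_width = 0.005, condition = "TGT"), class = "region_activity")
#' compute_iota(act, "R9")$iota
#' @export
compute_iota <- function(activity, region, t1 = 0.280, t2 = 0.600) {
  stopifnot(inherits(activity, "region_activity"))
  if (!region %in% activity$regions) {
    stop_invalid("region '%s' not present in activity", region)
  }
  if (t1 >= t2) stop_invalid("need t1 < t2")
  centers <- activity$bin_times + activity$bin_width / 2
  if (t1 < centers[1] - activity$bin_width / 2 - 1e-12 ||
      t2 > centers[length(centers)] + activity$bin_width / 2 + 1e-12) {
    stop_invalid("integration window [%g, %g] outside covered range", t1, t2)
  }
  y <- activity$I[region, ]
  inner <- centers[centers > t1 & centers < t2]
  xs <- c(t1, inner, t2)
  ys <- stats::approx(centers, y, xout = xs, rule = 2)$y
  structure(
    list(region = region, condition = activity$condition,
         iota = trapz(xs, ys), t1 = t1, t2 = t2),
    class = "iota_result"
  )
}

#' @export
print.iota_result <- function(x, ...) {
  cat(sprintf("<iota> %s (%s): %.4g units*s over [%g, %g] s\n",
              x$region, ifelse(is.na(x$condition), "?", x$condition),
              x$iota, x$t1, x$t2))
  invisible(x)
}

#' Most active regions by integrated charge
#'
#' Ranks regions by iota over `[t1, t2]`, descending. Not only the peak
#' current matters but how long it was maintained, so the ranking criterion
#' is the charge, not the maximum. Returns the top region plus any region
#' whose charge is within `tolerance` of the top, capped at `max_report`
#' (default 2, matching the at-most-two-areas reporting convention). Ties
#' break by label order.
#'
#' @param activity a `region_activity`.
#' @param t1,t2 integration window, seconds (defaults 0.280, 0.600).
#' @param tolerance co-reporting threshold as a fraction of the top charge
#'   (default 0.05).
#' @param max_report maximum regions returned (default 2).
#' @return data.frame with columns `region` and `iota`, ranked.
#' @export
most_active_regions <- function(activity, t1 = 0.280, t2 = 0.600,
                                tolerance = 0.05, max_report = 2L) {
  stopifnot(inherits(activity, "region_activity"))
  if (tolerance < 0 || tolerance > 1) stop_invalid("tolerance must be in [0, 1]")
  if (max_report < 1) stop_invalid("max_report must be at least 1")
  if (length(activity$regions) == 0L) {
    return(data.frame(region = character(), iota = numeric()))
  }
  iotas <- vapply(activity$regions,
                  function(rg) compute_iota(activity, rg, t1, t2)$iota, 0)
  ord <- order(-iotas, activity$regions)
  top <- iotas[ord[1]]
  keep <- ord[iotas[ord] >= (1 - tolerance) * top]
  keep <- keep[seq_len(min(length(keep), max_report))]
  data.frame(region = activity$regions[keep], iota = unname(iotas[keep]),
             row.names = NULL)
}

#' Run the full analysis pipeline on one recording
#'
#' Chains the stages: optional band-pass filter, epoching (test series
#' excluded), threshold artifact rejection, condition averaging (STD and
#' TGT separately), the sLORETA inverse, region aggregation on the 5 ms
#' grid, most-active-region ranking and iota for each reported region.
#'
#' @param recording an `eeg_recording`.
#' @param leadfield the `leadfield` matching the recording's montage.
#' @param atlas a `ba_atlas` over the lead field's source space.
#' @param config configuration list from [default_config()].
#' @param op optional precomputed `inverse_operator` (recomputed from the
#'   lead field when NULL).
#' @return Object of class `pipeline_result`: per-condition list
#'   (`conditions$STD`, `conditions$TGT`) each holding `activity`
#'   (`region_activity`), `ranked` (most-active data.frame), `iota` (list
#'   of `iota_result` for the reported regions) and `evoked_n`; plus
#'   `meta`, `n_epochs`, `n_kept` and the `config` snapshot.
#' @export
run_pipeline <- function(recording, leadfield, atlas,
                         config = default_config(), op = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) != nrow(leadfield$matrix)) {
    stop_invalid("recording and lead field disagree on channel count")
  }
  if (!is.null(config$bandpass)) {
    recording <- bandpass_filter(recording, config$bandpass[1],
                                 config$bandpass[2])
  }
  epochs <- epoch_recording(recording, window = config$window,
                            baseline = config$baseline)
  epochs <- reject_artifacts(epochs, ptp_threshold = config$ptp_threshold,
                             flat_threshold = config$flat_threshold)
  if (is.null(op)) {
    op <- compute_inverse_operator(leadfield, alpha = config$alpha,
                                   snr = config$snr)
  }
  conditions <- lapply(c(STD = "STD", TGT = "TGT"), function(cond) {
    ev <- average_epochs(epochs, cond)
    stc <- apply_sloreta(ev, op)
    act <- aggregate_to_regions(stc, atlas, bin_width = config$bin_width,
                                statistic = config$region_statistic)
    ranked <- most_active_regions(act, t1 = config$t1, t2 = config$t2,
                                  tolerance = config$tolerance,
                                  max_report = config$max_report)
    iota <- lapply(ranked$region, function(rg) {
      compute_iota(act, rg, t1 = config$t1, t2 = config$t2)
    })
    list(activity = act, ranked = ranked, iota = iota,
         evoked_n = ev$n_averaged)
  })
  structure(
    list(conditions = conditions, meta = recording$meta,
         n_epochs = length(epochs$conditions), n_kept = sum(epochs$kept),
         config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s: %d/%d epochs kept\n",
              x$meta$subject_id, x$n_kept, x$n_epochs))
  for (cond in names(x$conditions)) {
    r <- x$conditions[[cond]]$ranked
    cat(sprintf("  %s most active: %s\n", cond,
                paste(sprintf("%s (iota %.3g)", r$region, r$iota),
                      collapse = ", ")))
  }
  invisible(x)
}
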