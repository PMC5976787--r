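# Per-subject and cohort reporting mirroring the field's tabular
# convention: at most two most-active areas per condition, with the charge
# (iota) of each, per subject; counts of reported areas per diagnosis at
# the cohort level.

#' Build a per-subject report from pipeline outputs
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param meta optional `subject_meta` override (defaults to the one
#'   carried by the result).
#' @return Object of class `subject_report`: `subject_id`, `diagnosis`,
#'   `std_regions`, `tgt_regions` (each at most `max_report` labels),
#'   `std_iota`, `tgt_iota` (aligned values), `t1`, `t2`, `params`.
#' @export
build_subject_report <- function(result, meta = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  meta <- meta %||% result$meta
  grab <- function(cond) {
    c1 <- result$conditions[[cond]]
    if (is.null(c1)) return(list(regions = character(), iota = numeric()))
    list(regions = c1$ranked$region, iota = c1$ranked$iota)
  }
  std <- grab("STD")
  tgt <- grab("TGT")
  structure(
    list(subject_id = meta$subject_id, diagnosis = meta$diagnosis,
         std_regions = std$regions, tgt_regions = tgt$regions,
         std_iota = std$iota, tgt_iota = tgt$iota,
         t1 = result$config$t1, t2 = result$config$t2,
         params = result$config),
    class = "subject_report"
  )
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("<subject_report> %s (%s)\n  STD: %s\n  TGT: %s\n",
              x$subject_id, x$diagnosis,
              paste(x$std_regions, collapse = ", "),
              paste(x$tgt_regions, collapse = ", ")))
  invisible(x)
}

#' Subject-report table I/O
#'
#' Reports are written long-format as CSV with columns `subject_id`,
#' `diagnosis`, `condition`, `rank`, `region`, `iota`, `t1`, `t2` — one row
#' per reported region — and mirrored as JSON. Values round-trip exactly.
#' [format_subject_row()] renders the wide one-row-per-subject layout with
#' comma-joined region lists (e.g. "L36, R36") used in printed tables.
#'
#' @param reports a `subject_report` or list of them.
#' @param path output path; the JSON mirror replaces the extension.
#' @return the reports read, or `path` invisibly for the writer.
#' @name report_io
NULL

report_rows <- function(rep) {
  row <- function(cond, regions, iota) {
    if (length(regions) == 0L) return(NULL)
    data.frame(subject_id = rep$subject_id, diagnosis = rep$diagnosis,
               condition = cond, rank = seq_along(regions),
               region = regions, iota = iota, t1 = rep$t1, t2 = rep$t2)
  }
  rbind(row("STD", rep$std_regions, rep$std_iota),
        row("TGT", rep$tgt_regions, rep$tgt_iota))
}

#' @rdname report_io
#' @export
write_subject_reports <- function(reports, path) {
  if (inherits(reports, "subject_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, report_rows))
  utils::write.csv(df, path, row.names = FALSE)
  json_path <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(df, json_path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname report_io
#' @export
read_subject_reports <- function(path) {
  df <- utils::read.csv(path, colClasses = c(subject_id = "character",
                                             diagnosis = "character",
                                             condition = "character",
                                             region = "character"))
  lapply(split(df, factor(df$subject_id, levels = unique(df$subject_id))),
         function(d) {
           d <- d[order(match(d$condition, c("STD", "TGT")), d$rank), ]
           std <- d[d$condition == "STD", ]
           tgt <- d[d$condition == "TGT", ]
           structure(
             list(subject_id = d$subject_id[1], diagnosis = d$diagnosis[1],
                  std_regions = std$region, tgt_regions = tgt$region,
                  std_iota = std$iota, tgt_iota = tgt$iota,
                  t1 = d$t1[1], t2 = d$t2[1], params = NULL),
             class = "subject_report")
         })
}

#' @rdname report_io
#' @export
format_subject_row <- function(reports) {
  if (inherits(reports, "subject_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(
      subject_id = r$subject_id, diagnosis = r$diagnosis,
      std_most_active = paste(r$std_regions, collapse = ", "),
      tgt_most_active = paste(r$tgt_regions, collapse = ", "),
      iota_std = paste(signif(r$std_iota, 3), collapse = ", "),
      iota_tgt = paste(signif(r$tgt_iota, 3), collapse = ", "))
  }))
}

#' Cohort tally of most-active regions
#'
#' Counts how often each region is reported as most active, per diagnosis
#' and condition, over a list of subject reports. All listed regions count
#' (both when two areas are co-reported).
#'
#' @param reports list of `subject_report`s.
#' @return Object of class `cohort_summary`: `counts` data.frame
#'   (`diagnosis`, `condition`, `region`, `n`) and `n_subjects`.
#' @export
tally_cohort <- function(reports) {
  if (inherits(reports, "subject_report")) reports <- list(reports)
  if (length(reports) == 0L) stop_invalid("need at least one report")
  long <- do.call(rbind, lapply(reports, function(r) {
    rbind(
      if (length(r$std_regions))
        data.frame(diagnosis = r$diagnosis, condition = "STD",
                   region = r$std_regions),
      if (length(r$tgt_regions))
        data.frame(diagnosis = r$diagnosis, condition = "TGT",
                   region = r$tgt_regions))
  }))
  counts <- if (is.null(long)) {
    data.frame(diagnosis = character(), condition = character(),
               region = character(), n = integer())
  } else {
    agg <- stats::aggregate(list(n = rep(1L, nrow(long))),
                            long[, c("diagnosis", "condition", "region")],
                            sum)
    agg[order(agg$diagnosis, agg$condition, -agg$n, agg$region), ]
  }
  rownames(counts) <- NULL
  structure(list(counts = counts, n_subjects = length(reports)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d subjects\n", x$n_subjects))
  print(utils::head(x$counts, 10))
  invisible(x)
}

#' @rdname report_io
#' @export
write_cohort_summary <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  utils::write.csv(summary$counts, path, row.names = FALSE)
  json_path <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(n_subjects = summary$n_subjects, counts = summary$counts),
    json_path, digits = NA, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
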