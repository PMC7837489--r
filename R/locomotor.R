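# Locomotor activity: trajectories -> binned distance-moved series ->
# per-interval AUC metrics, normalized fast dark-photokinesis response, and
# lights-on windows.

#' Trajectory of one subject in one arena
#'
#' Per-frame, time-stamped positions. Missing positions (tracking dropouts)
#' are `NA` and handled downstream via the gap tolerance of
#' [distance_series()].
#'
#' @param t_s frame times in seconds, strictly increasing.
#' @param x_mm,y_mm positions in mm; `NA` marks a missing frame.
#' @param subject_id,genotype,arena_id identifiers.
#' @param frame_rate nominal acquisition rate, Hz.
#' @return A list of class `"trajectory"`.
#' @export
trajectory <- function(t_s, x_mm, y_mm, subject_id = "s1",
                       genotype = "unspecified", arena_id = "a1",
                       frame_rate = 60) {
  t_s <- as.numeric(t_s); x_mm <- as.numeric(x_mm); y_mm <- as.numeric(y_mm)
  stopifnot(length(t_s) == length(x_mm), length(t_s) == length(y_mm),
            frame_rate > 0)
  if (anyNA(t_s) || is.unsorted(t_s, strictly = TRUE))
    stop("frame times must be finite and strictly increasing")
  if (any(is.infinite(x_mm), na.rm = TRUE) || any(is.infinite(y_mm), na.rm = TRUE))
    stop("coordinates must be finite or NA")
  structure(list(t_s = t_s, x_mm = x_mm, y_mm = y_mm,
                 subject_id = as.character(subject_id),
                 genotype = as.character(genotype),
                 arena_id = as.character(arena_id),
                 frame_rate = frame_rate),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (%s): %d frames, %.1f s at %g Hz, %d missing\n",
              x$subject_id, x$genotype, length(x$t_s),
              diff(range(x$t_s)), x$frame_rate, sum(is.na(x$x_mm) | is.na(x$y_mm))))
  invisible(x)
}

#' Binned distance-moved series
#'
#' Sums Euclidean step lengths between consecutive tracked frames into
#' contiguous half-open time bins aligned to the schedule origin. A step is
#' assigned to the bin containing its midpoint. Tracking gaps up to
#' `gap_tolerance_s` are bridged by the straight-line step between the
#' flanking frames (linear interpolation); longer gaps contribute no distance
#' and flag every bin they touch, so flagged bins can be excluded from means.
#'
#' @param traj a [trajectory()].
#' @param bin_width_s bin width in seconds: 10 for the photokinesis assay,
#'   60 for diel trials.
#' @param origin_s time of the first bin edge (the schedule origin), seconds.
#' @param gap_tolerance_s longest tracking gap that is still interpolated.
#' @return A data.frame of class `"activity_series"` with columns
#'   `bin_start_s`, `distance_mm`, `flagged`, plus attributes `bin_width_s`,
#'   `origin_s`, `subject_id` and `genotype`.
#' @export
distance_series <- function(traj, bin_width_s = 10, origin_s = 0,
                            gap_tolerance_s = 1) {
  stopifnot(inherits(traj, "trajectory"), bin_width_s > 0, gap_tolerance_s > 0)
  ok <- !is.na(traj$x_mm) & !is.na(traj$y_mm)
  if (sum(ok) < 2) stop("trajectory has fewer than 2 tracked frames")
  t <- traj$t_s[ok]; x <- traj$x_mm[ok]; y <- traj$y_mm[ok]
  dt <- diff(t)
  len <- sqrt(diff(x)^2 + diff(y)^2)
  mid <- t[-length(t)] + dt / 2
  long_gap <- dt > gap_tolerance_s

  n_bins <- max(1L, ceiling((t[length(t)] - origin_s) / bin_width_s - 1e-9))
  starts <- origin_s + (seq_len(n_bins) - 1L) * bin_width_s
  idx <- floor((mid - origin_s) / bin_width_s) + 1L
  keep <- !long_gap & idx >= 1L & idx <= n_bins
  dist <- numeric(n_bins)
  if (any(keep)) {
    acc <- rowsum(len[keep], idx[keep])
    dist[as.integer(rownames(acc))] <- acc[, 1]
  }

  flagged <- logical(n_bins)
  for (g in which(long_gap)) {     # bins touched by an over-tolerance gap
    lo <- max(1L, floor((t[g] - origin_s) / bin_width_s) + 1L)
    hi <- min(n_bins, floor((t[g + 1L] - origin_s) / bin_width_s) + 1L)
    if (lo <= hi) flagged[lo:hi] <- TRUE
  }

  out <- data.frame(bin_start_s = starts, distance_mm = dist, flagged = flagged)
  structure(out, class = c("activity_series", "data.frame"),
            bin_width_s = bin_width_s, origin_s = origin_s,
            subject_id = traj$subject_id, genotype = traj$genotype)
}

# check that [start_s, end_s) sits on bin edges of `series`; returns bin mask
interval_bins <- function(series, start_s, end_s) {
  bw <- attr(series, "bin_width_s")
  org <- attr(series, "origin_s")
  if (end_s <= start_s) stop("interval must have end > start")
  misaligned <- function(z) abs(z / bw - round(z / bw)) > 1e-9
  if (misaligned(start_s - org) || misaligned(end_s - org))
    stop(sprintf("interval [%g, %g) is not aligned to %g-s bin edges",
                 start_s, end_s, bw))
  first <- series$bin_start_s[1]
  last_end <- series$bin_start_s[nrow(series)] + bw
  if (start_s < first - 1e-9 || end_s > last_end + 1e-9)
    stop(sprintf("interval [%g, %g) exceeds series extent [%g, %g)",
                 start_s, end_s, first, last_end))
  series$bin_start_s >= start_s - 1e-9 & series$bin_start_s < end_s - 1e-9
}

#' Area under the activity curve over one interval
#'
#' The AUC of a distance-per-bin series over an interval is the sum of its bin
#' values (units mm), the convention of commercial larval-tracking software
#' whose tracked quantity is already a distance per bin; `rule = "trapezoid"`
#' applies the trapezoidal rule to the bin values over bin start times
#' instead. The interval must sit on bin edges: partial bins are an error, not
#' a silent truncation. AUC is additive over a partition of the interval (for
#' the default `"sum"` rule).
#'
#' @param series an [distance_series()] result.
#' @param interval a [light_interval()], or `NULL` to use `start_s`/`end_s`.
#' @param start_s,end_s explicit window bounds, seconds.
#' @param rule `"sum"` (default) or `"trapezoid"`.
#' @return A list of class `"interval_metric"`: `auc_mm`, `n_bins`,
#'   `n_flagged`, `start_s`, `end_s`, `condition`, `subject_id`. Flagged bins
#'   contribute 0 to the AUC and are counted in `n_flagged`.
#' @export
interval_auc <- function(series, interval = NULL, start_s = NULL, end_s = NULL,
                         rule = c("sum", "trapezoid")) {
  stopifnot(inherits(series, "activity_series"))
  rule <- match.arg(rule)
  condition <- NA_character_
  if (!is.null(interval)) {
    stopifnot(inherits(interval, "light_interval"))
    start_s <- interval$start_s; end_s <- interval$end_s
    condition <- interval$condition
  }
  stopifnot(is.numeric(start_s), is.numeric(end_s))
  m <- interval_bins(series, start_s, end_s)
  d <- series$distance_mm[m]
  auc <- if (rule == "sum") sum(d)
         else trapezoid(series$bin_start_s[m], d)
  structure(list(auc_mm = auc, n_bins = sum(m),
                 n_flagged = sum(series$flagged[m]),
                 start_s = start_s, end_s = end_s, condition = condition,
                 subject_id = attr(series, "subject_id")),
            class = "interval_metric")
}

#' Per-condition activity totals for one subject
#'
#' Computes the [interval_auc()] of every non-acclimation interval of the
#' schedule and sums the AUCs of intervals sharing a light condition ("entire
#' light versus dark intervals"). A schedule interval not covered by the
#' series is an error.
#'
#' @param series an [distance_series()] result.
#' @param schedule a [light_schedule()].
#' @param include_acclimation include acclimation intervals in the totals?
#' @param rule AUC rule, see [interval_auc()].
#' @return data.frame with one row per condition: `condition`, `auc_mm`,
#'   `n_bins`, `n_flagged`, `subject_id`.
#' @export
condition_aggregate <- function(series, schedule, include_acclimation = FALSE,
                                rule = "sum") {
  stopifnot(inherits(series, "activity_series"),
            inherits(schedule, "light_schedule"))
  ivs <- analysis_intervals(schedule, include_acclimation)
  if (length(ivs) == 0) stop("schedule has no analysis intervals")
  mets <- lapply(ivs, function(iv) interval_auc(series, iv, rule = rule))
  d <- data.frame(
    condition = vapply(mets, `[[`, character(1), "condition"),
    auc_mm = vapply(mets, `[[`, numeric(1), "auc_mm"),
    n_bins = vapply(mets, `[[`, numeric(1), "n_bins"),
    n_flagged = vapply(mets, `[[`, numeric(1), "n_flagged"))
  out <- aggregate(d[c("auc_mm", "n_bins", "n_flagged")], d["condition"], sum)
  out$subject_id <- attr(series, "subject_id")
  out[order(out$condition), ]
}

# mean per-bin distance over [start_s, end_s), excluding flagged bins
window_bin_mean <- function(series, start_s, end_s) {
  m <- interval_bins(series, start_s, end_s)
  use <- m & !series$flagged
  if (!any(use)) return(NA_real_)
  mean(series$distance_mm[use])
}

#' Normalized fast dark-photokinesis response
#'
#' The transient activity surge in the first minutes after a sudden loss of
#' illumination, normalized for baseline activity differences between
#' genotypes: mean per-bin distance during the first `response_s` seconds
#' after a light-to-dark transition, divided by the mean per-bin distance over
#' the last `baseline_s` seconds of the darkness preceding that light interval
#' (in the standard photokinesis paradigm, the 5-min dark acclimation).
#' Division makes the ratio invariant to any common rescaling of distances
#' (e.g. camera calibration).
#'
#' @param series an [distance_series()] result.
#' @param schedule a [light_schedule()] (acclimation intervals count as
#'   darkness here).
#' @param transition which light-to-dark transition to analyze (1 = first).
#' @param response_s response window after light cessation, seconds
#'   (default 120 = first 2 min).
#' @param baseline_s baseline window of preceding darkness, seconds
#'   (default 300 = 5 min).
#' @return list of class `"dark_response"`: `ratio`, `response_mean_mm`,
#'   `baseline_mean_mm`, `transition_s`, `flag` (`NA` or `"zero_baseline"`).
#'   A zero baseline yields `ratio = NA` with the flag set, not an error.
#' @export
normalized_dark_response <- function(series, schedule, transition = 1L,
                                     response_s = 120, baseline_s = 300) {
  stopifnot(inherits(series, "activity_series"),
            inherits(schedule, "light_schedule"),
            response_s > 0, baseline_s > 0)
  ivs <- schedule$intervals
  conds <- vapply(ivs, `[[`, character(1), "condition")
  trans <- which(conds != "dark" & c(conds[-1], "") == "dark")
  if (length(trans) < transition)
    stop("schedule has no light-to-dark transition #", transition)
  li <- trans[transition]                       # index of the light interval
  dark_before <- which(conds[seq_len(li - 1)] == "dark")
  if (length(dark_before) == 0)
    stop("no darkness precedes the analyzed light interval")
  bl <- ivs[[max(dark_before)]]
  if (bl$end_s - bl$start_s < baseline_s - 1e-9)
    stop(sprintf("preceding darkness is shorter than the %g-s baseline window",
                 baseline_s))
  t_off <- ivs[[li]]$end_s
  resp <- window_bin_mean(series, t_off, t_off + response_s)
  base <- window_bin_mean(series, bl$end_s - baseline_s, bl$end_s)
  flag <- NA_character_
  ratio <- if (is.na(base) || base == 0) { flag <- "zero_baseline"; NA_real_ }
           else resp / base
  structure(list(ratio = ratio, response_mean_mm = resp,
                 baseline_mean_mm = base, transition_s = t_off, flag = flag),
            class = "dark_response")
}

#' Activity in the first minutes after lights-on
#'
#' For every dark-to-light transition of the schedule ("day"), the AUC over
#' each window `[t_on, t_on + w)`. Windows are nested, so the 30-min AUC never
#' exceeds the 90-min AUC of the same transition. A window extending past the
#' end of its light interval is an error.
#'
#' @param series an [distance_series()] result.
#' @param schedule a [light_schedule()].
#' @param windows_s window lengths in seconds (default 30 and 90 min).
#' @param rule AUC rule, see [interval_auc()].
#' @return data.frame with one row per transition x window: `transition`,
#'   `t_on_s`, `window_s`, `auc_mm`, `n_bins`, `subject_id`.
#' @export
lights_on_windows <- function(series, schedule, windows_s = c(1800, 5400),
                              rule = "sum") {
  stopifnot(inherits(series, "activity_series"),
            inherits(schedule, "light_schedule"), all(windows_s > 0))
  ivs <- schedule$intervals
  conds <- vapply(ivs, `[[`, character(1), "condition")
  on_idx <- which(conds != "dark" & c("", conds[-length(conds)]) == "dark")
  if (length(on_idx) == 0) stop("schedule has no dark-to-light transition")
  rows <- list()
  for (k in seq_along(on_idx)) {
    iv <- ivs[[on_idx[k]]]
    for (w in windows_s) {
      if (iv$start_s + w > iv$end_s + 1e-9)
        stop(sprintf("window %g s exceeds the %g-s light interval at t = %g",
                     w, iv$end_s - iv$start_s, iv$start_s))
      met <- interval_auc(series, start_s = iv$start_s,
                          end_s = iv$start_s + w, rule = rule)
      rows[[length(rows) + 1L]] <- data.frame(
        transition = k, t_on_s = iv$start_s, window_s = w,
        auc_mm = met$auc_mm, n_bins = met$n_bins,
        subject_id = met$subject_id)
    }
  }
  do.call(rbind, rows)
}

# ---- I/O -------------------------------------------------------------------

#' Read / write trajectory tables
#'
#' CSV with columns `subject_id`, `t_s`, `x_mm`, `y_mm` and optionally
#' `genotype`; missing coordinates blank. One file may hold several subjects.
#'
#' @param path file path.
#' @param trajs a list of [trajectory()] objects to write.
#' @param frame_rate nominal frame rate to stamp on trajectories read.
#' @return `read_trajectories()` a named list of [trajectory()] objects;
#'   `write_trajectories()` `path`, invisibly.
#' @rdname trajectory_io
#' @export
read_trajectories <- function(path, frame_rate = 60) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "t_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("%s: trajectory CSV lacks column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (nrow(d) == 0) stop(sprintf("%s: empty trajectory file", path))
  if (is.null(d$genotype)) d$genotype <- "unspecified"
  lapply(split(d, d$subject_id), function(s)
    trajectory(s$t_s, s$x_mm, s$y_mm, subject_id = s$subject_id[1],
               genotype = s$genotype[1], frame_rate = frame_rate))
}

#' @rdname trajectory_io
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  d <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(subject_id = tr$subject_id, genotype = tr$genotype,
               t_s = tr$t_s, x_mm = tr$x_mm, y_mm = tr$y_mm)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write an activity series CSV
#'
#' Columns `subject_id`, `bin_start_s`, `distance_mm`, `flagged`.
#'
#' @param series an [distance_series()] result.
#' @param path file path.
#' @export
write_activity_series <- function(series, path) {
  stopifnot(inherits(series, "activity_series"))
  utils::write.csv(data.frame(subject_id = attr(series, "subject_id"),
                              bin_start_s = series$bin_start_s,
                              distance_mm = series$distance_mm,
                              flagged = series$flagged),
                   path, row.names = FALSE)
  invisible(path)
}
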