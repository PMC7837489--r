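# Avoidance-index scoring: per-subject indices, size-tuning curves, and
# total avoidance (area under the tuning curve).

OUTCOME_LEVELS <- c("approach", "avoidance", "neutral")

#' Avoidance index of a set of scored dot interactions
#'
#' `AI = (number of avoidances - number of approaches) / total dots presented`,
#' where the denominator counts neutral interactions too. Bounded in
#' `[-1, 1]`; neutral outcomes dilute the index towards 0 without flipping its
#' sign.
#'
#' @param outcomes character vector with one entry per presented dot, each one
#'   of `"approach"`, `"avoidance"`, `"neutral"`. Typically the outcomes of one
#'   subject at one dot size.
#' @return The avoidance index, a scalar in `[-1, 1]`.
#' @export
#' @examples
#' avoidance_index(c("avoidance", "avoidance", "approach",
#'                   "neutral", "avoidance", "neutral"))  # (3 - 1) / 6
avoidance_index <- function(outcomes) {
  if (length(outcomes) == 0) stop("no interaction events to score")
  outcomes <- as.character(outcomes)
  bad <- setdiff(unique(outcomes), OUTCOME_LEVELS)
  if (length(bad))
    stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  (sum(outcomes == "avoidance") - sum(outcomes == "approach")) / length(outcomes)
}

# validate an interaction-event table and coerce its columns
check_events <- function(events) {
  need <- c("subject_id", "size_deg", "outcome")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(as.character(events$outcome)), OUTCOME_LEVELS)
  if (length(bad))
    stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  events$subject_id <- as.character(events$subject_id)
  events$size_deg <- as.numeric(events$size_deg)
  events$outcome <- as.character(events$outcome)
  if (is.null(events$genotype)) events$genotype <- "unspecified"
  events
}

#' Per-subject avoidance indices at every dot size
#'
#' @param events data.frame of scored interactions with columns `subject_id`,
#'   `size_deg`, `outcome`, and optionally `genotype`.
#' @return data.frame with one row per subject x size: `subject_id`,
#'   `genotype`, `size_deg`, `ai`, `n_dots`.
#' @export
subject_indices <- function(events) {
  events <- check_events(events)
  if (nrow(events) == 0) stop("no interaction events to score")
  key <- list(subject_id = events$subject_id, size_deg = events$size_deg)
  out <- aggregate(events["outcome"], key, function(o) avoidance_index(o))
  names(out)[names(out) == "outcome"] <- "ai"
  n <- aggregate(events["outcome"], key, length)
  out$n_dots <- n$outcome[match(paste(out$subject_id, out$size_deg),
                                paste(n$subject_id, n$size_deg))]
  gt <- events$genotype[match(out$subject_id, events$subject_id)]
  out$genotype <- gt
  out <- out[order(out$subject_id, out$size_deg),
             c("subject_id", "genotype", "size_deg", "ai", "n_dots")]
  rownames(out) <- NULL
  out
}

#' Size-discrimination tuning curve
#'
#' Cohort tuning curve: the per-subject avoidance index is computed first, then
#' averaged across subjects at each dot size (mean +/- SEM), matching the
#' usual "mean (+/- SEM)" presentation of size-tuning data. Subjects with no
#' events at a size are omitted from that point's `n`; with a single subject
#' the SEM is reported as 0 and flagged by `n = 1`.
#'
#' @inheritParams subject_indices
#' @return data.frame of class `"avoidance_curve"`: `size_deg` (strictly
#'   increasing), `mean_ai`, `sem`, `n`.
#' @export
tuning_curve <- function(events) {
  si <- subject_indices(events)
  agg <- aggregate(si["ai"], si["size_deg"], function(a)
    c(mean = mean(a), sd = stats::sd(a), n = length(a)))
  m <- agg$ai
  out <- data.frame(size_deg = agg$size_deg,
                    mean_ai = m[, "mean"],
                    sem = ifelse(m[, "n"] > 1, m[, "sd"] / sqrt(m[, "n"]), 0),
                    n = as.integer(m[, "n"]))
  out <- out[order(out$size_deg), ]
  rownames(out) <- NULL
  class(out) <- c("avoidance_curve", "data.frame")
  out
}

#' Total avoidance: area under the size-tuning curve
#'
#' Trapezoidal area of the avoidance index against dot size (in degrees) over
#' the measured size range, computed per subject and then summarized across
#' the cohort. The per-fish-first convention matches per-fish box-plot
#' presentations of total avoidance; integrating the cohort mean curve instead
#' gives the same cohort mean when all subjects cover all sizes.
#'
#' @inheritParams subject_indices
#' @return list of class `"total_avoidance"` with `per_subject` (data.frame
#'   `subject_id`, `genotype`, `area`) and cohort `summary`
#'   (`mean`, `sem`, `median`, `n`). Areas carry degree x AI units.
#' @export
total_avoidance <- function(events) {
  si <- subject_indices(events)
  per <- lapply(split(si, si$subject_id), function(d) {
    if (nrow(d) < 2) stop("area undefined: subject ", d$subject_id[1],
                          " has a single dot size")
    d <- d[order(d$size_deg), ]
    data.frame(subject_id = d$subject_id[1], genotype = d$genotype[1],
               area = trapezoid(d$size_deg, d$ai))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(list(
    per_subject = per,
    summary = list(mean = mean(per$area),
                   sem = if (nrow(per) > 1) stats::sd(per$area) / sqrt(nrow(per)) else 0,
                   median = stats::median(per$area),
                   n = nrow(per))),
    class = "total_avoidance")
}

#' @export
print.total_avoidance <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<total_avoidance> n = %d subjects: mean %.3g +/- %.3g (SEM), median %.3g deg*AI\n",
              s$n, s$mean, s$sem, s$median))
  invisible(x)
}

#' Read / write interaction-event tables
#'
#' CSV with columns `subject_id`, `genotype`, `size_deg`,
#' `presentation_index`, `outcome`.
#'
#' @param path file path.
#' @param events event data.frame to write.
#' @return `read_events()` the validated event data.frame; `write_events()`
#'   `path`, invisibly.
#' @rdname events_io
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(check_events(d),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e))))
}

#' @rdname events_io
#' @export
write_events <- function(events, path) {
  utils::write.csv(check_events(events), path, row.names = FALSE)
  invisible(path)
}

#' Write a tuning curve CSV
#'
#' @param curve an [tuning_curve()] result.
#' @param path file path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "avoidance_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
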