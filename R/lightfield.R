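# Light fields: emission spectra, photon flux, intensity scaling, Michelson
# contrast, and light/dark schedules.

# Planck constant times speed of light, J*m. Used to convert spectral
# irradiance (W m^-2 nm^-1) to photon flux.
HC_JM <- 1.98645e-25

#' Emission spectrum
#'
#' A tabulated emission spectrum: spectral irradiance sampled on a strictly
#' increasing wavelength grid.
#'
#' @param wavelength_nm numeric vector of wavelengths in nanometres, strictly
#'   increasing.
#' @param irradiance numeric vector of spectral irradiance in W m^-2 nm^-1,
#'   all values >= 0, same length as `wavelength_nm`.
#' @param label free-text label (e.g. `"white 100%"`).
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelength_nm`, `irradiance` and `label`.
#' @seealso [photon_flux()], [read_spectrum()]
#' @export
#' @examples
#' s <- spectrum(380:700, rep(1e-4, 321), label = "flat white")
#' photon_flux(s)
spectrum <- function(wavelength_nm, irradiance, label = "") {
  wavelength_nm <- as.numeric(wavelength_nm)
  irradiance <- as.numeric(irradiance)
  if (length(wavelength_nm) < 1L)
    stop("a spectrum needs at least one sample")
  if (length(wavelength_nm) != length(irradiance))
    stop("wavelength and irradiance must have equal length")
  if (anyNA(wavelength_nm) || anyNA(irradiance))
    stop("spectrum samples must be finite")
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (any(irradiance < 0))
    stop("irradiance values must be >= 0")
  structure(list(wavelength_nm = wavelength_nm, irradiance = irradiance,
                 label = as.character(label)[1]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavelength_nm)
  cat(sprintf("<spectrum> %s: %d samples, %g-%g nm, photon flux %.3g photons m^-2 s^-1\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavelength_nm), rng[1], rng[2],
              tryCatch(photon_flux(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Photon flux of a spectrum
#'
#' Integrates `E(lambda) * lambda / (h c)` over the sampled wavelength grid by
#' the trapezoidal rule, converting spectral irradiance to a total photon flux.
#' This is the "sum of photons" usually quoted next to a measured assay
#' spectrum.
#'
#' @param x a [spectrum()].
#' @param bandwidth_nm for a single-sample spectrum only: the effective
#'   rectangular bandwidth in nm. Without it a single sample cannot be
#'   integrated and an error is raised.
#' @return Photon flux in photons m^-2 s^-1 (non-negative scalar). Linear in
#'   the irradiance values.
#' @export
photon_flux <- function(x, bandwidth_nm = NULL) {
  stopifnot(inherits(x, "spectrum"))
  lam_m <- x$wavelength_nm * 1e-9
  # photons m^-2 s^-1 nm^-1 at each grid point
  dens <- x$irradiance * lam_m / HC_JM
  if (length(dens) == 1L) {
    if (is.null(bandwidth_nm))
      stop("cannot integrate a single-sample spectrum without an explicit bandwidth")
    stopifnot(bandwidth_nm > 0)
    return(dens * bandwidth_nm)
  }
  trapezoid(x$wavelength_nm, dens)
}

# trapezoidal integral of y over grid x
trapezoid <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

#' Scale a photon flux by a neutral-density factor
#'
#' @param flux photon flux (photons m^-2 s^-1), >= 0.
#' @param factor dimensionless intensity factor in `[0, 1]`; e.g. `0.35` for a
#'   background light reduced to 35% of its full intensity.
#' @return `flux * factor`.
#' @export
#' @examples
#' scale_intensity(2.2e13, 0.35)  # 7.7e12
scale_intensity <- function(flux, factor) {
  stopifnot(is.numeric(flux), all(flux >= 0))
  if (!is.numeric(factor) || anyNA(factor) || any(factor < 0) || any(factor > 1))
    stop("intensity factor must lie in [0, 1]")
  flux * factor
}

#' Michelson contrast
#'
#' `(L_max - L_min) / (L_max + L_min)` between two luminances in the same
#' arbitrary linear units, e.g. a dark moving dot against a bright screen
#' background. Invariant under a common rescaling of both luminances.
#'
#' @param l_max maximum luminance, `l_max >= l_min >= 0`, `l_max > 0`.
#' @param l_min minimum luminance.
#' @return Contrast in `[0, 1]`.
#' @export
#' @examples
#' michelson_contrast(0.35, 0.0127)  # ~0.930
michelson_contrast <- function(l_max, l_min) {
  stopifnot(is.numeric(l_max), is.numeric(l_min))
  if (any(l_min < 0) || any(l_max < l_min))
    stop("need l_max >= l_min >= 0")
  if (any(l_max == 0))
    stop("undefined contrast: l_max = l_min = 0")
  (l_max - l_min) / (l_max + l_min)
}

#' Light interval
#'
#' One half-open interval `[start_s, end_s)` of a light schedule, labelled with
#' a light condition.
#'
#' @param start_s,end_s interval bounds in seconds from trial origin,
#'   `end_s > start_s`.
#' @param condition one of `"dark"`, `"white"`, `"blue"`, `"green"`, `"red"`.
#' @param intensity optional intensity factor in `[0, 1]` (1 = full).
#' @param acclimation logical; acclimation intervals are excluded from
#'   analysis by default.
#' @return A list of class `"light_interval"`.
#' @export
light_interval <- function(start_s, end_s, condition,
                           intensity = 1, acclimation = FALSE) {
  condition <- match.arg(condition, c("dark", "white", "blue", "green", "red"))
  stopifnot(is.numeric(start_s), is.numeric(end_s), length(start_s) == 1L)
  if (!(end_s > start_s)) stop("light interval must have end > start")
  if (intensity < 0 || intensity > 1) stop("intensity factor must lie in [0, 1]")
  structure(list(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                 condition = condition, intensity = as.numeric(intensity),
                 acclimation = isTRUE(acclimation)),
            class = "light_interval")
}

#' Light schedule
#'
#' An ordered, contiguous, non-overlapping sequence of [light_interval()]s.
#'
#' @param intervals list of [light_interval()]s, contiguous
#'   (`end_s[i] == start_s[i + 1]`).
#' @param origin_zt zeitgeber time (hours since lights-on of the entraining
#'   cycle) at which the trial starts.
#' @return A list of class `"light_schedule"` with elements `intervals` and
#'   `origin_zt`.
#' @seealso [build_schedule()], [photokinesis_schedule()], [diel_schedule()]
#' @export
light_schedule <- function(intervals, origin_zt = 0) {
  stopifnot(is.list(intervals), length(intervals) > 0)
  ok <- vapply(intervals, inherits, logical(1), "light_interval")
  if (!all(ok)) stop("all elements must be light_interval objects")
  starts <- vapply(intervals, `[[`, numeric(1), "start_s")
  ends <- vapply(intervals, `[[`, numeric(1), "end_s")
  o <- order(starts)
  intervals <- intervals[o]; starts <- starts[o]; ends <- ends[o]
  if (length(intervals) > 1L &&
      any(abs(ends[-length(ends)] - starts[-1]) > 1e-9))
    stop("intervals must be contiguous and non-overlapping")
  structure(list(intervals = intervals, origin_zt = as.numeric(origin_zt)),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %d intervals, %g s total (origin ZT %g)\n",
              length(x$intervals), schedule_duration(x), x$origin_zt))
  for (iv in x$intervals)
    cat(sprintf("  [%8g, %8g) %-5s intensity %g%s\n", iv$start_s, iv$end_s,
                iv$condition, iv$intensity,
                if (iv$acclimation) "  (acclimation)" else ""))
  invisible(x)
}

#' Schedule durations
#'
#' @param schedule a [light_schedule()].
#' @param include_acclimation count acclimation intervals too?
#' @return Total duration in seconds.
#' @export
schedule_duration <- function(schedule, include_acclimation = TRUE) {
  stopifnot(inherits(schedule, "light_schedule"))
  keep <- if (include_acclimation) rep(TRUE, length(schedule$intervals))
          else !vapply(schedule$intervals, `[[`, logical(1), "acclimation")
  sum(vapply(schedule$intervals[keep],
             function(iv) iv$end_s - iv$start_s, numeric(1)))
}

#' Analysis intervals of a schedule
#'
#' The schedule's intervals with acclimation dropped (unless requested).
#'
#' @inheritParams schedule_duration
#' @return List of [light_interval()]s.
#' @export
analysis_intervals <- function(schedule, include_acclimation = FALSE) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (include_acclimation) return(schedule$intervals)
  Filter(function(iv) !iv$acclimation, schedule$intervals)
}

#' Build a block-structured light schedule
#'
#' Constructs a contiguous schedule from an optional acclimation phase followed
#' by `repeats` repetitions of a block list. The photokinesis paradigm, for
#' example, is 5 min of dark acclimation followed by 3 repeats of
#' (30 min light + 30 min dark), 3 h of analysis time in total.
#'
#' @param blocks data.frame with columns `condition` (character) and
#'   `duration_s` (> 0), and optionally `intensity`; one row per block, in
#'   presentation order.
#' @param repeats how many times the block list is repeated.
#' @param acclimation_s duration of an initial acclimation phase in seconds
#'   (0 = none); flagged and excluded from analysis by default.
#' @param acclimation_condition light condition during acclimation.
#' @param origin_zt zeitgeber hours at trial start.
#' @return A [light_schedule()].
#' @export
#' @examples
#' sched <- build_schedule(
#'   data.frame(condition = c("white", "dark"), duration_s = c(1800, 1800)),
#'   repeats = 3, acclimation_s = 300)
#' schedule_duration(sched, include_acclimation = FALSE) / 60  # 180 min
build_schedule <- function(blocks, repeats = 1, acclimation_s = 0,
                           acclimation_condition = "dark", origin_zt = 0) {
  stopifnot(is.data.frame(blocks),
            all(c("condition", "duration_s") %in% names(blocks)),
            nrow(blocks) > 0, repeats >= 1, acclimation_s >= 0)
  if (any(blocks$duration_s <= 0)) stop("block durations must be > 0")
  if (is.null(blocks$intensity)) blocks$intensity <- 1
  ivs <- list()
  t <- 0
  if (acclimation_s > 0) {
    ivs[[1]] <- light_interval(0, acclimation_s, acclimation_condition,
                               acclimation = TRUE)
    t <- acclimation_s
  }
  for (r in seq_len(repeats)) {
    for (b in seq_len(nrow(blocks))) {
      ivs[[length(ivs) + 1L]] <- light_interval(
        t, t + blocks$duration_s[b], blocks$condition[b],
        intensity = blocks$intensity[b])
      t <- t + blocks$duration_s[b]
    }
  }
  light_schedule(ivs, origin_zt = origin_zt)
}

#' Canned assay schedules
#'
#' `photokinesis_schedule()`: 5 min dark acclimation, then `repeats` repeats of
#' (30 min light + 30 min dark); with the defaults, 3 h of analysis time.
#' `diel_schedule()`: `days` consecutive days of (8 h dark + 16 h light),
#' starting at the lights-off transition (origin ZT 16 under a 16:8 cycle).
#'
#' @param light_condition light condition of the lit blocks.
#' @param repeats number of light/dark repeats.
#' @param acclimation_s dark acclimation before the first block, seconds.
#' @param days number of consecutive days.
#' @param dark_h,light_h hours of darkness and of light per day.
#' @return A [light_schedule()].
#' @rdname canned_schedules
#' @export
photokinesis_schedule <- function(light_condition = "white", repeats = 3,
                                  acclimation_s = 300) {
  build_schedule(
    data.frame(condition = c(light_condition, "dark"),
               duration_s = c(1800, 1800)),
    repeats = repeats, acclimation_s = acclimation_s)
}

#' @rdname canned_schedules
#' @export
diel_schedule <- function(light_condition = "blue", days = 2,
                          dark_h = 8, light_h = 16) {
  build_schedule(
    data.frame(condition = c("dark", light_condition),
               duration_s = c(dark_h, light_h) * 3600),
    repeats = days, origin_zt = light_h)
}

#' Light condition at a time point
#'
#' @param schedule a [light_schedule()].
#' @param t_s time in seconds from trial origin. Intervals are half-open, so
#'   every covered time point belongs to exactly one interval.
#' @return The [light_interval()] containing `t_s`, or `NULL` if outside the
#'   schedule.
#' @export
condition_at <- function(schedule, t_s) {
  stopifnot(inherits(schedule, "light_schedule"))
  for (iv in schedule$intervals)
    if (t_s >= iv$start_s && t_s < iv$end_s) return(iv)
  NULL
}

# ---- I/O -------------------------------------------------------------------

#' Read / write a spectrum CSV
#'
#' Two-column CSV `(wavelength_nm, irradiance_W_m2_nm)` with one header line.
#'
#' @param path file path.
#' @param label label for the spectrum read.
#' @param x a [spectrum()] to write.
#' @return `read_spectrum()` a [spectrum()]; `write_spectrum()` `path`,
#'   invisibly.
#' @rdname spectrum_io
#' @export
#' @examples
#' # bundled synthetic blue-LED spectrum
#' sp <- read_spectrum(system.file("extdata",
#'   "synthetic_blue_led_spectrum.csv", package = "photokin"))
#' photon_flux(sp)
read_spectrum <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2)
    stop(sprintf("%s: a spectrum CSV needs 2 columns (wavelength_nm, irradiance_W_m2_nm)",
                 path))
  spectrum(d[[1]], d[[2]], label = label)
}

#' @rdname spectrum_io
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  utils::write.csv(data.frame(wavelength_nm = x$wavelength_nm,
                              irradiance_W_m2_nm = x$irradiance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a light schedule JSON
#'
#' JSON with fields `origin_zt` and `intervals`, the latter an array of
#' `{start_s, end_s, condition, intensity, acclimation}` objects.
#'
#' @param path file path.
#' @param schedule a [light_schedule()] to write.
#' @return `read_schedule()` a [light_schedule()]; `write_schedule()` `path`,
#'   invisibly.
#' @rdname schedule_io
#' @export
read_schedule <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$intervals))
    stop(sprintf("%s: schedule JSON must contain an 'intervals' array", path))
  iv <- j$intervals
  ivs <- lapply(seq_len(nrow(iv)), function(i)
    light_interval(iv$start_s[i], iv$end_s[i], iv$condition[i],
                   intensity = if (is.null(iv$intensity)) 1 else iv$intensity[i],
                   acclimation = if (is.null(iv$acclimation)) FALSE
                                 else isTRUE(iv$acclimation[i])))
  light_schedule(ivs, origin_zt = if (is.null(j$origin_zt)) 0 else j$origin_zt)
}

#' @rdname schedule_io
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "light_schedule"))
  iv <- do.call(rbind, lapply(schedule$intervals, function(x)
    data.frame(start_s = x$start_s, end_s = x$end_s, condition = x$condition,
               intensity = x$intensity, acclimation = x$acclimation)))
  jsonlite::write_json(list(origin_zt = schedule$origin_zt, intervals = iv),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
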