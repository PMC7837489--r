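# Moving-dot stimulus protocol: visual-angle conversion and trial plans.

#' Convert a dot diameter from screen pixels to visual degrees
#'
#' Exact visual-angle formula `2 * atan(s / (2 * D))` where `s` is the physical
#' diameter on screen (`diameter_px * pixel_pitch_mm`) and `D` the viewing
#' distance. Strictly increasing in `diameter_px` and tending to 0 with it.
#'
#' @param diameter_px dot diameter in pixels, >= 0.
#' @param pixel_pitch_mm physical pixel pitch of the screen, mm per pixel,
#'   positive.
#' @param viewing_distance_mm distance from the animal's eye to the screen,
#'   mm, positive.
#' @return Diameter in degrees of the visual field, in `(0, 180)`.
#' @seealso [degrees_to_pixels()] for the inverse.
#' @export
#' @examples
#' pixels_to_degrees(100, 0.1, 10)  # 10 mm dot seen from 10 mm: 53.13 degrees
pixels_to_degrees <- function(diameter_px, pixel_pitch_mm, viewing_distance_mm) {
  if (any(pixel_pitch_mm <= 0) || any(viewing_distance_mm <= 0))
    stop("pixel pitch and viewing distance must be > 0")
  if (any(diameter_px < 0)) stop("diameter must be >= 0")
  2 * atan(diameter_px * pixel_pitch_mm / (2 * viewing_distance_mm)) * 180 / pi
}

#' Convert a visual angle back to screen pixels
#'
#' @param diameter_deg diameter in degrees, in `[0, 180)`.
#' @inheritParams pixels_to_degrees
#' @return Diameter in pixels.
#' @export
degrees_to_pixels <- function(diameter_deg, pixel_pitch_mm, viewing_distance_mm) {
  if (any(pixel_pitch_mm <= 0) || any(viewing_distance_mm <= 0))
    stop("pixel pitch and viewing distance must be > 0")
  if (any(diameter_deg < 0) || any(diameter_deg >= 180))
    stop("diameter_deg must lie in [0, 180)")
  2 * viewing_distance_mm * tan(diameter_deg * pi / 360) / pixel_pitch_mm
}

#' Moving-dot stimulus
#'
#' @param diameter_px dot diameter in pixels, > 0.
#' @param pixel_pitch_mm,viewing_distance_mm see [pixels_to_degrees()].
#' @param luminance dot luminance in arbitrary linear units (default 0: a
#'   black dot on a bright background).
#' @param speed_mm_s dot travel speed, mm/s (default 13.5).
#' @return A list of class `"dot_stimulus"` with `diameter_px`,
#'   `diameter_deg`, `luminance` and `speed_mm_s`.
#' @export
dot_stimulus <- function(diameter_px, pixel_pitch_mm, viewing_distance_mm,
                         luminance = 0, speed_mm_s = 13.5) {
  stopifnot(diameter_px > 0, speed_mm_s > 0, luminance >= 0)
  deg <- pixels_to_degrees(diameter_px, pixel_pitch_mm, viewing_distance_mm)
  structure(list(diameter_px = diameter_px, diameter_deg = deg,
                 luminance = luminance, speed_mm_s = speed_mm_s),
            class = "dot_stimulus")
}

#' Trial plan for the dot-avoidance assay
#'
#' A trial is a sequence of blocks, one dot size per block, each size presented
#' `reps` times, blocks separated by a stimulus-free gap. Blocks run either in
#' ascending size order or in a seeded pseudo-random order (a uniform shuffle
#' of the block sizes).
#'
#' @param sizes_deg distinct dot sizes in visual degrees (default ladder of 7).
#' @param order_mode `"ascending"` or `"pseudo_random"`.
#' @param reps presentations per block (default 6).
#' @param gap_s stimulus-free gap between consecutive blocks, seconds
#'   (default 19).
#' @param stimulus_s duration of one dot presentation, seconds. The default is
#'   the transit time of a dot crossing a 305-mm chamber at 13.5 mm/s.
#' @param seed integer seed for the pseudo-random order (required there;
#'   ignored for ascending order).
#' @return A list of class `"trial_plan"` with the ordered `sizes_deg`,
#'   `order_mode`, `reps`, `gap_s`, `stimulus_s` and `seed`.
#' @export
#' @examples
#' plan <- trial_plan(order_mode = "pseudo_random", seed = 7)
#' nrow(presentation_log(plan))  # 42 presentations: 7 blocks x 6 dots
trial_plan <- function(sizes_deg = c(5, 10, 20, 30, 40, 60, 80),
                       order_mode = c("ascending", "pseudo_random"),
                       reps = 6, gap_s = 19, stimulus_s = 305 / 13.5,
                       seed = NULL) {
  order_mode <- match.arg(order_mode)
  sizes_deg <- as.numeric(sizes_deg)
  stopifnot(all(sizes_deg > 0), all(sizes_deg < 180), reps >= 1, gap_s >= 0,
            stimulus_s > 0)
  if (anyDuplicated(sizes_deg)) stop("dot sizes must be distinct")
  if (order_mode == "ascending") {
    sizes_deg <- sort(sizes_deg)
  } else {
    if (is.null(seed)) stop("pseudo_random order requires a seed")
    sizes_deg <- with_seed(as.integer(seed), sample(sizes_deg))
  }
  structure(list(sizes_deg = sizes_deg, order_mode = order_mode,
                 reps = as.integer(reps), gap_s = gap_s,
                 stimulus_s = stimulus_s,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "trial_plan")
}

#' Presentation log of a trial plan
#'
#' Expands a [trial_plan()] into one row per dot presentation with its block
#' index, within-block presentation index, size and onset time. Gaps separate
#' consecutive blocks only, so there are `(blocks - 1)` gaps.
#'
#' @param plan a [trial_plan()].
#' @return data.frame with columns `block_index`, `presentation_index`,
#'   `size_deg`, `t_start_s`.
#' @export
presentation_log <- function(plan) {
  stopifnot(inherits(plan, "trial_plan"))
  nb <- length(plan$sizes_deg)
  out <- expand.grid(presentation_index = seq_len(plan$reps),
                     block_index = seq_len(nb))[, 2:1]
  out$size_deg <- plan$sizes_deg[out$block_index]
  block_len <- plan$reps * plan$stimulus_s
  out$t_start_s <- (out$block_index - 1) * (block_len + plan$gap_s) +
    (out$presentation_index - 1) * plan$stimulus_s
  rownames(out) <- NULL
  out
}

#' Read / write a trial plan JSON
#'
#' JSON with fields `sizes_deg`, `order_mode`, `reps`, `gap_s`, `stimulus_s`,
#' `seed`. Sizes are stored in presentation order, so a pseudo-random plan
#' round-trips without reshuffling.
#'
#' @param path file path.
#' @param plan a [trial_plan()] to write.
#' @return `read_trial_plan()` a [trial_plan()]; `write_trial_plan()` `path`,
#'   invisibly.
#' @rdname trial_plan_io
#' @export
read_trial_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- structure(list(sizes_deg = as.numeric(j$sizes_deg),
                         order_mode = j$order_mode, reps = as.integer(j$reps),
                         gap_s = j$gap_s, stimulus_s = j$stimulus_s,
                         seed = if (is.null(j$seed)) NA_integer_
                                else as.integer(j$seed)),
                    class = "trial_plan")
  if (anyDuplicated(plan$sizes_deg)) stop(sprintf("%s: duplicate sizes", path))
  plan
}

#' @rdname trial_plan_io
#' @export
write_trial_plan <- function(plan, path) {
  stopifnot(inherits(plan, "trial_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
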