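# Synthetic-data generators: two-state swim trajectories under a light
# schedule, dot-interaction events with size tuning and habituation, and qPCR
# plates. Every generator is deterministic given the configured seed, with
# per-subject substreams so cohorts are order-independent.

#' Simulation configuration
#'
#' Central parameter object for all generators. Defaults describe a larval
#' fish cohort: a rest/move two-state swim process whose rest-to-move rate
#' depends on the light condition (less spontaneous swimming in darkness),
#' log-normal bout speeds, a logistic size-tuning avoidance model with
#' habituation to large dots, and qPCR plates with replicate noise on the Ct
#' scale.
#'
#' @param seed integer master seed; per-subject streams are derived from it.
#' @param n_subjects subjects per genotype for cohort generators.
#' @param frame_rate tracking frame rate, Hz (60 in the tracked assays; lower
#'   it for long simulated schedules).
#' @param arena_mm rectangular arena width and height, mm (default the
#'   diameter of a 6-well plate well).
#' @param swim list: `rate_on` (named rest-to-move rates per light condition,
#'   s^-1), `rate_off` (move-to-rest rate, s^-1), `speed_meanlog`,
#'   `speed_sdlog` (log-normal bout speed, mm/s), `turn_rad_s` (heading
#'   diffusion, rad per sqrt(s)).
#' @param genotype list of mutant effects: `activity_multiplier` (multiplies
#'   the condition-specific rest-to-move rates), `theta0_shift_deg` (additive
#'   shift of the avoidance size threshold; negative = avoids smaller dots).
#' @param avoidance list: `theta0_deg` (half-maximum dot size), `slope`
#'   (logistic slope on log size), `max_avoid`, `max_approach` (probability
#'   ceilings), `habituation` (per-exposure multiplier in `(0, 1]`),
#'   `habituation_threshold_deg` (dot sizes at or above it count as
#'   habituating exposures).
#' @param qpcr list: `base_ct` (Ct of unit expression), `noise_sd` (technical
#'   replicate noise, cycles), `bio_sd_log2` (biological sample scatter in
#'   log2 expression units), `ref_gene`.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_subjects = 12,
                       frame_rate = 60,
                       arena_mm = c(35, 35),
                       swim = list(),
                       genotype = list(),
                       avoidance = list(),
                       qpcr = list()) {
  defaults <- list(
    swim = list(rate_on = c(dark = 0.04, white = 0.10, blue = 0.10,
                            green = 0.10, red = 0.10),
                rate_off = 1.0,
                speed_meanlog = log(20), speed_sdlog = 0.35,
                turn_rad_s = 1.5),
    genotype = list(activity_multiplier = 1, theta0_shift_deg = -5),
    avoidance = list(theta0_deg = 25, slope = 3, max_avoid = 0.9,
                     max_approach = 0.4, habituation = 0.9,
                     habituation_threshold_deg = 40),
    qpcr = list(base_ct = 20, noise_sd = 0.15, bio_sd_log2 = 0.2,
                ref_gene = "beta-actin"))
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              frame_rate = frame_rate, arena_mm = arena_mm,
              swim = utils::modifyList(defaults$swim, swim),
              genotype = utils::modifyList(defaults$genotype, genotype),
              avoidance = utils::modifyList(defaults$avoidance, avoidance),
              qpcr = utils::modifyList(defaults$qpcr, qpcr))
  stopifnot(all(cfg$swim$rate_on >= 0), cfg$swim$rate_off > 0,
            cfg$frame_rate > 0, length(cfg$arena_mm) == 2,
            all(cfg$arena_mm > 0),
            cfg$avoidance$habituation > 0, cfg$avoidance$habituation <= 1,
            cfg$qpcr$noise_sd >= 0)
  structure(cfg, class = "sim_config")
}

# deterministic per-subject substream seed (order-independent within cohorts)
stream_seed <- function(seed, subject_index, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(subject_index) * 1000003 +
                as.numeric(salt) * 104729) %% 2147483647)
}

# salt a genotype label into an integer
genotype_salt <- function(genotype) {
  sum(utf8ToInt(as.character(genotype))) %% 10007L
}

# fold an unconstrained coordinate into [0, w] (triangle-wave reflection)
fold_into <- function(u, w) w - abs((u %% (2 * w)) - w)

#' Simulate a swim trajectory under a light schedule
#'
#' Two-state (rest/move) continuous-time Markov chain with piecewise-constant
#' rates: the rest-to-move rate is set by the light condition of the current
#' schedule interval (acclimation intervals use their own condition) and, for
#' mutants, multiplied by the genotype activity multiplier; the move-to-rest
#' rate is constant. During a move bout the fish advances at a bout-specific
#' log-normal speed along a heading that diffuses per frame; arena walls
#' reflect (the path is folded into the arena rectangle). Output is sampled at
#' the configured frame rate. Deterministic given `config$seed` and
#' `subject_index`.
#'
#' @param config a [sim_config()].
#' @param schedule a [light_schedule()].
#' @param subject_id identifier stamped on the trajectory.
#' @param genotype `"wt"` or `"mutant"` (anything other than `"wt"` gets the
#'   mutant multipliers).
#' @param subject_index integer index deriving this subject's RNG substream.
#' @return A [trajectory()] with extra attributes `moving_time_s` (true time
#'   in the move state) and `path_length_mm` (true path length, before any
#'   wall-chord truncation).
#' @export
simulate_trajectory <- function(config, schedule, subject_id = "s1",
                                genotype = "wt", subject_index = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(schedule, "light_schedule"))
  sw <- config$swim
  mult <- if (identical(genotype, "wt")) 1 else config$genotype$activity_multiplier
  total <- schedule_duration(schedule)
  fr <- config$frame_rate
  n_frames <- floor(total * fr)

  with_seed(stream_seed(config$seed, subject_index, genotype_salt(genotype)), {
    # event-level CTMC: times at which the state flips (rest <-> move);
    # buffer grows by doubling to avoid quadratic appends
    flips <- numeric(256L)
    n_flips <- 0L
    state <- 0L   # 0 = rest, 1 = move
    t <- schedule$intervals[[1]]$start_s
    for (iv in schedule$intervals) {
      t <- max(t, iv$start_s)
      r_on <- unname(sw$rate_on[iv$condition]) * mult
      repeat {
        rate <- if (state == 0L) r_on else sw$rate_off
        dt <- if (rate > 0) stats::rexp(1, rate) else Inf
        if (t + dt >= iv$end_s) { t <- iv$end_s; break }
        t <- t + dt
        n_flips <- n_flips + 1L
        if (n_flips > length(flips)) flips <- c(flips, numeric(length(flips)))
        flips[n_flips] <- t
        state <- 1L - state
      }
    }
    flips <- flips[seq_len(n_flips)]

    ft <- schedule$intervals[[1]]$start_s + (seq_len(n_frames) - 1) / fr
    bout <- findInterval(ft, flips)        # 0-based bout index per frame
    moving <- bout %% 2L == 1L             # started at rest
    speeds <- stats::rlnorm(n_flips + 1L, sw$speed_meanlog, sw$speed_sdlog)
    turn <- stats::rnorm(n_frames, 0, sw$turn_rad_s / sqrt(fr))
    heading <- stats::runif(1, 0, 2 * pi) + cumsum(turn)
    step <- numeric(n_frames)
    step[moving] <- speeds[bout[moving] + 1L] / fr
    x0 <- stats::runif(1, 0, config$arena_mm[1])
    y0 <- stats::runif(1, 0, config$arena_mm[2])
    x <- fold_into(x0 + cumsum(step * cos(heading)), config$arena_mm[1])
    y <- fold_into(y0 + cumsum(step * sin(heading)), config$arena_mm[2])

    tr <- trajectory(ft, x, y, subject_id = subject_id, genotype = genotype,
                     frame_rate = fr)
    attr(tr, "moving_time_s") <- sum(moving) / fr
    attr(tr, "path_length_mm") <- sum(step)
    tr
  })
}

#' Simulate a cohort of trajectories
#'
#' @param config a [sim_config()].
#' @param schedule a [light_schedule()].
#' @param n_per_genotype subjects per genotype (default `config$n_subjects`).
#' @param genotypes genotype labels to simulate.
#' @return Named list of [trajectory()] objects (`wt_1`, ..., `mutant_1`,
#'   ...).
#' @export
simulate_cohort <- function(config, schedule,
                            n_per_genotype = config$n_subjects,
                            genotypes = c("wt", "mutant")) {
  out <- list()
  for (g in genotypes)
    for (i in seq_len(n_per_genotype)) {
      id <- paste0(g, "_", i)
      out[[id]] <- simulate_trajectory(config, schedule, subject_id = id,
                                       genotype = g, subject_index = i)
    }
  out
}

#' Closed-form expectations of the swim model
#'
#' Long-run move-state occupancy `r_on / (r_on + r_off)`, mean bout speed
#' `exp(meanlog + sdlog^2 / 2)`, and the expected distance rate
#' (occupancy x mean speed, mm/s) for a condition and genotype.
#'
#' @param config a [sim_config()].
#' @param condition light condition.
#' @param genotype `"wt"` or `"mutant"`.
#' @return list: `occupancy`, `mean_speed_mm_s`, `distance_rate_mm_s`.
#' @export
swim_expectations <- function(config, condition = "dark", genotype = "wt") {
  stopifnot(inherits(config, "sim_config"))
  sw <- config$swim
  mult <- if (identical(genotype, "wt")) 1 else config$genotype$activity_multiplier
  r_on <- unname(sw$rate_on[condition]) * mult
  occ <- r_on / (r_on + sw$rate_off)
  spd <- exp(sw$speed_meanlog + sw$speed_sdlog^2 / 2)
  list(occupancy = occ, mean_speed_mm_s = spd,
       distance_rate_mm_s = occ * spd)
}

# ---- avoidance simulator ---------------------------------------------------

#' Outcome probabilities of the avoidance model
#'
#' Logistic size tuning on log dot size with habituation:
#' `P(avoid) = L * plogis(a * (log(theta) - log(theta0))) * h^k` where `k`
#' counts prior presentations of dots at or above the habituation threshold;
#' `P(approach) = A * (1 - plogis(a * (log(theta) - log(theta0))))` declines
#' with size; the rest is neutral. Mutants shift `theta0` by
#' `genotype$theta0_shift_deg`.
#'
#' @param config a [sim_config()].
#' @param size_deg dot size(s) in visual degrees.
#' @param k number of prior habituating exposures (same length as `size_deg`
#'   or scalar).
#' @param genotype `"wt"` or `"mutant"`.
#' @return data.frame with columns `p_avoid`, `p_approach`, `p_neutral`.
#' @export
avoidance_probs <- function(config, size_deg, k = 0, genotype = "wt") {
  stopifnot(inherits(config, "sim_config"), all(size_deg > 0), all(k >= 0))
  av <- config$avoidance
  theta0 <- av$theta0_deg +
    if (identical(genotype, "wt")) 0 else config$genotype$theta0_shift_deg
  stopifnot(theta0 > 0)
  s <- stats::plogis(av$slope * (log(size_deg) - log(theta0)))
  p_av <- av$max_avoid * s * av$habituation^k
  p_ap <- av$max_approach * (1 - s)
  data.frame(p_avoid = p_av, p_approach = p_ap,
             p_neutral = 1 - p_av - p_ap)
}

# habituation exposure count before each presentation of a plan
habituation_counts <- function(config, plan) {
  log <- presentation_log(plan)
  thr <- config$avoidance$habituation_threshold_deg
  big <- log$size_deg >= thr
  c(0, cumsum(big))[seq_len(nrow(log))]
}

#' Expected avoidance index per dot size under a trial plan
#'
#' Closed-form counterpart of [simulate_avoidance_trial()]: for each size,
#' the mean over its presentations of `P(avoid) - P(approach)`, with the
#' habituation exposure count `k` accumulated along the plan's presentation
#' order. This is the quantity a large simulated cohort's mean AI converges
#' to.
#'
#' @param config a [sim_config()].
#' @param plan a [trial_plan()].
#' @param genotype `"wt"` or `"mutant"`.
#' @return data.frame per size (ascending): `size_deg`, `expected_ai`.
#' @export
expected_avoidance <- function(config, plan, genotype = "wt") {
  log <- presentation_log(plan)
  k <- habituation_counts(config, plan)
  pr <- avoidance_probs(config, log$size_deg, k, genotype)
  d <- aggregate(data.frame(expected_ai = pr$p_avoid - pr$p_approach),
                 log["size_deg"], mean)
  d[order(d$size_deg), ]
}

#' Simulate one subject's dot-interaction events
#'
#' Walks the plan's presentation order, drawing each outcome from the
#' categorical distribution of [avoidance_probs()] while accumulating the
#' habituation count. Deterministic given `config$seed` and `subject_index`.
#'
#' @param config a [sim_config()].
#' @param plan a [trial_plan()].
#' @param subject_id identifier stamped on the events.
#' @param genotype `"wt"` or `"mutant"`.
#' @param subject_index integer deriving the RNG substream.
#' @return data.frame of interaction events: `subject_id`, `genotype`,
#'   `size_deg`, `presentation_index`, `outcome`.
#' @export
simulate_avoidance_trial <- function(config, plan, subject_id = "s1",
                                     genotype = "wt", subject_index = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(plan, "trial_plan"))
  log <- presentation_log(plan)
  k <- habituation_counts(config, plan)
  pr <- avoidance_probs(config, log$size_deg, k, genotype)
  with_seed(stream_seed(config$seed, subject_index,
                        genotype_salt(genotype) + 17L), {
    u <- stats::runif(nrow(log))
    outcome <- ifelse(u < pr$p_avoid, "avoidance",
                      ifelse(u < pr$p_avoid + pr$p_approach,
                             "approach", "neutral"))
  })
  data.frame(subject_id = subject_id, genotype = genotype,
             size_deg = log$size_deg,
             presentation_index = log$presentation_index,
             outcome = outcome)
}

#' Simulate a cohort's dot-interaction events
#'
#' @inheritParams simulate_cohort
#' @param plan a [trial_plan()].
#' @return One event data.frame covering all subjects.
#' @export
simulate_avoidance_cohort <- function(config, plan,
                                      n_per_genotype = config$n_subjects,
                                      genotypes = c("wt", "mutant")) {
  rows <- list()
  for (g in genotypes)
    for (i in seq_len(n_per_genotype))
      rows[[paste0(g, "_", i)]] <-
        simulate_avoidance_trial(config, plan, paste0(g, "_", i), g, i)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# ---- qPCR simulator --------------------------------------------------------

#' Simulate a qPCR plate
#'
#' For each group and biological sample, a true expression per gene is drawn
#' as `expression * 2^N(0, bio_sd_log2)` (the reference gene has expression 1
#' and no biological scatter); every technical replicate's Ct is
#' `base_ct - log2(expression) + N(0, noise_sd)`. Duplicates share the
#' sample's expression, as in a duplicate-well plate design.
#'
#' @param config a [sim_config()].
#' @param expression data.frame with columns `group`, `gene`, `expression`
#'   (true relative expression of each target gene in each group).
#' @param n_per_group biological samples per group.
#' @param duplicates technical replicates per sample and gene (default 2).
#' @return A qPCR well table: `sample_id`, `group`, `gene`, `replicate`,
#'   `ct`.
#' @export
simulate_qpcr <- function(config, expression, n_per_group = 6,
                          duplicates = 2) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(expression),
            all(c("group", "gene", "expression") %in% names(expression)),
            all(expression$expression > 0), n_per_group >= 1, duplicates >= 1)
  q <- config$qpcr
  groups <- unique(expression$group)
  rows <- list()
  sidx <- 0L
  for (g in groups) {
    eg <- expression[expression$group == g, ]
    for (j in seq_len(n_per_group)) {
      sidx <- sidx + 1L
      sample_id <- sprintf("%s_%02d", g, j)
      rows[[sample_id]] <- with_seed(
        stream_seed(config$seed, sidx, genotype_salt(g) + 23L), {
          genes <- c(eg$gene, q$ref_gene)
          expr <- c(eg$expression *
                      2^stats::rnorm(nrow(eg), 0, q$bio_sd_log2), 1)
          true_ct <- q$base_ct - log2(expr)
          data.frame(
            sample_id = sample_id, group = g,
            gene = rep(genes, each = duplicates),
            replicate = rep(seq_len(duplicates), times = length(genes)),
            ct = rep(true_ct, each = duplicates) +
              stats::rnorm(length(genes) * duplicates, 0, q$noise_sd))
        })
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# ---- end-to-end parameter recovery -----------------------------------------

#' Parameter-recovery experiment over replicate cohorts
#'
#' Runs the full pipeline (trajectory simulation -> binned distance series ->
#' per-condition AUC -> two-group decision-tree test) on replicate simulated
#' cohorts of wild-type fish versus mutants carrying an activity multiplier,
#' and reports the estimated mutant/wild-type AUC ratio in the chosen
#' condition and the fraction of cohorts in which the comparison rejects
#' (power at the configured effect size; under `multiplier = 1` this is a
#' null calibration and the rate estimates the test's size).
#'
#' Runtime note: the default configuration samples at 5 frames/s rather than
#' the 60 frames/s of the real tracker. Per-frame displacement is
#' `speed / frame_rate`, so the AUC ratio and the test outcome are
#' frame-rate invariant; the lower rate only cuts compute.
#'
#' @param config a [sim_config()]; its `genotype$activity_multiplier` is
#'   overridden by `multiplier`.
#' @param n_cohorts replicate cohorts.
#' @param n_per_group fish per genotype per cohort.
#' @param multiplier mutant activity multiplier on the rest-to-move rates.
#' @param schedule a [light_schedule()] (default the 3-h photokinesis
#'   paradigm).
#' @param condition which condition's pooled AUC to compare.
#' @param alpha rejection level.
#' @return list of class `"recovery_report"`: `ratio_estimate` (mean cohort
#'   ratio), `true_ratio` (closed-form occupancy ratio), `power`,
#'   `rejections`, `cohort_ratios`, `n_cohorts`, `multiplier`.
#' @export
recovery_experiment <- function(config = sim_config(frame_rate = 5),
                                n_cohorts = 200, n_per_group = 24,
                                multiplier = 1.5,
                                schedule = photokinesis_schedule(),
                                condition = "dark", alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"), n_cohorts >= 1, n_per_group >= 2)
  config$genotype$activity_multiplier <- multiplier
  ratios <- numeric(n_cohorts)
  pvals <- numeric(n_cohorts)
  dark_total <- function(genotype, base_index) {
    vapply(seq_len(n_per_group), function(i) {
      tr <- simulate_trajectory(config, schedule,
                                subject_id = paste0(genotype, "_", i),
                                genotype = genotype,
                                subject_index = base_index + i)
      ser <- distance_series(tr, bin_width_s = 10, origin_s = 0)
      agg <- condition_aggregate(ser, schedule)
      agg$auc_mm[agg$condition == condition]
    }, numeric(1))
  }
  for (cc in seq_len(n_cohorts)) {
    base <- (cc - 1L) * 2L * n_per_group
    wt <- dark_total("wt", base)
    mut <- dark_total("mutant", base + n_per_group)
    ratios[cc] <- mean(mut) / mean(wt)
    pvals[cc] <- compare_groups(mut, wt, labels = c("mutant", "wt"))$p_two_tailed
  }
  sw <- swim_expectations(config, condition, "wt")
  sm <- swim_expectations(config, condition, "mutant")
  structure(list(ratio_estimate = mean(ratios),
                 true_ratio = sm$occupancy / sw$occupancy,
                 power = mean(pvals <= alpha),
                 rejections = sum(pvals <= alpha),
                 cohort_ratios = ratios, n_cohorts = n_cohorts,
                 multiplier = multiplier),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("<recovery_report> %d cohorts, multiplier %.3g: ",
                     "AUC ratio %.3f (closed form %.3f), power %.3f\n"),
              x$n_cohorts, x$multiplier, x$ratio_estimate, x$true_ratio,
              x$power))
  invisible(x)
}
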