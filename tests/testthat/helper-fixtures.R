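# Shared fixture builders and independent oracles.

# trajectory moving at constant speed v along x, sampled at `fr` Hz for T s
straight_trajectory <- function(v = 2, T = 60, fr = 10, subject_id = "s1",
                                genotype = "wt") {
  t <- seq(0, T, by = 1 / fr)
  trajectory(t, v * t, rep(0, length(t)), subject_id = subject_id,
             genotype = genotype, frame_rate = fr)
}

# hand-built activity series (bypasses distance_series) for window arithmetic
make_series <- function(distances, bin_width_s = 10, origin_s = 0,
                        subject_id = "s1", genotype = "wt",
                        flagged = rep(FALSE, length(distances))) {
  structure(data.frame(
    bin_start_s = origin_s + (seq_along(distances) - 1) * bin_width_s,
    distance_mm = distances, flagged = flagged),
    class = c("activity_series", "data.frame"),
    bin_width_s = bin_width_s, origin_s = origin_s,
    subject_id = subject_id, genotype = genotype)
}

# event table in which one subject shows a fixed outcome mix at each size
events_with_counts <- function(sizes, n_avoid, n_approach, n_neutral,
                               subject_id = "s1", genotype = "wt") {
  do.call(rbind, lapply(sizes, function(sz) {
    out <- c(rep("avoidance", n_avoid), rep("approach", n_approach),
             rep("neutral", n_neutral))
    data.frame(subject_id = subject_id, genotype = genotype, size_deg = sz,
               presentation_index = seq_along(out), outcome = out)
  }))
}

# Independent Mann-Whitney oracle: brute-force enumeration of every
# assignment of pooled values to the two groups, U computed by direct
# pairwise comparison (not via ranks).
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  lower <- mean(us <= u_obs + 1e-9)
  upper <- mean(us >= u_obs - 1e-9)
  list(u = u_obs, p = min(1, 2 * min(lower, upper)))
}

# seeded battery of small sample pairs, with and without ties
mw_battery <- function(n_pairs, seed) {
  set.seed(seed)
  lapply(seq_len(n_pairs), function(i) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    if (i %% 2 == 0) {
      list(x = sample(1:4, n, replace = TRUE),       # heavy ties
           y = sample(1:4, m, replace = TRUE))
    } else {
      list(x = round(rnorm(n), 2), y = round(rnorm(m, 0.5), 2))
    }
  })
}
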