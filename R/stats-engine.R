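# Two-sample statistics: D'Agostino-Pearson normality, two-tailed variance
# F-test, exact Mann-Whitney, and the normality-gated decision tree with star
# annotation.

# central sample moment of order k (biased, population convention)
cmoment <- function(x, k) mean((x - mean(x))^k)

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines z-transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into the omnibus statistic
#' `K2 = z_skew^2 + z_kurt^2`, referred to a chi-squared distribution with
#' 2 df. Valid for `n >= 8`.
#'
#' @param x numeric sample, `n >= 8`, finite, non-constant.
#' @return list of class `"normality_test"`: `k2`, `p`, `z_skew`, `z_kurt`,
#'   `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x) || any(is.infinite(x))) stop("sample must be finite")
  if (n < 8) stop("insufficient n for normality test (need n >= 8)")
  if (cmoment(x, 2) == 0) stop("constant sample: normality test undefined")

  # skewness z-transform
  g1 <- cmoment(x, 3) / cmoment(x, 2)^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z-transform
  b2 <- cmoment(x, 4) / cmoment(x, 2)^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + xx * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  structure(list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 z_skew = z1, z_kurt = z2, n = n),
            class = "normality_test")
}

#' Two-tailed F-test for equality of variances
#'
#' `F = s2_larger / s2_smaller` with a two-tailed p-value
#' `min(1, 2 * P(F >= f))` from the F distribution with the matching degrees
#' of freedom; for identical samples `F = 1` and `p = 1`. Assumes normality
#' (it is only applied after the normality gate passes).
#'
#' @param x,y numeric samples, both `n >= 2`.
#' @return list of class `"variance_test"`: `f`, `df1`, `df2`, `p`.
#' @export
variance_f_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (anyNA(c(x, y)) || any(is.infinite(c(x, y))))
    stop("samples must be finite")
  v <- c(stats::var(x), stats::var(y))
  n <- c(length(x), length(y))
  if (all(v == 0)) stop("zero variance in both groups: F-test undefined")
  hi <- which.max(v); lo <- 3 - hi
  f <- v[hi] / v[lo]
  df1 <- n[hi] - 1; df2 <- n[lo] - 1
  p <- if (is.infinite(f)) 0
       else min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  structure(list(f = f, df1 = df1, df2 = df2, p = p),
            class = "variance_test")
}

# U statistic of x vs y with midrank tie handling, from pooled midranks
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# enumeration cutoff for the exact tied branch
MW_ENUM_LIMIT <- 2e5

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test. The two-tailed p is the
#' doubled smaller tail probability of U under the permutation null, capped at
#' 1. Three evaluation branches:
#' \itemize{
#'   \item exact enumeration of all `choose(n+m, n)` rank assignments
#'     (midranks, so ties are handled exactly) whenever that count is at most
#'     `2e5` — this covers every `n + m <= 12` case, ties included;
#'   \item the exact closed-form null distribution of U for tie-free samples
#'     up to `n, m <= 50`;
#'   \item otherwise the normal approximation with midrank tie correction
#'     (no continuity correction).
#' }
#'
#' @param x,y numeric samples.
#' @return list of class `"mw_test"`: `u` (U of `x` versus `y`), `p`
#'   (two-tailed), `method` (`"exact_enumeration"`, `"exact_distribution"` or
#'   `"normal_approximation"`).
#' @export
#' @examples
#' exact_mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
exact_mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (anyNA(c(x, y)) || any(is.infinite(c(x, y))))
    stop("samples must be finite")
  n <- length(x); m <- length(y)
  u <- u_statistic(x, y)
  ties <- anyDuplicated(c(x, y)) > 0

  if (choose(n + m, min(n, m)) <= MW_ENUM_LIMIT) {
    r <- rank(c(x, y))
    combs <- utils::combn(n + m, n)
    us <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    lower <- mean(us <= u + 1e-9)
    upper <- mean(us >= u - 1e-9)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact_enumeration"
  } else if (!ties && n <= 50 && m <= 50) {
    lower <- stats::pwilcox(u, n, m)
    upper <- stats::pwilcox(n * m - u, n, m)  # P(U >= u) by symmetry
    p <- min(1, 2 * min(lower, upper))
    method <- "exact_distribution"
  } else {
    nt <- table(c(x, y))
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(nt^3 - nt) / ((n + m) * (n + m - 1)))
    z <- (u - n * m / 2) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  structure(list(u = u, p = p, method = method, n = c(n, m)),
            class = "mw_test")
}

#' Significance stars for a two-tailed p-value
#'
#' Boundary-inclusive mapping: `p <= 0.0001` four stars, `<= 0.001` three,
#' `<= 0.01` two, `<= 0.05` one, otherwise `"ns"`.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector over `{"ns", "*", "**", "***", "****"}`.
#' @export
star_annotation <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  cut_pts <- c(0.0001, 0.001, 0.01, 0.05)
  vapply(p, function(pi) {
    k <- sum(pi <= cut_pts)   # how many thresholds this p clears
    if (k == 0) "ns" else strrep("*", k)
  }, character(1))
}

#' Two-group comparison via the normality-gated decision tree
#'
#' Implements the test-selection procedure used for two-sample behavioral and
#' molecular comparisons:
#' \enumerate{
#'   \item If either group has `n < 8`, the normality test is undefined and
#'     the comparison is routed straight to the Mann-Whitney test.
#'   \item Otherwise [dagostino_pearson()] runs on each group at
#'     `alpha_gate`; if either group deviates from normality, Mann-Whitney.
#'   \item For two normal groups, [variance_f_test()] at `alpha_gate` decides
#'     between the unpaired Student t test (equal variances) and the Welch t
#'     test (unequal variances, Welch-Satterthwaite df).
#' }
#' All final p-values are two-tailed. Every gate taken is recorded in
#' `decision_trace`.
#'
#' @param x,y numeric samples, both `n >= 2`.
#' @param labels length-2 character vector naming the groups.
#' @param alpha_gate significance level of the normality and variance gates.
#' @return list of class `"stat_report"`: `test_name` (`"t"`, `"welch_t"` or
#'   `"mann_whitney"`), `statistic`, `df` (`NA` for Mann-Whitney),
#'   `p_two_tailed`, `stars`, `decision_trace` (data.frame `gate`, `outcome`,
#'   `p`), `labels`, `n`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # n < 8 -> Mann-Whitney, p = 0.1
compare_groups <- function(x, y, labels = c("x", "y"), alpha_gate = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 2, length(y) >= 2, length(labels) == 2)
  if (anyNA(c(x, y)) || any(is.infinite(c(x, y))))
    stop("samples must be finite")
  trace <- data.frame(gate = character(), outcome = character(), p = numeric())
  note <- function(gate, outcome, p = NA_real_)
    trace <<- rbind(trace, data.frame(gate = gate, outcome = outcome, p = p))

  mw <- function() {
    res <- exact_mann_whitney(x, y)
    note("final_test", paste0("mann_whitney (", res$method, ")"), res$p)
    list(test_name = "mann_whitney", statistic = c(U = res$u), df = NA_real_,
         p = res$p)
  }

  result <- if (length(x) < 8 || length(y) < 8) {
    note("normality", "insufficient n (< 8): gate bypassed to mann_whitney")
    mw()
  } else {
    nx <- dagostino_pearson(x); ny <- dagostino_pearson(y)
    note("normality_x", if (nx$p < alpha_gate) "non-normal" else "normal", nx$p)
    note("normality_y", if (ny$p < alpha_gate) "non-normal" else "normal", ny$p)
    if (nx$p < alpha_gate || ny$p < alpha_gate) {
      mw()
    } else {
      vt <- variance_f_test(x, y)
      eq <- vt$p >= alpha_gate
      note("variance_f", if (eq) "equal variances" else "unequal variances",
           vt$p)
      tt <- stats::t.test(x, y, var.equal = eq)
      name <- if (eq) "t" else "welch_t"
      note("final_test", name, tt$p.value)
      list(test_name = name, statistic = c(t = unname(tt$statistic)),
           df = unname(tt$parameter), p = tt$p.value)
    }
  }

  structure(list(test_name = result$test_name, statistic = result$statistic,
                 df = result$df, p_two_tailed = result$p,
                 stars = star_annotation(result$p), decision_trace = trace,
                 labels = labels, n = c(length(x), length(y))),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s vs %s (n = %d, %d): %s, %s = %.4g%s, p = %.4g [%s]\n",
              x$labels[1], x$labels[2], x$n[1], x$n[2], x$test_name,
              names(x$statistic)[1], x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %.4g", x$df),
              x$p_two_tailed, x$stars))
  cat("decision trace:\n")
  for (i in seq_len(nrow(x$decision_trace)))
    cat(sprintf("  %-12s %s%s\n", x$decision_trace$gate[i],
                x$decision_trace$outcome[i],
                if (is.na(x$decision_trace$p[i])) ""
                else sprintf(" (p = %.4g)", x$decision_trace$p[i])))
  invisible(x)
}

#' Serialize a stat report to JSON
#'
#' @param report a [compare_groups()] result.
#' @param path file path, or `NULL` to return the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_stat_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "stat_report"))
  obj <- list(test_name = report$test_name,
              statistic = unname(report$statistic),
              df = if (is.na(report$df)) NULL else report$df,
              p_two_tailed = report$p_two_tailed, stars = report$stars,
              labels = report$labels, n = report$n,
              decision_trace = report$decision_trace)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Type-I error calibration of the decision tree
#'
#' Simulates iid Gaussian null pairs and reports how often
#' [compare_groups()] rejects at level `alpha`. Used to check that the
#' normality- and variance-gated procedure keeps its nominal size.
#'
#' @param n_per_group sample size of each group.
#' @param n_sims number of simulated null comparisons.
#' @param seed RNG seed.
#' @param alpha rejection level applied to the final two-tailed p.
#' @return list: `rejection_rate`, `n_sims`, `alpha`, `test_counts` (how often
#'   each final test was chosen).
#' @export
type_i_error_rate <- function(n_per_group = 20, n_sims = 2000, seed = 1,
                              alpha = 0.05) {
  with_seed(as.integer(seed), {
    p <- numeric(n_sims)
    picked <- character(n_sims)
    for (i in seq_len(n_sims)) {
      r <- compare_groups(stats::rnorm(n_per_group), stats::rnorm(n_per_group))
      p[i] <- r$p_two_tailed
      picked[i] <- r$test_name
    }
    list(rejection_rate = mean(p <= alpha), n_sims = n_sims, alpha = alpha,
         test_counts = table(picked))
  })
}
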