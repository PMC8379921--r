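#' Welch two-sample t-test
#'
#' Two-tailed two-sample t-test with unequal variances (Welch).  When both
#' samples have zero variance and equal means the statistic is 0 and p = 1
#' by convention.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return a `test_result`: list with `statistic`, `p_value`, `n` (per
#'   group), `method = "two_sample_t"`.
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stat <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
    p <- if (mean(x) == mean(y)) 1 else 0
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(statistic = stat, p_value = p,
                 n = c(length(x), length(y)), method = "two_sample_t"),
            class = "test_result")
}

#' Two-proportion z-test (pooled variance, two-tailed)
#'
#' @param k1,n1 successes and size of the first group.
#' @param k2,n2 successes and size of the second group.
#' @return a `test_result` with the z statistic and two-tailed p.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp %in% c(0, 1)) {
    # degenerate pooled proportion: groups are necessarily equal
    z <- 0; p <- 1
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p_value = p, n = c(n1, n2),
                 method = "two_proportion_z"),
            class = "test_result")
}

#' Two-tailed binomial test against a fixed proportion
#'
#' Normal approximation for n >= 100, exact binomial otherwise (and always
#' when the observed proportion is 0 or 1 with small n).
#'
#' @param k successes.
#' @param n trials.
#' @param p0 null proportion (default 0.5).
#' @return a `test_result` with the z statistic (NA for the exact branch)
#'   and two-tailed p.
#' @export
binomial_two_tailed <- function(k, n, p0 = 0.5) {
  stopifnot(n >= 1, k >= 0, k <= n)
  phat <- k / n
  if (n < 100 || phat %in% c(0, 1)) {
    p <- stats::binom.test(k, n, p0)$p.value
    z <- NA_real_
  } else {
    z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p_value = min(p, 1), n = n,
                 method = "binomial_two_tailed"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$method, ": statistic = ",
      format(x$statistic, digits = 4), ", two-tailed p = ",
      format(x$p_value, digits = 4), ", n = ",
      paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Empirical type-I-error calibration of a test
#'
#' Repeatedly applies `test_fun` to data drawn from `null_generator` and
#' reports the rejection rate at level `alpha`; under a true null the rate
#' should match `alpha` within Monte-Carlo error.
#'
#' @param test_fun function(data) returning a `test_result` (or any list
#'   with a `p_value`).
#' @param null_generator function() producing one dataset under the null.
#' @param alpha nominal level.
#' @param reps Monte-Carlo repetitions (>= 1000 recommended).
#' @param seed RNG seed.
#' @return list with `rate`, `se` (binomial), `alpha`, `reps`.
#' @export
type_i_error_suite <- function(test_fun, null_generator, alpha = 0.05,
                               reps = 1000, seed = 1) {
  stopifnot(reps >= 1)
  set.seed(seed)
  rej <- vapply(seq_len(reps), function(i) {
    r <- test_fun(null_generator())
    as.numeric(r$p_value < alpha)
  }, numeric(1))
  rate <- mean(rej)
  list(rate = rate, se = sqrt(alpha * (1 - alpha) / reps),
       alpha = alpha, reps = reps)
}

#' Between-replicate standard deviation
#'
#' SD over replicate-level point estimates, the "±SD between experiments"
#' convention used for headline fractions.
#'
#' @param estimates numeric vector of per-replicate estimates.
#' @return the SD (NA for fewer than two replicates).
#' @export
between_replicate_sd <- function(estimates) {
  if (length(estimates) < 2) return(NA_real_)
  sd(estimates)
}
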