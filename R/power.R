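#' Analytic power of the pooled two-sample t-test
#'
#' Power of the two-sided pooled-variance t-test at significance level
#' `alpha`, using the noncentral t distribution with
#' \eqn{ncp = \delta / (\sigma_p \sqrt{1/n_1 + 1/n_2})} where \eqn{\sigma_p}
#' is the pooled standard deviation implied by the two group SDs. This is the
#' textbook analytic power of the test that is actually run (the pooled
#' test), which is the right comparator for simulations that draw the two
#' groups with unequal SDs.
#'
#' @param n1,n2 group sizes.
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations.
#' @param alpha two-sided significance level.
#' @return power in `[0, 1]`.
#' @export
analytic_t_test_power <- function(n1, n2, mean1, mean2, sd1, sd2,
                                  alpha = 0.05) {
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  ncp <- abs(mean2 - mean1) / (sp * sqrt(1 / n1 + 1 / n2))
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Monte-Carlo rejection frequency of the pooled t-test
#'
#' Simulates two normal groups at the given sizes, means and SDs, applies the
#' pooled two-sample t-test, and returns the fraction of replicates rejecting
#' at level `alpha`.
#'
#' @inheritParams analytic_t_test_power
#' @param n_sim number of replicates.
#' @param seed RNG seed.
#' @return estimated rejection frequency.
#' @export
simulate_t_test_power <- function(n1, n2, mean1, mean2, sd1, sd2,
                                  alpha = 0.05, n_sim = 2000, seed = 1L) {
  with_seed(seed, {
    rej <- vapply(seq_len(n_sim), function(i) {
      x <- stats::rnorm(n1, mean1, sd1)
      y <- stats::rnorm(n2, mean2, sd2)
      t_test_two_sample(x, y)$p_value < alpha
    }, logical(1))
    mean(rej)
  })
}
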