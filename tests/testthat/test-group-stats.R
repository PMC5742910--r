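published_table <- contingency_2x2(20, 5, 8, 11)

test_that("Pearson chi-squared matches the published 2x2 value", {
  res <- chi_square_2x2(published_table)
  expect_equal(round(res$chi_square, 3), 6.699)
  expect_equal(round(res$p_value, 3), 0.01)
  expect_equal(res$df, 1)
})

test_that("chi-squared agrees with first-principles expected counts", {
  expect_equal(chi_square_2x2(contingency_2x2(5, 5, 2, 8))$chi_square,
               chi2_oracle(matrix(c(5, 5, 2, 8), 2, byrow = TRUE)),
               tolerance = 1e-12)
  expect_equal(chi_square_2x2(contingency_2x2(10, 10, 10, 10))$chi_square, 0)
  expect_error(chi_square_2x2(contingency_2x2(0, 0, 3, 4)), "degenerate")
})

test_that("chi-squared is invariant under transposition and swaps", {
  set.seed(5)
  for (rep in 1:20) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2, 2)
    x2 <- chi_square_2x2(m)$chi_square
    expect_equal(chi_square_2x2(t(m))$chi_square, x2, tolerance = 1e-12)
    expect_equal(chi_square_2x2(m[2:1, 2:1])$chi_square, x2,
                 tolerance = 1e-12)
  }
})

test_that("phi reproduces the published correlation and its identity", {
  res <- phi_coefficient(published_table)
  expect_equal(round(res$r, 3), -0.39)
  expect_equal(round(res$p_value, 3), 0.009)
  chi <- chi_square_2x2(published_table)
  expect_lt(abs(abs(res$r) - sqrt(chi$chi_square / res$n)), 1e-10)
  expect_equal(phi_coefficient(contingency_2x2(10, 10, 10, 10))$r, 0)
})

test_that("phi squared times N equals chi-squared on random tables", {
  set.seed(9)
  for (rep in 1:30) {
    m <- matrix(sample(1:40, 4, replace = TRUE), 2, 2)
    chi <- chi_square_2x2(m)$chi_square
    phi <- phi_coefficient(m)$r
    expect_lt(abs(phi^2 * sum(m) - chi), 1e-10)
  }
})

test_that("the sign of phi follows the coding", {
  flipped <- default_coding()
  flipped$group <- c(control = 2, ADHD = 1)
  expect_equal(phi_coefficient(published_table, flipped)$r,
               -phi_coefficient(published_table)$r)
})

test_that("the pooled t-test behaves at its anchors", {
  res <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  sep <- t_test_two_sample(c(1, 2, 3), c(11, 12, 13))
  expect_gt(abs(sep$t), 10)
  expect_lt(sep$p_value, 1e-3)
  expect_error(t_test_two_sample(1, c(1, 2)), "at least 2")
  # Welch variant reacts to unequal variances
  set.seed(3)
  x <- rnorm(20, sd = 1); y <- rnorm(8, sd = 6)
  expect_false(isTRUE(all.equal(t_test_two_sample(x, y)$p_value,
                                t_test_two_sample(x, y, FALSE)$p_value)))
})

test_that("Mann-Whitney U equals the exhaustive pair-count oracle", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$Z, 0)
  expect_equal(same$p_value, 1)
  set.seed(21)
  for (rep in 1:40) {
    x <- sample(1:6, sample(1:8, 1), replace = TRUE)   # ties likely
    y <- sample(1:6, sample(1:8, 1), replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$U, u_count_oracle(x, y))
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test as cross-check", {
  set.seed(33)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(9, 0.5)           # continuous: no ties
    res <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(res$U, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("point-biserial correlation matches cor.test and its anchors", {
  vals <- c(1, 2, 3, 1, 2, 3)
  labs <- c("ADHD", "ADHD", "ADHD", "control", "control", "control")
  expect_equal(point_biserial(vals, labs)$r, 0)

  codes <- default_coding()$group[labs]
  res <- point_biserial(codes, labs)
  expect_equal(abs(res$r), 1)

  set.seed(8)
  v <- rnorm(30)
  l <- sample(c("ADHD", "control"), 30, replace = TRUE, prob = c(0.6, 0.4))
  res2 <- point_biserial(v, l)
  ref <- stats::cor.test(v, default_coding()$group[l])
  expect_equal(res2$r, unname(ref$estimate))
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(point_biserial(v, rep("ADHD", 30)), "both groups")
})

test_that("the assembled comparison reproduces its parts and is order-invariant", {
  set.seed(14)
  records <- data.frame(
    subject_id = sprintf("s%02d", 1:20),
    group = rep(c("ADHD", "control"), each = 10),
    age = round(rnorm(20, 30, 8), 1),
    gender = c(rep("male", 7), rep("female", 3),
               rep("male", 4), rep("female", 6)),
    ben = c(rnorm(10, 0.55, 0.1), rnorm(10, 0.65, 0.1)))
  cmp <- build_table1(records)
  expect_equal(cmp$ben$t_test$t,
               t_test_two_sample(records$ben[1:10], records$ben[11:20])$t)
  expect_equal(cmp$gender$chi_square$chi_square,
               chi_square_2x2(contingency_2x2(7, 3, 4, 6))$chi_square)
  expect_lt(abs(cmp$gender$phi$r^2 * 20 - cmp$gender$chi_square$chi_square),
            1e-10)
  shuffled <- build_table1(records[sample(20), ])
  expect_equal(as_table1_row(shuffled), as_table1_row(cmp))
})

test_that("identical groups yield null statistics and excluded rows are dropped", {
  base <- data.frame(
    subject_id = sprintf("s%02d", 1:12),
    group = rep(c("ADHD", "control"), each = 6),
    age = rep(c(25, 30, 35, 40, 45, 50), 2),
    gender = rep(c("male", "male", "male", "female", "female", "female"), 2),
    ben = rep(c(0.4, 0.5, 0.6, 0.45, 0.55, 0.65), 2))
  cmp <- build_table1(base)
  expect_equal(cmp$ben$t_test$t, 0)
  expect_equal(cmp$ben$t_test$p_value, 1)
  expect_equal(cmp$ben$mann_whitney$Z, 0)
  expect_equal(cmp$age$mann_whitney$Z, 0)
  expect_equal(cmp$gender$chi_square$chi_square, 0)

  with_na <- base
  with_na$ben[1] <- NA
  cmp2 <- build_table1(with_na)
  expect_equal(cmp2$excluded, "s01")
  expect_equal(unname(cmp2$n["ADHD"]), 5L)

  only_one <- base[c(1, 7:12), ]
  expect_error(build_table1(only_one), "empty group")
})

test_that("permuting null group labels rejects at about the nominal level", {
  set.seed(99)
  vals <- rnorm(44, 0.6, 0.12)              # one null cohort, no group effect
  rej <- vapply(seq_len(2000), function(i) {
    idx <- sample(44, 25)
    t_test_two_sample(vals[idx], vals[-idx])$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("analytic pooled-t power matches power.t.test at equal n and sd", {
  # power.t.test drops the far-tail rejection mass (~2e-4 here), so agreement
  # is to that order rather than machine precision
  ref <- stats::power.t.test(n = 20, delta = 0.5, sd = 1)$power
  expect_equal(analytic_t_test_power(20, 20, 0, 0.5, 1, 1), ref,
               tolerance = 1e-3)
  expect_gte(analytic_t_test_power(20, 20, 0, 0.5, 1, 1), ref)
})
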