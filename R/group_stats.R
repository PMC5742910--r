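#' Build a 2x2 gender-by-group contingency table
#'
#' Rows are groups (ADHD, control), columns genders (male, female).
#'
#' @param a,b,c,d cell counts: `a` = ADHD male, `b` = ADHD female,
#'   `c` = control male, `d` = control female.
#' @return an object of class `contingency_2x2` (an integer matrix with
#'   dimnames).
#' @examples
#' contingency_2x2(20, 5, 8, 11)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(counts) < 1) stop("degenerate table: N must be >= 1")
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE,
              dimnames = list(group = c("ADHD", "control"),
                              gender = c("male", "female")))
  structure(m, class = c("contingency_2x2", "matrix"))
}

as_table_2x2 <- function(table) {
  if (inherits(table, "contingency_2x2")) return(unclass(table))
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("a 2x2 table is required")
  m
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Pearson's chi-squared without continuity correction:
#' \eqn{\chi^2 = \sum (O - E)^2 / E} over the four cells, expected counts from
#' the row/column margins, p-value from the chi-squared distribution with one
#' degree of freedom. (The uncorrected statistic is the one SPSS labels
#' "Pearson Chi-Square".)
#'
#' @param table a [contingency_2x2()] or plain 2x2 matrix.
#' @return list with `chi_square`, `df` (= 1), and `p_value`.
#' @examples
#' chi_square_2x2(contingency_2x2(20, 5, 8, 11))$chi_square   # 6.699
#' @export
chi_square_2x2 <- function(table) {
  m <- as_table_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: every row and column margin must be positive")
  }
  # the small-expected-count advisory is suppressed: the statistic is exact
  # algebra and the precondition (positive margins) is checked above
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Default numeric coding for the binary variables
#'
#' Coding determines the sign of the phi and point-biserial correlations:
#' gender male = 1, female = 2; group control = 1, ADHD = 2. With a
#' male-dominated ADHD group this yields a negative gender-group phi, and a
#' control group with higher BEN yields a negative BEN-group correlation.
#'
#' @return named list with `gender` and `group` code maps.
#' @export
default_coding <- function() {
  list(gender = c(male = 1, female = 2),
       group = c(control = 1, ADHD = 2))
}

#' Phi coefficient of a 2x2 table
#'
#' The Pearson correlation of the two coded binary variables over all N
#' subjects. Satisfies \eqn{|\phi| = \sqrt{\chi^2 / N}} exactly; the sign
#' depends on the coding.
#'
#' @param table a [contingency_2x2()] or plain 2x2 matrix (rows ADHD/control,
#'   columns male/female).
#' @param coding code maps as from [default_coding()].
#' @return list with `r` (phi), `p_value` (via the t transform with
#'   `df = N - 2`), and `n`.
#' @examples
#' phi_coefficient(contingency_2x2(20, 5, 8, 11))$r   # -0.390
#' @export
phi_coefficient <- function(table, coding = default_coding()) {
  m <- as_table_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: every row and column margin must be positive")
  }
  gcode <- coding$group[c("ADHD", "control")]
  sexcode <- coding$gender[c("male", "female")]
  grp <- rep(rep(gcode, each = 2), times = as.vector(t(m)))
  sex <- rep(rep(sexcode, times = 2), times = as.vector(t(m)))
  n <- sum(m)
  r <- stats::cor(grp, sex)
  list(r = r, p_value = cor_p_value(r, n), n = n)
}

# two-sided p for a Pearson correlation via t = r sqrt(n-2)/sqrt(1-r^2)
cor_p_value <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Two-sample t-test on entropy values
#'
#' Pooled-variance two-sample t-test by default (the SPSS default row);
#' `var_equal = FALSE` gives the Welch variant. Two-sided.
#'
#' @param x,y numeric vectors (e.g. subject BEN per group), each of size >= 2.
#' @param var_equal pool the variances (default `TRUE`).
#' @return list with `t`, `df`, `p_value`, and the group means.
#' @export
t_test_two_sample <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group must contain at least 2 observations")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_x = mean(x), mean_y = mean(y))
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' U is the number of (x, y) pairs with x below y plus half the tied pairs,
#' computed from ranks. The Z statistic uses the normal approximation with the
#' tie-corrected variance and no continuity correction (the convention SPSS
#' prints); the two-sided p-value comes from Z.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with `U` (for the first sample), `Z`, and `p_value`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$U   # 0
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {                      # all values tied
    return(list(U = U, Z = 0, p_value = 1))
  }
  Z <- (U - mu) / sqrt(sigma2)
  list(U = U, Z = Z, p_value = 2 * stats::pnorm(-abs(Z)))
}

#' Point-biserial correlation between a continuous variable and group
#'
#' Pearson correlation between the values and the numeric group codes; the
#' p-value uses \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} with `n - 2` degrees of
#' freedom.
#'
#' @param values numeric vector (e.g. subject BEN).
#' @param labels group labels, same length, with exactly two levels present
#'   matching the names of `coding$group`.
#' @param coding code maps as from [default_coding()].
#' @return list with `r`, `p_value`, and `n`.
#' @export
point_biserial <- function(values, labels, coding = default_coding()) {
  labels <- as.character(labels)
  if (length(values) != length(labels) || length(values) < 3) {
    stop("values and labels must have equal length >= 3")
  }
  codes <- coding$group[labels]
  if (any(is.na(codes))) {
    stop("labels must be among: ", paste(names(coding$group), collapse = ", "))
  }
  if (length(unique(codes)) < 2) {
    stop("both groups must be represented")
  }
  r <- stats::cor(values, codes)
  list(r = r, p_value = cor_p_value(r, length(values)), n = length(values))
}

#' Assemble the full two-group comparison report
#'
#' Computes, from a subject table, the standard clinical comparison battery:
#' per-group mean +/- SD of BEN and age, pooled t-test on BEN, Mann-Whitney U
#' (Z) on age and on BEN, Pearson chi-squared and phi on the gender-by-group
#' table, and the point-biserial BEN-group correlation.
#'
#' @param records data frame with columns `subject_id`, `group` (ADHD /
#'   control), `age`, `gender` (male / female), `ben`; rows with missing BEN
#'   (excluded subjects) are dropped first.
#' @param coding numeric coding for the signed correlations.
#' @return an object of class `group_comparison`.
#' @export
build_table1 <- function(records, coding = default_coding()) {
  req <- c("subject_id", "group", "age", "gender", "ben")
  if (!all(req %in% names(records))) {
    stop("records must contain columns: ", paste(req, collapse = ", "))
  }
  excluded <- records$subject_id[is.na(records$ben)]
  records <- records[!is.na(records$ben), , drop = FALSE]
  x <- records[records$group == "ADHD", , drop = FALSE]
  y <- records[records$group == "control", , drop = FALSE]
  if (nrow(x) < 2 || nrow(y) < 2) {
    stop("empty group: need at least 2 subjects per group")
  }
  tab <- contingency_2x2(sum(x$gender == "male"), sum(x$gender == "female"),
                         sum(y$gender == "male"), sum(y$gender == "female"))
  chi <- chi_square_2x2(tab)
  phi <- phi_coefficient(tab, coding)
  structure(list(
    n = c(ADHD = nrow(x), control = nrow(y)),
    excluded = excluded,
    ben = list(mean = c(ADHD = mean(x$ben), control = mean(y$ben)),
               sd = c(ADHD = stats::sd(x$ben), control = stats::sd(y$ben)),
               t_test = t_test_two_sample(x$ben, y$ben),
               mann_whitney = mann_whitney_u(x$ben, y$ben)),
    age = list(mean = c(ADHD = mean(x$age), control = mean(y$age)),
               sd = c(ADHD = stats::sd(x$age), control = stats::sd(y$age)),
               mann_whitney = mann_whitney_u(x$age, y$age)),
    gender = list(table = tab, chi_square = chi, phi = phi),
    ben_group_correlation = point_biserial(records$ben, records$group, coding),
    coding = coding),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  f <- function(v) sprintf("%.3f", v)
  cat("Comparison of group characteristics\n")
  cat(sprintf("%-28s %-16s %-16s %10s %8s\n", "",
              sprintf("ADHD (n = %d)", x$n["ADHD"]),
              sprintf("Control (n = %d)", x$n["control"]), "Z/chi2", "p"))
  cat(sprintf("%-28s %-16s %-16s %10s %8s\n", "Age",
              paste0(f(x$age$mean["ADHD"]), " ± ", f(x$age$sd["ADHD"])),
              paste0(f(x$age$mean["control"]), " ± ",
                     f(x$age$sd["control"])),
              f(x$age$mann_whitney$Z), f(x$age$mann_whitney$p_value)))
  cat(sprintf("%-28s %-16s %-16s %10s %8s\n", "Gender (male/female)",
              paste(x$gender$table["ADHD", ], collapse = "/"),
              paste(x$gender$table["control", ], collapse = "/"),
              f(x$gender$chi_square$chi_square),
              f(x$gender$chi_square$p_value)))
  cat(sprintf("%-28s %-16s %-16s %10s %8s\n", "Brain entropy (BEN)",
              paste0(f(x$ben$mean["ADHD"]), " ± ", f(x$ben$sd["ADHD"])),
              paste0(f(x$ben$mean["control"]), " ± ",
                     f(x$ben$sd["control"])),
              f(x$ben$mann_whitney$Z), f(x$ben$t_test$p_value)))
  cat(sprintf("BEN-group correlation r = %s (p = %s); gender-group phi = %s (p = %s)\n",
              f(x$ben_group_correlation$r), f(x$ben_group_correlation$p_value),
              f(x$gender$phi$r), f(x$gender$phi$p_value)))
  if (length(x$excluded)) {
    cat("Excluded (no retained pixels):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a group comparison into a one-row data frame
#'
#' @param comparison a [build_table1()] result.
#' @return one-row data frame of the headline statistics (for CSV export).
#' @export
as_table1_row <- function(comparison) {
  stopifnot(inherits(comparison, "group_comparison"))
  x <- comparison
  data.frame(
    n_adhd = x$n[["ADHD"]], n_control = x$n[["control"]],
    ben_mean_adhd = x$ben$mean[["ADHD"]], ben_sd_adhd = x$ben$sd[["ADHD"]],
    ben_mean_control = x$ben$mean[["control"]],
    ben_sd_control = x$ben$sd[["control"]],
    ben_t = x$ben$t_test$t, ben_t_p = x$ben$t_test$p_value,
    ben_mw_z = x$ben$mann_whitney$Z, ben_mw_p = x$ben$mann_whitney$p_value,
    age_mean_adhd = x$age$mean[["ADHD"]], age_sd_adhd = x$age$sd[["ADHD"]],
    age_mean_control = x$age$mean[["control"]],
    age_sd_control = x$age$sd[["control"]],
    age_mw_z = x$age$mann_whitney$Z, age_mw_p = x$age$mann_whitney$p_value,
    gender_chi_square = x$gender$chi_square$chi_square,
    gender_chi_p = x$gender$chi_square$p_value,
    gender_phi = x$gender$phi$r, gender_phi_p = x$gender$phi$p_value,
    ben_group_r = x$ben_group_correlation$r,
    ben_group_r_p = x$ben_group_correlation$p_value,
    n_excluded = length(x$excluded))
}
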