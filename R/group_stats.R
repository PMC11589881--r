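#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The U statistic is computed from
#' midranks. The null distribution is exact (via the Wilcoxon rank-sum
#' distribution) when `min(n) <= exact_max_n` and there are no ties;
#' otherwise the tie-corrected normal approximation is used (without
#' continuity correction, so that identical samples give p = 1 exactly).
#'
#' @param x,y Numeric samples (non-empty).
#' @param group_a_label,group_b_label Labels carried into the result.
#' @param exact_max_n Largest `min(n)` for which the exact null is used
#'   (default 8).
#' @return An object of class `group_comparison`; see [tidy.group_comparison()].
#' @examples
#' gc <- mann_whitney_two_sided(c(1, 2), c(3, 4))
#' gc$p_two_sided # exact: 1/3
#' @export
mann_whitney_two_sided <- function(x, y, group_a_label = "a",
                                   group_b_label = "b", exact_max_n = 8L) {
  if (length(x) == 0 || length(y) == 0) {
    stop_input("both samples must be non-empty (%s: n=%d, %s: n=%d)",
               group_a_label, length(x), group_b_label, length(y))
  }
  if (any(!is.finite(c(x, y)))) stop_input("samples must be finite")
  n_a <- length(x)
  n_b <- length(y)
  r <- rank(c(x, y)) # midranks
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(n_a, n_b) <= exact_max_n && !ties) {
    p <- min(1, 2 * min(pwilcox(u, n_a, n_b),
                        1 - pwilcox(u - 1, n_a, n_b)))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(c(x, y))
    n <- n_a + n_b
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1 # all observations tied
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx_tie_corrected"
  }
  med_a <- median(x)
  med_b <- median(y)
  structure(
    list(group_a_label = group_a_label, group_b_label = group_b_label,
         n_a = n_a, n_b = n_b, U_statistic = u, p_two_sided = p,
         median_a = med_a, median_b = med_b,
         direction = if (med_a > med_b) group_a_label
                     else if (med_b > med_a) group_b_label
                     else "tie",
         method = method),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (n=%d, median %.3g) vs %s (n=%d, median %.3g)\n  U = %g, two-sided p = %.4g (%s); larger: %s\n",
    x$group_a_label, x$n_a, x$median_a, x$group_b_label, x$n_b, x$median_b,
    x$U_statistic, x$p_two_sided, x$method, x$direction))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the test's fields (broom convention:
#'   `statistic`, `p.value`, plus group sizes, medians, `direction`,
#'   `method`).
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(group_a = x$group_a_label, group_b = x$group_b_label,
         n_a = x$n_a, n_b = x$n_b,
         median_a = x$median_a, median_b = x$median_b,
         statistic = x$U_statistic, p.value = x$p_two_sided,
         direction = x$direction, method = x$method)
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(statistic = x$U_statistic, p.value = x$p_two_sided,
         n = x$n_a + x$n_b, method = x$method)
}

#' Compare C-tail metrics between orientation classes
#'
#' Restricts a cohort of tail profiles to posttranslationally inserting
#' proteins (tail shorter than the cotranslational threshold), splits it by
#' C-terminal orientation and compares a chosen metric between `C_cyt` and
#' `C_ext` with the two-sided Mann-Whitney test.
#'
#' @param profiles Tibble from [profile_cohort()].
#' @param metric Column to compare: `"tail_len"`, `"tail_dg"`,
#'   `"penultimate_loop_dg"` or `"n_tail_dg"`.
#' @param posttranslational_only Restrict to `route == "posttranslational"`
#'   (default `TRUE`, matching the cohort definition used for C-tail
#'   comparisons).
#' @return A `group_comparison` (group a = `C_cyt`, group b = `C_ext`).
#' @export
compare_by_orientation <- function(profiles,
                                   metric = c("tail_dg", "tail_len",
                                              "penultimate_loop_dg",
                                              "n_tail_dg"),
                                   posttranslational_only = TRUE) {
  metric <- match.arg(metric)
  dat <- as_tibble(profiles)
  if (posttranslational_only) {
    dat <- filter(dat, .data$route == "posttranslational")
  }
  x <- dat[[metric]][dat$orientation == "C_cyt"]
  y <- dat[[metric]][dat$orientation == "C_ext"]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  for (lab in c("C_cyt", "C_ext")) {
    nn <- if (lab == "C_cyt") length(x) else length(y)
    if (nn == 0) {
      stop_input("orientation group '%s' is empty for metric '%s'%s", lab,
                 metric,
                 if (posttranslational_only) " among posttranslational proteins"
                 else "")
    }
  }
  mann_whitney_two_sided(x, y, group_a_label = "C_cyt",
                         group_b_label = "C_ext")
}
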