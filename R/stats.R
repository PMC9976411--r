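#' Mean, sample SD and n of a set of measurements
#'
#' Matches the mean ± SD (n) reporting convention of the accuracy
#' experiments. The sample standard deviation uses the n - 1
#' denominator; for a single value the SD is 0 by convention.
#'
#' @param values numeric vector, length >= 1.
#' @return A list of class `summary_stats` with `mean`, `sd`, `n`.
#' @examples
#' summarize_values(c(2, 4, 4, 4, 5, 5, 7, 9))
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("need at least one value", call. = FALSE)
  s <- if (length(values) == 1L) 0 else stats::sd(values)
  structure(list(mean = mean(values), sd = s, n = length(values)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, digits = 2, ...) {
  cat(sprintf("%.*f +/- %.*f (n = %d)\n", digits, x$mean, digits, x$sd, x$n))
  invisible(x)
}

.comparison_result <- function(test_name, statistic, p_value, df = NA_real_,
                               gate = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), df = unname(df), gate = gate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, digits = 4, ...) {
  df_txt <- if (all(is.na(x$df))) "" else
    sprintf(", df = %s", paste(round(x$df, 2), collapse = ", "))
  cat(sprintf("%s: statistic = %.*f%s, p = %.4g\n", x$test_name, digits,
              x$statistic, df_txt, x$p_value))
  if (!is.null(x$gate)) {
    cat(sprintf("  normality gate (Shapiro-Wilk, alpha = %g): p_a = %.3g, p_b = %.3g -> %s\n",
                x$gate$alpha, x$gate$shapiro_p_a, x$gate$shapiro_p_b,
                if (x$gate$normal) "parametric" else "non-parametric"))
  }
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' The analysis plan of the phantom experiments: a Shapiro-Wilk test is
#' first applied to each group; if neither shows a significant departure
#' from normality (both p > `alpha`), a two-sided Student's t-test is
#' used, otherwise a Mann-Whitney U test.
#'
#' @param a,b numeric vectors, each of length >= 3 and not constant.
#' @param alpha significance level of the normality gate; default 0.05.
#' @return A `comparison_result` with `test_name` `"STUDENT_T"` or
#'   `"MANN_WHITNEY"` and the gate decision attached.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate (constant) group", call. = FALSE)
  }
  sa <- stats::shapiro.test(a)$p.value
  sb <- stats::shapiro.test(b)$p.value
  normal <- sa > alpha && sb > alpha
  gate <- list(alpha = alpha, shapiro_p_a = sa, shapiro_p_b = sb,
               normal = normal)
  if (normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    .comparison_result("STUDENT_T", tt$statistic, tt$p.value,
                       tt$parameter, gate)
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    .comparison_result("MANN_WHITNEY", wt$statistic, wt$p.value, gate = gate)
  }
}

#' Two-sample t-test from printed summary statistics
#'
#' Recomputes a two-sided two-sample t-test from group means, SDs and
#' sizes, enabling verification of comparisons reported only as
#' summaries. The pooled (classical Student) variance is the default;
#' `pooled = FALSE` gives the Welch variant with Satterthwaite degrees
#' of freedom.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries
#'   (`n_a, n_b >= 2`; SDs >= 0).
#' @param pooled use the pooled-variance Student statistic (default) or
#'   Welch.
#' @return A `comparison_result` (`"STUDENT_T"` or `"WELCH_T"`). When
#'   both variances are zero and the means are equal, p = 1 by
#'   convention.
#' @examples
#' t_test_from_summary(4.14, 1.08, 12, 4.20, 1.08, 12)   # p ~0.90
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                pooled = TRUE) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) {
      return(.comparison_result(if (pooled) "STUDENT_T" else "WELCH_T",
                                0, 1, n_a + n_b - 2))
    }
    stop("zero variance in both groups with unequal means: t undefined",
         call. = FALSE)
  }
  if (pooled) {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    t <- (mean_a - mean_b) / se
    .comparison_result("STUDENT_T", t, 2 * stats::pt(-abs(t), df), df)
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    t <- (mean_a - mean_b) / se
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    .comparison_result("WELCH_T", t, 2 * stats::pt(-abs(t), df), df)
  }
}

#' One-way ANOVA across groups
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return A `comparison_result` with `test_name` `"ANOVA_ONEWAY"`, the
#'   F statistic and `df = c(k - 1, N - k)`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  values <- unlist(groups)
  if (stats::sd(values) == 0) stop("degenerate groups: all values equal",
                                   call. = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  .comparison_result("ANOVA_ONEWAY", tab[["F value"]][1],
                     tab[["Pr(>F)"]][1], df = tab[["Df"]])
}

#' Shapiro-Wilk normality test wrapper
#'
#' @param values numeric vector (3 <= n <= 5000).
#' @return A `comparison_result` with `test_name` `"SHAPIRO_WILK"`.
#' @export
shapiro_wilk <- function(values) {
  s <- stats::shapiro.test(as.numeric(values))
  .comparison_result("SHAPIRO_WILK", s$statistic, s$p.value)
}
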