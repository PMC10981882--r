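#' Median, quartiles and percentage within range
#'
#' Quartiles use the weighted-average empirical quantile at plotting position
#' \code{p*(n+1)} (R's type 6), the default of the statistics package the
#' original tables were produced with, so printed (Q1, Q3) pairs are
#' reproducible; the more common R default (type 7) is selectable.
#' \code{pct_within} counts values strictly below the threshold; the printed
#' integer percentage rounds half up (33/40 -> 83).
#'
#' @param values Numeric vector of per-trial distances (mm).
#' @param threshold_mm Range threshold (default 5.00, strict \code{<}).
#' @param quantile_rule \code{"pn1"} (type 6, default) or \code{"linear"}
#'   (type 7).
#' @return List: \code{n}, \code{median_mm}, \code{q1_mm}, \code{q3_mm},
#'   \code{iqr_mm}, \code{n_within}, \code{pct_within} (exact),
#'   \code{pct_within_int} (rounded).
#' @export
summarize_metric <- function(values, threshold_mm = 5.00,
                             quantile_rule = c("pn1", "linear")) {
  quantile_rule <- match.arg(quantile_rule)
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    .np_stopf("values must be a nonempty finite numeric vector")
  type <- if (quantile_rule == "pn1") 6L else 7L
  qs <- unname(quantile(values, c(0.25, 0.5, 0.75), type = type))
  n_within <- sum(values < threshold_mm)
  pct <- 100 * n_within / length(values)
  list(n = length(values), median_mm = qs[2], q1_mm = qs[1], q3_mm = qs[3],
       iqr_mm = qs[3] - qs[1], n_within = n_within, pct_within = pct,
       pct_within_int = round_half_up(pct))
}

#' Shapiro-Wilk normality test
#'
#' Standard W statistic with Royston's p-value approximation, with the
#' contract's error handling: fewer than 3 values or a constant sample is
#' not testable.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return List with \code{W} and \code{p}.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 5000L)
    .np_stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  if (diff(range(values)) == 0)
    .np_stopf("Shapiro-Wilk not testable: all values identical")
  res <- shapiro.test(values)
  list(W = unname(res$statistic), p = unname(res$p.value))
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether the distribution is symmetric about \code{mu_mm} (the 5 mm
#' target by default). Zero differences are dropped (classic handling);
#' mid-ranks are used for ties in |d|. The two-sided p-value is exact (full
#' signed-rank distribution) when n <= 15 after zero removal and there are no
#' ties; otherwise a normal approximation with tie correction and continuity
#' correction is used, matching mainstream statistics packages.
#'
#' @param values Numeric vector.
#' @param mu_mm Hypothesized median (default 5.00).
#' @return List: \code{statistic} (V, sum of positive ranks), \code{p}
#'   (two-sided), \code{method} ("exact" or "normal"), \code{n} (nonzero
#'   differences).
#' @export
one_sample_wilcoxon <- function(values, mu_mm = 5.00) {
  d <- as.numeric(values) - mu_mm
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    .np_warnf("all differences from mu are zero; p = 1 by convention")
    return(list(statistic = 0, p = 1, method = "degenerate", n = 0L))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 15L && !ties) {
    p_le <- psignrank(V, n)
    p_ge <- 1 - psignrank(V - 1, n)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = V, p = p, method = "exact", n = n))
  }
  mu_v <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) {
    .np_warnf("degenerate signed-rank variance; p = 1 by convention")
    return(list(statistic = V, p = 1, method = "degenerate", n = n))
  }
  z <- (V - mu_v - 0.5 * sign(V - mu_v)) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = V, p = p, method = "normal", n = n)
}

#' One-sample t-test against the range threshold
#'
#' @param values Numeric vector (n >= 2, nonzero variance).
#' @param mu_mm Hypothesized mean (default 5.00).
#' @return List: \code{statistic} (t), \code{df}, \code{p} (two-sided).
#' @export
one_sample_t <- function(values, mu_mm = 5.00) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) .np_stopf("one-sample t-test requires n >= 2")
  s <- sd(values)
  if (s == 0) .np_stopf("one-sample t-test degenerate: zero variance")
  tstat <- (mean(values) - mu_mm) / (s / sqrt(n))
  list(statistic = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), n - 1))
}

#' Normality-gated test choice
#'
#' Wilcoxon signed-rank if the Shapiro-Wilk p-value is below \code{alpha}
#' (strict \code{<}), one-sample t otherwise; \code{NA} (untestable
#' normality, e.g. a constant sample) falls back to Wilcoxon.
#'
#' @param shapiro_p Shapiro-Wilk p-value in (0, 1], or NA.
#' @param alpha Significance level (default 0.05).
#' @return \code{"wilcoxon"} or \code{"t"}.
#' @export
choose_test <- function(shapiro_p, alpha = 0.05) {
  if (is.na(shapiro_p) || shapiro_p < alpha) "wilcoxon" else "t"
}

#' Scatter coordinates of placement accuracy
#'
#' One (x, y) = (signed lateral, signed depth) pair per trial, the
#' coordinates of the accuracy scatter with the nerve midline at the origin:
#' positive x = lateral to the subject's right, negative y = deeper than the
#' target, effective range = the 5 mm circle.
#'
#' @param results Data frame from \code{\link{assess_cohort}} (or a list of
#'   \code{accuracy_result}s).
#' @return Data frame with \code{trial_id}, \code{lateral_signed_mm},
#'   \code{depth_signed_mm}.
#' @export
scatter_coordinates <- function(results) {
  if (inherits(results, "accuracy_result")) results <- list(results)
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  if (is.null(results) || nrow(results) < 1L)
    .np_stopf("no results to plot")
  data.frame(trial_id = results$trial_id,
             lateral_signed_mm = results$lateral_signed_mm,
             depth_signed_mm = results$depth_signed_mm,
             stringsAsFactors = FALSE)
}

#' Cohort summary table
#'
#' Per metric (euclidean, lateral, depth): median, Q1/Q3/IQR under the
#' configured quantile rule, percentage of trials within the threshold,
#' Shapiro-Wilk normality p, and the normality-gated one-sample test against
#' the threshold (t if normal, Wilcoxon signed-rank otherwise).
#'
#' @param results Data frame from \code{\link{assess_cohort}} (columns
#'   \code{euclidean_mm}, \code{lateral_mm}, \code{depth_mm}), or a list of
#'   \code{accuracy_result}s.
#' @param threshold_mm Range threshold / hypothesized value (default 5.00).
#' @param alpha Normality-gate level (default 0.05).
#' @param quantile_rule See \code{\link{summarize_metric}}.
#' @return Data frame of class \code{cohort_summary}, one row per metric:
#'   \code{metric}, \code{n}, \code{median_mm}, \code{q1_mm}, \code{q3_mm},
#'   \code{iqr_mm}, \code{pct_within}, \code{pct_within_int},
#'   \code{shapiro_W}, \code{shapiro_p}, \code{test_used}, \code{statistic},
#'   \code{test_p}.
#' @export
cohort_table <- function(results, threshold_mm = 5.00, alpha = 0.05,
                         quantile_rule = c("pn1", "linear")) {
  quantile_rule <- match.arg(quantile_rule)
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  metrics <- c(euclidean = "euclidean_mm", lateral = "lateral_mm",
               depth = "depth_mm")
  rows <- lapply(names(metrics), function(m) {
    v <- results[[metrics[[m]]]]
    sm <- summarize_metric(v, threshold_mm, quantile_rule)
    sw <- tryCatch(shapiro_wilk(v), error = function(e) {
      .np_warnf("%s: %s", m, conditionMessage(e))
      list(W = NA_real_, p = NA_real_)
    })
    test <- choose_test(sw$p, alpha)
    tt <- if (test == "t") {
      r <- one_sample_t(v, threshold_mm)
      list(stat = r$statistic, p = r$p, name = "one-sample t")
    } else {
      r <- one_sample_wilcoxon(v, threshold_mm)
      list(stat = r$statistic, p = r$p, name = "one-sample Wilcoxon signed-rank")
    }
    data.frame(metric = m, n = sm$n, median_mm = sm$median_mm,
               q1_mm = sm$q1_mm, q3_mm = sm$q3_mm, iqr_mm = sm$iqr_mm,
               pct_within = sm$pct_within, pct_within_int = sm$pct_within_int,
               shapiro_W = sw$W, shapiro_p = sw$p, test_used = tt$name,
               statistic = tt$stat, test_p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", class(out))
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort accuracy summary (n = %d trials, threshold %s mm)\n\n",
              x$n[1], format(5.00, nsmall = 2)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-9s median %.2f mm, IQR %.2f (%.2f - %.2f), %d%% < 5.00 mm, %s p = %s\n",
                x$metric[i], x$median_mm[i], x$iqr_mm[i], x$q1_mm[i],
                x$q3_mm[i], x$pct_within_int[i], x$test_used[i],
                format.pval(x$test_p[i], digits = 3, eps = 0.001)))
  }
  invisible(x)
}
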