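#' Paired measurements from two methods
#'
#' Container for method-comparison statistics: equal-length vectors of the
#' same quantity (mm) measured by two methods, e.g. manual calipers at
#' landmark stations versus the continuous profile read at the same
#' stations.
#' @param method_a,method_b numeric vectors, equal length >= 3, finite.
#' @param labels optional station/visit identifiers.
#' @return a `paired_measures` tibble.
#' @export
paired_measures <- function(method_a, method_b, labels = NULL) {
  if (length(method_a) != length(method_b))
    stop("method_a and method_b must have equal length")
  if (length(method_a) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(method_a)) || !all(is.finite(method_b)))
    stop("measurements must be finite")
  out <- tibble::tibble(method_a = as.numeric(method_a),
                        method_b = as.numeric(method_b),
                        label = labels %||% as.character(seq_along(method_a)))
  class(out) <- c("paired_measures", class(out))
  out
}

as_paired <- function(pm) {
  if (inherits(pm, "paired_measures")) return(pm)
  if (is.list(pm) && !is.null(pm$method_a))
    return(paired_measures(pm$method_a, pm$method_b))
  stop("expected a paired_measures object")
}

#' Ordinary least-squares comparison of two methods
#'
#' Regression of method B on method A with the Pearson correlation and its
#' t-test p-value (n - 2 degrees of freedom).
#' @param pm a [paired_measures()].
#' @return list: slope, intercept, r_value, p_value, n.
#' @export
least_squares <- function(pm) {
  pm <- as_paired(pm)
  if (sd(pm$method_a) == 0) stop("method_a is constant; slope undefined")
  fit <- stats::lm(method_b ~ method_a, data = pm)
  r <- cor(pm$method_a, pm$method_b)
  n <- nrow(pm)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_value = r, p_value = p, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences d = a - b: bias is mean(d), the reproducibility coefficient
#' is 1.96 times the sample SD of d, and the limits of agreement are
#' bias +/- 1.96 SD.
#' @param pm a [paired_measures()].
#' @return a `bland_altman` list: bias, loa_low, loa_high,
#'   reproducibility_coefficient, sd_diff, mean_values, differences, n.
#' @export
bland_altman <- function(pm) {
  pm <- as_paired(pm)
  d <- pm$method_a - pm$method_b
  s <- sd(d)
  structure(list(bias = mean(d),
                 loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s,
                 reproducibility_coefficient = 1.96 * s,
                 sd_diff = s,
                 mean_values = (pm$method_a + pm$method_b) / 2,
                 differences = d,
                 n = nrow(pm)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f mm, limits [%.3f, %.3f], coefficient %.3f mm (n = %d)\n",
    x$bias, x$loa_low, x$loa_high, x$reproducibility_coefficient, x$n))
  invisible(x)
}

#' Passing-Bablok regression
#'
#' Distribution-free method-comparison regression.  The slope is the
#' shifted median of all pairwise slopes S_ij = (b_j - b_i)/(a_j - a_i),
#' i < j: slopes equal to -1 are excluded, undefined slopes (tied a with
#' untied b count as +/-infinity) are kept at the extremes, and the median
#' is offset by K, the number of slopes below -1, so the estimate is
#' invariant to swapping the methods.  Confidence bounds use the
#' rank-based normal approximation; the intercept is median(b - slope a)
#' with bounds from the slope bounds.
#' @param pm a [paired_measures()].
#' @param alpha two-sided confidence level complement (default 0.05).
#' @return a `passing_bablok` list: slope, intercept, slope_lower,
#'   slope_upper, intercept_lower, intercept_upper, n_slopes, n.
#' @export
passing_bablok <- function(pm, alpha = 0.05) {
  pm <- as_paired(pm)
  a <- pm$method_a
  b <- pm$method_b
  if (sd(a) == 0) stop("method_a is constant")
  n <- length(a)
  ij <- utils::combn(n, 2)
  da <- a[ij[2, ]] - a[ij[1, ]]
  db <- b[ij[2, ]] - b[ij[1, ]]
  Sij <- ifelse(da == 0 & db == 0, NA_real_,
                ifelse(da == 0, sign(db) * Inf, db / da))
  Sij <- Sij[!is.na(Sij) & Sij != -1]
  Sij <- sort(Sij)
  N <- length(Sij)
  if (N == 0L) stop("no valid pairwise slopes")
  K <- sum(Sij < -1)
  shifted_median <- function(offset) {
    # median of the sorted slopes shifted by offset ranks
    if (N %% 2 == 1) Sij[pmin(pmax((N + 1) / 2 + offset, 1), N)]
    else mean(Sij[pmin(pmax(c(N / 2, N / 2 + 1) + offset, 1), N)])
  }
  slope <- shifted_median(K)
  w <- qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - w) / 2)
  M2 <- N - M1 + 1
  slope_lower <- Sij[pmin(pmax(M1 + K, 1), N)]
  slope_upper <- Sij[pmin(pmax(M2 + K, 1), N)]
  intercept <- median(b - slope * a)
  intercept_lower <- median(b - slope_upper * a)
  intercept_upper <- median(b - slope_lower * a)
  structure(list(slope = slope, intercept = intercept,
                 slope_lower = slope_lower, slope_upper = slope_upper,
                 intercept_lower = intercept_lower,
                 intercept_upper = intercept_upper,
                 n_slopes = N, n = n, method_a = a, method_b = b),
            class = "passing_bablok")
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat(sprintf(
    "Passing-Bablok: slope %.4g (%.4g to %.4g), intercept %.4g (%.4g to %.4g)\n",
    x$slope, x$slope_lower, x$slope_upper,
    x$intercept, x$intercept_lower, x$intercept_upper))
  invisible(x)
}

#' Variance-ratio (F) concordance of visit-to-visit changes
#'
#' Compares the variances of the change values produced by two methods:
#' F is the larger sample variance over the smaller, against the
#' upper-tail critical value with matching degrees of freedom.  Because
#' the larger variance is always placed in the numerator, the critical
#' value is taken at 1 - alpha/2 so the test has overall size `alpha`.
#' Concordant (equivalent variances) when F < F_crit.
#' @param changes_a,changes_b numeric vectors of change values (mm).
#' @param alpha significance level (default 0.05).
#' @return list: f_value, f_crit, concordant, df1, df2, p_value.
#' @export
f_concordance <- function(changes_a, changes_b, alpha = 0.05) {
  na <- length(changes_a)
  nb <- length(changes_b)
  if (na < 2L || nb < 2L) stop("need at least 2 change values per method")
  va <- var(changes_a)
  vb <- var(changes_b)
  if (va == 0 && vb == 0) {
    return(list(f_value = 1, f_crit = qf(1 - alpha / 2, na - 1, nb - 1),
                concordant = TRUE, df1 = na - 1, df2 = nb - 1,
                p_value = 1))
  }
  if (va >= vb) {
    f <- va / max(vb, .Machine$double.xmin)
    df1 <- na - 1; df2 <- nb - 1
  } else {
    f <- vb / max(va, .Machine$double.xmin)
    df1 <- nb - 1; df2 <- na - 1
  }
  fc <- qf(1 - alpha / 2, df1, df2)
  list(f_value = f, f_crit = fc, concordant = f < fc,
       df1 = df1, df2 = df2,
       p_value = min(1, 2 * pf(f, df1, df2, lower.tail = FALSE)))
}

#' Full method-agreement report
#'
#' Bundles the least-squares correlation, Bland-Altman agreement and
#' Passing-Bablok regression of one paired comparison.
#' @param pm a [paired_measures()].
#' @param alpha confidence level complement (default 0.05).
#' @return an `agreement_report`.
#' @export
agreement_report <- function(pm, alpha = 0.05) {
  pm <- as_paired(pm)
  structure(list(least_squares = least_squares(pm),
                 bland_altman = bland_altman(pm),
                 passing_bablok = passing_bablok(pm, alpha),
                 pm = pm, alpha = alpha),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  ls <- x$least_squares
  cat(sprintf("Agreement report (n = %d pairs)\n", ls$n))
  cat(sprintf("  least squares: slope %.3f, intercept %.3f, R = %.3f (p = %.3g)\n",
              ls$slope, ls$intercept, ls$r_value, ls$p_value))
  print(x$bland_altman)
  print(x$passing_bablok)
  invisible(x)
}

#' Tidy an agreement report
#' @param x an `agreement_report`.
#' @param ... unused.
#' @return one row per statistic: term, estimate, conf.low, conf.high.
#' @export
tidy.agreement_report <- function(x, ...) {
  pb <- x$passing_bablok
  ba <- x$bland_altman
  ls <- x$least_squares
  tibble::tibble(
    term = c("ls_slope", "ls_intercept", "r_value", "bias",
             "reproducibility_coefficient", "pb_slope", "pb_intercept"),
    estimate = c(ls$slope, ls$intercept, ls$r_value, ba$bias,
                 ba$reproducibility_coefficient, pb$slope, pb$intercept),
    conf.low = c(NA, NA, NA, ba$loa_low, NA, pb$slope_lower,
                 pb$intercept_lower),
    conf.high = c(NA, NA, NA, ba$loa_high, NA, pb$slope_upper,
                  pb$intercept_upper))
}

#' One-line summary of an agreement report
#' @param x an `agreement_report`.
#' @param ... unused.
#' @return a one-row tibble: n, r_value, p_value, bias, loa_low, loa_high.
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n = x$least_squares$n,
                 r_value = x$least_squares$r_value,
                 p_value = x$least_squares$p_value,
                 bias = x$bland_altman$bias,
                 loa_low = x$bland_altman$loa_low,
                 loa_high = x$bland_altman$loa_high)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")
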