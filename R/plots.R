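#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_rect
#'   geom_hline geom_abline labs theme_minimal annotate
NULL

excluded_spans <- function(profile) {
  s <- profile$s_mm
  ex <- profile$excluded
  if (!any(ex)) return(NULL)
  half <- (attr(profile, "spacing") %||% 2) / 2
  runs <- rle(ex)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  data.frame(xmin = s[starts[runs$values]] - half,
             xmax = s[ends[runs$values]] + half)
}

#' Plot a continuous profile (diameter or area against arc length)
#'
#' One-dimensional line plot of the continuous measurement, with excluded
#' spans (branches, open contours) shaded.
#' @param object a `profile_table`.
#' @param what `"diameter"` or `"area"`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot profile_table
#' @export
autoplot.profile_table <- function(object, what = c("diameter", "area"),
                                   ...) {
  what <- match.arg(what)
  ycol <- if (what == "diameter") "max_diameter_mm" else "area_mm2"
  ylab <- if (what == "diameter") "maximum diameter (mm)" else
    expression(area ~ (mm^2))
  p <- ggplot(object, aes(x = .data$s_mm, y = .data[[ycol]]))
  spans <- excluded_spans(object)
  if (!is.null(spans))
    p <- p + geom_rect(data = spans,
                       aes(xmin = .data$xmin, xmax = .data$xmax),
                       ymin = -Inf, ymax = Inf, alpha = 0.35,
                       fill = "grey20", inherit.aes = FALSE)
  p + geom_line(na.rm = TRUE) +
    labs(x = "arc length from inlet (mm)", y = ylab) +
    theme_minimal()
}

#' Bland-Altman plot
#' @param object a `bland_altman` result.
#' @param ... unused.
#' @return a ggplot: differences against pair means, with bias and limits.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- data.frame(m = object$mean_values, d = object$differences)
  ggplot(df, aes(x = .data$m, y = .data$d)) +
    geom_point(shape = 18, size = 2) +
    geom_hline(yintercept = object$bias) +
    geom_hline(yintercept = c(object$loa_low, object$loa_high),
               linetype = "dashed") +
    labs(x = "mean of methods (mm)", y = "difference a - b (mm)") +
    theme_minimal()
}

#' Passing-Bablok regression plot
#' @param object a `passing_bablok` result.
#' @param ... unused.
#' @return a ggplot: scatter, fitted line, bound lines and identity.
#' @method autoplot passing_bablok
#' @export
autoplot.passing_bablok <- function(object, ...) {
  df <- data.frame(a = object$method_a, b = object$method_b)
  ggplot(df, aes(x = .data$a, y = .data$b)) +
    geom_point(shape = 18, size = 2) +
    geom_abline(slope = object$slope, intercept = object$intercept) +
    geom_abline(slope = object$slope_lower,
                intercept = object$intercept_upper, linetype = "dashed") +
    geom_abline(slope = object$slope_upper,
                intercept = object$intercept_lower, linetype = "dashed") +
    geom_abline(slope = 1, intercept = 0, colour = "darkgreen",
                linetype = "dotted") +
    labs(x = "method A (mm)", y = "method B (mm)") +
    theme_minimal()
}

#' Plot a distance field or change map as an unrolled scatter
#'
#' The 3D colour map lives in the PLY export; this plot shows the same
#' field against arc length for a quick look.
#' @param object a `distance_field` or `change_map`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot distance_field
#' @export
autoplot.distance_field <- function(object, ...) {
  ggplot(object[!is.na(object$s_mm), ],
         aes(x = .data$s_mm, y = .data$distance_mm)) +
    geom_point(alpha = 0.2, size = 0.4) +
    labs(x = "arc length of nearest centerline point (mm)",
         y = "Euclidean distance (mm)") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
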