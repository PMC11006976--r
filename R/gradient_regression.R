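#' Classify p-values into display significance tiers
#'
#' @param p Numeric p-values.
#' @param tiers Thresholds, strongest last.
#' @param labels Labels matching `tiers`.
#' @return Character vector (`"ns"` where no tier is met).
#' @export
significance_class <- function(p, tiers = c(0.05, 0.01, 0.001),
                               labels = c("p<0.05", "p<0.01", "p<0.001")) {
  stopifnot(length(tiers) == length(labels))
  out <- rep("ns", length(p))
  for (k in seq_along(tiers)) out[!is.na(p) & p < tiers[k]] <- labels[k]
  out
}

#' Simple linear regression of a trait on a geographic gradient
#'
#' Ordinary least squares of one trait on one gradient (latitude, longitude
#' or altitude), returning slope, intercept, R-squared, the slope t-test p
#' value and a significance class at the 0.05/0.01/0.001 tiers. A constant
#' response is treated as a degenerate flat fit (slope 0, R-squared 0, p 1)
#' rather than an error, so degenerate synthetic traits do not halt a panel.
#'
#' @param y Trait values (n >= 3).
#' @param x Gradient values, not constant.
#' @return List of class `regression_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, `significance_class`.
#' @export
fit_simple_regression <- function(y, x) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3L) stop("fit_simple_regression: need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("fit_simple_regression: x is constant", call. = FALSE)
  if (stats::sd(y) == 0) {
    fit <- list(slope = 0, intercept = y[1L], r_squared = 0, p_value = 1,
                n = n, significance_class = "ns")
    class(fit) <- "regression_fit"
    return(fit)
  }
  m <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(m)) # a perfect fit is legitimate here
  fit <- list(
    slope = unname(stats::coef(m)[2L]),
    intercept = unname(stats::coef(m)[1L]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2L, 4L],
    n = n,
    significance_class = significance_class(sm$coefficients[2L, 4L])
  )
  class(fit) <- "regression_fit"
  fit
}

#' Trait-by-gradient regression panel
#'
#' Fits one simple regression per trait x gradient cell, with traits first
#' aggregated to population means (one point per population, the default) or
#' left at replicate level.
#'
#' @param traits Trait table (`population_id`, `replicate`, trait columns).
#' @param sites Site table with `population_id`, `latitude`, `longitude`,
#'   `altitude` (additional columns ignored).
#' @param level `"population_mean"` (default) or `"replicate"`.
#' @return Long data frame: trait, gradient, slope, intercept, r_squared,
#'   p_value, n, significance_class.
#' @export
gradient_panel <- function(traits, sites, level = c("population_mean", "replicate")) {
  level <- match.arg(level)
  unmatched <- setdiff(unique(traits$population_id), sites$population_id)
  if (length(unmatched)) {
    stop("gradient_panel: population id(s) absent from sites: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  trait_cols <- setdiff(names(traits), c("population_id", "replicate"))
  if (level == "population_mean") {
    traits <- stats::aggregate(traits[trait_cols],
                               by = list(population_id = traits$population_id), FUN = mean)
  }
  merged <- merge(traits, sites[c("population_id", "latitude", "longitude", "altitude")],
                  by = "population_id")
  grads <- c("latitude", "longitude", "altitude")
  rows <- list()
  for (tc in trait_cols) {
    for (g in grads) {
      f <- fit_simple_regression(merged[[tc]], merged[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tc, gradient = g, slope = f$slope, intercept = f$intercept,
        r_squared = f$r_squared, p_value = f$p_value, n = f$n,
        significance_class = f$significance_class, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
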