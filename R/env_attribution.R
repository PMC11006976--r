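#' Standardize a numeric vector to z-scores
#'
#' Centers to mean 0 and scales to sample standard deviation 1, so regression
#' coefficients on standardized variables are directly comparable across
#' predictors measured in different units.
#'
#' @param values Numeric vector, >= 2 values, not constant.
#' @return z-scored vector.
#' @export
standardize <- function(values) {
  if (length(values) < 2L) stop("standardize: need >= 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("standardize: input is constant", call. = FALSE)
  (values - mean(values)) / s
}

#' Multiple regression of a trait on climate and soil predictors
#'
#' Ordinary least squares of one trait on the environmental predictor set
#' (by default MAT, MAP, SOC, AN, AP and pH entered simultaneously).
#' Coefficients are reported on standardized variables (both response and
#' predictors z-scored) so they are comparable as in a heat-map display;
#' `standardized = FALSE` fits the raw-scale model instead. Per-coefficient
#' t-test p values carry a marginal `p<0.1` tier in addition to the usual
#' 0.05/0.01/0.001 tiers, and the model R-squared gives the proportion of
#' trait variation explained by the environment.
#'
#' @param y Trait values.
#' @param X Data frame or matrix of predictors (columns named).
#' @param standardized Report coefficients on z-scored variables (default).
#' @return List of class `multi_regression_fit`: `coefficients` (named, no
#'   intercept), `p_values`, `model_r_squared`, `significance_classes`, `n`,
#'   `standardized`.
#' @export
fit_multiple_regression <- function(y, X, standardized = TRUE) {
  X <- as.data.frame(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) {
    stop("fit_multiple_regression: need more observations than parameters (n > p + 1)",
         call. = FALSE)
  }
  Xm <- as.matrix(X)
  if (qr(cbind(1, Xm))$rank < p + 1L) {
    # name the columns involved in the dependency
    r <- qr(cbind(1, Xm))
    dep <- colnames(Xm)[setdiff(seq_len(p), r$pivot[seq_len(r$rank)] - 1L)]
    stop("fit_multiple_regression: predictor matrix is rank deficient (collinear columns: ",
         paste(dep, collapse = ", "), ")", call. = FALSE)
  }
  if (standardized) {
    y <- standardize(y)
    X[] <- lapply(X, standardize)
  }
  m <- stats::lm(y ~ ., data = X)
  sm <- suppressWarnings(summary(m)) # exact linear combinations are legitimate
  co <- sm$coefficients[-1L, , drop = FALSE]
  pv <- co[, 4L]
  fit <- list(
    coefficients = co[, 1L],
    p_values = pv,
    model_r_squared = sm$r.squared,
    significance_classes = significance_class(
      pv, tiers = c(0.1, 0.05, 0.01, 0.001),
      labels = c("p<0.1", "p<0.05", "p<0.01", "p<0.001")),
    n = n,
    standardized = standardized
  )
  class(fit) <- "multi_regression_fit"
  fit
}

#' Environmental attribution panel over all traits
#'
#' Fits [fit_multiple_regression()] of every trait (population means) on the
#' six environmental predictors and returns a long table of standardized
#' coefficients, p values, significance classes and per-trait model R-squared.
#'
#' @param traits Trait table (`population_id`, `replicate`, trait columns).
#' @param sites Site table containing the predictor columns.
#' @param predictors Predictor column names (default MAT, MAP, SOC, AN, AP, pH).
#' @param standardized Passed to [fit_multiple_regression()].
#' @return Long data frame: trait, predictor, beta, p_value,
#'   significance_class, model_r_squared.
#' @export
env_attribution_panel <- function(traits, sites,
                                  predictors = c("MAT", "MAP", "SOC", "AN", "AP", "pH"),
                                  standardized = TRUE) {
  miss <- setdiff(predictors, names(sites))
  if (length(miss)) {
    stop("env_attribution_panel: sites is missing predictor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  trait_cols <- setdiff(names(traits), c("population_id", "replicate"))
  pm <- stats::aggregate(traits[trait_cols],
                         by = list(population_id = traits$population_id), FUN = mean)
  merged <- merge(pm, sites[c("population_id", predictors)], by = "population_id")
  rows <- list()
  for (tc in trait_cols) {
    f <- fit_multiple_regression(merged[[tc]], merged[predictors], standardized = standardized)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tc, predictor = predictors, beta = unname(f$coefficients),
      p_value = unname(f$p_values),
      significance_class = unname(f$significance_classes),
      model_r_squared = f$model_r_squared, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
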