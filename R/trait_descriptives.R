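#' Variation summary for one trait across populations
#'
#' Computes the descriptive statistics used to characterise among-population
#' trait variability: minimum, maximum, Max/Min ratio, mean and the
#' coefficient of variation (CV, 100 x sample standard deviation / mean,
#' n - 1 denominator).
#'
#' @param values Positive trait values (>= 2 of them).
#' @return Named list: `minimum`, `maximum`, `max_min_ratio`, `mean`,
#'   `cv_percent`.
#' @export
#' @examples
#' summarize_trait(c(1, 2, 3)) # mean 2, CV 50%
summarize_trait <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("summarize_trait: need at least 2 values", call. = FALSE)
  if (any(values <= 0)) {
    stop("summarize_trait: all values must be > 0 (CV and Max/Min undefined otherwise)",
         call. = FALSE)
  }
  m <- mean(values)
  list(
    minimum = min(values),
    maximum = max(values),
    max_min_ratio = max(values) / min(values),
    mean = m,
    cv_percent = 100 * stats::sd(values) / m
  )
}

#' One-way fixed-effects ANOVA across populations
#'
#' Classical one-way ANOVA of trait values grouped by population, as used to
#' test whether traits differ among natural populations. Replicates are the
#' observations; populations the groups.
#'
#' @param values Numeric observations.
#' @param groups Grouping labels (population ids), same length as `values`.
#' @return Named list: `df_between`, `df_within`, `f_statistic`, `p_value`.
#' @export
one_way_anova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2L) stop("one_way_anova: need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("one_way_anova: every group needs >= 2 observations", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  list(
    df_between = tab[["Df"]][1L],
    df_within = tab[["Df"]][2L],
    f_statistic = tab[["F value"]][1L],
    p_value = tab[["Pr(>F)"]][1L]
  )
}

#' Variation table over all traits (Table-1 layout)
#'
#' Applies [summarize_trait()] and [one_way_anova()] to every trait column of
#' a population x replicate trait table and returns one row per trait with the
#' columns minimum, maximum, Max/Min, mean, CV (%), df, F and P.
#'
#' @param traits Data frame with columns `population_id`, `replicate` and one
#'   numeric column per trait (e.g. length, width, LWR, TGW, CSP, CSS, CS,
#'   CCF, GDTI, GCTI, GSTI).
#' @param digits If non-`NULL`, round the reported summary columns (df, F and
#'   P kept at full precision except F rounded likewise) for display; default
#'   `NULL` keeps full precision.
#' @return Data frame, one row per trait.
#' @export
trait_variation_table <- function(traits, digits = NULL) {
  trait_cols <- setdiff(names(traits), c("population_id", "replicate"))
  rows <- lapply(trait_cols, function(tc) {
    s <- summarize_trait(traits[[tc]])
    a <- one_way_anova(traits[[tc]], traits$population_id)
    data.frame(
      trait = tc, minimum = s$minimum, maximum = s$maximum,
      max_min_ratio = s$max_min_ratio, mean = s$mean, cv_percent = s$cv_percent,
      df = a$df_between, f_statistic = a$f_statistic, p_value = a$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    num <- c("minimum", "maximum", "max_min_ratio", "mean", "cv_percent", "f_statistic")
    out[num] <- lapply(out[num], round, digits = digits)
  }
  rownames(out) <- NULL
  out
}
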