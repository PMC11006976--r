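#' Default treatment scheme for the three germination stress experiments
#'
#' Returns the treatment grids used in the stress-tolerance assays: five
#' osmotic water potentials (MPa, imposed with PEG-6000), five incubation
#' temperatures (degrees C) and five saline-alkali concentrations (mmol/L).
#' Level 1 of each experiment is the unstressed control and carries weight 1.
#'
#' @return A list of class `treatment_scheme` with elements `drought_levels`,
#'   `cold_levels`, `saline_levels` (each length 5, level 1 = control) and
#'   `reference_temperature` (the control temperature used as the numerator of
#'   the cold weight).
#' @export
#' @examples
#' default_treatment_scheme()
default_treatment_scheme <- function() {
  scheme <- list(
    drought_levels = c(0, -0.3, -0.6, -0.9, -1.2),
    cold_levels = c(25, 20, 15, 10, 5),
    saline_levels = c(0, 50, 100, 150, 200),
    reference_temperature = 25
  )
  class(scheme) <- "treatment_scheme"
  validate_treatment_scheme(scheme)
  scheme
}

validate_treatment_scheme <- function(scheme) {
  for (nm in c("drought_levels", "cold_levels", "saline_levels")) {
    if (length(scheme[[nm]]) != 5L) {
      stop("treatment scheme: '", nm, "' must have exactly 5 levels", call. = FALSE)
    }
  }
  if (any(scheme$cold_levels <= 0)) {
    stop("treatment scheme: cold levels must be strictly positive (the weight T1/Ti is undefined at or below 0 degrees C)",
         call. = FALSE)
  }
  if (any(scheme$drought_levels > 0)) {
    stop("treatment scheme: water potentials must be <= 0 MPa", call. = FALSE)
  }
  invisible(scheme)
}

#' Germination index of a single dish
#'
#' The germination index (GI) is the speed-weighted germination count
#' \eqn{GI = \sum_d n_d / t_d}, where \eqn{n_d} is the number of seeds newly
#' germinated on day \eqn{t_d} (1-based day of counting). Faster germination
#' of the same number of seeds yields a larger GI.
#'
#' @param daily_counts Integer vector of newly germinated seeds per observation
#'   day (day 1, 2, ...). A trial terminated early simply has a shorter vector.
#' @param seeds_per_dish Number of seeds sown in the dish (default 50); the
#'   counts may not sum to more than this.
#' @param dish_id Optional label used in error messages.
#' @return Non-negative scalar; 0 when no seed germinated.
#' @export
#' @examples
#' germination_index(c(5, 3, 2)) # 5/1 + 3/2 + 2/3
germination_index <- function(daily_counts, seeds_per_dish = 50, dish_id = NULL) {
  lab <- if (is.null(dish_id)) "dish" else paste0("dish '", dish_id, "'")
  if (length(daily_counts) < 1L) {
    stop(lab, ": daily_counts must contain at least one day", call. = FALSE)
  }
  if (any(!is.finite(daily_counts)) || any(daily_counts < 0)) {
    stop(lab, ": negative or non-finite daily count", call. = FALSE)
  }
  if (sum(daily_counts) > seeds_per_dish) {
    stop(lab, ": total germinated (", sum(daily_counts),
         ") exceeds seeds_per_dish (", seeds_per_dish, ")", call. = FALSE)
  }
  sum(daily_counts / seq_along(daily_counts))
}

#' Treatment weight for a drought (osmotic) level
#'
#' Weight \eqn{D_R = 1 + |W|} for water potential \eqn{W} (MPa, non-positive);
#' the 0 MPa control has weight 1.
#'
#' @param W Water potential in MPa, `W <= 0`.
#' @return Weight `>= 1`.
#' @export
drought_weight <- function(W) {
  if (any(!is.finite(W)) || any(W > 0)) {
    stop("drought_weight: water potential must be finite and <= 0 MPa", call. = FALSE)
  }
  1 + abs(W)
}

#' Treatment weight for a cold (low-temperature) level
#'
#' Weight \eqn{C_R = T_1 / T} for incubation temperature \eqn{T} relative to
#' the control temperature \eqn{T_1} (both in degrees C, strictly positive);
#' the control level has weight 1.
#'
#' @param T_level Incubation temperature, degrees C, `0 < T_level <= T1`.
#' @param T1 Control temperature, degrees C (default 25).
#' @return Weight `>= 1`.
#' @export
cold_weight <- function(T_level, T1 = 25) {
  if (any(!is.finite(T_level)) || any(T_level <= 0)) {
    stop("cold_weight: temperature must be finite and > 0 degrees C", call. = FALSE)
  }
  if (any(T_level > T1)) {
    stop("cold_weight: treatment temperature exceeds the control temperature", call. = FALSE)
  }
  T1 / T_level
}

#' Treatment weight for a saline-alkali level
#'
#' The control level (index 1, 0 mmol/L) has weight 1; stress levels 2-5 have
#' weight \eqn{S_R = S / 10} for concentration \eqn{S} in mmol/L.
#'
#' @param S Concentration in mmol/L.
#' @param level_index Treatment level, integer 1..5; level 1 is the control.
#' @return Weight `>= 1`.
#' @export
saline_weight <- function(S, level_index) {
  if (length(S) != length(level_index) && length(level_index) != 1L && length(S) != 1L) {
    stop("saline_weight: S and level_index lengths differ", call. = FALSE)
  }
  if (any(level_index < 1L) || any(level_index > 5L) || any(level_index != round(level_index))) {
    stop("saline_weight: level_index must be an integer in 1..5", call. = FALSE)
  }
  if (any(S < 0)) stop("saline_weight: concentration must be >= 0", call. = FALSE)
  if (any(level_index >= 2L & S <= 0)) {
    stop("saline_weight: stress levels (index >= 2) need a positive concentration", call. = FALSE)
  }
  ifelse(level_index == 1L, 1, S / 10)
}

#' Weighted stress-tolerance index over the five treatment levels
#'
#' Each experiment's tolerance index is the mean over its five treatment
#' levels of the germination index weighted by treatment severity:
#' \eqn{(\sum_{i=1}^{5} GI_i w_i) / 5}. With `gsti_literal = TRUE` the
#' alternative saline-index reading that drops the control GI,
#' \eqn{w_1 (\sum_{i=2}^{5} GI_i w_i) / 5}, is used instead (only sensible for
#' the saline experiment, where \eqn{w_1 = 1} so the two readings differ by
#' the control term \eqn{GI_1/5}).
#'
#' @param gi_by_level Germination indices at levels 1..5 (level 1 = control).
#' @param weights_by_level Severity weights at levels 1..5, each `>= 1`.
#' @param gsti_literal Use the control-dropping variant (default `FALSE`).
#' @return Non-negative scalar.
#' @export
#' @examples
#' tolerance_index(rep(1, 5), drought_weight(c(0, -0.3, -0.6, -0.9, -1.2)))
tolerance_index <- function(gi_by_level, weights_by_level, gsti_literal = FALSE) {
  if (length(gi_by_level) != 5L || length(weights_by_level) != 5L) {
    stop("tolerance_index: need exactly 5 GI values and 5 weights", call. = FALSE)
  }
  if (any(weights_by_level < 1)) {
    stop("tolerance_index: weights must all be >= 1", call. = FALSE)
  }
  if (any(gi_by_level < 0)) {
    stop("tolerance_index: germination indices must be >= 0", call. = FALSE)
  }
  if (gsti_literal) {
    weights_by_level[1L] * sum(gi_by_level[-1L] * weights_by_level[-1L]) / 5
  } else {
    sum(gi_by_level * weights_by_level) / 5
  }
}

#' Compute tolerance indices for a set of germination trials
#'
#' Aggregates dish-level daily counts into one germination index per dish,
#' binds the severity weight of each treatment level (drought weights to the
#' PEG experiment, cold weights to the temperature experiment, saline weights
#' to the saline-alkali experiment) and returns GDTI, GCTI and GSTI.
#'
#' With `aggregation = "per_replicate"` the index is computed for each
#' replicate by pairing replicate r's dishes across the five levels,
#' preserving within-population replication for downstream ANOVA. With
#' `"population_mean"` the germination indices are first averaged over
#' replicates at each level and one index per population is returned
#' (`replicate` is `NA`).
#'
#' @param trials Data frame with columns `population_id`, `experiment` (one of
#'   `"drought"`, `"cold"`, `"saline"`), `level_index` (1..5), `level_value`,
#'   `replicate`, `day`, `n_germinated` and optionally `seeds_per_dish`
#'   (long format, one row per dish-day).
#' @param scheme A [default_treatment_scheme()]-style scheme used to validate
#'   level values and supply the control temperature.
#' @param aggregation `"per_replicate"` (default) or `"population_mean"`.
#' @param gsti_literal Passed to [tolerance_index()] for the saline index.
#' @return Data frame with columns `population_id`, `replicate`, `GDTI`,
#'   `GCTI`, `GSTI`.
#' @export
compute_indices <- function(trials, scheme = default_treatment_scheme(),
                            aggregation = c("per_replicate", "population_mean"),
                            gsti_literal = FALSE) {
  aggregation <- match.arg(aggregation)
  validate_treatment_scheme(scheme)
  req <- c("population_id", "experiment", "level_index", "level_value",
           "replicate", "day", "n_germinated")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop("compute_indices: trials is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_exp <- setdiff(unique(trials$experiment), c("drought", "cold", "saline"))
  if (length(bad_exp)) {
    stop("compute_indices: unknown experiment(s): ", paste(bad_exp, collapse = ", "),
         call. = FALSE)
  }
  spd <- if ("seeds_per_dish" %in% names(trials)) trials$seeds_per_dish else rep(50L, nrow(trials))

  # one GI per dish
  key <- interaction(trials$population_id, trials$experiment, trials$level_index,
                     trials$replicate, drop = TRUE)
  gi_rows <- lapply(split(seq_len(nrow(trials)), key), function(idx) {
    d <- trials[idx, ]
    d <- d[order(d$day), ]
    if (!all(d$day == seq_len(nrow(d)))) {
      stop("compute_indices: days must be consecutive 1..D for dish (",
           d$population_id[1], ", ", d$experiment[1], ", level ", d$level_index[1],
           ", rep ", d$replicate[1], ")", call. = FALSE)
    }
    data.frame(
      population_id = d$population_id[1], experiment = d$experiment[1],
      level_index = d$level_index[1], level_value = d$level_value[1],
      replicate = d$replicate[1],
      gi = germination_index(d$n_germinated, seeds_per_dish = spd[idx][1],
                             dish_id = paste(d$population_id[1], d$experiment[1],
                                             d$level_index[1], d$replicate[1], sep = "/")),
      stringsAsFactors = FALSE
    )
  })
  gi <- do.call(rbind, gi_rows)

  if (aggregation == "population_mean") {
    agg <- stats::aggregate(gi ~ population_id + experiment + level_index + level_value,
                            data = gi, FUN = mean)
    agg$replicate <- NA_integer_
    gi <- agg
  }

  level_weight <- function(experiment, level_index, level_value) {
    switch(experiment,
      drought = drought_weight(level_value),
      cold = cold_weight(level_value, T1 = scheme$reference_temperature),
      saline = saline_weight(level_value, level_index)
    )
  }

  out <- list()
  for (pop in unique(gi$population_id)) {
    gpop <- gi[gi$population_id == pop, ]
    for (rep_id in unique(gpop$replicate)) {
      grep_ <- if (is.na(rep_id)) gpop else gpop[gpop$replicate == rep_id, ]
      idx <- c(GDTI = NA_real_, GCTI = NA_real_, GSTI = NA_real_)
      for (exp_nm in c("drought", "cold", "saline")) {
        ge <- grep_[grep_$experiment == exp_nm, ]
        ge <- ge[order(ge$level_index), ]
        if (!identical(as.integer(ge$level_index), 1:5)) {
          missing_lv <- setdiff(1:5, ge$level_index)
          stop("compute_indices: missing treatment level(s) ",
               paste(missing_lv, collapse = ", "), " for (", pop, ", ", exp_nm,
               if (!is.na(rep_id)) paste0(", replicate ", rep_id) else "", ")",
               call. = FALSE)
        }
        w <- level_weight(exp_nm, ge$level_index, ge$level_value)
        val <- tolerance_index(ge$gi, w,
                               gsti_literal = gsti_literal && exp_nm == "saline")
        idx[[switch(exp_nm, drought = "GDTI", cold = "GCTI", saline = "GSTI")]] <- val
      }
      out[[length(out) + 1L]] <- data.frame(
        population_id = pop, replicate = rep_id,
        GDTI = idx[["GDTI"]], GCTI = idx[["GCTI"]], GSTI = idx[["GSTI"]],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$population_id, res$replicate), , drop = FALSE]
}
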