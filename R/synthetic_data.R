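# Synthetic study generator. Emulates the sampling design the analyses
# assume: 21 collection sites in the Qinghai-Tibetan plateau envelope
# (35.83-38.32 deg N, 90.86-102.76 deg E, 1866-3832 m; MAP 67-427 mm rising
# eastward; MAT -1.5 to 8.3 degC falling with altitude), three replicates per
# population, 50 seeds per dish, five treatment levels per stress experiment
# and daily counts over up to 15 days. Traits follow a linear-Gaussian
# version of the causal diagram the path model assumes (soil -> morphology,
# climate + soil -> nutrients), and a per-experiment latent tolerance enters
# the germination hazard multiplicatively so that the index arithmetic, not
# the generator, determines index magnitudes.

#' Simulation configuration
#'
#' @param n_populations Number of collection sites/populations (default 21).
#' @param n_replicates Replicates (dishes) per population and level (default 3).
#' @param seeds_per_dish Seeds sown per dish (default 50).
#' @param n_days Observation days (default 15).
#' @param random_seed Integer seed controlling every random draw.
#' @param structural_coefficients Named list of standardized structural
#'   coefficients on the composite scale, keyed `"from->to"` over the nodes
#'   climate, soil, morphology, nutrients, GDTI, GCTI, GSTI.
#' @param gradient_effects Optional named list: trait name -> named vector of
#'   standardized slopes on `latitude`, `longitude`, `altitude`, added to the
#'   trait's latent score (default none).
#' @param noise_sds Named list of noise standard deviations: `MAT` (degC),
#'   `MAP` (mm), `population` and `replicate` (standardized trait scale).
#' @param base_hazard Daily germination probability of an average, unstressed
#'   dish.
#' @param tolerance_effect Log-scale effect of the latent tolerance z-score on
#'   the hazard.
#' @param stress_sensitivity Named list of hazard log-decay rates per unit
#'   severity: `drought` (per MPa), `cold` (per degC below control), `saline`
#'   (per mmol/L).
#' @param stopping_rule Terminate a dish after 5 consecutive zero-count days
#'   (default `FALSE`, fixed rectangular panels).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_populations = 21L, n_replicates = 3L,
                              seeds_per_dish = 50L, n_days = 15L,
                              random_seed = 1L,
                              structural_coefficients = list(
                                "climate->morphology" = 0,
                                "soil->morphology" = 0.6,
                                "climate->nutrients" = 0.5,
                                "soil->nutrients" = 0.4,
                                "climate->soil" = 0.5,
                                "climate->GDTI" = 0.4,
                                "morphology->GDTI" = 0.5,
                                "climate->GCTI" = 0.4,
                                "soil->GCTI" = 0.3,
                                "nutrients->GCTI" = 0.4,
                                "climate->GSTI" = 0.4,
                                "morphology->GSTI" = 0.5),
                              gradient_effects = list(),
                              noise_sds = list(MAT = 0.5, MAP = 20,
                                               population = 0.5, replicate = 0.3),
                              base_hazard = 0.25,
                              tolerance_effect = 0.35,
                              stress_sensitivity = list(drought = 1.2,
                                                        cold = 0.08,
                                                        saline = 0.012),
                              stopping_rule = FALSE) {
  cfg <- list(n_populations = as.integer(n_populations),
              n_replicates = as.integer(n_replicates),
              seeds_per_dish = as.integer(seeds_per_dish),
              n_days = as.integer(n_days),
              random_seed = as.integer(random_seed),
              structural_coefficients = structural_coefficients,
              gradient_effects = gradient_effects,
              noise_sds = noise_sds,
              base_hazard = base_hazard,
              tolerance_effect = tolerance_effect,
              stress_sensitivity = stress_sensitivity,
              stopping_rule = isTRUE(stopping_rule))
  if (cfg$n_populations < 3L) stop("simulation_config: n_populations must be >= 3", call. = FALSE)
  if (any(unlist(noise_sds) <= 0)) stop("simulation_config: noise SDs must be > 0", call. = FALSE)
  if (base_hazard < 0 || base_hazard > 1) {
    stop("simulation_config: base_hazard must lie in [0, 1]", call. = FALSE)
  }
  if (any(unlist(stress_sensitivity) < 0)) {
    stop("simulation_config: stress sensitivities must be >= 0", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

sc <- function(config, key) {
  v <- config$structural_coefficients[[key]]
  if (is.null(v)) 0 else v
}

# unit-variance latent score: signal + Gaussian noise filling the variance
latent_score <- function(signal_var_budget, signal, n) {
  noise_var <- max(1 - signal_var_budget, 0.05)
  standardize(signal + stats::rnorm(n, sd = sqrt(noise_var)))
}

#' Generate the site table
#'
#' Geography uniform in the study envelope; MAT decreasing with altitude and
#' MAP increasing eastward (both plus Gaussian noise, clipped to the stated
#' ranges); soil variables driven by a climate composite through the
#' configured `climate->soil` coefficient plus independent noise.
#'
#' @param config A [simulation_config()].
#' @return Data frame: `population_id`, `latitude`, `longitude`, `altitude`,
#'   `MAT`, `MAP`, `SOC`, `AN`, `AP`, `pH`.
#' @export
generate_sites <- function(config) {
  set.seed(config$random_seed)
  n <- config$n_populations
  lat <- stats::runif(n, 35.83, 38.32)
  lon <- stats::runif(n, 90.86, 102.76)
  alt <- stats::runif(n, 1866, 3832)
  MAP <- 67 + (427 - 67) * (lon - 90.86) / (102.76 - 90.86) +
    stats::rnorm(n, sd = config$noise_sds$MAP)
  MAP <- pmin(pmax(MAP, 67), 427)
  MAT <- 8.3 - (8.3 - (-1.5)) * (alt - 1866) / (3832 - 1866) +
    stats::rnorm(n, sd = config$noise_sds$MAT)
  MAT <- pmin(pmax(MAT, -1.5), 8.3)
  clim_z <- standardize((standardize(MAT) + standardize(MAP)) / sqrt(2))
  b <- sc(config, "climate->soil")
  soil_z <- function() latent_score(b^2, b * clim_z, n)
  data.frame(
    population_id = sprintf("P%02d", seq_len(n)),
    latitude = lat, longitude = lon, altitude = alt,
    MAT = MAT, MAP = MAP,
    SOC = pmax(8 + 4 * soil_z(), 0.5),
    AN = pmax(80 + 30 * soil_z(), 5),
    AP = pmax(8 + 3 * soil_z(), 0.5),
    pH = pmin(pmax(8.2 - 0.4 * soil_z(), 6.5), 9.5),
    stringsAsFactors = FALSE
  )
}

# realistic trait scales: mean and CV (%) on the observed scale
trait_scales <- function() {
  data.frame(
    trait = c("length", "width", "TGW", "CSP", "CSS", "CS", "CCF"),
    mean = c(3.31, 1.00, 0.55, 28.16, 28.45, 49.12, 0.21),
    cv = c(15.8, 11.6, 23.0, 12.9, 23.9, 11.5, 17.9),
    block = c("morphology", "morphology", "morphology",
              "nutrients", "nutrients", "nutrients", "nutrients"),
    stringsAsFactors = FALSE
  )
}

#' Generate the population x replicate trait table
#'
#' Population-level block composites follow the configured structural
#' coefficients (soil and climate driving morphology and nutrients); each
#' observed trait loads on its block composite with a population intercept
#' and replicate noise, then is mapped onto a realistic mean/CV scale. LWR is
#' computed as length/width. Optional `gradient_effects` add direct
#' standardized slopes of z-scored latitude/longitude/altitude to a trait's
#' latent score. Non-positive values are resampled (with a warning count).
#' The returned table carries a `latent_tolerance` attribute: per-population
#' tolerance z-scores for the drought, cold and saline experiments, derived
#' from the configured composite-to-index coefficients, which
#' [generate_germination()] feeds into the hazard.
#'
#' @param sites Output of [generate_sites()].
#' @param config A [simulation_config()].
#' @return Data frame: `population_id`, `replicate`, `length`, `width`, `LWR`,
#'   `TGW`, `CSP`, `CSS`, `CS`, `CCF`.
#' @export
generate_traits <- function(sites, config) {
  set.seed(config$random_seed + 1L)
  n <- nrow(sites)
  clim_z <- standardize((standardize(sites$MAT) + standardize(sites$MAP)) / sqrt(2))
  soil_z <- standardize((standardize(sites$SOC) + standardize(sites$AN) +
                           standardize(sites$AP) - standardize(sites$pH)) / 2)
  b_cm <- sc(config, "climate->morphology"); b_sm <- sc(config, "soil->morphology")
  b_cn <- sc(config, "climate->nutrients"); b_sn <- sc(config, "soil->nutrients")
  morph_z <- latent_score(b_cm^2 + b_sm^2, b_cm * clim_z + b_sm * soil_z, n)
  nutr_z <- latent_score(b_cn^2 + b_sn^2, b_cn * clim_z + b_sn * soil_z, n)
  block_scores <- list(morphology = morph_z, nutrients = nutr_z)

  grad_z <- list(latitude = standardize(sites$latitude),
                 longitude = standardize(sites$longitude),
                 altitude = standardize(sites$altitude))

  sc_tab <- trait_scales()
  reps <- config$n_replicates
  pop_sd <- config$noise_sds$population
  rep_sd <- config$noise_sds$replicate
  load <- 0.7  # trait loading on its block composite

  out <- data.frame(
    population_id = rep(sites$population_id, each = reps),
    replicate = rep(seq_len(reps), times = n),
    stringsAsFactors = FALSE
  )
  n_resampled <- 0L
  for (k in seq_len(nrow(sc_tab))) {
    tr <- sc_tab$trait[k]
    mu <- sc_tab$mean[k]
    sd_obs <- sc_tab$cv[k] / 100 * mu
    z_pop <- load * block_scores[[sc_tab$block[k]]] + stats::rnorm(n, sd = pop_sd)
    ge <- config$gradient_effects[[tr]]
    if (!is.null(ge)) {
      for (gnm in names(ge)) z_pop <- z_pop + ge[[gnm]] * grad_z[[gnm]]
    }
    z <- rep(z_pop, each = reps) + stats::rnorm(n * reps, sd = rep_sd)
    val <- mu + sd_obs * z / sqrt(load^2 + pop_sd^2 + rep_sd^2)
    bad <- which(val <= 0)
    tries <- 0L
    while (length(bad) && tries < 100L) {
      val[bad] <- mu + sd_obs * stats::rnorm(length(bad), sd = 0.5)
      n_resampled <- n_resampled + length(bad)
      bad <- which(val <= 0)
      tries <- tries + 1L
    }
    if (length(bad)) stop("generate_traits: could not produce positive values for ", tr,
                          call. = FALSE)
    out[[tr]] <- val
  }
  if (n_resampled > 0L) {
    warning("generate_traits: resampled ", n_resampled, " non-positive trait value(s)")
  }
  out$LWR <- out$length / out$width
  out <- out[c("population_id", "replicate", "length", "width", "LWR", "TGW",
               "CSP", "CSS", "CS", "CCF")]

  tol <- data.frame(population_id = sites$population_id, stringsAsFactors = FALSE)
  tol$drought <- latent_score(
    sc(config, "climate->GDTI")^2 + sc(config, "morphology->GDTI")^2,
    sc(config, "climate->GDTI") * clim_z + sc(config, "morphology->GDTI") * morph_z, n)
  tol$cold <- latent_score(
    sc(config, "climate->GCTI")^2 + sc(config, "soil->GCTI")^2 + sc(config, "nutrients->GCTI")^2,
    sc(config, "climate->GCTI") * clim_z + sc(config, "soil->GCTI") * soil_z +
      sc(config, "nutrients->GCTI") * nutr_z, n)
  tol$saline <- latent_score(
    sc(config, "climate->GSTI")^2 + sc(config, "morphology->GSTI")^2,
    sc(config, "climate->GSTI") * clim_z + sc(config, "morphology->GSTI") * morph_z, n)
  attr(out, "latent_tolerance") <- tol
  out
}

#' Generate dish-level daily germination counts
#'
#' Each seed germinates on a given day with a discrete hazard
#' `base_hazard x exp(tolerance_effect x latent tolerance) x stress multiplier`,
#' where the stress multiplier decays exponentially in treatment severity
#' (|W| in MPa, degrees below the control temperature, or mmol/L). Daily
#' counts are binomial draws over the seeds still ungerminated. With
#' `stopping_rule = TRUE` a dish's record is truncated after five consecutive
#' zero-count days.
#'
#' @param traits Output of [generate_traits()] (its `latent_tolerance`
#'   attribute supplies the per-population tolerance scores).
#' @param config A [simulation_config()].
#' @param scheme Treatment scheme (default [default_treatment_scheme()]).
#' @return Long data frame, one row per dish-day: `population_id`,
#'   `experiment`, `level_index`, `level_value`, `replicate`, `day`,
#'   `n_germinated`, `seeds_per_dish`.
#' @export
generate_germination <- function(traits, config, scheme = default_treatment_scheme()) {
  set.seed(config$random_seed + 2L)
  tol <- attr(traits, "latent_tolerance")
  if (is.null(tol)) {
    stop("generate_germination: traits lack the latent_tolerance attribute; ",
         "use generate_traits()", call. = FALSE)
  }
  sens <- config$stress_sensitivity
  severity <- list(
    drought = abs(scheme$drought_levels) * sens$drought,
    cold = (scheme$reference_temperature - scheme$cold_levels) * sens$cold,
    saline = scheme$saline_levels * sens$saline
  )
  levels_of <- list(drought = scheme$drought_levels, cold = scheme$cold_levels,
                    saline = scheme$saline_levels)
  max_mult <- exp(config$tolerance_effect * max(abs(unlist(tol[c("drought", "cold", "saline")]))))
  if (config$base_hazard * max_mult > 1) {
    stop("generate_germination: configured hazard exceeds 1; lower base_hazard ",
         "or tolerance_effect", call. = FALSE)
  }

  rows <- vector("list", nrow(tol) * 3L * 5L * config$n_replicates)
  ri <- 0L
  for (p in seq_len(nrow(tol))) {
    for (exp_nm in c("drought", "cold", "saline")) {
      tol_mult <- exp(config$tolerance_effect * tol[[exp_nm]][p])
      for (lv in 1:5) {
        hazard <- config$base_hazard * tol_mult * exp(-severity[[exp_nm]][lv])
        for (r in seq_len(config$n_replicates)) {
          remaining <- config$seeds_per_dish
          counts <- integer(config$n_days)
          for (d in seq_len(config$n_days)) {
            k <- stats::rbinom(1L, remaining, hazard)
            counts[d] <- k
            remaining <- remaining - k
          }
          if (config$stopping_rule) {
            run <- rle(counts == 0L)
            # truncate after the day on which the 5th consecutive zero falls
            zero_end <- cumsum(run$lengths)
            hit <- which(run$values & run$lengths >= 5L)
            if (length(hit)) {
              stop_day <- zero_end[hit[1L]] - run$lengths[hit[1L]] + 5L
              counts <- counts[seq_len(stop_day)]
            }
          }
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            population_id = tol$population_id[p], experiment = exp_nm,
            level_index = lv, level_value = levels_of[[exp_nm]][lv],
            replicate = r, day = seq_along(counts), n_germinated = counts,
            seeds_per_dish = config$seeds_per_dish, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete study
#'
#' Runs [generate_sites()], [generate_traits()] and [generate_germination()]
#' and computes the tolerance indices, returning every table the downstream
#' analyses need.
#'
#' @param config A [simulation_config()].
#' @param scheme Treatment scheme.
#' @param aggregation Passed to [compute_indices()].
#' @return List: `sites`, `traits` (with GDTI/GCTI/GSTI columns joined),
#'   `trials`, `indices`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             scheme = default_treatment_scheme(),
                             aggregation = "per_replicate") {
  sites <- generate_sites(config)
  traits <- generate_traits(sites, config)
  trials <- generate_germination(traits, config, scheme)
  indices <- compute_indices(trials, scheme, aggregation = aggregation)
  merged <- merge(traits, indices, by = c("population_id", "replicate"))
  merged <- merged[order(merged$population_id, merged$replicate), ]
  rownames(merged) <- NULL
  attr(merged, "latent_tolerance") <- attr(traits, "latent_tolerance")
  list(sites = sites, traits = merged, trials = trials, indices = indices,
       config = config)
}

#' Simulate standardized composite-level path data
#'
#' Draws linear-Gaussian data directly on the composite scale of a path
#' specification: exogenous nodes are standard-normal (with the configured
#' pairwise coefficient applied between the first two), each endogenous node
#' is the coefficient-weighted sum of its parents plus Gaussian noise topping
#' the variance up to 1. Used for parameter-recovery checks of the path
#' model at large n.
#'
#' @param spec A [path_spec()].
#' @param coefficients Named list `"from->to"` -> standardized coefficient.
#' @param n Number of rows.
#' @param exo_cor Correlation between the first two exogenous nodes (default 0).
#' @return Data frame with one column per node.
#' @export
simulate_path_data <- function(spec, coefficients, n, exo_cor = 0) {
  stopifnot(inherits(spec, "path_spec"))
  dat <- as.data.frame(matrix(NA_real_, n, length(spec$nodes),
                              dimnames = list(NULL, spec$nodes)))
  exo <- spec$exogenous
  dat[exo] <- stats::rnorm(n * length(exo))
  if (length(exo) >= 2L && exo_cor != 0) {
    dat[[exo[2L]]] <- exo_cor * dat[[exo[1L]]] +
      sqrt(1 - exo_cor^2) * dat[[exo[2L]]]
  }
  for (node in spec$endogenous) {
    parents <- spec$edges$from[spec$edges$to == node]
    b <- vapply(parents, function(pp) {
      v <- coefficients[[paste0(pp, "->", node)]]
      if (is.null(v)) 0 else v
    }, 0)
    signal <- as.matrix(dat[parents]) %*% b
    noise_var <- max(1 - stats::var(drop(signal)), 0.05)
    dat[[node]] <- drop(signal) + stats::rnorm(n, sd = sqrt(noise_var))
  }
  dat
}
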