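# Table I/O with schema validation and the end-to-end pipeline driver.
# Tables are CSV (UTF-8, '.' decimal separator); model fits are written as
# JSON. The exported functions are the package's interface; each pipeline
# stage maps onto one of them.

#' Read and validate a CSV table against a column schema
#'
#' @param path CSV file path.
#' @param schema Named character vector mapping required column names to types
#'   (`"character"`, `"integer"`, `"numeric"`). Extra columns are kept as-is.
#' @return Validated data frame.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("read_table: file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(schema), names(tab))
  if (length(miss)) {
    stop("read_table: ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  for (col in names(schema)) {
    if (schema[[col]] %in% c("integer", "numeric")) {
      val <- suppressWarnings(as.numeric(tab[[col]]))
      bad <- which(is.na(val) & !is.na(tab[[col]]) & tab[[col]] != "")
      if (length(bad)) {
        problems <- c(problems, paste0("column '", col, "', row(s) ",
                                       paste(utils::head(bad, 5L), collapse = ", "),
                                       ": not numeric"))
      }
      tab[[col]] <- if (schema[[col]] == "integer") as.integer(val) else val
    } else {
      tab[[col]] <- as.character(tab[[col]])
    }
  }
  if (length(problems)) {
    stop("read_table: ", path, ": ", paste(problems, collapse = "; "), call. = FALSE)
  }
  tab
}

#' Schemas for the pipeline's input tables
#' @return Named list of column-type schemas for `trials`, `traits`, `sites`.
#' @export
table_schemas <- function() {
  list(
    trials = c(population_id = "character", experiment = "character",
               level_index = "integer", level_value = "numeric",
               replicate = "integer", day = "integer", n_germinated = "integer"),
    traits = c(population_id = "character", replicate = "integer",
               length = "numeric", width = "numeric", LWR = "numeric",
               TGW = "numeric", CSP = "numeric", CSS = "numeric",
               CS = "numeric", CCF = "numeric"),
    sites = c(population_id = "character", latitude = "numeric",
              longitude = "numeric", altitude = "numeric", MAT = "numeric",
              MAP = "numeric", SOC = "numeric", AN = "numeric",
              AP = "numeric", pH = "numeric")
  )
}

#' Read a trials table with germination-specific row validation
#' @param path CSV path in the long dish-day layout.
#' @return Validated data frame.
#' @export
read_trials <- function(path) {
  tab <- read_table(path, table_schemas()$trials)
  bad <- which(tab$n_germinated < 0)
  if (length(bad)) {
    stop("read_trials: negative n_germinated at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  tab
}

#' Run the full analysis pipeline
#'
#' Chains every stage on in-memory tables: tolerance indices, the trait
#' variation table, the geographic gradient panel, the environmental
#' attribution panel, the three mixed models with block decomposition, and
#' the path model. When `out_dir` is given, each stage's table is written
#' (CSV for tables, JSON for model fits) together with a small run manifest.
#'
#' @param trials,traits,sites The three input tables (see [table_schemas()]).
#' @param scheme Treatment scheme.
#' @param spec Path-model specification.
#' @param out_dir Optional output directory.
#' @param gsti_literal,aggregation Passed to [compute_indices()].
#' @return Named list with elements `indices`, `trait_table`,
#'   `variation`, `gradients`, `env`, `lmm`, `sem`, `manifest`.
#' @export
run_all <- function(trials, traits, sites, scheme = default_treatment_scheme(),
                    spec = default_path_spec(), out_dir = NULL,
                    gsti_literal = FALSE, aggregation = "per_replicate") {
  stage <- "indices"
  res <- tryCatch({
    indices <- compute_indices(trials, scheme, aggregation = aggregation,
                               gsti_literal = gsti_literal)
    trait_table <- merge(traits, indices, by = c("population_id", "replicate"))

    stage <- "summarize"
    variation <- trait_variation_table(trait_table)

    stage <- "gradients"
    gradients <- gradient_panel(trait_table, sites)

    stage <- "env"
    env <- env_attribution_panel(trait_table, sites)

    stage <- "lmm"
    lmm <- mixed_effects_panel(trait_table)

    stage <- "sem"
    sem <- path_analysis(trait_table, sites, spec = spec)

    list(indices = indices, trait_table = trait_table, variation = variation,
         gradients = gradients, env = env, lmm = lmm, sem = sem)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })

  res$manifest <- list(
    stages = c("indices", "summarize", "gradients", "env",
               "lmm_GDTI", "lmm_GCTI", "lmm_GSTI", "sem"),
    n_populations = length(unique(traits$population_id)),
    rows = list(trials = nrow(trials), traits = nrow(traits), sites = nrow(sites),
                indices = nrow(res$indices)),
    package_version = as.character(utils::packageVersion("seedtol"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$indices, file.path(out_dir, "indices.csv"), row.names = FALSE)
    utils::write.csv(res$variation, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(res$gradients, file.path(out_dir, "gradients.csv"), row.names = FALSE)
    utils::write.csv(res$env, file.path(out_dir, "env_attribution.csv"), row.names = FALSE)
    for (resp in names(res$lmm)) {
      f <- res$lmm[[resp]]
      jsonlite::write_json(
        list(fixed_effects = as.list(f$fit$fixed_effects),
             p_values = as.list(f$fit$p_values),
             random_intercept_variance = f$fit$random_intercept_variance,
             residual_variance = f$fit$residual_variance,
             singular = f$fit$singular,
             marginal_r_squared = f$fit$marginal_r_squared,
             block_shares = as.list(f$block_shares)),
        file.path(out_dir, paste0("lmm_", resp, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(
      list(coefficients = res$sem$coefficients,
           r_squared = as.list(res$sem$r_squared),
           fit = res$sem$fit),
      file.path(out_dir, "sem_fit.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(res$sem$effects, file.path(out_dir, "sem_effects.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
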