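# Recursive path model over observed block composites. Every endogenous
# variable is regressed on its parents; for a fully recursive system these
# per-equation OLS estimates are the maximum-likelihood estimates, so no
# iterative covariance fitting is needed. The implied covariance assembled
# from the structural coefficients and residual (co)variances feeds the
# standard ML discrepancy and fit indices.

#' First principal component scores of a variable block
#'
#' Variables are z-scored and the first principal component of their
#' correlation matrix is extracted. The component is oriented so that the sum
#' of its loadings is positive (ties broken by the sign of the first
#' variable's loading), which makes scores deterministic and reads as a
#' "more = more" composite.
#'
#' @param block_matrix Data frame or matrix (rows = populations, columns =
#'   block variables), >= 3 rows, no missing values.
#' @return List: `scores` (mean-zero vector), `loadings`,
#'   `explained_variance` (fraction in the first component).
#' @export
block_pca_scores <- function(block_matrix) {
  X <- as.matrix(block_matrix)
  if (nrow(X) < 3L) stop("block_pca_scores: need >= 3 rows", call. = FALSE)
  if (anyNA(X)) stop("block_pca_scores: missing values not allowed", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("block_pca_scores: constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1L]
  s <- sum(load1)
  flip <- if (s != 0) sign(s) else sign(load1[1L])
  load1 <- load1 * flip
  scores <- drop(Z %*% load1)
  list(
    scores = scores,
    loadings = load1,
    explained_variance = pc$sdev[1L]^2 / sum(pc$sdev^2)
  )
}

#' Path-model specification as a directed acyclic edge list
#'
#' @param edges Data frame with character columns `from` and `to`.
#' @return Object of class `path_spec` (validated: acyclic, every endogenous
#'   node reachable).
#' @export
path_spec <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  nodes <- unique(c(edges$from, edges$to))
  # Kahn topological sort; failure to consume all nodes means a cycle
  order <- character(0)
  pool <- nodes
  active <- edges
  while (length(pool)) {
    sources <- setdiff(pool, active$to)
    if (!length(sources)) stop("path_spec: edge list contains a cycle", call. = FALSE)
    order <- c(order, sources)
    pool <- setdiff(pool, sources)
    active <- active[active$from %in% pool, , drop = FALSE]
  }
  spec <- list(edges = edges, nodes = order,
               exogenous = setdiff(nodes, edges$to),
               endogenous = intersect(order, unique(edges$to)))
  class(spec) <- "path_spec"
  spec
}

#' Default path-model specification for the tolerance-index system
#'
#' Climate and soil are covarying exogenous composites; soil drives seed
#' morphology and seed nutrients, climate drives seed nutrients (and a
#' climate-to-morphology path is estimated); the drought and saline indices
#' receive climate and morphology paths, and the cold index receives climate,
#' soil and nutrient paths.
#'
#' @return A [path_spec()].
#' @export
default_path_spec <- function() {
  path_spec(data.frame(
    from = c("climate", "soil", "climate", "soil",
             "climate", "morphology",
             "climate", "soil", "nutrients",
             "climate", "morphology"),
    to = c("morphology", "morphology", "nutrients", "nutrients",
           "GDTI", "GDTI",
           "GCTI", "GCTI", "GCTI",
           "GSTI", "GSTI"),
    stringsAsFactors = FALSE
  ))
}

#' Saturated (just-identified) recursive specification
#'
#' Orders the nodes and regresses each on all of its predecessors, which
#' reproduces the sample covariance exactly (chi-square 0, df 0).
#'
#' @param nodes Node names in causal order (exogenous first).
#' @param n_exogenous Number of leading nodes treated as covarying exogenous.
#' @return A [path_spec()].
#' @export
saturated_path_spec <- function(nodes = c("climate", "soil", "morphology",
                                          "nutrients", "GDTI", "GCTI", "GSTI"),
                                n_exogenous = 2L) {
  from <- character(0); to <- character(0)
  for (j in seq_along(nodes)) {
    if (j <= n_exogenous) next
    from <- c(from, nodes[seq_len(j - 1L)])
    to <- c(to, rep(nodes[j], j - 1L))
  }
  path_spec(data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

#' Maximum-likelihood covariance-structure fit indices
#'
#' Computes the ML discrepancy
#' \eqn{F_{ML} = \log|\Sigma| + tr(S\Sigma^{-1}) - \log|S| - p} between the
#' sample covariance S and the model-implied covariance, and the derived
#' indices: \eqn{\chi^2 = (n-1) F_{ML}};
#' GFI \eqn{= 1 - tr[(\Sigma^{-1}S - I)^2] / tr[(\Sigma^{-1}S)^2]};
#' CFI \eqn{= 1 - \max(\chi^2-df, 0) / \max(\chi^2_b-df_b, \chi^2-df, 0)}
#' against an independence baseline; RMSEA
#' \eqn{= \sqrt{\max(\chi^2-df, 0) / (df (n-1))}}, defined as 0 when df = 0.
#'
#' @param sample_cov,implied_cov Symmetric positive-definite matrices, same order.
#' @param n Sample size.
#' @param df Model degrees of freedom.
#' @param baseline_chi_square,baseline_df Chi-square and df of the baseline
#'   (independence) model.
#' @return Named list: `chi_square`, `df`, `gfi`, `cfi`, `rmsea`, `f_ml`.
#' @export
fit_indices <- function(sample_cov, implied_cov, n, df,
                        baseline_chi_square, baseline_df) {
  S <- as.matrix(sample_cov)
  Sig <- as.matrix(implied_cov)
  p <- nrow(S)
  if (!isTRUE(all.equal(S, t(S))) || !isTRUE(all.equal(Sig, t(Sig)))) {
    stop("fit_indices: covariance matrices must be symmetric", call. = FALSE)
  }
  evS <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  evSig <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(evS) <= 0 || min(evSig) <= 0) {
    stop("fit_indices: covariance matrices must be positive definite", call. = FALSE)
  }
  Siginv <- solve(Sig)
  f_ml <- determinant(Sig, logarithm = TRUE)$modulus[1] +
    sum(diag(S %*% Siginv)) -
    determinant(S, logarithm = TRUE)$modulus[1] - p
  f_ml <- max(f_ml, 0)
  chi2 <- (n - 1) * f_ml
  M <- Siginv %*% S
  gfi <- 1 - sum(diag((M - diag(p)) %*% (M - diag(p)))) / sum(diag(M %*% M))
  denom <- max(baseline_chi_square - baseline_df, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2 - df, 0) / denom
  rmsea <- if (df == 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  list(chi_square = chi2, df = df, gfi = gfi, cfi = cfi, rmsea = rmsea, f_ml = f_ml)
}

#' Fit a recursive path model on standardized observed variables
#'
#' Z-scores every variable, regresses each endogenous node on its parents
#' (per-equation OLS = ML for a recursive system), assembles the implied
#' covariance from the structural coefficients, the residual variances and
#' the saturated exogenous covariance block, and reports standardized path
#' coefficients with p values, per-equation R-squared, the
#' direct/indirect/total effect decomposition along directed paths, and the
#' ML fit indices against an independence baseline.
#'
#' @param data Data frame containing one column per node of `spec`.
#' @param spec A [path_spec()].
#' @return List of class `path_fit`: `coefficients` (edge table with
#'   `estimate`, `se`, `p_value`, `significance_class`), `r_squared` and
#'   `residual_variance` per endogenous node, `effects` (long table of
#'   direct/indirect/total for every ancestor-descendant pair),
#'   `fit` (chi-square, df, GFI, CFI, RMSEA), `implied_cov`, `sample_cov`, `n`.
#' @export
fit_path_model <- function(data, spec) {
  stopifnot(inherits(spec, "path_spec"))
  nodes <- spec$nodes
  miss <- setdiff(nodes, names(data))
  if (length(miss)) {
    stop("fit_path_model: data is missing node column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  n_free <- nrow(spec$edges) + length(spec$endogenous) +
    length(spec$exogenous) * (length(spec$exogenous) + 1) / 2
  if (n <= n_free) {
    stop("fit_path_model: sample size must exceed the number of free parameters (",
         n_free, ")", call. = FALSE)
  }
  Z <- as.data.frame(lapply(data[nodes], standardize))
  p <- length(nodes)
  S <- stats::cov(Z)

  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  psi <- matrix(0, p, p, dimnames = list(nodes, nodes))
  exo <- spec$exogenous
  psi[exo, exo] <- S[exo, exo, drop = FALSE]

  coef_rows <- list()
  r2 <- resid_var <- stats::setNames(numeric(0), character(0))
  for (node in spec$endogenous) {
    parents <- spec$edges$from[spec$edges$to == node]
    m <- stats::lm(stats::reformulate(parents, response = node), data = Z)
    sm <- summary(m)
    co <- sm$coefficients[parents, , drop = FALSE]
    B[node, parents] <- co[, 1L]
    rss <- sum(stats::residuals(m)^2)
    psi[node, node] <- rss / (n - 1)  # same denominator as the sample covariance
    r2[node] <- sm$r.squared
    resid_var[node] <- psi[node, node]
    coef_rows[[node]] <- data.frame(
      from = parents, to = node, estimate = co[, 1L], se = co[, 2L],
      p_value = co[, 4L],
      significance_class = significance_class(co[, 4L]),
      stringsAsFactors = FALSE
    )
  }
  coefs <- do.call(rbind, coef_rows)
  rownames(coefs) <- NULL

  IB <- solve(diag(p) - B)
  implied <- IB %*% psi %*% t(IB)
  dimnames(implied) <- list(nodes, nodes)

  df <- p * (p + 1) / 2 - n_free
  S_base <- diag(diag(S)); dimnames(S_base) <- dimnames(S)
  f_base <- determinant(S_base, logarithm = TRUE)$modulus[1] +
    sum(diag(as.matrix(S) %*% solve(S_base))) -
    determinant(as.matrix(S), logarithm = TRUE)$modulus[1] - p
  chi2_base <- (n - 1) * max(f_base, 0)
  df_base <- p * (p + 1) / 2 - p
  fit <- fit_indices(as.matrix(S), implied, n = n, df = df,
                     baseline_chi_square = chi2_base, baseline_df = df_base)

  total <- IB - diag(p)
  eff_rows <- list()
  for (src in nodes) {
    for (tgt in nodes) {
      tot <- total[tgt, src]
      dir <- B[tgt, src]
      if (tot == 0 && dir == 0) next
      eff_rows[[length(eff_rows) + 1L]] <- data.frame(
        source = src, target = tgt, direct = dir,
        indirect = tot - dir, total = tot, stringsAsFactors = FALSE
      )
    }
  }
  effects <- do.call(rbind, eff_rows)
  rownames(effects) <- NULL

  out <- list(coefficients = coefs, r_squared = r2, residual_variance = resid_var,
              effects = effects, fit = fit, implied_cov = implied,
              sample_cov = as.matrix(S), n = n,
              baseline = list(chi_square = chi2_base, df = df_base),
              spec = spec)
  class(out) <- "path_fit"
  out
}

#' Build block composites and run the path model
#'
#' Convenience wrapper: computes per-population first-PC composite scores for
#' the climate, soil, morphology and nutrient blocks, joins population-mean
#' tolerance indices, and fits the path model.
#'
#' @param traits Trait table with morphology/nutrient columns and the indices.
#' @param sites Site table with climate and soil columns.
#' @param spec A [path_spec()] (default [default_path_spec()]).
#' @param blocks Named list mapping composite names to source columns.
#' @return A `path_fit` with an extra element `composites` (the per-population
#'   score table).
#' @export
path_analysis <- function(traits, sites, spec = default_path_spec(),
                          blocks = list(
                            climate = c("MAT", "MAP"),
                            soil = c("SOC", "AN", "AP", "pH"),
                            morphology = c("length", "width", "LWR", "TGW"),
                            nutrients = c("CSP", "CSS", "CS", "CCF"))) {
  trait_cols <- setdiff(names(traits), c("population_id", "replicate"))
  pm <- stats::aggregate(traits[trait_cols],
                         by = list(population_id = traits$population_id), FUN = mean)
  merged <- merge(pm, sites, by = "population_id")
  comp <- data.frame(population_id = merged$population_id)
  for (bn in names(blocks)) {
    comp[[bn]] <- block_pca_scores(merged[blocks[[bn]]])$scores
  }
  for (idx in c("GDTI", "GCTI", "GSTI")) {
    if (idx %in% names(merged)) comp[[idx]] <- merged[[idx]]
  }
  fit <- fit_path_model(comp, spec)
  fit$composites <- comp
  fit
}
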