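# Random-intercept linear mixed model fitted by profiling the REML criterion
# over the variance ratio lambda = sigma^2_group / sigma^2_residual. Because
# the random design is a group indicator, V = I + lambda Z Z' is block
# diagonal and V^{-1}, log|V| and all GLS quantities have closed group-wise
# forms, so the fit reduces to a bounded 1-D optimization over log(lambda).

# apply V(lambda)^{-1} to the columns of M, groups as integer index list
vinv_mult <- function(M, group_rows, lambda) {
  M <- as.matrix(M)
  out <- M
  for (rows in group_rows) {
    ni <- length(rows)
    shrink <- lambda / (1 + lambda * ni)
    cs <- colSums(M[rows, , drop = FALSE])
    out[rows, ] <- M[rows, , drop = FALSE] - rep(shrink * cs, each = ni)
  }
  out
}

# GLS fit and REML criterion at a fixed lambda
reml_profile_at <- function(lambda, y, X, group_rows) {
  n <- length(y)
  p <- ncol(X)
  ViX <- vinv_mult(X, group_rows, lambda)
  Viy <- vinv_mult(matrix(y), group_rows, lambda)
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(ViX, y))
  r <- y - X %*% beta
  quad <- sum(r * vinv_mult(r, group_rows, lambda))
  sigma2 <- quad / (n - p)
  logdetV <- sum(log(1 + lambda * lengths(group_rows)))
  crit <- (n - p) * log(sigma2) + logdetV + determinant(XtViX, logarithm = TRUE)$modulus[1]
  list(criterion = crit, beta = drop(beta), sigma2_resid = sigma2,
       XtViX = XtViX)
}

#' Random-intercept linear mixed model by profile REML
#'
#' Fits \eqn{y = X\beta + b_{group} + e} with a single random intercept per
#' group, \eqn{b \sim N(0, \sigma^2_g)}, \eqn{e \sim N(0, \sigma^2_e)}. The
#' REML criterion is profiled over the variance ratio
#' \eqn{\lambda = \sigma^2_g / \sigma^2_e}: at each \eqn{\lambda} the fixed
#' effects are the GLS solution and the residual variance has a closed form,
#' leaving a bounded scalar optimization over \eqn{\log\lambda} (plus an
#' explicit check of the \eqn{\lambda = 0} boundary). A boundary fit is
#' reported as `random_intercept_variance = 0` and flagged `singular`, never
#' as an error. Fixed-effect p values use t statistics with
#' \eqn{n - p - g + 1} residual degrees of freedom, where p counts fixed-effect
#' columns (intercept included) and g the number of groups; this approximates
#' the Satterthwaite-based output of reference mixed-model software.
#'
#' @param y Response vector.
#' @param X Fixed-effect design (data frame or matrix, no intercept column;
#'   one is added).
#' @param groups Grouping factor (population ids).
#' @param lambda_bounds Search interval for \eqn{\lambda} (default
#'   `c(1e-8, 1e8)`).
#' @return List of class `lmm_fit`: `fixed_effects`, `se`, `t_values`,
#'   `p_values`, `df_residual`, `random_intercept_variance`,
#'   `residual_variance`, `lambda`, `reml_criterion` (-2 profiled restricted
#'   log-likelihood up to a constant), `singular`, `marginal_r_squared`,
#'   plus the inputs needed for effect decomposition.
#' @export
fit_random_intercept_lmm <- function(y, X, groups, lambda_bounds = c(1e-8, 1e8)) {
  X <- as.data.frame(X)
  groups <- factor(groups)
  n <- length(y)
  if (nlevels(groups) < 2L) stop("fit_random_intercept_lmm: need >= 2 groups", call. = FALSE)
  if (max(table(groups)) < 2L) {
    stop("fit_random_intercept_lmm: need >= 2 observations in at least one group",
         call. = FALSE)
  }
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  if (qr(Xm)$rank < ncol(Xm)) {
    stop("fit_random_intercept_lmm: fixed-effect design is rank deficient", call. = FALSE)
  }
  group_rows <- split(seq_len(n), groups)

  obj <- function(loglam) reml_profile_at(exp(loglam), y, Xm, group_rows)$criterion
  opt <- stats::optimize(obj, interval = log(lambda_bounds), tol = 1e-9)
  at_zero <- reml_profile_at(0, y, Xm, group_rows)
  if (at_zero$criterion <= opt$objective) {
    lambda <- 0
    best <- at_zero
    crit <- at_zero$criterion
  } else {
    lambda <- exp(opt$minimum)
    best <- reml_profile_at(lambda, y, Xm, group_rows)
    crit <- opt$objective
  }
  sigma2_e <- best$sigma2_resid
  sigma2_g <- lambda * sigma2_e
  # treat a lambda pinned at the lower search bound as a boundary (singular) fit
  singular <- lambda <= lambda_bounds[1] * (1 + 1e-6)
  if (singular) {
    lambda <- 0
    best <- at_zero
    crit <- at_zero$criterion
    sigma2_e <- best$sigma2_resid
    sigma2_g <- 0
  }

  p <- ncol(Xm)
  g <- nlevels(groups)
  vc <- sigma2_e * solve(best$XtViX)
  se <- sqrt(diag(vc))
  tval <- best$beta / se
  df_res <- max(n - p - g + 1L, 1L)
  pval <- 2 * stats::pt(abs(tval), df = df_res, lower.tail = FALSE)

  yhat_fixed <- drop(Xm %*% best$beta)
  var_fixed <- stats::var(yhat_fixed) * (n - 1) / n
  r2_marg <- var_fixed / (var_fixed + sigma2_g + sigma2_e)

  fit <- list(
    fixed_effects = stats::setNames(best$beta, colnames(Xm)),
    se = stats::setNames(se, colnames(Xm)),
    t_values = stats::setNames(tval, colnames(Xm)),
    p_values = stats::setNames(pval, colnames(Xm)),
    df_residual = df_res,
    random_intercept_variance = sigma2_g,
    residual_variance = sigma2_e,
    lambda = lambda,
    reml_criterion = crit,
    singular = singular,
    marginal_r_squared = r2_marg,
    n = n, n_groups = g,
    y = y, X = X, groups = groups
  )
  class(fit) <- "lmm_fit"
  fit
}

#' Block-wise decomposition of the variation explained by fixed effects
#'
#' Partitions the marginal R-squared of a random-intercept fit between two
#' predictor blocks (e.g. seed morphology vs seed nutrient traits) by a
#' commonality-style partition: each block receives its unique contribution
#' (full-model R-squared minus the R-squared of the model without it) plus
#' half of the portion common to both blocks, and the two shares are
#' normalized to sum to 1. The alternative `"abs_coef"` method divides the
#' blocks' summed absolute standardized coefficients instead.
#'
#' @param fit A fit from [fit_random_intercept_lmm()].
#' @param blocks Named list of two character vectors of predictor column
#'   names, e.g. `list(morphology = ..., nutrients = ...)`.
#' @param method `"commonality"` (default) or `"abs_coef"`.
#' @return Named numeric vector of block shares in `[0, 1]`, summing to 1
#'   (attribute `"marginal_r_squared"` carries the full-model value).
#' @export
block_effect_decomposition <- function(fit, blocks, method = c("commonality", "abs_coef")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "lmm_fit"))
  if (length(blocks) != 2L || any(!lengths(blocks))) {
    stop("block_effect_decomposition: need exactly two non-empty blocks", call. = FALSE)
  }
  miss <- setdiff(unlist(blocks), names(fit$X))
  if (length(miss)) {
    stop("block_effect_decomposition: predictors not in the fit: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  nm <- names(blocks)
  if (method == "abs_coef") {
    bz <- vapply(blocks, function(cols) {
      sum(abs(fit$fixed_effects[cols] * vapply(fit$X[cols], stats::sd, 0)))
    }, 0)
    shares <- bz / sum(bz)
    attr(shares, "marginal_r_squared") <- fit$marginal_r_squared
    return(shares)
  }
  r2_of <- function(cols) {
    fit_random_intercept_lmm(fit$y, fit$X[cols], fit$groups)$marginal_r_squared
  }
  r2_full <- fit$marginal_r_squared
  r2_a <- r2_of(blocks[[1L]])
  r2_b <- r2_of(blocks[[2L]])
  unique_a <- max(r2_full - r2_b, 0)
  unique_b <- max(r2_full - r2_a, 0)
  common <- max(r2_a + r2_b - r2_full, 0)
  raw <- c(unique_a + common / 2, unique_b + common / 2)
  if (sum(raw) == 0) raw <- c(0.5, 0.5)
  shares <- stats::setNames(raw / sum(raw), nm)
  attr(shares, "marginal_r_squared") <- r2_full
  shares
}

#' Mixed-model panel for the three tolerance indices
#'
#' Fits one random-intercept model per tolerance index (GDTI, GCTI, GSTI) on
#' the eight seed-attribute fixed effects, with populations as the random
#' intercept, and decomposes the explained variation between the morphology
#' and nutrient blocks.
#'
#' @param traits Trait table containing the predictor columns, the index
#'   columns and `population_id`.
#' @param responses Index columns to model (default the three indices).
#' @param morphology,nutrients Column names of the two predictor blocks.
#' @param method Decomposition method, see [block_effect_decomposition()].
#' @return Named list of per-response lists with elements `fit` (the
#'   `lmm_fit`) and `block_shares`.
#' @export
mixed_effects_panel <- function(traits, responses = c("GDTI", "GCTI", "GSTI"),
                                morphology = c("length", "width", "LWR", "TGW"),
                                nutrients = c("CSP", "CSS", "CS", "CCF"),
                                method = "commonality") {
  preds <- c(morphology, nutrients)
  miss <- setdiff(c(preds, responses, "population_id"), names(traits))
  if (length(miss)) {
    stop("mixed_effects_panel: traits is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- lapply(responses, function(resp) {
    fit <- fit_random_intercept_lmm(traits[[resp]], traits[preds], traits$population_id)
    shares <- block_effect_decomposition(
      fit, list(morphology = morphology, nutrients = nutrients), method = method)
    list(fit = fit, block_shares = shares)
  })
  stats::setNames(out, responses)
}
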