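test_that("block PCA scores reduce to the z-scored variable for one column", {
  set.seed(1)
  v <- rnorm(12, 5, 2)
  res <- block_pca_scores(data.frame(v = v))
  expect_equal(res$scores, standardize(v), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$explained_variance, 1)
})

test_that("two perfectly correlated variables load on one component", {
  set.seed(2)
  a <- rnorm(15)
  res <- block_pca_scores(data.frame(a = a, b = 3 * a + 2))
  expect_equal(res$explained_variance, 1, tolerance = 1e-12)
})

test_that("scores match an eigendecomposition-by-hand oracle after orientation", {
  X <- matrix(c(1.0, 2.1, 0.7, 3.2, 2.8, 1.5,
                0.4, 1.9, 0.9, 2.7, 3.1, 1.2,
                2.2, 0.8, 1.6, 0.5, 1.1, 2.9), ncol = 3)
  colnames(X) <- c("u", "v", "w")
  res <- block_pca_scores(X)
  Z <- scale(X)
  ev <- eigen(cor(X), symmetric = TRUE)
  load1 <- ev$vectors[, 1]
  if (sum(load1) < 0 || (sum(load1) == 0 && load1[1] < 0)) load1 <- -load1
  expect_equal(unname(res$scores), unname(drop(Z %*% load1)), tolerance = 1e-10)
  expect_equal(res$explained_variance, ev$values[1] / 3, tolerance = 1e-10)
  expect_gt(sum(res$loadings), 0)
})

test_that("constant columns and missing values are rejected by name", {
  X <- data.frame(a = 1:5, b = rep(2, 5))
  expect_error(block_pca_scores(X), "b")
  X2 <- data.frame(a = c(1, NA, 3), b = c(2, 1, 4), c = c(0, 1, 2))
  expect_error(block_pca_scores(X2), "missing")
})

test_that("path specs validate acyclicity and classify nodes", {
  spec <- default_path_spec()
  expect_setequal(spec$exogenous, c("climate", "soil"))
  expect_setequal(spec$endogenous, c("morphology", "nutrients", "GDTI", "GCTI", "GSTI"))
  expect_error(path_spec(data.frame(from = c("a", "b"), to = c("b", "a"))), "cycle")
})

test_that("the saturated recursive model reproduces the sample covariance", {
  set.seed(3)
  spec <- saturated_path_spec()
  dat <- simulate_path_data(default_path_spec(), list("climate->GDTI" = 0.5), n = 60,
                            exo_cor = 0.3)
  fit <- fit_path_model(dat, spec)
  expect_lte(fit$fit$chi_square, 1e-8)
  expect_equal(fit$fit$df, 0)
  expect_equal(fit$fit$rmsea, 0)
  expect_equal(fit$fit$gfi, 1, tolerance = 1e-8)
  expect_equal(fit$fit$cfi, 1, tolerance = 1e-8)
  expect_equal(fit$implied_cov, fit$sample_cov, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a generated causal chain yields the product-of-paths indirect effect", {
  set.seed(4)
  spec <- path_spec(data.frame(from = c("climate", "nutrients"),
                               to = c("nutrients", "GCTI")))
  dat <- simulate_path_data(spec, list("climate->nutrients" = 0.7,
                                       "nutrients->GCTI" = 0.6), n = 2000)
  fit <- fit_path_model(dat, spec)
  eff <- fit$effects
  row <- eff[eff$source == "climate" & eff$target == "GCTI", ]
  expect_equal(row$direct, 0)
  expect_lt(abs(row$indirect - 0.42), 0.05)
  expect_equal(row$total, row$direct + row$indirect, tolerance = 1e-10)
})

test_that("path coefficients equal the per-equation OLS oracle on a small fixture", {
  set.seed(5)
  spec <- default_path_spec()
  dat <- simulate_path_data(spec, list("soil->morphology" = 0.6,
                                       "climate->nutrients" = 0.5,
                                       "morphology->GDTI" = 0.5), n = 21, exo_cor = 0.4)
  fit <- fit_path_model(dat, spec)
  Z <- as.data.frame(lapply(dat, standardize))
  for (node in spec$endogenous) {
    parents <- spec$edges$from[spec$edges$to == node]
    co <- oracle_ols(Z[[node]], Z[parents])
    got <- fit$coefficients[fit$coefficients$to == node, ]
    expect_equal(got$estimate[match(parents, got$from)], unname(co[-1]),
                 tolerance = 1e-10)
    # per-equation R2 equals the OLS R2
    expect_equal(unname(fit$r_squared[node]),
                 summary(lm(Z[[node]] ~ ., data = Z[parents]))$r.squared,
                 tolerance = 1e-10)
  }
  # total = direct + indirect for every pair
  expect_equal(fit$effects$total, fit$effects$direct + fit$effects$indirect,
               tolerance = 1e-10)
})

test_that("total effects match reduced-form regressions on linear-Gaussian data", {
  set.seed(6)
  spec <- default_path_spec()
  coefs <- list("soil->morphology" = 0.5, "climate->nutrients" = 0.5,
                "soil->nutrients" = 0.3, "morphology->GDTI" = 0.5,
                "climate->GDTI" = 0.3)
  dat <- simulate_path_data(spec, coefs, n = 2000)
  fit <- fit_path_model(dat, spec)
  # with independent exogenous nodes, the reduced-form coefficient of GDTI on
  # soil is the total effect along soil -> morphology -> GDTI
  rf <- oracle_ols(standardize(dat$GDTI),
                   data.frame(climate = standardize(dat$climate),
                              soil = standardize(dat$soil)))
  tot <- fit$effects[fit$effects$source == "soil" & fit$effects$target == "GDTI", "total"]
  expect_lt(abs(tot - unname(rf["soil"])), 0.05)
})

test_that("fit indices behave at their analytic limits", {
  set.seed(7)
  S <- cov(matrix(rnorm(80), 20, 4))
  f <- fit_indices(S, S, n = 20, df = 2, baseline_chi_square = 50, baseline_df = 6)
  expect_equal(f$chi_square, 0)
  expect_equal(f$gfi, 1, tolerance = 1e-10)
  expect_equal(f$cfi, 1)
  expect_equal(f$rmsea, 0)

  # hand determinant/trace oracle on a 3x3 fixture
  S3 <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.3, 0.2, 0.3, 1), 3)
  Sig3 <- diag(diag(S3))
  f_ml_hand <- log(det(Sig3)) + sum(diag(S3 %*% solve(Sig3))) - log(det(S3)) - 3
  f3 <- fit_indices(S3, Sig3, n = 50, df = 3, baseline_chi_square = 49 * f_ml_hand,
                    baseline_df = 3)
  expect_equal(f3$chi_square, 49 * f_ml_hand, tolerance = 1e-8)
  expect_gt(f3$chi_square, 0) # independence model on correlated data misfits
  expect_equal(f3$cfi, 0, tolerance = 1e-10) # the baseline scored against itself
  expect_error(fit_indices(S3, matrix(0, 3, 3), 50, 3, 1, 1), "positive definite")
})

test_that("chi-square and RMSEA are invariant to row relabeling", {
  set.seed(8)
  spec <- default_path_spec()
  dat <- simulate_path_data(spec, list("soil->morphology" = 0.6), n = 40)
  f1 <- fit_path_model(dat, spec)
  f2 <- fit_path_model(dat[sample(nrow(dat)), ], spec)
  expect_equal(f1$fit$chi_square, f2$fit$chi_square, tolerance = 1e-9)
  expect_equal(f1$fit$rmsea, f2$fit$rmsea, tolerance = 1e-9)
})

test_that("the composite pipeline runs on simulated study data", {
  sim <- demo_sim(seed = 71)
  fit <- path_analysis(sim$traits, sim$sites)
  expect_s3_class(fit, "path_fit")
  expect_true(all(c("climate", "soil", "morphology", "nutrients") %in%
                    names(fit$composites)))
  expect_true(all(abs(vapply(fit$composites[c("climate", "soil", "morphology",
                                              "nutrients")], mean, 0)) < 1e-10))
  expect_true(all(fit$r_squared >= 0 & fit$r_squared <= 1))
  expect_gte(fit$fit$rmsea, 0)
})

test_that("undersized samples are rejected", {
  spec <- default_path_spec()
  set.seed(9)
  dat <- simulate_path_data(spec, list(), n = 10)
  expect_error(fit_path_model(dat, spec), "free parameters")
})
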