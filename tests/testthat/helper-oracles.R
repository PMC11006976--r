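# Independent flat-loop / closed-form oracles used to cross-check the
# package's vectorised implementations. Deliberately written in the dumbest
# possible style.

# germination index and tolerance indices by explicit loops
oracle_gi <- function(daily_counts) {
  total <- 0
  for (d in seq_along(daily_counts)) total <- total + daily_counts[d] / d
  total
}

oracle_indices <- function(trials, T1 = 25) {
  out <- NULL
  for (pop in unique(trials$population_id)) {
    for (r in unique(trials$replicate[trials$population_id == pop])) {
      vals <- c(GDTI = NA, GCTI = NA, GSTI = NA)
      for (ex in c("drought", "cold", "saline")) {
        acc <- 0
        for (lv in 1:5) {
          d <- trials[trials$population_id == pop & trials$replicate == r &
                        trials$experiment == ex & trials$level_index == lv, ]
          d <- d[order(d$day), ]
          gi <- oracle_gi(d$n_germinated)
          w <- if (ex == "drought") 1 + abs(d$level_value[1]) else
            if (ex == "cold") T1 / d$level_value[1] else
              if (lv == 1) 1 else d$level_value[1] / 10
          acc <- acc + gi * w
        }
        vals[c(drought = "GDTI", cold = "GCTI", saline = "GSTI")[ex]] <- acc / 5
      }
      out <- rbind(out, data.frame(population_id = pop, replicate = r,
                                   GDTI = vals[["GDTI"]], GCTI = vals[["GCTI"]],
                                   GSTI = vals[["GSTI"]]))
    }
  }
  out[order(out$population_id, out$replicate), ]
}

# OLS by normal equations
oracle_ols <- function(y, X) {
  Xm <- cbind(1, as.matrix(X))
  solve(t(Xm) %*% Xm, t(Xm) %*% y)[, 1]
}

# one-way ANOVA from explicit sums of squares
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  dfb <- length(unique(groups)) - 1
  dfw <- length(values) - length(unique(groups))
  F <- (ssb / dfb) / (ssw / dfw)
  list(df_between = dfb, df_within = dfw, f_statistic = F,
       p_value = pf(F, dfb, dfw, lower.tail = FALSE))
}

# dense-matrix REML criterion for the random-intercept model (independent of
# the package's group-wise shortcut)
oracle_reml_criterion <- function(lambda, y, Xm, groups) {
  groups <- factor(groups)
  n <- length(y)
  Z <- stats::model.matrix(~ groups - 1)
  V <- diag(n) + lambda * Z %*% t(Z)
  Vi <- solve(V)
  beta <- solve(t(Xm) %*% Vi %*% Xm, t(Xm) %*% Vi %*% y)
  r <- y - Xm %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / (n - ncol(Xm))
  (n - ncol(Xm)) * log(s2) + determinant(V, logarithm = TRUE)$modulus[1] +
    determinant(t(Xm) %*% Vi %*% Xm, logarithm = TRUE)$modulus[1]
}

# small deterministic demo dataset shared across tests
demo_sim <- function(seed = 42, ...) {
  simulate_dataset(simulation_config(random_seed = seed, ...))
}
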