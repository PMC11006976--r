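test_that("germination index is the speed-weighted count", {
  expect_equal(germination_index(10), 10.0)
  expect_equal(germination_index(c(0, 0, 0)), 0.0)
  expect_equal(germination_index(c(5, 3, 2)), 5 / 1 + 3 / 2 + 2 / 3, tolerance = 1e-12)
  expect_equal(germination_index(c(5, 3, 2)), 7.1667, tolerance = 1e-4)
})

test_that("invalid dish records are rejected with the dish named", {
  expect_error(germination_index(c(5, -1), dish_id = "P01/drought/2/1"),
               "P01/drought/2/1")
  expect_error(germination_index(c(30, 30), seeds_per_dish = 50), "exceeds")
  expect_error(germination_index(numeric(0)), "at least one day")
})

test_that("treatment weights match their closed forms on the full grids", {
  scheme <- default_treatment_scheme()
  expect_equal(drought_weight(scheme$drought_levels), c(1, 1.3, 1.6, 1.9, 2.2))
  expect_equal(cold_weight(scheme$cold_levels, T1 = 25), c(1, 1.25, 25 / 15, 2.5, 5))
  expect_equal(saline_weight(scheme$saline_levels, 1:5), c(1, 5, 10, 15, 20))
  # controls carry weight exactly 1
  expect_identical(drought_weight(0), 1)
  expect_identical(cold_weight(25, 25), 1)
  expect_identical(saline_weight(0, 1), 1)
})

test_that("weight preconditions are enforced", {
  expect_error(drought_weight(0.1), "<= 0 MPa")
  expect_error(cold_weight(0, 25), "> 0 degrees C")
  expect_error(cold_weight(-5, 25), "> 0")
  expect_error(saline_weight(100, 6), "1..5")
  expect_error(saline_weight(0, 2), "positive concentration")
})

test_that("tolerance index averages weighted GI over the five levels", {
  expect_equal(tolerance_index(rep(1, 5), c(1, 1.3, 1.6, 1.9, 2.2)), 1.6)
  expect_equal(tolerance_index(rep(0, 5), c(1, 5, 10, 15, 20)), 0)
  expect_equal(tolerance_index(rep(1, 5), c(1, 1.25, 25 / 15, 2.5, 5)),
               (1 + 1.25 + 25 / 15 + 2.5 + 5) / 5, tolerance = 1e-12)
  expect_equal(tolerance_index(rep(1, 5), c(1, 1.25, 25 / 15, 2.5, 5)), 2.2833,
               tolerance = 1e-3)
  # literal saline reading drops the control's GI term (= GI_1/5 here)
  expect_equal(tolerance_index(rep(1, 5), c(1, 5, 10, 15, 20), gsti_literal = TRUE),
               tolerance_index(rep(1, 5), c(1, 5, 10, 15, 20)) - 1 / 5)
  expect_error(tolerance_index(rep(1, 4), rep(1, 5)), "exactly 5")
  expect_error(tolerance_index(rep(1, 5), c(0.5, 1, 1, 1, 1)), ">= 1")
})

make_full_trials <- function(pop = "P01", counts = c(50)) {
  scheme <- default_treatment_scheme()
  levels_of <- list(drought = scheme$drought_levels, cold = scheme$cold_levels,
                    saline = scheme$saline_levels)
  do.call(rbind, lapply(c("drought", "cold", "saline"), function(ex) {
    do.call(rbind, lapply(1:5, function(lv) {
      do.call(rbind, lapply(1:3, function(r) {
        data.frame(population_id = pop, experiment = ex, level_index = lv,
                   level_value = levels_of[[ex]][lv], replicate = r,
                   day = seq_along(counts), n_germinated = counts,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
}

test_that("full germination on day 1 at every level gives the hand-computed indices", {
  trials <- make_full_trials(counts = 50)
  idx <- compute_indices(trials)
  # GI = 50 at every level; indices = 50 * (sum of weights) / 5
  expect_equal(unique(idx$GDTI), 50 * (1 + 1.3 + 1.6 + 1.9 + 2.2) / 5)
  expect_equal(unique(idx$GCTI), 50 * (1 + 1.25 + 25 / 15 + 2.5 + 5) / 5)
  expect_equal(unique(idx$GSTI), 50 * (1 + 5 + 10 + 15 + 20) / 5)
  expect_equal(nrow(idx), 3L) # one row per replicate
})

test_that("zero germination everywhere yields all-zero indices", {
  trials <- make_full_trials(counts = c(0, 0, 0))
  idx <- compute_indices(trials)
  expect_true(all(idx$GDTI == 0 & idx$GCTI == 0 & idx$GSTI == 0))
})

test_that("a missing treatment level is a structured error", {
  trials <- make_full_trials(counts = 50)
  trials <- trials[!(trials$experiment == "cold" & trials$level_index == 3), ]
  expect_error(compute_indices(trials), "missing treatment level")
  expect_error(compute_indices(trials), "cold")
})

test_that("indices match the independent flat-loop oracle on simulated data", {
  sim <- demo_sim(seed = 11)
  got <- compute_indices(sim$trials)
  want <- oracle_indices(sim$trials)
  expect_equal(got$GDTI, want$GDTI, tolerance = 1e-9)
  expect_equal(got$GCTI, want$GCTI, tolerance = 1e-9)
  expect_equal(got$GSTI, want$GSTI, tolerance = 1e-9)
})

test_that("index properties: scale equivariance, weight floor, monotonicity, control-only", {
  set.seed(5)
  for (i in 1:20) {
    gi <- runif(5, 0, 40)
    w <- drought_weight(default_treatment_scheme()$drought_levels)
    ti <- tolerance_index(gi, w)
    # scale equivariance
    expect_equal(tolerance_index(3 * gi, w), 3 * ti, tolerance = 1e-12)
    # weight floor: index >= mean GI
    expect_gte(ti, sum(gi) / 5 - 1e-12)
    # monotonicity: raising one level's GI never lowers the index
    j <- sample(1:5, 1)
    gi2 <- gi; gi2[j] <- gi2[j] + 1
    expect_gte(tolerance_index(gi2, w), ti)
  }
  # control-only germination: index = GI_1 / 5
  expect_equal(tolerance_index(c(12, 0, 0, 0, 0), c(1, 5, 10, 15, 20)), 12 / 5)
})

test_that("population_mean aggregation averages GI before weighting", {
  t1 <- make_full_trials(counts = c(10, 5))
  t2 <- make_full_trials(counts = c(20, 10))
  t2$replicate <- t2$replicate + 3L
  trials <- rbind(t1, t2)
  trials <- trials[trials$replicate %in% c(1, 4), ]
  pm <- compute_indices(trials, aggregation = "population_mean")
  pr <- compute_indices(trials, aggregation = "per_replicate")
  expect_equal(nrow(pm), 1L)
  expect_true(is.na(pm$replicate))
  # linear weighting: mean of per-replicate indices equals the index of mean GI
  expect_equal(pm$GDTI, mean(pr$GDTI), tolerance = 1e-12)
})
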