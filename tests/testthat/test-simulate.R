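test_that("default design yields 31 villages, 620 participants, 160/160/300 arms", {
  trial <- fixture_trial
  expect_equal(length(unique(trial$cluster_id)), 31)
  expect_equal(nrow(trial), 620)
  counts <- table(trial$arm)
  expect_equal(unname(counts[c("group", "combined", "control")]),
               c(160, 160, 300), ignore_attr = TRUE)
})

test_that("arm is constant within every cluster", {
  per_cluster <- tapply(as.character(fixture_trial$arm),
                        fixture_trial$cluster_id,
                        function(x) length(unique(x)))
  expect_true(all(per_cluster == 1))
})

test_that("the same seed reproduces the dataset exactly", {
  a <- simulate_trial(sim_config(seed = 99))
  b <- simulate_trial(sim_config(seed = 99))
  expect_identical(a, b)
  c2 <- simulate_trial(sim_config(seed = 100))
  expect_false(identical(a$fci_activities, c2$fci_activities))
})

test_that("loss to follow-up is close to the configured 7.6% rate", {
  lost <- vapply(1:40, function(s) {
    mean(!simulate_trial(sim_config(seed = 200 + s, items = FALSE))$followed_up)
  }, numeric(1))
  # 40 x 620 Bernoulli draws: MC standard error ~0.0017
  expect_lt(abs(mean(lost) - 0.076), 0.006)
})

test_that("lost participants carry no endline responses", {
  trial <- fixture_trial_items
  lost <- !trial$followed_up
  expect_true(all(is.na(trial$cesd[lost])))
  expect_true(all(vapply(trial$fci_items[lost], is.null, logical(1))))
})

test_that("generated scores respect their documented supports", {
  trial <- fixture_trial
  in_range <- function(x, lo, hi) all(x >= lo & x <= hi, na.rm = TRUE)
  expect_true(in_range(trial$fci_activities, 0, 6))
  expect_true(in_range(trial$fci_materials, 0, 6))
  expect_true(in_range(trial$fci_observation, 0, 11))
  expect_true(in_range(trial$cesd, 0, 60))
  expect_true(in_range(trial$asqi_communication, 0, 60))
  expect_true(all(trial$asqi_communication %% 5 == 0, na.rm = TRUE))
  expect_true(in_range(trial$child_age_months, 4, 26))
  expect_true(all(is.na(trial$cdi_expressive[trial$child_age_months <= 9])))
})

test_that("configuration validation names the offending field", {
  expect_error(sim_config(icc = 1.2), "icc")
  expect_error(sim_config(attrition_rate = -0.1), "attrition_rate")
  expect_error(sim_config(residual_sd = c(cesd = -1)), "residual_sd")
  expect_error(sim_config(outcome_effects = list(nonesuch = c(group = 1))),
               "outcome_effects")
})

test_that("ANOVA ICC estimate recovers the generating value", {
  # large design: 200 clusters of 20 so the estimator's own error is small
  big_plan <- tibble::tibble(stratum = "A",
                             arm = c("group", "combined", "control"),
                             n_clusters = c(67L, 67L, 66L))
  big <- simulate_trial(sim_config(clusters = big_plan, icc = 0.20,
                                   attrition_rate = 0, seed = 31,
                                   items = FALSE))
  expect_lt(abs(estimate_icc(big, "cesd") - 0.20), 0.05)

  null <- simulate_trial(sim_config(icc = 0, seed = 32, items = FALSE))
  expect_lt(abs(estimate_icc(null, "cesd")), 0.06)
})

test_that("ICC is undefined for one cluster or constant outcomes", {
  d <- tibble::tibble(cluster_id = rep("v1", 10), y = rnorm(10))
  expect_error(estimate_icc(d, "y"), "fewer than 2 clusters")
  d2 <- tibble::tibble(cluster_id = rep(c("v1", "v2"), each = 5), y = 1)
  expect_error(estimate_icc(d2, "y"), "zero total variance")
})

test_that("null trials keep arm-wise outcome distributions exchangeable", {
  # with icc = 0 individual records are iid across arms, so the KS test
  # rejects at close to its nominal 5% rate across replicates
  rej <- vapply(1:60, function(s) {
    d <- simulate_trial(sim_config(icc = 0, seed = 400 + s, items = FALSE))
    ks <- suppressWarnings(stats::ks.test(
      d$cesd[d$arm == "group" & d$followed_up],
      d$cesd[d$arm == "control" & d$followed_up]))
    ks$p.value < 0.05
  }, logical(1))
  expect_lte(sum(rej), 10)  # P(X > 10 | Bin(60, 0.05)) < 1e-3
})

test_that("trial CSV round-trips without list columns", {
  path <- tempfile(fileext = ".csv")
  cfg_path <- tempfile(fileext = ".yaml")
  write_trial_csv(fixture_trial_items, path, cfg_path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 620)
  expect_false(any(c("fci_items", "cesd_items") %in% names(back)))
  cfg <- yaml::read_yaml(cfg_path)
  expect_equal(cfg$icc, 0.20)
  expect_equal(cfg$participants_per_cluster, 20)
})
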