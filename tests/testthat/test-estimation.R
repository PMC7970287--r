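test_that("unadjusted g-computation equals the raw arm contrast exactly", {
  trial <- fixture_trial
  est <- gcompute(trial, "fci_activities")$estimate
  raw <- mean(trial$fci_activities[trial$arm == "group"], na.rm = TRUE) -
    mean(trial$fci_activities[trial$arm == "control"], na.rm = TRUE)
  expect_equal(est, raw, tolerance = 1e-12)

  best <- gcompute(trial, "lead_knowledge", scale = "binary")$estimate
  praw <- mean(trial$lead_knowledge[trial$arm == "group"], na.rm = TRUE) -
    mean(trial$lead_knowledge[trial$arm == "control"], na.rm = TRUE)
  expect_equal(best, praw, tolerance = 1e-12)
})

test_that("linear g-computation with covariates equals the arm coefficient", {
  withr::with_seed(31, d <- random_two_arm_data())
  est <- gcompute(d, "y", covariates = c("x", "g"))$estimate
  fit <- lm(y ~ arm + x + g, data = droplevels(d))
  expect_equal(est, unname(coef(fit)["armgroup"]), tolerance = 1e-10)
})

test_that("g-computation matches the brute-force counterfactual oracle", {
  withr::with_seed(32, {
    for (i in 1:10) {
      d <- random_two_arm_data(binary = FALSE)
      expect_equal(gcompute(d, "y", covariates = c("x", "g"))$estimate,
                   oracle_gcompute(d, "y", "continuous", c("x", "g"),
                                   c("group", "control")),
                   tolerance = 1e-10)
      db <- random_two_arm_data(binary = TRUE)
      expect_equal(gcompute(db, "y", scale = "binary",
                            covariates = c("x", "g"))$estimate,
                   oracle_gcompute(db, "y", "binary", c("x", "g"),
                                   c("group", "control")),
                   tolerance = 1e-10)
    }
  })
})

test_that("logistic g-computation is not the arm coefficient (non-collapsibility)", {
  withr::with_seed(33, {
    d <- random_two_arm_data(n_clusters = 40, m = 30, binary = TRUE,
                             beta_x = 2.5, beta_arm = 1)
  })
  est <- gcompute(d, "y", scale = "binary", covariates = "x")$estimate
  fit <- glm(y ~ arm + x, data = droplevels(d), family = binomial())
  b <- coef(fit)
  conditional_rd <- plogis(b["(Intercept)"] + b["armgroup"]) - plogis(b["(Intercept)"])
  expect_gt(abs(est - unname(conditional_rd)), 0.01)
})

test_that("prescreen retains real predictors and orders candidates", {
  trial <- fixture_trial
  scr <- prescreen_covariates(trial, "fci_activities")
  expect_true(scr$retained[scr$candidate == "baseline_fci_activities"])
  expect_equal(scr$candidate, candidate_covariates("fci_activities", trial))

  # a perfect predictor is always retained
  d <- fixture_trial
  d$shadow <- d$cesd + rnorm(nrow(d), 0, 0.01)
  scr2 <- prescreen_covariates(d, "cesd", candidates = "shadow")
  expect_true(scr2$retained)

  empty <- prescreen_covariates(trial, "cesd", candidates = character(0))
  expect_equal(nrow(empty), 0)
})

test_that("cluster bootstrap honours determinism and degenerate estimators", {
  two <- fixture_trial[fixture_trial$arm %in% c("group", "control"),
                       c("cluster_id", "arm", "fci_activities")]
  const <- cluster_bootstrap(two, function(d) 1.23, B = 50, seed = 5)
  expect_equal(const$ci_low, 1.23)
  expect_equal(const$ci_high, 1.23)

  est_fn <- function(d) mean(d$fci_activities[d$arm == "group"], na.rm = TRUE) -
    mean(d$fci_activities[d$arm == "control"], na.rm = TRUE)
  a <- cluster_bootstrap(two, est_fn, B = 200, seed = 9)
  b <- cluster_bootstrap(two, est_fn, B = 200, seed = 9)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  c2 <- cluster_bootstrap(two, est_fn, B = 200, seed = 10)
  expect_false(identical(a$ci_low, c2$ci_low))

  expect_error(cluster_bootstrap(two, function(d) stop("boom"), B = 20,
                                 seed = 1),
               "replicate failures")
})

test_that("bootstrap resampling is stratified: arm cluster counts preserved", {
  two <- fixture_trial[fixture_trial$arm %in% c("group", "control"), ]
  probe <- function(d) {
    tab <- table(unique(d[c("cluster_id", "arm")])$arm)
    # resampled data repeats cluster ids; count rows per arm instead
    sum(d$arm == "group") * 1e-6 + length(unique(d$cluster_id[d$arm == "group"]))
  }
  reps <- attr(cluster_bootstrap(two, probe, B = 30, seed = 2), "replicates")
  # never more distinct group clusters than the 8 in the design
  expect_true(all(reps <= 8 + 160 * 1e-6 + 1e-9))
})

test_that("estimate converges to the generating effect as clusters grow", {
  big_plan <- tibble::tibble(stratum = "A",
                             arm = c("group", "control"),
                             n_clusters = c(100L, 100L))
  ests <- vapply(1:8, function(s) {
    cfg <- sim_config(clusters = big_plan, seed = 500 + s, items = FALSE,
                      bound_scales = FALSE,
                      outcome_effects = list(cesd = c(group = -2)))
    gcompute(simulate_trial(cfg), "cesd")$estimate
  }, numeric(1))
  # SE of one estimate ~ sd * sqrt(DE * 2/(100*20)) ~ 0.28; 8 reps -> 0.1
  expect_lt(abs(mean(ests) + 2), 0.3)
})

test_that("adjusted means with constant age equal raw arm means", {
  trial <- fixture_trial
  trial$child_age_months <- 12
  am <- adjusted_means(trial, "fci_observation", B = 50, seed = 4)
  raw <- tapply(trial$fci_observation, trial$arm, mean, na.rm = TRUE)
  expect_equal(am$mean, as.vector(raw[as.character(am$arm)]),
               tolerance = 1e-10)
  expect_equal(as.character(am$arm), c("control", "group", "combined"))
  expect_true(all(am$ci_low <= am$mean & am$mean <= am$ci_high))
})

test_that("Cohen's d reproduces the closed form and rejects zero spread", {
  expect_equal(cohens_d(5, 2, 50, 5, 2, 50)$d, 0)
  r <- cohens_d(6, 2, 40, 5, 2, 60)
  sp <- sqrt((39 * 4 + 59 * 4) / 98)
  expect_equal(r$d, 1 / sp)
  expect_error(cohens_d(1, 0, 10, 1, 0, 10), "pooled SD")
})

test_that("the pipeline reports two unadjusted-for-multiplicity comparisons", {
  trial <- fixture_trial
  specs <- dplyr::bind_rows(outcome_spec("fci_activities"),
                            outcome_spec("lead_knowledge", scale = "binary"))
  eff <- estimate_effects(trial, specs, B = 60, seed = 8)
  expect_s3_class(eff, "effect_estimates")
  expect_equal(nrow(eff), 4)  # 2 outcomes x 2 comparisons, no pooling
  expect_setequal(unique(eff$comparison),
                  c("group vs control", "combined vs control"))
  expect_true(all(eff$ci_low <= eff$estimate & eff$estimate <= eff$ci_high))
  eff2 <- estimate_effects(trial, specs, B = 60, seed = 8)
  expect_equal(as.data.frame(eff), as.data.frame(eff2))
  g <- glance(eff)
  expect_equal(g$n_outcomes, 2)
  expect_equal(g$n_comparisons, 4)
})

test_that("standardised outcomes are analysed on the z scale with exclusions", {
  trial <- fixture_trial
  s <- standardize_scores(trial, "asqi_communication")
  specs <- outcome_spec("asqi_communication", standardized = TRUE)
  eff <- estimate_effects(s, specs, B = 40, seed = 12)
  expect_equal(unique(eff$analysis_column), "asqi_communication_z")
  # z-scale estimates are in SD units
  expect_true(all(abs(eff$estimate) < 2))
})
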