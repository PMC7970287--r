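# Shared fixtures, built once per test run.

# a default-design trial with item-level responses
fixture_trial_items <- simulate_trial(sim_config(seed = 42))

# the same design without item generation (fast, for estimation tests)
fixture_trial <- simulate_trial(sim_config(seed = 42, items = FALSE))

# a small hand-made two-arm dataset generator for estimation oracles:
# clustered records with a numeric and a factor covariate
random_two_arm_data <- function(n_clusters = 8, m = 12, binary = FALSE,
                                beta_x = 1, beta_arm = 0.8) {
  cl <- paste0("c", seq_len(n_clusters))
  arm <- rep(c("control", "group"), length.out = n_clusters)
  d <- tibble::tibble(
    cluster_id = rep(cl, each = m),
    arm = factor(rep(arm, each = m), levels = c("control", "group", "combined")),
    x = rnorm(n_clusters * m),
    g = factor(sample(c("u", "v", "w"), n_clusters * m, replace = TRUE))
  )
  u <- rnorm(n_clusters, 0, 0.4)
  eta <- 0.2 + beta_arm * (d$arm == "group") + beta_x * d$x +
    0.5 * (d$g == "v") + u[match(d$cluster_id, cl)]
  d$y <- if (binary) rbinom(nrow(d), 1, plogis(eta)) else eta + rnorm(nrow(d))
  d
}

# Brute-force g-computation oracle, deliberately independent of the
# package internals: fit with lm()/glm(), overwrite every record's arm,
# predict with predict(), average, difference.
oracle_gcompute <- function(data, outcome, scale, covariates, comparison) {
  d <- data[data$arm %in% comparison, , drop = FALSE]
  d <- d[stats::complete.cases(d[c(outcome, "arm", covariates)]), , drop = FALSE]
  d$arm <- factor(as.character(d$arm), levels = c(comparison[2], comparison[1]))
  f <- stats::reformulate(c("arm", covariates), response = outcome)
  fit <- if (scale == "continuous") {
    stats::lm(f, data = d)
  } else {
    stats::glm(f, data = d, family = stats::binomial())
  }
  d1 <- d
  d1$arm <- factor(comparison[1], levels = levels(d$arm))
  d0 <- d
  d0$arm <- factor(comparison[2], levels = levels(d$arm))
  mean(stats::predict(fit, newdata = d1, type = "response")) -
    mean(stats::predict(fit, newdata = d0, type = "response"))
}

# named FCI response vector covering all three subscales
make_fci_items <- function(activities = 0, materials = 0, observation = 0) {
  dict <- instrument_dictionary("fci")
  v <- function(ids, k) stats::setNames(as.integer(seq_along(ids) <= k), ids)
  c(v(dict$activities, activities), v(dict$materials, materials),
    v(dict$observation, observation))
}

# word ids mirroring the shipped CDI dictionary layout
cdi_word_ids_test <- function(domain) {
  paste0(substr(domain, 1, 3), "_w", sprintf("%03d", 1:100))
}
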