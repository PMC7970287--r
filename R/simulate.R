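# Synthetic cluster-RCT generator.  Continuous outcomes follow a village
# random-intercept model y_ij = mu + beta_age * age_ij + effect[arm] +
# u_j + e_ij with u_j ~ N(0, rho * sigma^2), e_ij ~ N(0, (1 - rho) * sigma^2),
# then clipped/rounded to the instrument's documented support.  Binary
# outcomes use a logistic-normal random intercept with the ICC interpreted
# on the latent logistic scale.

#' Configuration for the synthetic trial generator
#'
#' Defines a three-arm (control / group / combined) cluster-randomised
#' trial.  Defaults reproduce the design of a two-subdistrict trial with
#' 31 village clusters allocated 5:5:8 and 3:3:7 (group, combined,
#' control), 20 participants per village, intracluster correlation 0.20,
#' endline child ages 4-26 months and 7.6% loss to follow-up.
#'
#' @param clusters Data frame with columns `stratum`, `arm`, `n_clusters`
#'   giving the allocation plan.  Default: stratum A 5/5/8 and stratum B
#'   3/3/7 for group/combined/control.
#' @param participants_per_cluster Positive integer, participants enrolled
#'   per village (default 20).
#' @param icc Intracluster correlation rho in `[0, 1)` (default 0.20).
#' @param outcome_effects Named list: outcome name -> named numeric vector
#'   of additive treatment effects (continuous outcomes, outcome scale) or
#'   log-odds shifts (binary outcomes) for arms `group` and `combined`.
#'   Outcomes not named get zero effects (a null trial).
#' @param residual_sd Named numeric overriding the catalogue residual SD
#'   (sigma, the non-age outcome SD) per continuous outcome.
#' @param age_range_months Length-2 numeric, endline child age support
#'   (default `c(4, 26)`).
#' @param attrition_rate Proportion lost to follow-up, completely at
#'   random (default 0.076).
#' @param items Logical; also generate item-level instrument responses
#'   (list-columns) consistent with the generated scores (default `TRUE`).
#' @param bound_scales Logical; clip and round continuous scores onto the
#'   instrument's documented support (default `TRUE`).  Set `FALSE` to
#'   keep the latent (uncensored) scores, e.g. for estimator-consistency
#'   experiments where ceiling censoring would attenuate an additive
#'   effect; requires `items = FALSE`.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' trial <- simulate_trial(cfg)
#' dplyr::count(trial, arm)
sim_config <- function(clusters = default_cluster_plan(),
                       participants_per_cluster = 20,
                       icc = 0.20,
                       outcome_effects = list(),
                       residual_sd = NULL,
                       age_range_months = c(4, 26),
                       attrition_rate = 0.076,
                       items = TRUE,
                       bound_scales = TRUE,
                       seed = NULL) {
  clusters <- as_tibble(clusters)
  stopifnot(all(c("stratum", "arm", "n_clusters") %in% names(clusters)))
  if (any(clusters$n_clusters <= 0)) {
    abort("invalid `clusters`: n_clusters must be positive")
  }
  if (!all(clusters$arm %in% trial_arms())) {
    abort("invalid `clusters`: arm must be one of control/group/combined")
  }
  if (!is.numeric(icc) || icc < 0 || icc >= 1) {
    abort("invalid `icc`: must lie in [0, 1)")
  }
  if (!is.numeric(attrition_rate) || attrition_rate < 0 || attrition_rate >= 1) {
    abort("invalid `attrition_rate`: must lie in [0, 1)")
  }
  if (participants_per_cluster < 1) {
    abort("invalid `participants_per_cluster`: must be >= 1")
  }
  if (!is.null(residual_sd) && any(residual_sd <= 0)) {
    abort("invalid `residual_sd`: all values must be > 0")
  }
  if (length(age_range_months) != 2 || diff(age_range_months) <= 0) {
    abort("invalid `age_range_months`: need an increasing length-2 range")
  }
  if (isTRUE(items) && !isTRUE(bound_scales)) {
    abort("invalid `items`: item-level responses require bound_scales = TRUE")
  }
  cat <- outcome_catalogue()
  bad <- setdiff(names(outcome_effects), cat$outcome)
  if (length(bad)) {
    abort(paste0("invalid `outcome_effects`: unknown outcome(s) ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(clusters = clusters,
                 participants_per_cluster = as.integer(participants_per_cluster),
                 icc = icc,
                 outcome_effects = outcome_effects,
                 residual_sd = residual_sd,
                 age_range_months = age_range_months,
                 attrition_rate = attrition_rate,
                 items = isTRUE(items),
                 bound_scales = isTRUE(bound_scales),
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  total <- sum(x$clusters$n_clusters)
  cat("<sim_config> ", total, " clusters x ", x$participants_per_cluster,
      " participants, ICC ", x$icc, ", attrition ", x$attrition_rate, "\n",
      sep = "")
  invisible(x)
}

trial_arms <- function() c("control", "group", "combined")

#' Default village allocation plan
#'
#' Two strata (subdistricts) with group/combined/control cluster counts
#' 5/5/8 and 3/3/7 — 31 villages in total, 8/8/15 per arm.
#'
#' @return A tibble with columns `stratum`, `arm`, `n_clusters`.
#' @export
default_cluster_plan <- function() {
  tibble(stratum = rep(c("A", "B"), each = 3),
         arm = rep(c("group", "combined", "control"), 2),
         n_clusters = c(5L, 5L, 8L, 3L, 3L, 7L))
}

# Generator catalogue: control-arm location/scale and support for every
# outcome.  Continuous rows give the age model mu(age) = intercept +
# beta_age * age and the non-age residual SD sigma; binary rows give the
# control prevalence.  Scales match published endline control summaries.
outcome_catalogue <- function() {
  tribble(
    ~outcome,            ~type,        ~intercept, ~beta_age, ~sigma, ~lo, ~hi, ~step, ~prevalence, ~baseline,
    "fci_activities",     "continuous", 3.2,        0,         1.5,    0,   6,   1,     NA,          TRUE,
    "fci_materials",      "continuous", 2.5,        0,         1.4,    0,   6,   1,     NA,          TRUE,
    "fci_observation",    "continuous", 8.3,        0,         1.5,    0,   11,  1,     NA,          TRUE,
    "asqi_communication", "continuous", 33.5,       1.5,       13.3,   0,   60,  5,     NA,          FALSE,
    "asqi_gross_motor",   "continuous", 37.6,       1.4,       12.2,   0,   60,  5,     NA,          FALSE,
    "asqi_fine_motor",    "continuous", 35.2,       1.0,       9.3,    0,   60,  5,     NA,          FALSE,
    "asqi_problem_solving","continuous", 34.6,      1.4,       13.1,   0,   60,  5,     NA,          FALSE,
    "asqi_personal_social","continuous", 34.3,      1.4,       13.7,   0,   60,  5,     NA,          FALSE,
    "cdi_receptive",      "continuous", -0.2,       3.0,       14.1,   0,   100, 1,     NA,          FALSE,
    "cdi_expressive",     "continuous", -21.7,      2.2,       13.4,   0,   100, 1,     NA,          FALSE,
    "cesd",               "continuous", 15.0,       0,         9.0,    0,   60,  1,     NA,          TRUE,
    "maternal_food_groups","continuous", 5.0,       0,         1.3,    0,   10,  1,     NA,          FALSE,
    "child_food_groups",  "continuous", 2.9,        0.06,      1.4,    0,   8,   1,     NA,          FALSE,
    "hygienic_latrine",   "binary",     NA,         NA,        NA,     NA,  NA,  NA,    0.34,        FALSE,
    "handwashing_station","binary",     NA,         NA,        NA,     NA,  NA,  NA,    0.21,        FALSE,
    "potty_use",          "binary",     NA,         NA,        NA,     NA,  NA,  NA,    0.20,        FALSE,
    "lead_knowledge",     "binary",     NA,         NA,        NA,     NA,  NA,  NA,    0.24,        FALSE
  )
}

arm_effect <- function(config, outcome, arm) {
  eff <- config$outcome_effects[[outcome]]
  if (is.null(eff)) return(numeric(length(arm)) * 0)
  out <- rep(0, length(arm))
  for (a in names(eff)) out[arm == a] <- eff[[a]]
  out
}

clip_round <- function(x, lo, hi, step) {
  x <- pmin(pmax(x, lo), hi)
  round(x / step) * step
}

#' Simulate a cluster-randomised trial dataset
#'
#' Generates one participant-level dataset under the random-intercept
#' model described in `vignette("cluster-trial-analysis")`: continuous
#' outcomes carry a village effect contributing a fraction `icc` of the
#' non-age outcome variance; binary outcomes use a logistic-normal village
#' intercept with the same ICC on the latent scale; bounded instrument
#' scales are clipped and rounded onto their documented support; loss to
#' follow-up is completely at random.  With `items = TRUE`, item-level
#' instrument responses consistent with each generated score are attached
#' as list-columns, so the scoring functions reproduce the generated
#' scores exactly.
#'
#' @param config A [sim_config()].
#' @return A `trial_data` tibble, one row per enrolled participant, with
#'   design columns (`participant_id`, `cluster_id`, `stratum`, `arm`),
#'   baseline covariates, endline outcome columns (NA when lost to
#'   follow-up) and, optionally, item-response list-columns.
#' @export
simulate_trial <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object")
  }
  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(config$seed)
  }

  plan <- config$clusters
  m <- config$participants_per_cluster
  rho <- config$icc

  cl <- plan |>
    rowwise() |>
    reframe(stratum = .data$stratum, arm = .data$arm, idx = seq_len(.data$n_clusters)) |>
    mutate(cluster_id = sprintf("v%02d", row_number()))
  k <- nrow(cl)

  dat <- tibble(
    cluster_id = rep(cl$cluster_id, each = m),
    stratum = rep(cl$stratum, each = m),
    arm = factor(rep(cl$arm, each = m), levels = trial_arms())
  ) |>
    mutate(participant_id = sprintf("p%04d", row_number()), .before = 1)
  n <- nrow(dat)

  # baseline covariates: marginals follow the enrolled-population summaries
  dat <- dat |> mutate(
    pregnant_at_baseline = runif(n) < 0.20,
    child_age_months = runif(n, config$age_range_months[1], config$age_range_months[2]),
    child_sex = factor(ifelse(runif(n) < 0.55, "female", "male")),
    maternal_primary_education = runif(n) < 0.57,
    household_income = round(exp(rnorm(n, log(12000), 0.6))),
    wall_material = runif(n) < 0.21,
    electricity = runif(n) < 0.86,
    asset_count = rbinom(n, 7, 0.45),
    interviewer = factor(sample(sprintf("int%02d", 1:8), n, replace = TRUE))
  ) |>
    mutate(household_income_above_median =
             .data$household_income > stats::median(.data$household_income))

  cat <- outcome_catalogue()
  cl_index <- match(dat$cluster_id, cl$cluster_id)

  # continuous outcomes: shared per-outcome village intercepts
  for (i in which(cat$type == "continuous")) {
    oc <- cat[i, ]
    sigma <- (config$residual_sd[[oc$outcome]] %||% oc$sigma)
    u <- rnorm(k, 0, sqrt(rho) * sigma)
    e <- rnorm(n, 0, sqrt(1 - rho) * sigma)
    latent <- oc$intercept + oc$beta_age * dat$child_age_months +
      arm_effect(config, oc$outcome, as.character(dat$arm)) + u[cl_index] + e
    dat[[oc$outcome]] <- if (config$bound_scales) {
      clip_round(latent, oc$lo, oc$hi, oc$step)
    } else {
      latent
    }
    if (oc$baseline) {
      r <- 0.3
      z <- (u[cl_index] + e) / sigma
      b <- oc$intercept + sigma * (r * z + sqrt(1 - r^2) * rnorm(n))
      if (config$bound_scales) b <- clip_round(b, oc$lo, oc$hi, oc$step)
      dat[[paste0("baseline_", oc$outcome)]] <- b
    }
  }

  # binary outcomes: logistic-normal village intercept, ICC on latent scale
  sigma_b <- sqrt(rho / (1 - rho) * pi^2 / 3)
  for (i in which(cat$type == "binary")) {
    oc <- cat[i, ]
    b <- rnorm(k, 0, sigma_b)
    eta <- qlogis(oc$prevalence) + arm_effect(config, oc$outcome, as.character(dat$arm)) +
      b[cl_index]
    dat[[oc$outcome]] <- runif(n) < plogis(eta)
  }

  # expressive vocabulary is only assessed for children over 9 months,
  # child diet only over 6 months
  dat$cdi_expressive[dat$child_age_months <= 9] <- NA_real_
  dat$child_food_groups[dat$child_age_months <= 6] <- NA_real_

  # loss to follow-up, completely at random
  dat$followed_up <- runif(n) >= config$attrition_rate
  endline <- c(cat$outcome, "cdi_expressive", "child_food_groups")
  for (col in intersect(unique(endline), names(dat))) {
    dat[[col]][!dat$followed_up] <- NA
  }

  if (config$items) {
    dat <- add_item_responses(dat)
  }

  class(dat) <- c("trial_data", class(dat))
  attr(dat, "sim_config") <- config
  dat
}

# Construct item-level responses consistent with each generated score:
# counts endorse a random item subset; ASQ domain raws decompose into
# yes/sometimes/not-yet under the 10/5/0 scheme; CES-D totals spread over
# the 20 items and are stored with the reverse-coded key applied.
add_item_responses <- function(dat) {
  n <- nrow(dat)
  dict <- instrument_dictionary()
  fci_ids <- c(fci_item_ids("activities"), fci_item_ids("materials"),
               fci_item_ids("observation"))
  rev_items <- dict$cesd$reverse_items
  domains <- asqi_domains()
  npd <- dict$asqi$items_per_domain

  endorse <- function(ids, count) {
    out <- setNames(integer(length(ids)), ids)
    if (!is.na(count) && count > 0) out[sample(length(ids), count)] <- 1L
    out
  }

  dat$fci_items <- pmap(list(dat$fci_activities, dat$fci_materials,
                             dat$fci_observation, dat$followed_up),
    function(a, m, o, fu) {
      if (!fu) return(NULL)
      c(endorse(fci_item_ids("activities"), a),
        endorse(fci_item_ids("materials"), m),
        endorse(fci_item_ids("observation"), o))
    })

  asqi_cols <- paste0("asqi_", c("communication", "gross_motor", "fine_motor",
                                 "problem_solving", "personal_social"))
  domain_items <- function(domain, raw) {
    ids <- asqi_item_ids(domain, npd)
    resp <- rep("not_yet", npd)
    n10 <- raw %/% 10
    if (n10 > 0) resp[seq_len(n10)] <- "yes"
    if (raw %% 10 >= 5) resp[n10 + 1] <- "sometimes"
    setNames(sample(resp), ids)   # shuffle which items are attained
  }
  dat$asqi_items <- pmap(c(unname(as.list(dat[asqi_cols])), list(dat$followed_up)),
    function(co, gm, fm, ps, so, fu) {
      if (!fu) return(NULL)
      raws <- c(co, gm, fm, ps, so)
      unlist(map2(domains, raws, domain_items))
    })

  dat$cesd_items <- map2(dat$cesd, dat$followed_up, function(total, fu) {
    if (!fu) return(NULL)
    base <- total %/% 20
    rem <- total %% 20
    vals <- rep(base, 20)
    if (rem > 0) vals[sample(20, rem)] <- base + 1
    vals[rev_items] <- 3L - vals[rev_items]   # stored with reverse key applied
    setNames(as.integer(vals), cesd_item_ids())
  })

  dat$cdi_items <- pmap(list(dat$cdi_receptive, dat$cdi_expressive, dat$followed_up),
    function(rec, expr, fu) {
      if (!fu) return(NULL)
      c(endorse(cdi_word_ids("receptive"), rec),
        if (!is.na(expr)) endorse(cdi_word_ids("expressive"), expr))
    })

  mg <- diet_groups("maternal")
  cg <- diet_groups("child")
  dat$diet_maternal <- map2(dat$maternal_food_groups, dat$followed_up,
    function(kk, fu) {
      if (!fu || is.na(kk)) return(NULL)
      sample(mg, kk)
    })
  dat$diet_child <- map2(dat$child_food_groups, dat$followed_up,
    function(kk, fu) {
      if (!fu || is.na(kk)) return(NULL)
      sample(cg, kk)
    })
  dat
}

#' ANOVA estimate of the intracluster correlation
#'
#' One-way analysis-of-variance estimator of the ICC of a continuous
#' outcome over clusters, using the unbalanced-design average cluster size
#' `m0 = (N - sum(n_j^2) / N) / (k - 1)`:
#' `ICC = (MSB - MSW) / (MSB + (m0 - 1) MSW)`.
#'
#' @param data A data frame with a `cluster_id` column.
#' @param outcome Name of a continuous outcome column.
#' @return The ICC estimate (a number in `(-1/(m0-1), 1]`).
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(seed = 7))
#' estimate_icc(trial, "fci_activities")
estimate_icc <- function(data, outcome) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  d <- data[!is.na(data[[outcome]]), c("cluster_id", outcome)]
  y <- d[[outcome]]
  g <- factor(d$cluster_id)
  kk <- nlevels(droplevels(g))
  if (kk < 2) abort("ICC undefined: fewer than 2 clusters with data")
  if (var(y) == 0) abort("ICC undefined: outcome has zero total variance")
  nj <- tabulate(droplevels(g))
  N <- length(y)
  gm <- mean(y)
  cm <- tapply(y, droplevels(g), mean)
  ssb <- sum(nj * (cm - gm)^2)
  ssw <- sum((y - cm[droplevels(g)])^2)
  msb <- ssb / (kk - 1)
  msw <- ssw / (N - kk)
  m0 <- (N - sum(nj^2) / N) / (kk - 1)
  (msb - msw) / (msb + (m0 - 1) * msw)
}

#' Write a trial dataset to CSV (with its generating configuration)
#'
#' Writes the participant table (item list-columns are dropped; scored
#' columns remain) as CSV, and optionally the generating `sim_config` as
#' YAML alongside it.
#'
#' @param data A trial tibble.
#' @param path CSV output path.
#' @param config_path Optional YAML path for the attached `sim_config`.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path, config_path = NULL) {
  flat <- data[!vapply(data, is.list, logical(1))]
  utils::write.csv(flat, path, row.names = FALSE)
  cfg <- attr(data, "sim_config")
  if (!is.null(config_path) && !is.null(cfg)) {
    payload <- list(
      clusters = lapply(seq_len(nrow(cfg$clusters)), function(i) {
        as.list(cfg$clusters[i, ])
      }),
      participants_per_cluster = cfg$participants_per_cluster,
      icc = cfg$icc,
      outcome_effects = lapply(cfg$outcome_effects, as.list),
      age_range_months = as.list(cfg$age_range_months),
      attrition_rate = cfg$attrition_rate,
      seed = cfg$seed)
    yaml::write_yaml(payload, config_path)
  }
  invisible(path)
}
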