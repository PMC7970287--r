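# Intention-to-treat estimation: LRT covariate prescreen, parametric
# g-computation (marginal standardisation) for adjusted mean / prevalence
# differences, village-clustered percentile bootstrap CIs, and pooled-SD
# effect sizes.

#' Declare an outcome for effect estimation
#'
#' @param name Outcome column name (raw scale).
#' @param scale `"continuous"` or `"binary"`.
#' @param candidates Candidate covariates for the adjustment screen
#'   (default: the registered dictionary via [candidate_covariates()]).
#' @param standardized If `TRUE` the analysis uses the internally
#'   age-standardised score `<name>_z` with its `|z| > 4` exclusions.
#' @return A one-row tibble (an outcome spec).
#' @export
outcome_spec <- function(name, scale = c("continuous", "binary"),
                         candidates = NULL, standardized = FALSE) {
  scale <- match.arg(scale)
  tibble(name = name, scale = scale,
         candidates = list(candidates %||% candidate_covariates(name)),
         standardized = standardized)
}

# model-matrix fitting backend shared by gcompute/adjusted_means: fast
# lm.fit/glm.fit on an explicit design, with aliased columns zeroed so
# counterfactual prediction stays defined under bootstrap level dropping.
fit_outcome_model <- function(d, outcome, covariates, scale) {
  rhs <- c("arm", covariates)
  X <- model.matrix(reformulate(rhs), d)
  y <- as.numeric(d[[outcome]])
  if (scale == "continuous") {
    fit <- lm.fit(X, y)
    beta <- fit$coefficients
  } else {
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    if (!fit$converged) {
      abort(paste0("logistic model for '", outcome, "' did not converge (",
                   "deviance ", signif(fit$deviance, 4), ")"))
    }
    beta <- fit$coefficients
    if (any(abs(beta[!is.na(beta)]) > 20)) {
      abort(paste0("separation suspected for '", outcome,
                   "': |coefficient| > 20"))
    }
  }
  beta[is.na(beta)] <- 0
  list(X = X, beta = beta, n = nrow(X))
}

set_arm_columns <- function(X, arm_levels, target) {
  cols <- paste0("arm", arm_levels[-1])   # reference = first level
  present <- intersect(cols, colnames(X))
  X[, present] <- 0
  tgt <- paste0("arm", target)
  if (tgt %in% colnames(X)) X[, tgt] <- 1
  X
}

#' Parametric g-computation point estimate
#'
#' Fits the outcome regression (linear for continuous outcomes, logistic
#' for binary) on the complete-case records of the two compared arms,
#' predicts every analysed record's outcome under assignment to the
#' treatment arm and under assignment to control, and returns the
#' difference of the two prediction means — an adjusted mean difference,
#' or a prevalence difference on the probability scale.
#'
#' @param data Participant-level data frame with `arm` and `cluster_id`.
#' @param outcome Outcome column to model.
#' @param scale `"continuous"` or `"binary"`.
#' @param covariates Covariate columns entering the model (default none:
#'   the unadjusted arm contrast).
#' @param comparison Length-2 character `c(treatment, control)` naming the
#'   compared arms (default `c("group", "control")`).
#' @return One-row tibble: `outcome`, `comparison`, `estimate`,
#'   `n_analyzed`, `n_clusters`, `scale`, `covariates` (list-column).
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(seed = 11, items = FALSE))
#' gcompute(trial, "fci_activities", covariates = "child_age_months")
gcompute <- function(data, outcome, scale = c("continuous", "binary"),
                     covariates = character(),
                     comparison = c("group", "control")) {
  scale <- match.arg(scale)
  stopifnot(length(comparison) == 2, outcome %in% names(data))
  pt <- gcompute_point(data, outcome, scale, covariates, comparison)
  tibble(outcome = outcome,
         comparison = paste(comparison, collapse = " vs "),
         estimate = pt$estimate, n_analyzed = pt$n_analyzed,
         n_clusters = pt$n_clusters,
         scale = scale, covariates = list(covariates))
}

# bare-metal g-computation core shared by gcompute() and the bootstrap
# replicates: identical arithmetic, no tibble allocation.
gcompute_point <- function(data, outcome, scale, covariates, comparison) {
  need <- c(outcome, "arm", "cluster_id", covariates)
  d <- as.data.frame(data[need])
  d <- d[d$arm %in% comparison & complete.cases(d), , drop = FALSE]
  d$arm <- factor(as.character(d$arm), levels = c(comparison[2], comparison[1]))
  if (any(tabulate(d$arm, 2L) == 0)) {
    abort(paste0("comparison ", paste(comparison, collapse = " vs "),
                 ": an arm has no analysable records"))
  }
  fit <- fit_outcome_model(d, outcome, covariates, scale)
  lv <- levels(d$arm)
  eta1 <- drop(set_arm_columns(fit$X, lv, comparison[1]) %*% fit$beta)
  eta0 <- drop(set_arm_columns(fit$X, lv, comparison[2]) %*% fit$beta)
  est <- if (scale == "continuous") {
    mean(eta1) - mean(eta0)
  } else {
    mean(plogis(eta1)) - mean(plogis(eta0))
  }
  list(estimate = est, n_analyzed = fit$n,
       n_clusters = length(unique(d$cluster_id)))
}

#' Likelihood-ratio prescreen of candidate covariates
#'
#' For each candidate, compares the outcome model containing the arm
#' indicators with and without that single candidate by a likelihood
#' ratio test, on the candidate's complete cases.  Candidates with
#' `p < alpha_screen` (default 0.20) are retained, in registered order.
#' A candidate whose model fails to converge is dropped with a warning.
#'
#' @inheritParams gcompute
#' @param candidates Character vector of candidate covariate columns.
#' @param alpha_screen Retention threshold on the LRT p-value
#'   (default 0.20).
#' @return Tibble with one row per candidate: `candidate`, `p_value`,
#'   `retained`.
#' @export
prescreen_covariates <- function(data, outcome,
                                 scale = c("continuous", "binary"),
                                 candidates = candidate_covariates(outcome, data),
                                 alpha_screen = 0.20) {
  scale <- match.arg(scale)
  if (!length(candidates)) {
    return(tibble(candidate = character(), p_value = numeric(),
                  retained = logical()))
  }
  rows <- map(candidates, function(cand) {
    d <- data[complete.cases(data[c(outcome, "arm", cand)]), , drop = FALSE]
    d$arm <- droplevels(factor(d$arm))
    p <- tryCatch({
      f0 <- reformulate("arm", response = outcome)
      f1 <- reformulate(c("arm", cand), response = outcome)
      if (scale == "continuous") {
        m0 <- lm(f0, data = d)
        m1 <- lm(f1, data = d)
      } else {
        m0 <- glm(f0, data = d, family = binomial())
        m1 <- glm(f1, data = d, family = binomial())
        if (!m0$converged || !m1$converged) stop("non-convergence")
      }
      lmtest::lrtest(m0, m1)[["Pr(>Chisq)"]][2]
    }, error = function(e) {
      warn(paste0("prescreen: candidate '", cand, "' dropped (",
                  conditionMessage(e), ")"))
      NA_real_
    })
    tibble(candidate = cand, p_value = p,
           retained = !is.na(p) && p < alpha_screen)
  })
  list_rbind(rows)
}

#' Village-clustered bootstrap confidence interval
#'
#' Resamples whole clusters with replacement, stratified within arm so
#' every replicate keeps the design's arm-wise cluster counts, re-runs
#' the estimator on the stacked resampled records, and returns percentile
#' confidence limits of the replicate estimates.  Replicates whose
#' estimator fails are redrawn up to a retry budget of `B` extra draws;
#' more than `max_failure_rate` irrecoverable failures is an error.
#'
#' @param data Participant-level data frame with `arm` and `cluster_id`.
#' @param estimator Function `data -> numeric` (scalar or fixed-length
#'   vector) computing the statistic.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @param conf Confidence level (default 0.95, i.e. the 2.5th and 97.5th
#'   percentiles).
#' @param max_failure_rate Maximum tolerated fraction of irrecoverable
#'   replicate failures (default 0.05).
#' @return Tibble with `ci_low`, `ci_high` (one row per estimator
#'   component) and `n_failures`; the replicate matrix is attached as
#'   attribute `"replicates"`.
#' @export
cluster_bootstrap <- function(data, estimator, B = 1000, seed = NULL,
                              conf = 0.95, max_failure_rate = 0.05) {
  stopifnot(B >= 1)
  arm_of <- tapply(as.character(data$arm), data$cluster_id, function(x) x[1])
  if (any(tapply(data$arm, data$cluster_id,
                 function(x) length(unique(x))) > 1)) {
    abort("arm is not constant within cluster")
  }
  data <- as.data.frame(data)   # fast positional row indexing in the loop
  rows_by_cluster <- split(seq_len(nrow(data)), data$cluster_id)
  clusters_by_arm <- split(names(rows_by_cluster), arm_of[names(rows_by_cluster)])
  if (any(lengths(clusters_by_arm) < 2)) {
    abort("cluster bootstrap needs at least 2 clusters per arm")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  one_rep <- function() {
    picked <- unlist(map(clusters_by_arm, function(cl) {
      sample(cl, length(cl), replace = TRUE)
    }), use.names = FALSE)
    rows <- unlist(rows_by_cluster[picked], use.names = FALSE)
    estimator(data[rows, , drop = FALSE])
  }
  reps <- vector("list", B)
  failures <- 0L
  budget <- B   # extra draws allowed for failed replicates
  b <- 1L
  while (b <= B) {
    val <- tryCatch(one_rep(), error = function(e) e)
    if (inherits(val, "error")) {
      failures <- failures + 1L
      budget <- budget - 1L
      if (failures > max_failure_rate * B || budget < 0L) {
        abort(paste0("cluster bootstrap: ", failures,
                     " replicate failures exceed the tolerated rate; last: ",
                     conditionMessage(val)))
      }
      next
    }
    reps[[b]] <- val
    b <- b + 1L
  }
  mat <- do.call(rbind, reps)
  alpha <- (1 - conf) / 2
  qs <- apply(mat, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE,
              type = 7)
  out <- tibble(ci_low = qs[1, ], ci_high = qs[2, ], n_failures = failures)
  attr(out, "replicates") <- mat
  out
}

#' Age-adjusted marginal arm means
#'
#' Fits the outcome on arm plus the adjustment covariates over all three
#' arms, then reports each arm's mean prediction over the pooled analysed
#' covariate (age) distribution, with village-clustered bootstrap CIs.
#'
#' @inheritParams gcompute
#' @param adjust_for Covariates to adjust over (default child age).
#' @param B,seed,conf Passed to [cluster_bootstrap()].
#' @return Tibble, one row per arm in control / group / combined order:
#'   `arm`, `mean`, `ci_low`, `ci_high`, `n_analyzed`.
#' @export
adjusted_means <- function(data, outcome, scale = c("continuous", "binary"),
                           adjust_for = "child_age_months",
                           B = 1000, seed = NULL, conf = 0.95) {
  scale <- match.arg(scale)
  arms <- intersect(trial_arms(), unique(as.character(data$arm)))
  point_fn <- function(d) {
    d <- d[complete.cases(d[c(outcome, "arm", adjust_for)]), , drop = FALSE]
    d$arm <- factor(as.character(d$arm), levels = arms)
    fit <- fit_outcome_model(d, outcome, adjust_for, scale)
    vapply(arms, function(a) {
      eta <- drop(set_arm_columns(fit$X, arms, a) %*% fit$beta)
      if (scale == "continuous") mean(eta) else mean(plogis(eta))
    }, numeric(1))
  }
  pt <- point_fn(data)
  ci <- cluster_bootstrap(data, point_fn, B = B, seed = seed, conf = conf)
  n <- sum(complete.cases(data[c(outcome, "arm", adjust_for)]))
  tibble(arm = factor(arms, levels = trial_arms()), mean = unname(pt),
         ci_low = ci$ci_low, ci_high = ci$ci_high, n_analyzed = n) |>
    arrange(.data$arm)
}

#' Cohen's d with a normal-approximation confidence interval
#'
#' `d = (mean1 - mean2) / s_pooled`, pooling the two variances over
#' `n1 - 1` and `n2 - 1` degrees of freedom; the CI uses the asymptotic
#' variance `(n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2))`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2 (the reference).
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `d`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' cohens_d(4.2, 1.5, 144, 3.2, 1.5, 281)
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2, conf = 0.95) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) abort("cohens_d: pooled SD is zero")
  d <- (mean1 - mean2) / sp
  v <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  z <- qnorm(1 - (1 - conf) / 2)
  tibble(d = d, ci_low = d - z * sqrt(v), ci_high = d + z * sqrt(v))
}

derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + 97 * i) %% (.Machine$integer.max - 1)) + 1L
}

#' Estimate intention-to-treat effects for a set of outcomes
#'
#' The full analysis pipeline: for each outcome, prescreen the candidate
#' covariates once on the original data (LRT, p < `alpha_screen`), then
#' for each treatment-vs-control comparison compute the g-computation
#' point estimate with the retained covariates and a village-clustered
#' percentile bootstrap CI.  Standardised outcomes are analysed on their
#' `_z` score with `|z| > 4` records excluded.  A run-level seed fans out
#' deterministically to per-outcome bootstrap streams.  No multiplicity
#' adjustment is applied: each outcome yields one comparison per
#' treatment arm against control.
#'
#' @param data Scored (and, where applicable, standardised) trial data.
#' @param specs Outcome specs: a tibble from [outcome_spec()] rows
#'   (e.g. `dplyr::bind_rows(outcome_spec(...), ...)`).
#' @param comparisons List of `c(treatment, control)` pairs (default both
#'   intervention arms vs control).
#' @param B Bootstrap replicates per CI (default 1000).
#' @param seed Run-level integer seed.
#' @param alpha_screen LRT retention threshold (default 0.20).
#' @return An `effect_estimates` tibble: one row per outcome x
#'   comparison with `estimate`, `ci_low`, `ci_high`, `n_analyzed`,
#'   `n_clusters`, `covariates_used`, `B`, `seed`.
#' @export
estimate_effects <- function(data, specs,
                             comparisons = list(c("group", "control"),
                                                c("combined", "control")),
                             B = 1000, seed = NULL, alpha_screen = 0.20) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1)
  out <- vector("list", 0)
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    col <- if (spec$standardized) paste0(spec$name, "_z") else spec$name
    d <- data
    if (spec$standardized) {
      excl <- paste0(spec$name, "_excluded")
      if (!col %in% names(d)) {
        abort(paste0("standardised column '", col, "' not found; run ",
                     "standardize_scores() first"))
      }
      d <- d[is.na(d[[excl]]) | !d[[excl]], , drop = FALSE]
    }
    cands <- intersect(spec$candidates[[1]], names(d))
    screen <- prescreen_covariates(d, col, spec$scale, cands,
                                   alpha_screen = alpha_screen)
    retained <- screen$candidate[screen$retained]
    keep_cols <- unique(c("participant_id", "cluster_id", "stratum", "arm",
                          col, retained))
    slim <- d[intersect(keep_cols, names(d))]
    for (j in seq_along(comparisons)) {
      cmp <- comparisons[[j]]
      pt <- gcompute(slim, col, spec$scale, retained, cmp)
      est_fn <- function(dd) {
        gcompute_point(dd, col, spec$scale, retained, cmp)$estimate
      }
      two <- slim[slim$arm %in% cmp, , drop = FALSE]
      ci <- cluster_bootstrap(two, est_fn, B = B,
                              seed = derive_seed(seed, (i - 1) * 10 + j))
      out[[length(out) + 1]] <- tibble(
        outcome = spec$name, analysis_column = col,
        comparison = pt$comparison, scale = spec$scale,
        estimate = pt$estimate, ci_low = ci$ci_low, ci_high = ci$ci_high,
        n_analyzed = pt$n_analyzed, n_clusters = pt$n_clusters,
        covariates_used = list(retained), B = as.integer(B),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    }
  }
  res <- list_rbind(out)
  class(res) <- c("effect_estimates", class(res))
  res
}

#' Tidy and summarise effect-estimate tables
#'
#' @param x An `effect_estimates` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy effect_estimates
#' @export
tidy.effect_estimates <- function(x, ...) {
  as_tibble(x) |>
    mutate(covariates_used = map_chr(.data$covariates_used, paste, collapse = ";"))
}

#' @rdname tidy.effect_estimates
#' @method glance effect_estimates
#' @export
glance.effect_estimates <- function(x, ...) {
  tibble(n_outcomes = length(unique(x$outcome)),
         n_comparisons = nrow(x),
         B = unique(x$B)[1], seed = unique(x$seed)[1])
}
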