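# Cluster-trial design: design effect, normal-approximation power,
# required cluster counts under an allocation ratio, stratified
# randomisation, and the demographic village-eligibility screen.

#' Design effect of a cluster design
#'
#' Variance inflation `1 + (m - 1) * icc` for clusters of `m`
#' participants with intracluster correlation `icc`.
#'
#' @param m Participants per cluster (>= 1).
#' @param icc Intracluster correlation in `[0, 1)`.
#' @return The design effect (>= 1).
#' @export
#' @examples
#' design_effect(20, 0.20)  # 4.8
design_effect <- function(m, icc) {
  stopifnot(m >= 1, icc >= 0, icc < 1)
  1 + (m - 1) * icc
}

#' Power of a two-arm cluster-randomised comparison
#'
#' Normal-approximation power of the two-sided two-sample test of a mean
#' difference `delta` between a treatment arm of `k_treatment` clusters
#' and a control arm of `k_control` clusters, each of `m` participants,
#' with outcome SD `sd` and intracluster correlation `icc`.  The standard
#' error is `sd * sqrt(DE * (1/(k_t m) + 1/(k_c m)))` with
#' `DE = 1 + (m - 1) icc`, and power is
#' `Phi(|delta| / SE - z_{1 - alpha/2})`.
#'
#' @param delta Target mean difference (default 2.0).
#' @param sd Outcome standard deviation (default 3.3).
#' @param icc Intracluster correlation (default 0.20).
#' @param m Participants per cluster (default 20).
#' @param k_treatment,k_control Cluster counts in the two arms.
#' @param alpha Two-sided type-I error (default 0.05).
#' @param df_method `"normal"` (default) or `"t"`; the t variant uses
#'   `k_treatment + k_control - 2` cluster-level degrees of freedom and is
#'   more conservative.
#' @return The power, a proportion.
#' @export
#' @examples
#' crt_power(k_treatment = 8, k_control = 15)
crt_power <- function(delta = 2.0, sd = 3.3, icc = 0.20, m = 20,
                      k_treatment, k_control, alpha = 0.05,
                      df_method = c("normal", "t")) {
  df_method <- match.arg(df_method)
  stopifnot(alpha > 0, alpha < 1, sd > 0, m >= 1)
  if (k_treatment < 1 || k_control < 1) {
    abort("both arms need at least one cluster")
  }
  de <- design_effect(m, icc)
  se <- sd * sqrt(de * (1 / (k_treatment * m) + 1 / (k_control * m)))
  ncp <- abs(delta) / se
  if (df_method == "normal") {
    pnorm(ncp - qnorm(1 - alpha / 2))
  } else {
    df <- k_treatment + k_control - 2
    stats::pt(ncp - stats::qt(1 - alpha / 2, df), df)
  }
}

#' Cluster counts required to reach a target power
#'
#' Smallest integer cluster counts `(k_treatment, k_control)` on the
#' allocation ratio achieving at least `power_target`, by stepping the
#' ratio multiplier through the closed-form power.
#'
#' @inheritParams crt_power
#' @param power_target Target power (default 0.80).
#' @param ratio Length-2 numeric `c(treatment, control)` cluster
#'   allocation ratio (default `c(8, 15)`).
#' @param max_clusters Cap on the per-arm search (default 10000); an
#'   unreachable target (e.g. `delta = 0`) is an error.
#' @return One-row tibble: `k_treatment`, `k_control`, `power`.
#' @export
#' @examples
#' required_clusters()  # 8 treatment vs 15 control under the defaults
required_clusters <- function(delta = 2.0, sd = 3.3, icc = 0.20, m = 20,
                              alpha = 0.05, power_target = 0.80,
                              ratio = c(8, 15), max_clusters = 10000) {
  stopifnot(length(ratio) == 2, all(ratio > 0),
            power_target > 0, power_target < 1)
  scale <- ratio / min(ratio)
  i <- 1
  repeat {
    kt <- ceiling(scale[1] * i)
    kc <- ceiling(scale[2] * i)
    if (max(kt, kc) > max_clusters) {
      abort("target power unreachable within max_clusters")
    }
    p <- crt_power(delta, sd, icc, m, kt, kc, alpha)
    if (p >= power_target) {
      return(tibble(k_treatment = kt, k_control = kc, power = p))
    }
    i <- i + 1
  }
}

#' Stratified randomisation of villages to arms
#'
#' Uniformly random assignment within stratum honouring the allocation
#' plan's per-arm cluster counts; reproducible from `seed`.
#'
#' @param villages Data frame with columns `village_id` and `stratum`.
#' @param plan Allocation plan: data frame with `stratum`, `arm`,
#'   `n_clusters` (default [default_cluster_plan()]).
#' @param seed Integer seed.
#' @return `villages` with an `arm` factor column added.
#' @export
randomize_villages <- function(villages, plan = default_cluster_plan(),
                               seed = NULL) {
  stopifnot(all(c("village_id", "stratum") %in% names(villages)))
  counts <- villages |> count(.data$stratum, name = "n_villages")
  plan_tot <- plan |>
    group_by(.data$stratum) |>
    summarise(n_plan = sum(.data$n_clusters), .groups = "drop")
  chk <- full_join(counts, plan_tot, by = "stratum")
  if (anyNA(chk$n_villages) || anyNA(chk$n_plan) ||
      any(chk$n_villages != chk$n_plan)) {
    abort("village counts per stratum do not match the allocation plan")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  assigned <- villages |>
    group_by(.data$stratum) |>
    group_modify(function(vd, key) {
      p <- plan[plan$stratum == key$stratum[[1]], ]
      labels <- rep(p$arm, p$n_clusters)
      vd$arm <- sample(labels)
      vd
    }) |>
    ungroup()
  assigned$arm <- factor(assigned$arm, levels = trial_arms())
  assigned
}

#' Demographic village-eligibility screen
#'
#' Retains villages whose every screened statistic lies within
#' `threshold` district standard deviations of the district mean
#' (default 1.5 SDs).
#'
#' @param village_stats Data frame: `village_id` plus one numeric column
#'   per screened statistic.
#' @param district_means,district_sds Named numeric vectors over the
#'   screened statistics.
#' @param threshold Maximum tolerated `|z|` (default 1.5).
#' @return The eligible subset of `village_stats`, with an `eligible`
#'   logical column added to the full table as attribute `"screen"`.
#' @export
screen_villages <- function(village_stats, district_means, district_sds,
                            threshold = 1.5) {
  stats_cols <- names(district_means)
  stopifnot(all(stats_cols %in% names(village_stats)),
            setequal(stats_cols, names(district_sds)))
  if (any(district_sds[stats_cols] == 0)) {
    abort("zero district SD for a screened statistic")
  }
  z <- map(stats_cols, function(s) {
    abs((village_stats[[s]] - district_means[[s]]) / district_sds[[s]])
  })
  ok <- Reduce(`&`, map(z, ~ .x <= threshold))
  screen <- village_stats |> mutate(eligible = ok)
  out <- village_stats[ok, , drop = FALSE]
  attr(out, "screen") <- screen
  out
}
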