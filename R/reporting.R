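# CONSORT-style accounting and results-table assembly.  All printed
# percentages are recomputed from counts at render time; display rounding
# is round-half-up.

#' Round half away from zero (display rounding)
#'
#' Unlike [round()], exact halves round away from zero: `round_half_up(7.65, 1)`
#' is 7.7.  Used for displayed percentages and estimates only.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' CONSORT flow accounting
#'
#' Counts enrolled and lost-to-follow-up participants per arm and
#' overall, with loss percentages recomputed as `100 * lost / enrolled`
#' rounded (half-up) to one decimal.
#'
#' @param data Trial data with `arm` and `followed_up` columns.
#' @return Tibble with one row per arm plus an `overall` row: `arm`,
#'   `enrolled`, `lost`, `followed`, `pct_lost`.
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(seed = 5, items = FALSE))
#' consort_flow(trial)
consort_flow <- function(data) {
  stopifnot(all(c("arm", "followed_up") %in% names(data)))
  per_arm <- data |>
    group_by(arm = as.character(.data$arm)) |>
    summarise(enrolled = dplyr::n(), lost = sum(!.data$followed_up),
              .groups = "drop")
  overall <- tibble(arm = "overall", enrolled = nrow(data),
                    lost = sum(!data$followed_up))
  bind_rows(per_arm, overall) |>
    mutate(followed = .data$enrolled - .data$lost,
           pct_lost = round_half_up(100 * .data$lost / .data$enrolled, 1))
}

#' Per-outcome analysed counts
#'
#' Number of analysable (followed-up, non-missing, not outlier-excluded)
#' records per outcome — the per-outcome n that the `|z| > 4` screen and
#' instrument age gates produce.
#'
#' @param data Scored/standardised trial data.
#' @param outcomes Character vector of analysis columns (use `<name>_z`
#'   for standardised outcomes).
#' @return Tibble `outcome`, `n_analyzed`.
#' @export
analyzed_counts <- function(data, outcomes) {
  list_rbind(map(outcomes, function(oc) {
    keep <- !is.na(data[[oc]])
    excl <- sub("_z$", "_excluded", oc)
    if (excl != oc && excl %in% names(data)) {
      keep <- keep & !(data[[excl]] %in% TRUE)
    }
    tibble(outcome = oc, n_analyzed = sum(keep))
  }))
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round_half_up(x, digits), format = "f",
                               digits = digits))
}

fmt_ci <- function(est, lo, hi, digits = 2) {
  ifelse(is.na(est), "",
         paste0(fmt_num(est, digits), " (", fmt_num(lo, digits), " to ",
                fmt_num(hi, digits), ")"))
}

#' Assemble a results table
#'
#' One row per outcome: unadjusted mean±SD (continuous) or n (%)
#' (binary) per arm, alongside the adjusted difference columns
#' (estimate and 95% CI) for each treatment-vs-control comparison.
#' Differences print to two decimals, prevalences as proportions to two
#' decimals, percentages to whole percent.
#'
#' @param effects An `effect_estimates` tibble from [estimate_effects()].
#' @param data The analysed dataset, for the unadjusted descriptive
#'   columns (raw scale).
#' @return A formatted tibble, one row per outcome; missing comparisons
#'   render as blank cells.
#' @export
results_table <- function(effects, data) {
  arms <- trial_arms()
  rows <- map(unique(effects$outcome), function(oc) {
    e <- effects[effects$outcome == oc, ]
    scale <- e$scale[1]
    desc <- setNames(vector("character", length(arms)), arms)
    for (a in arms) {
      v <- data[[oc]][data$arm == a]
      v <- v[!is.na(v)]
      desc[a] <- if (!length(v)) {
        ""
      } else if (scale == "continuous") {
        paste0(fmt_num(mean(v), 1), "±", fmt_num(sd(v), 1))
      } else {
        paste0(sum(v), " (", fmt_num(100 * mean(v), 0), "%)")
      }
    }
    cell <- function(cmp_arm) {
      r <- e[startsWith(e$comparison, cmp_arm), ]
      if (!nrow(r)) {
        warn(paste0("results_table: no '", cmp_arm, "' comparison for '",
                    oc, "'"))
        return("")
      }
      fmt_ci(r$estimate[1], r$ci_low[1], r$ci_high[1], 2)
    }
    tibble(outcome = oc, control = desc["control"], group = desc["group"],
           combined = desc["combined"],
           group_vs_control = cell("group"),
           combined_vs_control = cell("combined"))
  })
  if (!length(rows)) {
    return(tibble(outcome = character(), control = character(),
                  group = character(), combined = character(),
                  group_vs_control = character(),
                  combined_vs_control = character()))
  }
  list_rbind(rows)
}

#' Render a results table as Markdown
#'
#' @param table A tibble (e.g. from [results_table()]).
#' @return A character vector of Markdown lines.
#' @export
format_markdown <- function(table) {
  hdr <- paste0("| ", paste(names(table), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(table)), collapse = "|"), "|")
  body <- apply(table, 1, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  c(hdr, sep, body)
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to re-run an analysis bit-for-bit: the
#' run seed, bootstrap replicates, retained covariates and analysed n
#' per outcome x comparison.
#'
#' @param effects An `effect_estimates` tibble.
#' @return A list (serialise with `jsonlite::write_json()` if desired).
#' @export
run_manifest <- function(effects) {
  list(seed = unique(effects$seed)[1],
       B = unique(effects$B)[1],
       estimates = lapply(seq_len(nrow(effects)), function(i) {
         list(outcome = effects$outcome[i],
              comparison = effects$comparison[i],
              n_analyzed = effects$n_analyzed[i],
              n_clusters = effects$n_clusters[i],
              covariates_used = effects$covariates_used[[i]])
       }))
}
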