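# Internal age-standardisation: development scores are z-scored against
# age-conditional means and SDs estimated from the trial's own control
# arm, and |z| > 4 outliers are flagged for exclusion.

#' Fit an internal age-standardiser on the control arm
#'
#' Estimates age-conditional means and SDs of a raw development score
#' from control-arm, followed-up records.  The default method cuts age
#' into fixed-width bins (3 months), merging sparse bins with their
#' neighbour until every bin holds at least `min_per_bin` records; the
#' `"polynomial"` method fits a quadratic mean model and a linear model
#' for the absolute residual (scaled to an SD).
#'
#' @param data Trial data frame with `arm`, `followed_up`, an age column
#'   and the raw outcome column.
#' @param outcome Name of the raw score column to standardise.
#' @param method `"age_bins"` (default) or `"polynomial"`.
#' @param bin_width_months Bin width in months (default 3).
#' @param min_per_bin Minimum control-arm records per retained bin
#'   (default 15); sparse bins are merged with the adjacent bin.
#' @param age_col Name of the age column (months).
#' @return An `age_standardizer` object with `mean_fn(age)` and
#'   `sd_fn(age)` accessors, usable with [standardize()] and
#'   [tidy()]/[glance()].
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(seed = 3, items = FALSE))
#' std <- fit_standardizer(trial, "asqi_communication")
#' glance(std)
fit_standardizer <- function(data, outcome,
                             method = c("age_bins", "polynomial"),
                             bin_width_months = 3, min_per_bin = 15,
                             age_col = "child_age_months") {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), outcome %in% names(data),
            age_col %in% names(data))
  ctrl <- data[data$arm == "control" & data$followed_up &
                 !is.na(data[[outcome]]) & !is.na(data[[age_col]]), ]
  age <- ctrl[[age_col]]
  y <- ctrl[[outcome]]
  n <- length(y)
  if (n < min_per_bin) {
    abort(paste0("too few control-arm records (", n, ") to fit a standardiser"))
  }

  if (method == "age_bins") {
    edges <- seq(floor(min(age)), max(age) + bin_width_months, by = bin_width_months)
    bin <- findInterval(age, edges, rightmost.closed = TRUE)
    # merge sparse bins leftwards into their neighbour
    repeat {
      counts <- table(bin)
      small <- names(counts)[counts < min_per_bin]
      if (!length(small)) break
      b <- as.integer(small[1])
      levels_present <- sort(unique(bin))
      target <- if (b == min(levels_present)) {
        levels_present[which(levels_present == b) + 1]
      } else {
        levels_present[which(levels_present == b) - 1]
      }
      if (is.na(target)) break
      bin[bin == b] <- target
    }
    stats_tbl <- tibble(bin = bin, age = age, y = y) |>
      group_by(.data$bin) |>
      summarise(age_lo = min(.data$age), age_hi = max(.data$age),
                n = dplyr::n(), mean = mean(.data$y), sd = sd(.data$y),
                .groups = "drop") |>
      arrange(.data$age_lo)
    if (any(stats_tbl$sd == 0)) {
      abort("zero within-bin variance: cannot standardise")
    }
    # lookup boundaries between consecutive bins; edge ages clamp to the
    # boundary bins
    cuts <- (stats_tbl$age_lo[-1] + stats_tbl$age_hi[-nrow(stats_tbl)]) / 2
    fitted <- list(bins = stats_tbl, cuts = cuts)
  } else {
    mean_fit <- lm(y ~ poly(age, 2, raw = TRUE))
    abs_res <- abs(stats::residuals(mean_fit))
    sd_fit <- lm(abs_res ~ age)
    # E|Z| = sqrt(2/pi) for a normal residual: rescale the absolute
    # residual line to an SD
    fitted <- list(mean_fit = mean_fit, sd_fit = sd_fit,
                   scale = sqrt(pi / 2))
  }

  structure(list(outcome = outcome, method = method,
                 bin_width_months = bin_width_months,
                 min_per_bin = min_per_bin, age_col = age_col,
                 age_range = range(age), fit_n = n, fit_arm = "control",
                 fitted = fitted),
            class = "age_standardizer")
}

std_bin_index <- function(std, age) {
  findInterval(age, std$fitted$cuts) + 1L
}

std_mean <- function(std, age) {
  age <- pmin(pmax(age, std$age_range[1]), std$age_range[2])
  if (std$method == "age_bins") {
    std$fitted$bins$mean[std_bin_index(std, age)]
  } else {
    unname(predict(std$fitted$mean_fit, data.frame(age = age)))
  }
}

std_sd <- function(std, age) {
  age <- pmin(pmax(age, std$age_range[1]), std$age_range[2])
  if (std$method == "age_bins") {
    std$fitted$bins$sd[std_bin_index(std, age)]
  } else {
    s <- unname(predict(std$fitted$sd_fit, data.frame(age = age))) * std$fitted$scale
    if (any(s <= 0)) abort("sd model predicts non-positive SD in the age range")
    s
  }
}

#' @export
print.age_standardizer <- function(x, ...) {
  cat("<age_standardizer> outcome '", x$outcome, "', method ", x$method,
      ", fitted on ", x$fit_n, " control-arm records\n", sep = "")
  invisible(x)
}

#' Standardise raw scores with a fitted age-standardiser
#'
#' Computes `z = (raw - mean(age)) / sd(age)` for each record and flags
#' records with `|z| > threshold` (default 4 control-arm SDs) for
#' exclusion.  Ages outside the fitted range are clamped to the boundary
#' bin.
#'
#' @param data Data frame with the raw outcome and age columns.
#' @param standardizer A fitted [fit_standardizer()] object.
#' @param threshold Exclusion threshold on `|z|` (default 4).
#' @return `data` with two added columns: `<outcome>_z` and
#'   `<outcome>_excluded`.
#' @export
standardize <- function(data, standardizer, threshold = 4) {
  stopifnot(inherits(standardizer, "age_standardizer"))
  z <- z_score(standardizer, data[[standardizer$outcome]],
               data[[standardizer$age_col]], threshold = threshold)
  data[[paste0(standardizer$outcome, "_z")]] <- z$z
  data[[paste0(standardizer$outcome, "_excluded")]] <- z$excluded
  data
}

#' Z-score raw values at given ages
#'
#' Vectorised transform underlying [standardize()].
#'
#' @inheritParams standardize
#' @param raw Numeric raw scores.
#' @param age_months Numeric ages (months).
#' @param standardizer A fitted [fit_standardizer()] object.
#' @return Tibble with columns `z` and `excluded`.
#' @export
z_score <- function(standardizer, raw, age_months, threshold = 4) {
  mu <- std_mean(standardizer, age_months)
  sg <- std_sd(standardizer, age_months)
  z <- (raw - mu) / sg
  tibble(z = z, excluded = !is.na(z) & abs(z) > threshold)
}

#' Standardise a set of outcomes in one pipeline step
#'
#' Fits a control-arm standardiser for each outcome and appends the
#' `<outcome>_z` / `<outcome>_excluded` columns.  The exclusion screen is
#' applied per outcome independently, so analysed n varies by outcome.
#'
#' @inheritParams fit_standardizer
#' @param outcomes Character vector of raw score columns.
#' @param ... Passed to [fit_standardizer()].
#' @return The data with standardised-score columns added.
#' @export
standardize_scores <- function(data, outcomes, ...) {
  for (oc in outcomes) {
    std <- fit_standardizer(data, oc, ...)
    data <- standardize(data, std)
  }
  data
}

#' @describeIn fit_standardizer Tidy the fitted age-conditional moments
#'   (one row per age bin, or per polynomial coefficient).
#' @param x An `age_standardizer`.
#' @param ... Unused.
#' @method tidy age_standardizer
#' @export
tidy.age_standardizer <- function(x, ...) {
  if (x$method == "age_bins") {
    x$fitted$bins |> select("age_lo", "age_hi", "n", "mean", "sd")
  } else {
    tibble(term = names(coef(x$fitted$mean_fit)),
           mean_coef = unname(coef(x$fitted$mean_fit)))
  }
}

#' @describeIn fit_standardizer One-row fit summary.
#' @method glance age_standardizer
#' @export
glance.age_standardizer <- function(x, ...) {
  tibble(outcome = x$outcome, method = x$method, fit_n = x$fit_n,
         fit_arm = x$fit_arm,
         n_bins = if (x$method == "age_bins") nrow(x$fitted$bins) else NA_integer_,
         age_min = x$age_range[1], age_max = x$age_range[2])
}

#' Serialise an age-standardiser to YAML
#'
#' Writes the bin edges, means and SDs (or polynomial coefficients) for
#' audit.
#'
#' @param standardizer A fitted `age_standardizer`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_standardizer_yaml <- function(standardizer, path) {
  x <- standardizer
  payload <- list(outcome = x$outcome, method = x$method, fit_n = x$fit_n,
                  fit_arm = x$fit_arm, age_range = as.list(x$age_range))
  if (x$method == "age_bins") {
    payload$bins <- lapply(seq_len(nrow(x$fitted$bins)), function(i) {
      as.list(x$fitted$bins[i, c("age_lo", "age_hi", "n", "mean", "sd")])
    })
  } else {
    payload$mean_coefficients <- as.list(coef(x$fitted$mean_fit))
    payload$sd_coefficients <- as.list(coef(x$fitted$sd_fit))
  }
  yaml::write_yaml(payload, path)
  invisible(path)
}
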