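# Instrument scorers.  All scorers are strict: responses are validated
# against the registered dictionaries, and missing required items yield a
# missing score (no imputation or pro-rating).

check_items <- function(items, expected, instrument) {
  if (is.null(items)) return(FALSE)
  missing_ids <- setdiff(expected, names(items))
  extra <- setdiff(names(items), expected)
  if (length(extra)) {
    abort(paste0(instrument, ": unknown item(s) ", paste(head(extra, 3), collapse = ", ")))
  }
  length(missing_ids) == 0 && !anyNA(items[expected])
}

#' Score the Family Care Indicators instrument
#'
#' Counts endorsed stimulation activities by the primary caregiver over
#' the previous 3 days (0-6), observed play-material varieties (0-6), and
#' sums the 11 caregiver-responsiveness / home-environment observation
#' items (0-11).
#'
#' @param items Named binary (0/1 or logical) vector of FCI item
#'   responses; item ids per `instrument_dictionary("fci")`.  Items beyond
#'   the FCI dictionary raise an error; incomplete subscales score `NA`.
#' @param respondent Whose stimulation activities are counted.  The
#'   default, `"primary_caregiver"`, restricts to the caregiver enrolled
#'   in the trial; `"any_adult"` is a reporting variant.
#' @return One-row tibble with `fci_activities`, `fci_materials`,
#'   `fci_observation`.
#' @export
#' @examples
#' items <- setNames(rep(1, 23), unlist(instrument_dictionary("fci")[1:3]))
#' score_fci(items)
score_fci <- function(items, respondent = c("primary_caregiver", "any_adult")) {
  respondent <- match.arg(respondent)
  all_ids <- c(fci_item_ids("activities"), fci_item_ids("materials"),
               fci_item_ids("observation"))
  if (!is.null(items)) {
    extra <- setdiff(names(items), all_ids)
    if (length(extra)) {
      abort(paste0("fci: unknown item(s) ", paste(head(extra, 3), collapse = ", ")))
    }
    bad <- !items[!is.na(items)] %in% c(0, 1)
    if (any(bad)) abort("fci: responses must be binary 0/1")
  }
  subscale_sum <- function(subscale) {
    ids <- fci_item_ids(subscale)
    if (is.null(items) || !all(ids %in% names(items)) || anyNA(items[ids])) {
      return(NA_integer_)
    }
    as.integer(sum(items[ids]))
  }
  tibble(fci_activities = subscale_sum("activities"),
         fci_materials = subscale_sum("materials"),
         fci_observation = subscale_sum("observation"))
}

#' Score the Ages and Stages inventory
#'
#' Per-domain raw scores are the sum of item scores under the scoring
#' scheme (default: yes = 10, sometimes = 5, not yet = 0); the total is
#' the sum of the five domain raws, computed on the raw (unstandardised)
#' scale.  A domain with any missing item scores `NA`, and the total is
#' `NA` if any domain is.
#'
#' @param items Named character vector of responses in
#'   `c("yes", "sometimes", "not_yet")`, item ids `<domain>_<i>`.
#' @param scheme Named numeric scoring scheme (default the 10/5/0 ASQ
#'   convention).
#' @param items_per_domain Items per domain in this adaptation
#'   (default from the dictionary).
#' @return One-row tibble with `asqi_<domain>` raw scores and
#'   `asqi_total`.
#' @export
score_asqi <- function(items, scheme = NULL, items_per_domain = NULL) {
  dict <- instrument_dictionary("asqi")
  scheme <- scheme %||% unlist(dict$default_scheme)
  npd <- items_per_domain %||% dict$items_per_domain
  domains <- dict$domains
  all_ids <- unlist(map(domains, asqi_item_ids, n_items = npd))
  if (!is.null(items)) {
    extra <- setdiff(names(items), all_ids)
    if (length(extra)) {
      abort(paste0("asqi: unknown item(s) ", paste(head(extra, 3), collapse = ", ")))
    }
    bad <- !items[!is.na(items)] %in% names(scheme)
    if (any(bad)) {
      abort(paste0("asqi: responses must be one of ",
                   paste(names(scheme), collapse = "/")))
    }
  }
  domain_raw <- function(domain) {
    ids <- asqi_item_ids(domain, npd)
    if (is.null(items) || !all(ids %in% names(items)) || anyNA(items[ids])) {
      return(NA_real_)
    }
    sum(scheme[items[ids]])
  }
  raws <- setNames(map_dbl(domains, domain_raw), paste0("asqi_", domains))
  out <- as_tibble(as.list(raws))
  out$asqi_total <- if (anyNA(raws)) NA_real_ else sum(raws)
  out
}

#' Score minimum dietary diversity
#'
#' Maternal indicator (MDD-W): adequate diversity when at least 5 of the
#' 10 registered food groups were consumed in the previous 24 hours.
#' Child indicator: at least 5 of 8 groups, counting breastmilk as a
#' group.
#'
#' @param food_groups Character vector (a set) of food groups consumed,
#'   drawn from the registered list for the role.
#' @param role `"maternal"` or `"child"`.
#' @param breastfed For the child indicator, adds `"breastmilk"` to the
#'   set when `TRUE` (ignored for maternal).
#' @return Logical flag (`NA` if `food_groups` is `NULL`).
#' @export
#' @examples
#' score_mdd(c("grains", "legumes", "dairy", "eggs", "other_fruits"), "maternal")
score_mdd <- function(food_groups, role = c("maternal", "child"), breastfed = FALSE) {
  role <- match.arg(role)
  if (is.null(food_groups)) return(NA)
  registered <- diet_groups(role)
  if (role == "child" && isTRUE(breastfed)) {
    food_groups <- union(food_groups, "breastmilk")
  }
  bad <- setdiff(food_groups, registered)
  if (length(bad)) {
    abort(paste0("diet (", role, "): unregistered food group(s) ",
                 paste(head(bad, 3), collapse = ", ")))
  }
  threshold <- instrument_dictionary("diet")[[paste0(role, "_threshold")]]
  length(unique(food_groups)) >= threshold
}

#' Score the CES-D depressive-symptom scale
#'
#' Sums the 20 items (each 0-3) to the continuous 0-60 score, after
#' reverse-coding the positively-worded items (4, 8, 12, 16) per the
#' standard key.
#'
#' @param items Named integer vector of the 20 raw item responses
#'   (`cesd_1` .. `cesd_20`, codes 0-3, as administered — i.e. before
#'   reverse-coding).
#' @return Integer total in `[0, 60]` (`NA` on incomplete response).
#' @export
score_cesd <- function(items) {
  ids <- cesd_item_ids()
  if (is.null(items)) return(NA_integer_)
  if (length(items) != 20 || !setequal(names(items), ids)) {
    abort("cesd: exactly the 20 registered items are required")
  }
  vals <- items[ids]
  if (anyNA(vals)) return(NA_integer_)
  if (any(!vals %in% 0:3)) abort("cesd: responses must be integers 0-3")
  rev_items <- instrument_dictionary("cesd")$reverse_items
  vals[rev_items] <- 3 - vals[rev_items]
  as.integer(sum(vals))
}

#' Score the communicative development word inventories
#'
#' Counts endorsed words in the receptive and expressive inventories.
#' The expressive score is only defined for children over 9 months.
#'
#' @param items Named binary vector over the registered word ids
#'   (receptive required; expressive optional for younger children).
#' @param age_months Child age in months at assessment.
#' @return One-row tibble with `cdi_receptive` and `cdi_expressive`.
#' @export
score_cdi <- function(items, age_months = NA_real_) {
  rec_ids <- cdi_word_ids("receptive")
  exp_ids <- cdi_word_ids("expressive")
  if (is.null(items)) {
    return(tibble(cdi_receptive = NA_integer_, cdi_expressive = NA_integer_))
  }
  extra <- setdiff(names(items), c(rec_ids, exp_ids))
  if (length(extra)) {
    abort(paste0("cdi: unknown word id(s) ", paste(head(extra, 3), collapse = ", ")))
  }
  count <- function(ids) {
    if (!all(ids %in% names(items)) || anyNA(items[ids])) return(NA_integer_)
    as.integer(sum(items[ids]))
  }
  expressive <- count(exp_ids)
  min_age <- instrument_dictionary("cdi")$expressive_min_age_months
  if (!is.na(age_months) && age_months <= min_age) expressive <- NA_integer_
  tibble(cdi_receptive = count(rec_ids), cdi_expressive = expressive)
}

#' Score every instrument across a trial dataset
#'
#' Maps the item-response list-columns of a trial dataset through the
#' instrument scorers and appends/overwrites the scored outcome columns,
#' including the two minimum-dietary-diversity flags.  Rows without item
#' responses (e.g. lost to follow-up) score `NA` throughout.
#'
#' @param data A trial tibble with item list-columns as produced by
#'   [simulate_trial()] (`fci_items`, `asqi_items`, `cesd_items`,
#'   `cdi_items`, `diet_maternal`, `diet_child`).
#' @param instruments Character vector choosing which instruments to
#'   score (default all present).
#' @return The data with scored outcome columns replaced by the scores
#'   computed from items.
#' @export
score_trial <- function(data,
                        instruments = c("fci", "asqi", "cesd", "cdi", "diet")) {
  stopifnot(is.data.frame(data))
  instruments <- match.arg(instruments, several.ok = TRUE)
  if ("fci" %in% instruments && "fci_items" %in% names(data)) {
    sc <- list_rbind(map(data$fci_items, score_fci))
    data[names(sc)] <- sc
  }
  if ("asqi" %in% instruments && "asqi_items" %in% names(data)) {
    sc <- list_rbind(map(data$asqi_items, score_asqi))
    data[names(sc)] <- sc
  }
  if ("cesd" %in% instruments && "cesd_items" %in% names(data)) {
    data$cesd <- map_dbl(data$cesd_items, function(x) as.numeric(score_cesd(x)))
  }
  if ("cdi" %in% instruments && "cdi_items" %in% names(data)) {
    sc <- list_rbind(map2(data$cdi_items, data$child_age_months,
                          function(x, a) score_cdi(x, a)))
    data[names(sc)] <- sc
  }
  if ("diet" %in% instruments && "diet_maternal" %in% names(data)) {
    data$maternal_mdd <- map_lgl(data$diet_maternal, score_mdd, role = "maternal")
    min_age <- instrument_dictionary("diet")$child_min_age_months
    data$child_mdd <- map2_lgl(data$diet_child, data$child_age_months,
      function(g, a) {
        if (is.na(a) || a <= min_age) return(NA)
        score_mdd(g, role = "child")
      })
  }
  data
}
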