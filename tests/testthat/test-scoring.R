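test_that("FCI subscales count endorsed items within their ranges", {
  full <- make_fci_items(6, 6, 11)
  expect_equal(score_fci(full),
               tibble::tibble(fci_activities = 6L, fci_materials = 6L,
                              fci_observation = 11L))
  none <- make_fci_items(0, 0, 0)
  expect_equal(unlist(score_fci(none)), c(fci_activities = 0L,
                                          fci_materials = 0L,
                                          fci_observation = 0L))
  # three endorsed activities -> activities = 3, independent of which
  three <- make_fci_items(0, 0, 0)
  three[c("played_with", "sang_songs", "read_books")] <- 1L
  expect_equal(score_fci(three)$fci_activities, 3L)
})

test_that("FCI scoring rejects unknown items and propagates missingness", {
  expect_error(score_fci(c(unknown_item = 1)), "unknown item")
  partial <- make_fci_items(2, 3, 5)
  partial["sang_songs"] <- NA
  sc <- score_fci(partial)
  expect_true(is.na(sc$fci_activities))
  expect_equal(sc$fci_materials, 3L)   # other subscales unaffected
})

test_that("ASQ inventory domain raws follow the 10/5/0 scheme and add up", {
  domains <- instrument_dictionary("asqi")$domains
  ids <- unlist(lapply(domains, function(d) paste0(d, "_", 1:6)))
  all_yes <- setNames(rep("yes", 30), ids)
  sc <- score_asqi(all_yes)
  expect_true(all(unlist(sc[paste0("asqi_", domains)]) == 60))
  expect_equal(sc$asqi_total, 300)
  all_no <- setNames(rep("not_yet", 30), ids)
  expect_equal(score_asqi(all_no)$asqi_total, 0)

  # additivity on a random mixed sheet, invariant to item order
  withr::with_seed(7, {
    mixed <- setNames(sample(c("yes", "sometimes", "not_yet"), 30, TRUE), ids)
  })
  sc1 <- score_asqi(mixed)
  expect_equal(sc1$asqi_total, sum(unlist(sc1[paste0("asqi_", domains)])))
  sc2 <- score_asqi(mixed[sample(names(mixed))])
  expect_equal(sc1, sc2)
})

test_that("ASQ missing domains disable that domain and the total", {
  domains <- instrument_dictionary("asqi")$domains
  ids <- unlist(lapply(domains, function(d) paste0(d, "_", 1:6)))
  resp <- setNames(rep("sometimes", 30), ids)
  resp <- resp[names(resp) != "gross_motor_3"]
  sc <- score_asqi(resp)
  expect_true(is.na(sc$asqi_gross_motor))
  expect_true(is.na(sc$asqi_total))
  expect_equal(sc$asqi_communication, 30)
  expect_error(score_asqi(c(resp, bogus_9 = "yes")), "unknown item")
})

test_that("dietary diversity thresholds are 5 of 10 (maternal) and 5 of 8 (child)", {
  mg <- diet_groups("maternal")
  expect_true(score_mdd(mg[1:5], "maternal"))
  expect_false(score_mdd(mg[1:4], "maternal"))
  expect_true(score_mdd(c("breastmilk", "grains", "eggs", "dairy",
                          "flesh_foods"), "child"))
  expect_true(score_mdd(c("grains", "eggs", "dairy", "flesh_foods"), "child",
                        breastfed = TRUE))
  expect_false(score_mdd(character(0), "maternal"))
  expect_error(score_mdd(c("pizza"), "maternal"), "unregistered")
})

test_that("CES-D scoring reverse-codes the positive items and sums to 0-60", {
  ids <- paste0("cesd_", 1:20)
  rev_items <- instrument_dictionary("cesd")$reverse_items
  floor_resp <- setNames(rep(0L, 20), ids)
  floor_resp[rev_items] <- 3L          # reverse-coded: contributes 0
  expect_equal(score_cesd(floor_resp), 0L)
  ceiling_resp <- setNames(rep(3L, 20), ids)
  ceiling_resp[rev_items] <- 0L
  expect_equal(score_cesd(ceiling_resp), 60L)
  # hand-summed sheet: non-reverse items 1,2,3,5 at raw 1 contribute 4 and
  # item 7 at raw 3 contributes 3; reverse item 4 at raw 1 contributes 2;
  # reverse items 8/12/16 at raw 3 contribute 0.  Total = 9.
  sheet <- setNames(rep(0L, 20), ids)
  sheet[1:5] <- 1L
  sheet[7] <- 3L
  sheet[c(8, 12, 16)] <- 3L
  expect_equal(score_cesd(sheet), 9L)
  expect_error(score_cesd(setNames(rep(0L, 19), ids[1:19])), "20")
  expect_error(score_cesd(setNames(c(rep(0L, 19), 5L), ids)), "0-3")
})

test_that("CDI counts endorsed words and gates expressive at 9 months", {
  rec <- setNames(rep(0L, 100), cdi_word_ids_test("receptive"))
  rec[1:12] <- 1L
  expr <- setNames(rep(0L, 100), cdi_word_ids_test("expressive"))
  expr[1:4] <- 1L
  sc <- score_cdi(c(rec, expr), age_months = 15)
  expect_equal(sc$cdi_receptive, 12L)
  expect_equal(sc$cdi_expressive, 4L)
  young <- score_cdi(c(rec, expr), age_months = 7)
  expect_true(is.na(young$cdi_expressive))
  expect_equal(young$cdi_receptive, 12L)
  expect_error(score_cdi(c(nonword = 1), 15), "unknown word")
})

test_that("scoring the generated item responses reproduces the generated scores", {
  trial <- fixture_trial_items
  rescored <- score_trial(trial)
  for (col in c("fci_activities", "fci_materials", "fci_observation",
                "cesd", "cdi_receptive", "cdi_expressive",
                paste0("asqi_", instrument_dictionary("asqi")$domains))) {
    expect_equal(as.numeric(rescored[[col]]), as.numeric(trial[[col]]),
                 info = col)
  }
  expect_equal(rescored$asqi_total,
               rowSums(rescored[paste0("asqi_",
                                       instrument_dictionary("asqi")$domains)]))
  # MDD flags equal the threshold rule applied to the group counts
  followed <- rescored$followed_up
  expect_equal(rescored$maternal_mdd[followed],
               trial$maternal_food_groups[followed] >= 5)
})
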