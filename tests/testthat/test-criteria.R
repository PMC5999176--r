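test_that("single-proband presentations match the expected criteria", {
  expect_identical(matched(crc_proband_hist(45)), 1L)
  expect_identical(evaluate_history(crc_proband_hist(45))$recommendation,
                   "refer_lynch")

  # CRC over 70, nothing else: no rule can fire
  r <- evaluate_history(crc_proband_hist(75))
  expect_identical(r$matched_criteria, integer(0))
  expect_identical(r$recommendation, "no_referral")

  # endometrial carcinoma under 50 also fires criterion 1
  expect_identical(matched(hist_of(48, endo(48))), 1L)

  # synchronous second CRC under 70
  h5 <- hist_of(55, dplyr::bind_rows(crc(55), crc(55, "synchronous")))
  expect_true(5L %in% matched(h5))

  # metachronous Lynch tumor under 70 alongside CRC
  h6 <- hist_of(62, dplyr::bind_rows(
    crc(58),
    tumor_diagnosis("stomach", age_at_diagnosis = 62, chronology = "metachronous")
  ))
  expect_true(6L %in% matched(h6))

  # prior-testing answer alone routes to the discretionary referral
  h13 <- hist_of(60, prior_testing_unclear = TRUE)
  r13 <- evaluate_history(h13)
  expect_identical(r13$matched_criteria, 13L)
  expect_identical(r13$recommendation, "refer_other")
})

test_that("family criteria combine proband and relative conditions", {
  # first-degree relative with CRC < 50, healthy proband: criterion 2 only
  h2 <- hist_of(40, NULL, relative("sibling", diagnoses = crc(45)))
  expect_identical(matched(h2), 2L)

  # CRC proband (any age) + first-degree relative < 50: criteria 2 and 7
  h27 <- crc_proband_hist(65, relative("sibling", diagnoses = crc(45)))
  expect_identical(matched(h27), c(2L, 7L))
  expect_identical(evaluate_history(h27)$recommendation, "refer_lynch")

  # both 50-70: familial CRC criterion 11
  h11 <- crc_proband_hist(60, relative("sibling", diagnoses = crc(55)))
  expect_identical(matched(h11), 11L)
  expect_identical(evaluate_history(h11)$recommendation, "refer_fcc")

  # proband 50-70 + second-degree relative < 70: criterion 12
  h12 <- crc_proband_hist(60, relative("aunt_uncle", "maternal", crc(65)))
  expect_identical(matched(h12), 12L)
  expect_identical(evaluate_history(h12)$recommendation, "refer_fcc")

  # known MMR mutation anywhere in the family: criterion 3
  h3 <- hist_of(40, NULL, relative("grandparent", "paternal",
                                   known_mmr_mutation = TRUE))
  expect_identical(matched(h3), 3L)

  # double-counting: aunt with CRC + endometrial carcinoma counts as two
  # relatives, grandparent as the third, all maternal: criterion 4
  h4 <- hist_of(40, NULL,
    relative("aunt_uncle", "maternal", dplyr::bind_rows(crc(60), endo(64))),
    relative("grandparent", "maternal", crc(62))
  )
  expect_identical(matched(h4), 4L)
  expect_identical(evaluate_history(h4)$recommendation, "refer_lynch")

  # criterion 8: affected proband under 70 with two affected relatives
  h8 <- crc_proband_hist(60,
    relative("sibling", diagnoses = crc(62)),
    relative("aunt_uncle", "maternal", endo(55))
  )
  expect_true(8L %in% matched(h8))

  # criterion 9: healthy proband, two first-degree relatives 50-70
  h9 <- hist_of(40, NULL,
    relative("parent", "maternal", crc(60)),
    relative("sibling", diagnoses = crc(65))
  )
  expect_true(9L %in% matched(h9))

  # criterion 10: first-degree 50-70 plus second-degree < 70, same side
  h10 <- hist_of(40, NULL,
    relative("sibling", diagnoses = crc(60)),
    relative("grandparent", "paternal", crc(45))
  )
  expect_true(10L %in% matched(h10))
})

test_that("check_criterion agrees with evaluate and rejects bad indices", {
  h <- crc_proband_hist(45)
  expect_true(check_criterion(h, 1))
  expect_false(check_criterion(h, 9))
  for (k in 1:13) {
    expect_identical(check_criterion(h, k), k %in% matched(h))
  }
  h13 <- hist_of(60, prior_testing_unclear = TRUE)
  expect_true(check_criterion(h13, 13))
  expect_error(check_criterion(h, 0), "between 1 and 13")
  expect_error(check_criterion(h, 14), "between 1 and 13")
})

test_that("age boundaries are literal: strict '<' and inclusive '50-70'", {
  # criterion 1 at the 50 boundary
  expect_true(1L %in% matched(crc_proband_hist(49)))
  expect_false(1L %in% matched(crc_proband_hist(50)))

  # [50, 70] includes both endpoints (criterion 11)
  for (ages in list(c(50, 50), c(70, 70), c(50, 70))) {
    h <- crc_proband_hist(ages[1],
                          relative("sibling", diagnoses = crc(ages[2])))
    expect_true(11L %in% matched(h), label = paste(ages, collapse = "/"))
  }
  h71 <- crc_proband_hist(71, relative("sibling", diagnoses = crc(60)))
  expect_false(11L %in% matched(h71))
  h49 <- crc_proband_hist(49, relative("sibling", diagnoses = crc(60)))
  expect_false(11L %in% matched(h49))

  # 70 never satisfies '< 70' (criterion 12's second-degree condition)
  h70 <- crc_proband_hist(60, relative("aunt_uncle", "maternal", crc(70)))
  expect_false(12L %in% matched(h70))
  h69 <- crc_proband_hist(60, relative("aunt_uncle", "maternal", crc(69)))
  expect_true(12L %in% matched(h69))

  # proband at exactly 70 satisfies 50-70 (criterion 12) but not the
  # 'person' predicate nor '< 70'
  h_p70 <- crc_proband_hist(70, relative("aunt_uncle", "maternal", crc(65)))
  expect_true(12L %in% matched(h_p70))
  expect_false(8L %in% matched(h_p70))
  expect_false(4L %in% matched(h_p70))
})

test_that("lineage separation: opposite sides never combine", {
  # two second-degree relatives on opposite sides: no footnote-d criterion
  h_opp <- hist_of(40, NULL,
    relative("aunt_uncle", "maternal", crc(60)),
    relative("grandparent", "paternal", dplyr::bind_rows(crc(55), endo(60)))
  )
  expect_identical(matched(h_opp), integer(0))

  # same configuration on one side fires criterion 4
  h_same <- hist_of(40, NULL,
    relative("aunt_uncle", "paternal", crc(60)),
    relative("grandparent", "paternal", dplyr::bind_rows(crc(55), endo(60)))
  )
  expect_identical(matched(h_same), 4L)

  # direct relatives bridge either side (the sibling also pairs with the
  # grandparent for criterion 10)
  h_direct <- hist_of(40, NULL,
    relative("sibling", diagnoses = dplyr::bind_rows(crc(55), endo(60))),
    relative("grandparent", "paternal", crc(60))
  )
  expect_identical(matched(h_direct), c(4L, 10L))

  # criterion 10 demands the two relatives share a side
  h10_opp <- hist_of(40, NULL,
    relative("parent", "maternal", crc(60)),
    relative("grandparent", "paternal", crc(45))
  )
  expect_false(10L %in% matched(h10_opp))
})

test_that("the 'person' predicate gates criteria 4, 9 and 10", {
  rels <- list(
    relative("parent", "maternal", crc(60)),
    relative("sibling", diagnoses = crc(65))
  )
  # CRC proband at 60 is a 'patient', not a 'person': criterion 9 blocked
  h_patient <- do.call(hist_of, c(list(60, crc(60)), rels))
  expect_false(9L %in% matched(h_patient))
  # CRC diagnosed over 70 restores 'person' status
  h_old_crc <- do.call(hist_of, c(list(75, crc(75)), rels))
  expect_true(9L %in% matched(h_old_crc))
  # a non-CRC, non-Lynch cancer at any age also leaves 'person' status
  h_breast <- do.call(hist_of, c(
    list(45, tumor_diagnosis("breast", age_at_diagnosis = 45)), rels))
  expect_true(9L %in% matched(h_breast))
  # unknown age on a CRC fails the '> 70' branch conservatively
  h_na <- do.call(hist_of, c(list(75, tumor_diagnosis("colorectum")), rels))
  expect_false(9L %in% matched(h_na))
})

test_that("a referral result tidies to one labelled row per criterion", {
  td <- tidy(evaluate_history(crc_proband_hist(45)))
  expect_identical(nrow(td), 13L)
  expect_identical(td$criterion[td$matched], 1L)
  expect_identical(td$group, c(rep("lynch", 8), rep("fcc", 4), "other"))
})

test_that("evaluation refuses invalid histories, naming the field", {
  bad <- hist_of(60, tumor_diagnosis("colorectum", age_at_diagnosis = 200))
  expect_error(evaluate_history(bad), "age_at_diagnosis")
})
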