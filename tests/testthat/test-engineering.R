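test_that("inclusion filters partition the input and log the first failing rule", {
  coh <- generate_cohort(cohort_spec(n_patients = 481, seed = 8, censor_prop = 0.3))
  flt <- apply_inclusion_filters(coh)
  expect_equal(nrow(flt$kept) + nrow(flt$excluded), nrow(coh))
  expect_equal(nrow(flt$log), nrow(flt$excluded))
  expect_true(all(flt$log$rule %in% c("missing_fields", "min_followup",
                                      "insufficient_followup_progression_free")))
  # kept rows all classifiable at the one-year boundary
  expect_silent(derive_progression_category(
    flt$kept$pfs_months, flt$kept$event, flt$kept$followup_months))

  # threshold case: censored at half a month fails the minimum follow-up rule
  short <- coh[1, ]
  short$followup_months <- 0.5; short$pfs_months <- 0.5; short$event <- 0L
  one <- apply_inclusion_filters(short)
  expect_equal(nrow(one$kept), 0L)
  expect_equal(one$log$rule, "min_followup")

  # vacuous filter: complete rows, long follow-up, all progressed
  clean <- coh[1:20, ]
  clean$followup_months <- 24; clean$pfs_months <- 6; clean$event <- 1L
  expect_equal(nrow(apply_inclusion_filters(clean)$excluded), 0L)

  expect_error(apply_inclusion_filters(coh[, -2]), "age")
})

test_that("a 481-row table with 163 rule-failing rows keeps 318", {
  coh <- generate_cohort(cohort_spec(n_patients = 481, seed = 13, censor_prop = 0))
  # force exactly 163 rows to fail (censored progression-free, short follow-up)
  bad <- seq_len(163)
  coh$followup_months[bad] <- 0.5
  coh$pfs_months[bad] <- 0.5
  coh$event[bad] <- 0L
  flt <- apply_inclusion_filters(coh)
  expect_equal(nrow(flt$kept), 318L)
  expect_equal(nrow(flt$log), 163L)
  expect_equal(round(100 * nrow(flt$log) / nrow(coh)), 34)
})

test_that("action codes follow the line x generation dictionary", {
  expect_equal(derive_action_code(1, "1"), 0L)
  expect_equal(derive_action_code(1, "2+"), 1L)
  expect_equal(derive_action_code(2, "2+"), 3L)
  expect_equal(derive_action_code(5, "1"), 2L)
  expect_equal(derive_action_code(c(1, 1, 3, 2), c("1", "2+", "1", "2+")),
               c(0L, 1L, 2L, 3L))
  expect_error(derive_action_code(0, "1"), "tki_line")
  expect_error(derive_action_code(1, "3rd"), "tki_generation")

  # round trip: code decodes back to (line dichotomy, generation)
  line <- c(1, 1, 2, 4); gen <- c("1", "2+", "2+", "1")
  code <- derive_action_code(line, gen)
  expect_equal(code >= 2, line >= 2)
  expect_equal(code %in% c(1, 3), gen == "2+")
})

test_that("progression category dichotomizes PFS at an inclusive 12 months", {
  expect_equal(derive_progression_category(6, 1, 8), 1L)
  expect_equal(derive_progression_category(12, 1, 12), 0L)  # boundary: >= one year
  expect_equal(derive_progression_category(14, 0, 14), 0L)
  expect_error(derive_progression_category(6, 0, 6), "unclassifiable")
})

test_that("feature engineering adds the derived columns and keeps rows", {
  coh <- generate_cohort(cohort_spec(n_patients = 318, seed = 4))
  kept <- apply_inclusion_filters(coh)$kept
  eng <- engineer_features(kept)
  expect_equal(nrow(eng), nrow(kept))
  expect_equal(eng[, cohort_columns()], kept)
  expect_equal(eng$lognlr, log(kept$neutrophils / kept$lymphocytes),
               tolerance = 1e-12)

  row <- kept[1, ]
  row$neutrophils <- 3200; row$lymphocytes <- 1000
  expect_equal(engineer_features(row)$lognlr, log(3.2), tolerance = 1e-9)
  row$age <- 1
  expect_equal(engineer_features(row)$logage, 0)
  row$neutrophils <- 0
  expect_error(engineer_features(row), row$patient_id)
})

test_that("cohort summary reproduces count percentages", {
  coh <- generate_cohort(cohort_spec(n_patients = 318, seed = 21, censor_prop = 0))
  # realize the published action counts exactly: 202/47/15/54
  act <- rep(0:3, c(202, 47, 15, 54))
  coh$tki_line <- ifelse(act <= 1, 1L, 2L)
  coh$tki_generation <- ifelse(act %in% c(1, 3), "2+", "1")
  eng <- engineer_features(apply_inclusion_filters(coh)$kept)
  expect_equal(nrow(eng), 318L)
  s <- summarize_cohort(eng)
  acts <- s$categorical[s$categorical$variable == "action_code", ]
  expect_equal(acts$pct[acts$level == "0"], 63.5)
  expect_equal(acts$n[acts$level == "0"], 202L)

  # 166 of 318 female prints as 52.2%
  coh$gender <- rep(c("female", "male"), c(166, 152))
  s2 <- summarize_cohort(coh)
  fem <- s2$categorical[s2$categorical$variable == "gender", ]
  expect_equal(fem$pct[fem$level == "female"], 52.2)

  # percentages per variable sum to 100 within rounding slack
  sums <- tapply(s$categorical$pct, s$categorical$variable, sum)
  expect_true(all(abs(sums - 100) <= 0.11))

  # single-level factor normalizes to 100%
  coh$gender <- "female"
  s3 <- summarize_cohort(coh)
  expect_equal(s3$categorical$pct[s3$categorical$variable == "gender"], 100.0)

  expect_error(summarize_cohort(coh[0, ]), "empty")
})

test_that("NLR t-test is the pooled two-sample test with df = n1 + n2 - 2", {
  eng <- make_engineered(500, seed = 6)
  # force group sizes 196 / 122
  idx <- c(which(eng$progression_category == 1)[1:196],
           which(eng$progression_category == 0)[1:122])
  sub <- eng[idx, ]
  res <- nlr_progression_ttest(sub)
  expect_equal(res$df, 316L)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)

  # 5 vs 5 fixture against the hand-computed pooled formula
  x1 <- c(2.1, 3.4, 1.9, 4.2, 2.8)   # progressing group NLRs
  x0 <- c(3.0, 2.5, 3.8, 4.1, 3.3)   # progression-free group NLRs
  tiny <- data.frame(
    neutrophils = c(x1, x0) * 1000, lymphocytes = 1000,
    progression_category = rep(c(1L, 0L), each = 5))
  res2 <- nlr_progression_ttest(tiny)
  sp2 <- (4 * var(x1) + 4 * var(x0)) / 8
  t_oracle <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(res2$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res2$df, 8L)
  expect_equal(res2$p_value, 2 * pt(-abs(t_oracle), 8), tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  same <- data.frame(neutrophils = rep(c(2000, 3000), 4), lymphocytes = 1000,
                     progression_category = rep(c(0L, 1L), each = 4))
  res3 <- nlr_progression_ttest(same)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)

  expect_error(nlr_progression_ttest(tiny[c(1, 6:10), ]), "at least 2")
})
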