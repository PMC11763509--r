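test_that("Q summaries collapse correctly for constant networks and one state", {
  states <- matrix(rnorm(20), 10, 2)
  fit <- make_manual_fit(constant_net(2, bias = c(1, 2, 3, 4)),
                         c("f1", "f2"), states)
  s <- summarize_q(fit)
  expect_equal(unname(unlist(s["mean", ])), c(1, 2, 3, 4))
  expect_equal(unname(unlist(s["min", ])), c(1, 2, 3, 4))
  expect_equal(unname(unlist(s["max", ])), c(1, 2, 3, 4))
  expect_equal(unname(unlist(s["sd", ])), rep(0, 4))

  one <- make_manual_fit(linear_net(2, j = 1, slope = 1), c("f1", "f2"),
                         matrix(c(0.3, -1), 1, 2))
  s1 <- summarize_q(one)
  expect_equal(unlist(s1["mean", ]), unlist(s1["min", ]))
  expect_equal(unlist(s1["mean", ]), unlist(s1["max", ]))
  expect_true(all(s1["min", ] <= s1["mean", ] & s1["mean", ] <= s1["max", ]))

  expect_error(summarize_q(make_manual_fit(constant_net(2), c("f1", "f2"),
                                           matrix(0, 0, 2))), "empty")
})

test_that("action frequencies conserve n and respect masking", {
  states <- matrix(rnorm(60), 30, 2)
  later <- rep(c(FALSE, TRUE), c(18, 12))
  fit <- make_manual_fit(constant_net(2, bias = c(0, 0, 0, 1)),
                         c("f1", "f2"), states, line_later = later)
  fr <- action_frequencies(fit)
  expect_equal(sum(fr), 30)
  expect_equal(sum(fr["first_line", ]), 18)
  expect_equal(sum(fr["later_line", ]), 12)
  # masked: first-line rows cannot land on actions 2/3
  expect_equal(unname(fr["first_line", c("action_2", "action_3")]), c(0L, 0L))
  # equal Q on unmasked first-line actions: tie broken toward action 0
  expect_equal(unname(fr["first_line", "action_0"]), 18L)
  # later-line rows prefer the biased action 3
  expect_equal(unname(fr["later_line", "action_3"]), 12L)
})

test_that("partial dependence is flat for constant networks and linear for linear ones", {
  states <- matrix(rnorm(40), 20, 2)
  flatfit <- make_manual_fit(constant_net(2, bias = c(5, 6, 7, 8)),
                             c("f1", "f2"), states)
  pd <- partial_dependence(flatfit, "f1", grid = seq(-2, 2, length.out = 5))
  expect_true(all(apply(pd[, -1], 2, function(col) max(col) - min(col)) == 0))

  # network adding slope * f1 to action 1 only: curve slope on the
  # (identity-scaled) feature equals the planted slope
  slope <- 1.7
  linfit <- make_manual_fit(linear_net(2, j = 1, slope = slope),
                            c("f1", "f2"), states)
  grid <- seq(-3, 3, length.out = 7)
  pd2 <- partial_dependence(linfit, "f1", grid = grid)
  est <- coef(lm(pd2$action_1 ~ grid))[2]
  expect_equal(unname(est), slope, tolerance = 1e-9)
  expect_true(all(pd2$action_0 == 0 & pd2$action_2 == 0 & pd2$action_3 == 0))

  # binary feature defaults to a two-point grid
  bstates <- cbind(f1 = rep(c(0, 1), 10), f2 = rnorm(20))
  bfit <- make_manual_fit(linear_net(2), c("f1", "f2"), bstates)
  pd3 <- partial_dependence(bfit, "f1")
  expect_equal(nrow(pd3), 2L)
  expect_equal(pd3$f1, c(0, 1))

  expect_error(partial_dependence(linfit, "nope"), "unknown feature")
})

test_that("the ranking AUC hits its analytic anchors and transform invariance", {
  set.seed(20)
  out <- rbinom(200, 1, 0.5)
  expect_equal(ranking_auc(out, out), 1)
  expect_lt(abs(ranking_auc(rnorm(200), out) - 0.5), 0.1)
  sc <- rnorm(200)
  expect_equal(ranking_auc(sc, out), ranking_auc(exp(3 * sc) + 7, out))
  expect_error(ranking_auc(sc, rep(1, 200)), "both classes")
})

test_that("policy AUC scores patients by their recorded-action Q", {
  eng <- make_engineered(200, seed = 23)
  fit <- tki_dqn(eng, control = train_config(total_timesteps = 4000, seed = 3))
  auc <- policy_score_auc(fit)
  q <- predict_q(fit)
  sc <- q[cbind(seq_len(nrow(q)), eng$action_code + 1L)]
  expect_equal(auc, ranking_auc(sc, 1L - eng$progression_category))
  # rewards favour matched good outcomes, so the planted signal ranks above chance
  expect_gt(auc, 0.5)
  expect_equal(policy_score_auc(fit, eng), auc)
})

test_that("recommend masks by line, breaks ties low, and validates input", {
  states <- matrix(rnorm(20), 10, 2)
  net <- constant_net(11, bias = c(2, 2, 1, 1))
  feats <- c("logage", "lognlr", "male", "ecog_high", "exon19", "smoker",
             "mets_4plus", "bone_or_liver_met", "brain_met", "comorbidity",
             "line_later")
  fit <- make_manual_fit(net, feats, matrix(rnorm(110), 10, 11))

  r_first <- recommend(fit, example_patient(tki_line = 1))
  expect_true(r_first$action %in% 0:1)
  expect_equal(r_first$action, 0L)  # tie on (2, 2) -> lowest code
  expect_equal(r_first$scenario, "first-line")
  expect_equal(r_first$masked_actions, 2:3)

  r_later <- recommend(fit, example_patient(tki_line = 3))
  expect_true(r_later$action %in% 2:3)
  expect_equal(r_later$action, 2L)  # tie on (1, 1)
  expect_equal(r_later$scenario, "later-line")
  expect_equal(r_later$label, action_label(2))

  p <- example_patient(); p$age <- NULL; p$lymphocytes <- NULL
  expect_error(recommend(fit, p), "age, lymphocytes")
  expect_output(print(r_later), "Recommended action 2")
})
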