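test_that("training is bit-reproducible under a fixed seed", {
  eng <- make_engineered(120, seed = 2)
  ctl <- train_config(total_timesteps = 3000, seed = 5)
  f1 <- tki_dqn(eng, control = ctl)
  f2 <- tki_dqn(eng, control = ctl)
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, type = "action"), predict(f2, type = "action"))
  f3 <- tki_dqn(eng, control = train_config(total_timesteps = 3000, seed = 6))
  expect_false(identical(f1$params, f3$params))
})

test_that("one-step Q-estimates move toward the enumerated mean reward", {
  # short-run sanity on the discrete fixture; the full-length convergence
  # check at training scale lives in the acceptance suite
  eng <- make_discrete_fixture(n_per = 40, good_frac = 0.4)
  cfg <- reward_config(line_inconsistency_penalty = 0)
  oracle <- brute_force_q(eng, cfg, "penalized")
  fit <- suppressMessages(tki_dqn(
    eng, reward = cfg, scenario = "penalized",
    control = train_config(total_timesteps = 10000, gamma = 0, tau = 2,
                           seed = 3)))
  q <- predict_q(fit)
  key <- paste(eng$brain_met, as.integer(eng$tki_line >= 2))
  for (s in rownames(oracle)) {
    i <- which(key == s)[1]
    expect_equal(unname(q[i, ]), unname(oracle[s, ]), tolerance = 1)
  }
})

test_that("raising the generation bonus never lowers higher-generation use", {
  eng <- make_engineered(150, seed = 15)
  freq_13 <- vapply(c(0, 2), function(g) {
    fit <- tki_dqn(eng, reward = reward_config(generation_bonus = g),
                   control = train_config(total_timesteps = 8000, seed = 4))
    mean(predict(fit, type = "action") %in% c(1L, 3L))
  }, numeric(1))
  expect_gte(freq_13[2], freq_13[1])
})

test_that("masked mode never recommends a line-inconsistent action", {
  eng <- make_engineered(200, seed = 16)
  fit <- tki_dqn(eng, control = train_config(total_timesteps = 4000, seed = 1))
  a <- predict(fit, type = "action")
  first <- eng$tki_line == 1
  expect_false(any(a[first] %in% c(2L, 3L)))
  expect_false(any(a[!first] %in% c(0L, 1L)))
})

test_that("prediction applies the stored scaler and flags extrapolation", {
  eng <- make_engineered(150, seed = 17)
  fit <- tki_dqn(eng, control = train_config(total_timesteps = 2000, seed = 2))
  q <- predict_q(fit)
  expect_equal(dim(q), c(fit$n, 4L))
  expect_true(all(is.finite(q)))
  # pure function: same record scores identically, via both spellings
  q1 <- predict_q(fit, eng[5, , drop = FALSE])
  q2 <- predict(fit, eng[5, , drop = FALSE], type = "q")
  expect_identical(q1, q2)
  expect_equal(unname(drop(q1)), unname(q[5, ]), tolerance = 1e-12)
  # out-of-range record warns but is still scored
  odd <- eng[5, , drop = FALSE]
  odd$age <- 200
  odd$logage <- log(200)
  expect_warning(q_odd <- predict_q(fit, odd), "training range")
  expect_true(all(is.finite(q_odd)))
  # missing feature named in the error
  expect_error(apply_scaler(fit$scaler, matrix(0, 1, 1,
                                               dimnames = list(NULL, "logage"))),
               "lognlr")

  expect_error(train_config(total_timesteps = 0), "total_timesteps")
  expect_error(train_config(tau = 0), "tau")
})

test_that("the fitted object honours the modelling-method contracts", {
  eng <- make_engineered(150, seed = 18)
  fit <- tki_dqn(eng, control = train_config(total_timesteps = 2000, seed = 7,
                                             log_window = 250))
  expect_s3_class(fit, "tki_dqn")
  expect_output(print(fit), "One-step DQN")
  expect_named(coef(fit), c("W1", "b1", "W2", "b2", "W3", "b3"))
  expect_equal(dim(coef(fit)$W1), c(length(fit$feature_names), 64L))
  expect_equal(dim(coef(fit)$W3), c(64L, 4L))
  # training log covers the run in windows
  expect_equal(max(fit$log$timestep), 2000L)
  expect_true(all(is.finite(fit$log$mean_reward)))
  # simulate draws valid, line-consistent actions
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3L))
  expect_true(all(sims %in% 0:3))
  expect_false(any(sims[eng$tki_line == 1, ] %in% c(2L, 3L)))
  s <- summary(fit)
  expect_s3_class(s, "summary.tki_dqn")
  expect_output(print(s), "Q-values by action")
})

test_that("a fitted policy round-trips through its JSON model file", {
  eng <- make_engineered(120, seed = 19)
  fit <- tki_dqn(eng, control = train_config(total_timesteps = 1500, seed = 8))
  f <- tempfile(fileext = ".json")
  write_tki_dqn(fit, f)
  back <- read_tki_dqn(f)
  expect_equal(predict_q(back, eng), predict_q(fit, eng), tolerance = 1e-12)
  r1 <- recommend(fit, example_patient())
  r2 <- recommend(back, example_patient())
  expect_equal(r1$action, r2$action)
  expect_equal(r1$q, r2$q, tolerance = 1e-12)
})
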