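# Shared fixtures: all generated in code, seeded.

# filtered + engineered synthetic cohort
make_engineered <- function(n = 200, seed = 11, ...) {
  coh <- generate_cohort(cohort_spec(n_patients = n, seed = seed, ...))
  engineer_features(apply_inclusion_filters(coh)$kept)
}

# Engineered table with exactly four distinct states (brain_met x line),
# deterministic recorded actions and outcomes, so expected rewards per
# (stratum, action) are exact finite averages.
# Per stratum: n_per records; recorded action split evenly between the two
# line-consistent codes; within each half, `good_frac` progression-free.
make_discrete_fixture <- function(n_per = 40, good_frac = 0.4) {
  strata <- expand.grid(brain = c(0, 1), later = c(0, 1))
  rows <- lapply(seq_len(nrow(strata)), function(s) {
    brain <- strata$brain[s]; later <- strata$later[s]
    acts <- if (later) c(2L, 3L) else c(0L, 1L)
    rec_action <- rep(acts, each = n_per / 2)
    n_good <- round(good_frac * n_per / 2)
    prog <- rep(rep(c(0L, 1L), c(n_good, n_per / 2 - n_good)), 2)
    data.frame(
      patient_id = sprintf("S%d_%03d", s, seq_len(n_per)),
      age = 60, gender = "male", ecog = "0-1", mutation = "exon19",
      smoking = "never_former", n_mets_cat = "1-3",
      bone_or_liver_met = 0, brain_met = brain, comorbidity = 0,
      neutrophils = 3000, lymphocytes = 1000,
      tki_line = if (later) 2L else 1L,
      tki_generation = ifelse(rec_action %in% c(1L, 3L), "2+", "1"),
      pfs_months = ifelse(prog == 0, 14, 6),
      event = ifelse(prog == 0, 0L, 1L),
      followup_months = ifelse(prog == 0, 14, 8),
      lognlr = log(3), logage = log(60),
      action_code = rec_action, progression_category = prog,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# brute-force oracle: mean shaped reward of each action within each of the
# four (brain, later) strata of the discrete fixture
brute_force_q <- function(fixture, cfg, scenario = "penalized") {
  key <- paste(fixture$brain_met, as.integer(fixture$tki_line >= 2))
  strata <- sort(unique(key))
  out <- matrix(NA_real_, length(strata), 4,
                dimnames = list(strata, paste0("action_", 0:3)))
  for (s in strata) {
    rows <- fixture[key == s, ]
    for (a in 0:3) {
      out[s, a + 1] <- mean(compute_reward(rows, a, cfg, scenario))
    }
  }
  out
}

# hand-built tki_dqn object around explicit weights and an identity scaler
make_manual_fit <- function(params, feature_names, states,
                            line_later = rep(FALSE, nrow(states)),
                            action_code = NULL, progression_category = NULL,
                            scenario = "masked") {
  scaler <- structure(list(
    center = setNames(rep(0, length(feature_names)), feature_names),
    scale = setNames(rep(1, length(feature_names)), feature_names),
    features = feature_names, dropped = character(0)),
    class = "feature_scaler")
  colnames(states) <- feature_names
  structure(list(
    params = params,
    qspec = qnetwork_spec(length(feature_names)),
    scaler = scaler, feature_names = feature_names,
    reward = reward_config(), scenario = scenario,
    control = train_config(total_timesteps = 1),
    log = data.frame(timestep = 1, mean_reward = 0),
    states = states, line_later = line_later,
    action_code = action_code, progression_category = progression_category,
    n = nrow(states), call = quote(manual)
  ), class = "tki_dqn")
}

# zero network emitting a constant bias per action
constant_net <- function(d, bias = c(1, 2, 3, 4)) {
  list(W1 = matrix(0, d, 64), b1 = numeric(64),
       W2 = matrix(0, 64, 64), b2 = numeric(64),
       W3 = matrix(0, 64, 4), b3 = bias)
}

# network whose action-1 output is exactly slope * feature j (identity
# carried through ReLU by a positive/negative unit pair)
linear_net <- function(d, j = 1, slope = 2) {
  W1 <- matrix(0, d, 64); W1[j, 1] <- 1; W1[j, 2] <- -1
  W2 <- matrix(0, 64, 64); W2[1, 1] <- 1; W2[2, 2] <- 1
  W3 <- matrix(0, 64, 4); W3[1, 2] <- slope; W3[2, 2] <- -slope
  list(W1 = W1, b1 = numeric(64), W2 = W2, b2 = numeric(64),
       W3 = W3, b3 = numeric(4))
}

# one complete raw patient record for recommend()
example_patient <- function(tki_line = 2) {
  list(age = 64, gender = "female", ecog = "0-1", mutation = "exon19",
       smoking = "never_former", n_mets_cat = "1-3", bone_or_liver_met = 0,
       brain_met = 0, comorbidity = 0, neutrophils = 4200,
       lymphocytes = 1400, tki_line = tki_line)
}
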