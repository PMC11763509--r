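#' Reward shaping for the one-step treatment environment
#'
#' Maps (chosen action, recorded action, one-year outcome) to a scalar
#' reward. When the agent picks the treatment the patient actually received,
#' the realized outcome speaks: a progression-free year pays `match_good`,
#' early progression pays `match_bad`. When the agent picks a different
#' treatment the data are silent on the counterfactual, so a neutral
#' `mismatch` reward between the two is paid (a pluggable reward function on
#' the environment can replace this if a counterfactual model is available).
#' Actions using a second-or-higher-generation TKI (codes 1 and 3) earn an
#' additive `generation_bonus`, encoding the clinical prior that
#' higher-generation TKIs improve progression-free survival. In the
#' `"penalized"` scenario an action whose line half contradicts the
#' patient's recorded line loses `line_inconsistency_penalty`; in the
#' default `"masked"` scenario such actions are unavailable instead.
#'
#' Defaults put Q magnitudes in the low teens.
#'
#' @param match_good Reward for the recorded action when the patient was
#'   progression-free at one year.
#' @param match_bad Reward for the recorded action when progression or death
#'   occurred within a year. Must be below `match_good`.
#' @param mismatch Reward for any action other than the recorded one.
#' @param generation_bonus Additive bonus for actions 1 and 3 (>= 0).
#' @param line_inconsistency_penalty Penalty used in `"penalized"` mode.
#' @return Object of class `reward_config`.
#' @export
reward_config <- function(match_good = 15, match_bad = 10, mismatch = 12,
                          generation_bonus = 1,
                          line_inconsistency_penalty = 4) {
  if (match_good <= match_bad) {
    stop("match_good must exceed match_bad: a progression-free year must be preferred",
         call. = FALSE)
  }
  if (generation_bonus < 0) stop("generation_bonus must be >= 0", call. = FALSE)
  structure(list(match_good = match_good, match_bad = match_bad,
                 mismatch = mismatch, generation_bonus = generation_bonus,
                 line_inconsistency_penalty = line_inconsistency_penalty),
            class = "reward_config")
}

#' Reward for one treatment decision
#'
#' Deterministic given the record and chosen action; see [reward_config()]
#' for the shaping rules.
#'
#' @param record Engineered record(s): `data.frame` or list with
#'   `action_code`, `progression_category`, `tki_line`.
#' @param action Chosen action code(s) in 0..3 (recycled against records).
#' @param cfg A [reward_config()].
#' @param scenario `"masked"` (line consistency enforced upstream by action
#'   masking) or `"penalized"` (inconsistent lines penalized here).
#' @return Numeric reward vector.
#' @examples
#' rec <- list(action_code = 2, progression_category = 0, tki_line = 2)
#' compute_reward(rec, action = 2)  # match, good outcome
#' compute_reward(rec, action = 3)  # mismatch + generation bonus
#' @export
compute_reward <- function(record, action, cfg = reward_config(),
                           scenario = c("masked", "penalized")) {
  scenario <- match.arg(scenario)
  if (any(!action %in% 0:3)) stop("action must lie in 0..3", call. = FALSE)
  match <- action == record$action_code
  base <- ifelse(match,
                 ifelse(record$progression_category == 0,
                        cfg$match_good, cfg$match_bad),
                 cfg$mismatch)
  r <- base + cfg$generation_bonus * (action %in% c(1L, 3L))
  if (scenario == "penalized") {
    line_later <- record$tki_line >= 2
    inconsistent <- (action >= 2) != line_later
    r <- r - cfg$line_inconsistency_penalty * inconsistent
  }
  r
}

#' One-step treatment environment
#'
#' Episodic environment over a fixed set of engineered patient records: each
#' episode samples one patient uniformly, the agent chooses one of the four
#' line-by-generation actions, receives the shaped reward, and the episode
#' terminates. States are the standardized feature vectors. In `"masked"`
#' mode only the actions consistent with the patient's recorded treatment
#' line are selectable (first-line patients: actions 0/1; later-line:
#' actions 2/3).
#'
#' @param engineered Engineered `data.frame` from [engineer_features()].
#' @param reward A [reward_config()].
#' @param scenario `"masked"` or `"penalized"`.
#' @param scaler Optional pre-fit [standardize()] scaler to reuse.
#' @param reward_fn Optional override `function(record, action)` replacing
#'   [compute_reward()] (counterfactual hook; also used by test fixtures).
#' @return Object of class `treatment_env`.
#' @export
treatment_env <- function(engineered, reward = reward_config(),
                          scenario = c("masked", "penalized"),
                          scaler = NULL, reward_fn = NULL) {
  scenario <- match.arg(scenario)
  x <- encode_features(engineered, line = "dichotomized")
  if (is.null(scaler)) {
    std <- standardize(x)
    states <- std$states
    scaler <- std$scaler
  } else {
    states <- apply_scaler(scaler, x)
  }
  line_later <- engineered$tki_line >= 2
  allowed <- matrix(TRUE, nrow(states), 4L)
  if (scenario == "masked") {
    allowed[line_later, 1:2] <- FALSE   # actions 0, 1
    allowed[!line_later, 3:4] <- FALSE  # actions 2, 3
  }
  structure(list(states = states, scaler = scaler, allowed = allowed,
                 line_later = line_later,
                 action_code = engineered$action_code,
                 progression_category = engineered$progression_category,
                 tki_line = engineered$tki_line,
                 reward = reward, scenario = scenario, reward_fn = reward_fn,
                 n = nrow(states)),
            class = "treatment_env")
}

env_reward <- function(env, i, action) {
  rec <- list(action_code = env$action_code[i],
              progression_category = env$progression_category[i],
              tki_line = env$tki_line[i])
  if (!is.null(env$reward_fn)) env$reward_fn(rec, action)
  else compute_reward(rec, action, env$reward, env$scenario)
}

#' Run one episode of the treatment environment
#'
#' Samples one patient uniformly, asks the selector for an action among the
#' allowed ones, and returns the transition. Episodes are one decision long,
#' so `terminal` is always `TRUE`.
#'
#' @param env A [treatment_env()].
#' @param action_selector `function(state, allowed)` returning an action code;
#'   `allowed` is a logical 4-vector.
#' @return List with `index`, `state`, `action`, `reward`, `terminal`.
#' @export
run_episode <- function(env, action_selector) {
  if (env$n < 1) stop("environment holds no patients", call. = FALSE)
  i <- sample.int(env$n, 1L)
  a <- action_selector(env$states[i, ], env$allowed[i, ])
  list(index = i, state = env$states[i, ], action = a,
       reward = env_reward(env, i, a), terminal = TRUE)
}

#' Boltzmann (softmax) action probabilities and sampling
#'
#' `boltzmann_probs()` returns `P(a) = exp(q_a / tau) / sum_b exp(q_b / tau)`
#' computed with max-subtraction for overflow safety; `-Inf` entries (masked
#' actions) get probability 0. `boltzmann_select()` samples one action code
#' (0-based) from that distribution. Low temperatures approach the argmax,
#' high temperatures the uniform distribution.
#'
#' @param q Numeric vector of action values.
#' @param tau Temperature, strictly positive.
#' @return `boltzmann_probs()`: probability vector summing to 1;
#'   `boltzmann_select()`: a single 0-based action code.
#' @examples
#' boltzmann_probs(c(14.0, 14.1, 13.5, 14.7), tau = 1)
#' @export
boltzmann_probs <- function(q, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("tau must be a single positive number", call. = FALSE)
  }
  if (any(is.nan(q)) || any(q == Inf)) {
    stop("q values must be finite (or -Inf for masked actions)", call. = FALSE)
  }
  z <- (q - max(q)) / tau
  w <- exp(z)
  w / sum(w)
}

#' @rdname boltzmann_probs
#' @export
boltzmann_select <- function(q, tau) {
  p <- boltzmann_probs(q, tau)
  sample.int(length(q), 1L, prob = p) - 1L
}

#' Standardize a feature matrix, remembering the transform
#'
#' Centers and scales every column to mean 0, sd 1 over the table.
#' Zero-variance columns are dropped and recorded on the scaler so inference
#' can reproduce the exact training-time transform.
#'
#' @param x Numeric matrix.
#' @return List with `states` (standardized matrix) and `scaler` (class
#'   `feature_scaler` holding `center`, `scale`, `features`, `dropped`).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[is.na(scl) | scl == 0]
  keep <- setdiff(colnames(x), dropped)
  if (length(dropped)) {
    message("dropping zero-variance feature(s): ", paste(dropped, collapse = ", "))
  }
  scaler <- structure(list(center = ctr[keep], scale = scl[keep],
                           features = keep, dropped = dropped),
                      class = "feature_scaler")
  list(states = apply_scaler(scaler, x), scaler = scaler)
}

#' @rdname standardize
#' @param scaler A `feature_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- as.matrix(x)
  missing <- setdiff(scaler$features, colnames(x))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[, scaler$features, drop = FALSE]
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' Q-network architecture
#'
#' Multi-layer perceptron mapping a standardized state to one Q-value per
#' action: two hidden layers of 64 rectified-linear units and a linear
#' 4-unit output layer.
#'
#' @param input_dim Number of standardized features.
#' @param hidden Hidden layer widths.
#' @param output_dim Number of actions (4).
#' @return Object of class `qnetwork_spec`.
#' @export
qnetwork_spec <- function(input_dim, hidden = c(64L, 64L), output_dim = 4L) {
  stopifnot(input_dim >= 1, output_dim == 4L, all(hidden >= 1))
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim)),
            class = "qnetwork_spec")
}

#' Training configuration for the one-step DQN
#'
#' @param total_timesteps Environment interactions (default 50000).
#' @param learning_rate Adam step size.
#' @param gamma Discount factor in `[0, 1]`; inert for one-step episodes but
#'   part of the Q-learning target for completeness.
#' @param batch_size Replay minibatch size.
#' @param replay_capacity Replay buffer capacity.
#' @param target_update_interval Timesteps between target-network syncs.
#' @param tau Boltzmann exploration temperature (> 0).
#' @param seed Integer RNG seed governing all training stochasticity.
#' @param log_window Timesteps per training-log row (mean reward).
#' @return Object of class `train_config`.
#' @export
train_config <- function(total_timesteps = 50000L, learning_rate = 1e-3,
                         gamma = 0.99, batch_size = 32L,
                         replay_capacity = 10000L,
                         target_update_interval = 500L, tau = 1,
                         seed = 1L, log_window = 500L) {
  if (total_timesteps < 1) stop("total_timesteps must be >= 1", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  structure(list(total_timesteps = as.integer(total_timesteps),
                 learning_rate = learning_rate, gamma = gamma,
                 batch_size = as.integer(batch_size),
                 replay_capacity = as.integer(replay_capacity),
                 target_update_interval = as.integer(target_update_interval),
                 tau = tau, seed = as.integer(seed),
                 log_window = as.integer(log_window)),
            class = "train_config")
}

init_mlp <- function(qspec) {
  dims <- c(qspec$input_dim, qspec$hidden, qspec$output_dim)
  params <- list()
  for (l in seq_len(length(dims) - 1L)) {
    fan_in <- dims[l]
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(fan_in * dims[l + 1L], 0, sqrt(2 / fan_in)),
      fan_in, dims[l + 1L])
    params[[paste0("b", l)]] <- numeric(dims[l + 1L])
  }
  params
}

mlp_forward <- function(params, x) {
  n_layers <- length(params) / 2L
  a <- x
  n <- nrow(x)
  for (l in seq_len(n_layers)) {
    z <- a %*% params[[paste0("W", l)]]
    z <- z + rep(params[[paste0("b", l)]], each = n)
    a <- if (l < n_layers) pmax(z, 0) else z
  }
  a
}

# single-state fast path: x a plain numeric vector, returns a 4-vector
mlp_forward1 <- function(params, x) {
  n_layers <- length(params) / 2L
  a <- x
  for (l in seq_len(n_layers)) {
    z <- drop(a %*% params[[paste0("W", l)]]) + params[[paste0("b", l)]]
    a <- if (l < n_layers) pmax(z, 0) else z
  }
  a
}

# gradient of 0.5 * mean((Q[i, a_i] - y_i)^2) wrt all parameters
mlp_grad <- function(params, x, actions, targets) {
  n_layers <- length(params) / 2L
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- x
  nb <- nrow(x)
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% params[[paste0("W", l)]] +
      rep(params[[paste0("b", l)]], each = nb)
    acts[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else z
  }
  q <- acts[[n_layers + 1L]]
  n <- nrow(x)
  idx <- cbind(seq_len(n), actions + 1L)
  err <- q[idx] - targets
  loss <- 0.5 * mean(err^2)
  delta <- matrix(0, n, ncol(q))
  delta[idx] <- err / n
  grads <- list()
  for (l in rev(seq_len(n_layers))) {
    grads[[paste0("W", l)]] <- crossprod(acts[[l]], delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params[[paste0("W", l)]])) * (acts[[l]] > 0)
    }
  }
  list(grads = grads, loss = loss)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a one-step deep Q-network on a treatment environment
#'
#' Q-learning with a neural function approximator, experience replay,
#' Boltzmann exploration, and a periodically synchronized target network.
#' Because every episode is a single terminal decision, the Q-learning
#' target reduces to the immediate reward, so the network converges toward
#' the expected shaped reward of each (state, action) pair.
#'
#' @param env A [treatment_env()].
#' @param qspec A [qnetwork_spec()]; defaults to the environment's width.
#' @param cfg A [train_config()].
#' @return List with `params` (network weights), `log` (`data.frame` of
#'   `timestep`, `mean_reward`), `qspec`, `cfg`.
#' @export
train_dqn <- function(env, qspec = NULL, cfg = train_config()) {
  stopifnot(inherits(env, "treatment_env"), inherits(cfg, "train_config"))
  if (env$n < 1) stop("environment holds no patients", call. = FALSE)
  if (is.null(qspec)) qspec <- qnetwork_spec(ncol(env$states))
  set.seed(cfg$seed)
  params <- init_mlp(qspec)
  target <- params
  opt <- adam_init(params)

  cap <- cfg$replay_capacity
  buf_i <- integer(cap); buf_a <- integer(cap); buf_r <- numeric(cap)
  size <- 0L; pos <- 0L

  n_log <- ceiling(cfg$total_timesteps / cfg$log_window)
  log_t <- integer(n_log); log_r <- numeric(n_log)
  win_sum <- 0; win_n <- 0L; log_row <- 0L

  states <- env$states
  allowed <- env$allowed

  for (t in seq_len(cfg$total_timesteps)) {
    i <- sample.int(env$n, 1L)
    q <- mlp_forward1(params, states[i, ])
    q[!allowed[i, ]] <- -Inf
    a <- boltzmann_select(q, cfg$tau)
    r <- env_reward(env, i, a)

    pos <- if (pos == cap) 1L else pos + 1L
    buf_i[pos] <- i; buf_a[pos] <- a; buf_r[pos] <- r
    if (size < cap) size <- size + 1L

    win_sum <- win_sum + r; win_n <- win_n + 1L

    if (size >= cfg$batch_size) {
      b <- sample.int(size, cfg$batch_size, replace = TRUE)
      # one-step terminal episodes: target = r (+ gamma * 0 from target net)
      g <- mlp_grad(params, states[buf_i[b], , drop = FALSE],
                    buf_a[b], buf_r[b])
      if (!is.finite(g$loss)) {
        stop(sprintf("non-finite DQN loss at timestep %d (lr = %g); training aborted",
                     t, cfg$learning_rate), call. = FALSE)
      }
      step <- adam_step(params, g$grads, opt, cfg$learning_rate)
      params <- step$params; opt <- step$state
    }
    if (t %% cfg$target_update_interval == 0L) target <- params
    if (t %% cfg$log_window == 0L || t == cfg$total_timesteps) {
      log_row <- log_row + 1L
      log_t[log_row] <- t
      log_r[log_row] <- win_sum / win_n
      win_sum <- 0; win_n <- 0L
    }
  }
  list(params = params,
       log = data.frame(timestep = log_t[seq_len(log_row)],
                        mean_reward = log_r[seq_len(log_row)]),
       qspec = qspec, cfg = cfg)
}
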