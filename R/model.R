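#' Fit a one-step DQN treatment policy
#'
#' The package's central fitting function. Takes an engineered patient table
#' (see [engineer_features()]), builds the one-step treatment environment
#' with shaped rewards, standardizes the features, and trains the Q-network
#' by Q-learning with experience replay and Boltzmann exploration. The
#' result is a classed model object whose Q-function underlies every report:
#' `summary()` gives per-action Q summaries and action frequencies by
#' treatment line, `predict()` returns Q-values or greedy masked actions,
#' `plot()` shows the training curve or partial dependence, and
#' [recommend()] scores a single new patient.
#'
#' @param data Engineered `data.frame` from [engineer_features()].
#' @param reward A [reward_config()].
#' @param scenario `"masked"` (default; actions inconsistent with the
#'   recorded treatment line are unavailable) or `"penalized"`.
#' @param control A [train_config()].
#' @param seed Convenience override of `control$seed`.
#' @param reward_fn Optional counterfactual reward hook, see
#'   [treatment_env()].
#' @return Object of class `tki_dqn`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_spec(n_patients = 120, seed = 3))
#' eng <- engineer_features(apply_inclusion_filters(coh)$kept)
#' fit <- tki_dqn(eng, control = train_config(total_timesteps = 2000))
#' summary(fit)
#' }
#' @export
tki_dqn <- function(data, reward = reward_config(),
                    scenario = c("masked", "penalized"),
                    control = train_config(), seed = NULL,
                    reward_fn = NULL) {
  scenario <- match.arg(scenario)
  if (!all(c("action_code", "progression_category") %in% names(data))) {
    stop("data must be an engineered table; run engineer_features() first",
         call. = FALSE)
  }
  if (!is.null(seed)) control$seed <- as.integer(seed)
  env <- treatment_env(data, reward = reward, scenario = scenario,
                       reward_fn = reward_fn)
  trained <- train_dqn(env, cfg = control)
  structure(list(
    params = trained$params,
    qspec = trained$qspec,
    scaler = env$scaler,
    feature_names = env$scaler$features,
    reward = reward,
    scenario = scenario,
    control = control,
    log = trained$log,
    states = env$states,
    line_later = env$line_later,
    action_code = env$action_code,
    progression_category = env$progression_category,
    n = env$n,
    call = match.call()
  ), class = "tki_dqn")
}

encode_newdata <- function(object, newdata) {
  if (is.null(newdata)) {
    return(list(states = object$states, line_later = object$line_later))
  }
  if (is.matrix(newdata)) {
    states <- apply_scaler(object$scaler, newdata)
    ll <- if ("line_later" %in% colnames(newdata)) newdata[, "line_later"] == 1
          else rep(NA, nrow(newdata))
    return(list(states = states, line_later = ll))
  }
  x <- encode_features(newdata, line = "dichotomized")
  states <- apply_scaler(object$scaler, x)
  if (any(abs(states) > 5)) {
    warning("some feature values lie far outside the training range (>5 sd); ",
            "Q-values are extrapolations", call. = FALSE)
  }
  list(states = states, line_later = newdata$tki_line >= 2)
}

mask_q <- function(q, line_later, scenario) {
  if (scenario != "masked") return(q)
  q[which(line_later), 1:2] <- -Inf
  q[which(!line_later), 3:4] <- -Inf
  q
}

greedy_actions <- function(q) {
  apply(q, 1L, function(r) which(r == max(r))[1L] - 1L)
}

#' Predict Q-values or greedy actions for patients
#'
#' @param object A fitted [tki_dqn()] model.
#' @param newdata Engineered `data.frame`, an encoded feature matrix, or
#'   `NULL` for the training patients.
#' @param type `"q"` for the n x 4 Q-value matrix, `"action"` for greedy
#'   (line-masked) action codes, `"label"` for their labels.
#' @param ... Unused.
#' @return Matrix of Q-values, or a vector of actions/labels.
#' @export
predict.tki_dqn <- function(object, newdata = NULL,
                            type = c("q", "action", "label"), ...) {
  type <- match.arg(type)
  enc <- encode_newdata(object, newdata)
  q <- mlp_forward(object$params, enc$states)
  colnames(q) <- paste0("action_", 0:3)
  rownames(q) <- rownames(enc$states)
  if (type == "q") return(q)
  if (any(is.na(enc$line_later))) {
    stop("treatment line unknown for newdata; cannot mask actions", call. = FALSE)
  }
  a <- greedy_actions(mask_q(q, enc$line_later, object$scenario))
  if (type == "action") a else action_label(a)
}

#' Q-values of a fitted policy for raw records
#'
#' Functional spelling of [predict.tki_dqn()] restricted to Q-values:
#' applies the stored training-time scaler, then the network.
#'
#' @param qf A fitted [tki_dqn()] model.
#' @param newdata Engineered `data.frame` or encoded feature matrix.
#' @return Numeric n x 4 matrix of finite Q-values.
#' @export
predict_q <- function(qf, newdata = NULL) {
  predict(qf, newdata = newdata, type = "q")
}

#' @export
print.tki_dqn <- function(x, ...) {
  cat("One-step DQN treatment policy\n")
  cat(sprintf("  %d patients, %d features, scenario '%s'\n",
              x$n, length(x$feature_names), x$scenario))
  cat(sprintf("  trained %d timesteps (tau = %g, lr = %g, seed = %d)\n",
              x$control$total_timesteps, x$control$tau,
              x$control$learning_rate, x$control$seed))
  cat(sprintf("  final mean reward per episode: %.2f\n",
              utils::tail(x$log$mean_reward, 1)))
  invisible(x)
}

#' @export
summary.tki_dqn <- function(object, ...) {
  structure(list(
    q_summary = summarize_q(object),
    frequencies = action_frequencies(object),
    auc = policy_score_auc(object),
    scenario = object$scenario,
    n = object$n
  ), class = "summary.tki_dqn")
}

#' @export
print.summary.tki_dqn <- function(x, ...) {
  cat(sprintf("One-step DQN policy over %d patients (scenario '%s')\n\n",
              x$n, x$scenario))
  cat("Q-values by action:\n")
  print(round(x$q_summary, 2))
  cat("\nGreedy action frequencies by treatment line:\n")
  print(x$frequencies)
  cat(sprintf("\nPolicy score AUC (recorded-action Q vs progression-free year): %.3f\n",
              x$auc))
  invisible(x)
}

#' @export
coef.tki_dqn <- function(object, ...) object$params

#' Sample treatment actions from the fitted Boltzmann policy
#'
#' Draws `nsim` Boltzmann-distributed action codes per patient at the
#' training temperature (line-masked under the `"masked"` scenario).
#'
#' @param object A fitted [tki_dqn()] model.
#' @param nsim Number of draws per patient.
#' @param seed Optional seed.
#' @param newdata As in [predict.tki_dqn()].
#' @param tau Temperature override.
#' @param ... Unused.
#' @return Integer matrix, patients x `nsim`.
#' @export
simulate.tki_dqn <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                             tau = object$control$tau, ...) {
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_newdata(object, newdata)
  q <- mask_q(mlp_forward(object$params, enc$states), enc$line_later,
              object$scenario)
  out <- matrix(NA_integer_, nrow(q), nsim)
  for (s in seq_len(nsim)) {
    out[, s] <- apply(q, 1L, boltzmann_select, tau = tau)
  }
  rownames(out) <- rownames(enc$states)
  out
}

#' @export
plot.tki_dqn <- function(x, type = c("training", "partial"), feature = NULL,
                         ...) {
  type <- match.arg(type)
  if (type == "training") {
    graphics::plot(x$log$timestep, x$log$mean_reward, type = "l",
                   xlab = "timestep", ylab = "mean reward per episode",
                   main = "DQN training curve", ...)
  } else {
    if (is.null(feature)) stop("supply 'feature' for a partial dependence plot",
                               call. = FALSE)
    pd <- partial_dependence(x, feature)
    plot(pd, ...)
  }
  invisible(x)
}

#' Serialize a fitted policy to a single JSON model file
#'
#' Writes network weights, the feature scaler, reward and training
#' configuration to plain JSON so the fitted recommender can be reloaded
#' (e.g., by the command-line recommender) without refitting.
#'
#' @param fit A fitted [tki_dqn()] model.
#' @param path File path.
#' @return `write_tki_dqn()` returns `path` invisibly; `read_tki_dqn()`
#'   returns a `tki_dqn` object (without the training states; reports that
#'   need them must be given `newdata`).
#' @export
write_tki_dqn <- function(fit, path) {
  stopifnot(inherits(fit, "tki_dqn"))
  out <- list(
    package = "tkipolicy", object = "tki_dqn",
    qspec = unclass(fit$qspec),
    params = lapply(fit$params, function(p)
      if (is.matrix(p)) list(nrow = nrow(p), ncol = ncol(p),
                             data = as.numeric(p))
      else list(nrow = 0L, ncol = 0L, data = as.numeric(p))),
    scaler = unclass(fit$scaler),
    reward = unclass(fit$reward),
    scenario = fit$scenario,
    control = unclass(fit$control),
    log = fit$log
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tki_dqn
#' @export
read_tki_dqn <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(raw$object, "tki_dqn")) {
    stop("not a serialized tki_dqn model: ", path, call. = FALSE)
  }
  params <- lapply(raw$params, function(p) {
    dat <- as.numeric(unlist(p$data))
    if (p$nrow > 0) matrix(dat, p$nrow, p$ncol) else dat
  })
  scaler <- raw$scaler
  scaler$center <- unlist(scaler$center)
  scaler$scale <- unlist(scaler$scale)
  scaler$features <- as.character(unlist(scaler$features))
  scaler$dropped <- as.character(unlist(scaler$dropped))
  class(scaler) <- "feature_scaler"
  structure(list(
    params = params,
    qspec = structure(raw$qspec, class = "qnetwork_spec"),
    scaler = scaler,
    feature_names = scaler$features,
    reward = structure(raw$reward, class = "reward_config"),
    scenario = raw$scenario,
    control = structure(raw$control, class = "train_config"),
    log = data.frame(
      timestep = vapply(raw$log, function(r) as.numeric(r$timestep), numeric(1)),
      mean_reward = vapply(raw$log, function(r) as.numeric(r$mean_reward),
                           numeric(1))),
    states = NULL, line_later = NULL, action_code = NULL,
    progression_category = NULL, n = 0L,
    call = quote(read_tki_dqn(path))
  ), class = "tki_dqn")
}
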