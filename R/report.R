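#' Per-action summary of Q-values over a set of patients
#'
#' Columnwise mean, standard deviation, minimum and maximum of the
#' Q-function over a state set — the policy's per-action value profile.
#'
#' @param qf A fitted [tki_dqn()] model.
#' @param newdata Engineered `data.frame`, encoded matrix, or `NULL` for the
#'   training patients.
#' @return `data.frame` with rows mean/sd/min/max and one column per action.
#' @export
summarize_q <- function(qf, newdata = NULL) {
  q <- predict_q(qf, newdata)
  if (nrow(q) == 0L) stop("empty state set", call. = FALSE)
  out <- rbind(mean = colMeans(q),
               sd = apply(q, 2, stats::sd),
               min = apply(q, 2, min),
               max = apply(q, 2, max))
  as.data.frame(out)
}

#' Greedy action frequencies by treatment line
#'
#' Counts of the policy's greedy (line-masked) recommendation, split into
#' the first-line (chemotherapy-naive) and later-line (chemotherapy
#' refractory) scenarios. Counts sum to the number of patients per scenario;
#' masked actions have zero frequency by construction.
#'
#' @param qf A fitted [tki_dqn()] model.
#' @param newdata As in [summarize_q()]; needs a known treatment line.
#' @return Integer matrix, rows `first_line`/`later_line`, columns actions.
#' @export
action_frequencies <- function(qf, newdata = NULL) {
  enc <- encode_newdata(qf, newdata)
  if (any(is.na(enc$line_later))) {
    stop("treatment line unknown; cannot split scenarios", call. = FALSE)
  }
  if (length(enc$line_later) != nrow(enc$states)) {
    stop("line flags misaligned with states", call. = FALSE)
  }
  q <- mask_q(mlp_forward(qf$params, enc$states), enc$line_later, qf$scenario)
  a <- greedy_actions(q)
  out <- rbind(
    first_line = tabulate(a[!enc$line_later] + 1L, nbins = 4L),
    later_line = tabulate(a[enc$line_later] + 1L, nbins = 4L)
  )
  colnames(out) <- paste0("action_", 0:3)
  out
}

#' Partial dependence of the Q-function on one feature
#'
#' For each grid value the feature column is overwritten in every state and
#' the Q-values are averaged, giving one mean-Q curve per action — how the
#' policy's valuation of each treatment moves with a single clinical
#' feature, all else as observed.
#'
#' @param qf A fitted [tki_dqn()] model.
#' @param feature Name of a scaler-known feature (see `qf$feature_names`).
#' @param grid Numeric grid of raw-scale feature values; defaults to
#'   `c(0, 1)` for binary features, else 25 points across the observed
#'   training range.
#' @param newdata Engineered `data.frame` to evaluate over, or `NULL` for
#'   the training patients.
#' @return `data.frame` of class `partial_dependence`: `grid` plus one
#'   mean-Q column per action.
#' @export
partial_dependence <- function(qf, feature, grid = NULL, newdata = NULL) {
  if (!feature %in% qf$feature_names) {
    stop("unknown feature '", feature, "'; known features: ",
         paste(qf$feature_names, collapse = ", "), call. = FALSE)
  }
  x_std <- if (is.null(newdata)) qf$states
           else encode_newdata(qf, newdata)$states
  j <- match(feature, qf$feature_names)
  ctr <- qf$scaler$center[[feature]]
  scl <- qf$scaler$scale[[feature]]
  if (is.null(grid)) {
    raw <- x_std[, j] * scl + ctr
    grid <- if (all(raw %in% c(0, 1))) c(0, 1)
            else seq(min(raw), max(raw), length.out = 25L)
  }
  qbar <- t(vapply(grid, function(g) {
    x_std[, j] <- (g - ctr) / scl
    colMeans(mlp_forward(qf$params, x_std))
  }, numeric(4)))
  out <- data.frame(grid = grid, qbar)
  names(out) <- c(feature, paste0("action_", 0:3))
  class(out) <- c("partial_dependence", "data.frame")
  out
}

#' @export
plot.partial_dependence <- function(x, ...) {
  feature <- names(x)[1L]
  q <- as.matrix(x[, -1L])
  graphics::matplot(x[[1L]], q, type = "l", lty = 1, lwd = 2,
                    xlab = feature, ylab = "mean Q-value",
                    main = paste("Partial dependence:", feature), ...)
  graphics::legend("topright", legend = paste("action", 0:3),
                   col = seq_len(4), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Area under the ROC curve of a ranking score
#'
#' Probability (with tie correction) that a randomly chosen positive
#' outcome outranks a randomly chosen negative one — invariant to strictly
#' increasing transforms of the score.
#'
#' @param scores Numeric ranking scores.
#' @param outcomes Binary outcomes aligned with `scores` (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
ranking_auc <- function(scores, outcomes) {
  if (length(unique(outcomes)) != 2L) {
    stop("outcomes must contain both classes", call. = FALSE)
  }
  as.numeric(pROC::auc(pROC::roc(
    response = factor(outcomes == max(outcomes), levels = c(FALSE, TRUE)),
    predictor = scores, quiet = TRUE,
    levels = c(FALSE, TRUE), direction = "<")))
}

#' Policy AUC against the one-year progression-free outcome
#'
#' Scores each patient by the fitted Q-value at the treatment actually
#' received, then computes the AUC of that score against the
#' progression-free-at-one-year outcome. This is the package's definition
#' of a classification-comparable AUC for a policy: no canonical AUC exists
#' for an RL recommender, so the recorded-action Q is used as the ranking
#' score and documented as such.
#'
#' @param qf A fitted [tki_dqn()] model.
#' @param newdata Engineered `data.frame`, or `NULL` for the training
#'   patients.
#' @return AUC in `[0, 1]`.
#' @export
policy_score_auc <- function(qf, newdata = NULL) {
  if (is.null(newdata)) {
    q <- predict_q(qf)
    act <- qf$action_code
    outcome <- 1L - qf$progression_category
  } else {
    q <- predict_q(qf, newdata)
    act <- newdata$action_code
    outcome <- 1L - newdata$progression_category
  }
  scores <- q[cbind(seq_len(nrow(q)), act + 1L)]
  ranking_auc(scores, outcome)
}

recommend_required_fields <- function() {
  c("age", "gender", "ecog", "mutation", "smoking", "n_mets_cat",
    "bone_or_liver_met", "brain_met", "comorbidity", "neutrophils",
    "lymphocytes", "tki_line")
}

#' Recommend a TKI treatment for one patient
#'
#' Scores a single raw patient record with the fitted Q-function, masks the
#' actions inconsistent with the patient's treatment line (under the
#' `"masked"` scenario), and returns the argmax action with ties broken by
#' the lowest action code.
#'
#' @param qf A fitted [tki_dqn()] model.
#' @param patient Named list or one-row `data.frame` with fields
#'   `age, gender, ecog, mutation, smoking, n_mets_cat, bone_or_liver_met,
#'   brain_met, comorbidity, neutrophils, lymphocytes, tki_line`.
#' @return Object of class `tki_recommendation`: `action`, `label`, `q`
#'   (named 4-vector), `scenario` (`"first-line"`/`"later-line"`),
#'   `masked_actions`.
#' @export
recommend <- function(qf, patient) {
  patient <- as.list(patient)
  missing <- setdiff(recommend_required_fields(), names(patient))
  if (length(missing)) {
    stop("patient record is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rec <- as.data.frame(patient[recommend_required_fields()],
                       stringsAsFactors = FALSE)
  rec$patient_id <- "query"
  rec$lognlr <- log(rec$neutrophils / rec$lymphocytes)
  rec$logage <- log(rec$age)
  x <- encode_features(rec, line = "dichotomized")
  q <- drop(mlp_forward(qf$params, apply_scaler(qf$scaler, x)))
  names(q) <- paste0("action_", 0:3)
  later <- rec$tki_line >= 2
  masked <- if (qf$scenario == "masked") { if (later) 0:1 else 2:3 } else integer(0)
  qm <- q
  qm[masked + 1L] <- -Inf
  action <- as.integer(which(qm == max(qm))[1L] - 1L)
  structure(list(action = action, label = action_label(action), q = q,
                 scenario = if (later) "later-line" else "first-line",
                 masked_actions = as.integer(masked)),
            class = "tki_recommendation")
}

#' @export
print.tki_recommendation <- function(x, ...) {
  cat(sprintf("Recommended action %d: %s\n", x$action, x$label))
  cat(sprintf("Scenario: %s", x$scenario))
  if (length(x$masked_actions)) {
    cat(sprintf(" (actions %s unavailable)",
                paste(x$masked_actions, collapse = ", ")))
  }
  cat("\nQ-values:\n")
  print(round(x$q, 3))
  invisible(x)
}
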