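#' Column dictionary of the patient table
#'
#' Fixed column names used by every reader/writer in the package: one row per
#' patient, header required.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "age", "gender", "ecog", "mutation", "smoking",
    "n_mets_cat", "bone_or_liver_met", "brain_met", "comorbidity",
    "neutrophils", "lymphocytes", "tki_line", "tki_generation",
    "pfs_months", "event", "followup_months")
}

#' Strata over which the planted treatment effect is defined
#'
#' Default stratification is EGFR mutation category crossed with the
#' dichotomized treatment line of the first TKI.
#'
#' @return Character vector of stratum labels.
#' @export
cohort_strata <- function() {
  c("exon19.first", "exon19.later", "other.first", "other.later")
}

#' Default planted action -> outcome effect table
#'
#' Probability of a progression-free first year, P(PFS >= 12 months), for each
#' (stratum, action) pair. Values are chosen so that second-or-higher
#' generation TKIs (actions 1 and 3) carry a moderate advantage and the
#' cohort-wide progression-free share lands near 38%, the share observed in
#' EGFR-mutant advanced NSCLC cohorts of this kind. The table is a simulation
#' device for policy-recovery testing, not an estimate from data.
#'
#' @return 4 x 4 numeric matrix, rows [cohort_strata()], columns actions 0-3.
#' @export
default_effect_table <- function() {
  m <- rbind(
    exon19.first = c(0.40, 0.52, 0.30, 0.42),
    exon19.later = c(0.32, 0.40, 0.25, 0.45),
    other.first  = c(0.30, 0.42, 0.22, 0.35),
    other.later  = c(0.22, 0.30, 0.18, 0.38)
  )
  colnames(m) <- paste0("action_", 0:3)
  m
}

#' Specification of a synthetic EGFR-mutant NSCLC cohort
#'
#' Parameterizes the seeded generator: marginal distributions of the clinical
#' features (defaults follow the published cohort's marginals), the
#' distribution of the four-level action variable (treatment line x TKI
#' generation), a planted per-stratum action->outcome effect table, and an
#' administrative censoring rate. Identical spec + seed yields an identical
#' table.
#'
#' @param n_patients Number of patients (non-negative integer).
#' @param age_mean,age_sd Age distribution in years.
#' @param female_prop Proportion female.
#' @param ecog_high_prop Proportion with ECOG performance status 2-4.
#' @param exon19_prop Proportion with Exon 19 deletion (vs other mutations).
#' @param smoker_prop Proportion currently smoking.
#' @param mets_4plus_prop Proportion with 4 or more metastatic sites.
#' @param bone_liver_prop Proportion with bone and/or liver metastases.
#' @param brain_prop Proportion with brain metastases.
#' @param comorbidity_prop Proportion with significant comorbidity.
#' @param nlr_meanlog,nlr_sdlog Log-scale parameters of the log-normal
#'   neutrophil-to-lymphocyte ratio; defaults target mean 3.9, median 3.2.
#' @param line_dist Probability vector over action codes 0-3 (must sum to 1).
#' @param effect_table 4 x 4 matrix of P(PFS >= 12 months) per
#'   (stratum, action); see [default_effect_table()].
#' @param censor_prop Probability a record's follow-up is administratively
#'   truncated after the outcome draw (produces excludable rows).
#' @param seed Integer RNG seed.
#'
#' @return Object of class `cohort_spec`.
#' @seealso [generate_cohort()], [planted_policy()]
#' @export
cohort_spec <- function(n_patients = 318L,
                        age_mean = 62.7, age_sd = 11.4,
                        female_prop = 0.522,
                        ecog_high_prop = 0.167,
                        exon19_prop = 0.642,
                        smoker_prop = 0.368,
                        mets_4plus_prop = 0.535,
                        bone_liver_prop = 0.569,
                        brain_prop = 0.371,
                        comorbidity_prop = 0.30,
                        nlr_meanlog = log(3.2),
                        nlr_sdlog = sqrt(2 * log(3.9 / 3.2)),
                        line_dist = c(0.635, 0.148, 0.047, 0.170),
                        effect_table = default_effect_table(),
                        censor_prop = 0.08,
                        seed = 1L) {
  spec <- list(
    n_patients = n_patients, age_mean = age_mean, age_sd = age_sd,
    female_prop = female_prop, ecog_high_prop = ecog_high_prop,
    exon19_prop = exon19_prop, smoker_prop = smoker_prop,
    mets_4plus_prop = mets_4plus_prop, bone_liver_prop = bone_liver_prop,
    brain_prop = brain_prop, comorbidity_prop = comorbidity_prop,
    nlr_meanlog = nlr_meanlog, nlr_sdlog = nlr_sdlog,
    line_dist = line_dist, effect_table = effect_table,
    censor_prop = censor_prop, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (length(spec$n_patients) != 1L || is.na(spec$n_patients) ||
      spec$n_patients < 0 || spec$n_patients != round(spec$n_patients)) {
    stop("invalid cohort spec: 'n_patients' must be a non-negative integer",
         call. = FALSE)
  }
  props <- c("female_prop", "ecog_high_prop", "exon19_prop", "smoker_prop",
             "mets_4plus_prop", "bone_liver_prop", "brain_prop",
             "comorbidity_prop", "censor_prop")
  for (p in props) {
    v <- spec[[p]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("invalid cohort spec: '%s' must lie in [0, 1]", p),
           call. = FALSE)
    }
  }
  if (length(spec$line_dist) != 4L || any(spec$line_dist < 0) ||
      abs(sum(spec$line_dist) - 1) > 1e-9) {
    stop("invalid cohort spec: 'line_dist' must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  et <- spec$effect_table
  if (!is.matrix(et) || !all(cohort_strata() %in% rownames(et)) || ncol(et) != 4L) {
    stop("invalid cohort spec: 'effect_table' must be a matrix with rows ",
         paste(cohort_strata(), collapse = ", "), " and 4 action columns",
         call. = FALSE)
  }
  if (any(is.na(et)) || any(et < 0) || any(et > 1)) {
    stop("invalid cohort spec: 'effect_table' probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (spec$age_sd <= 0) {
    stop("invalid cohort spec: 'age_sd' must be positive", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic EGFR-mutant NSCLC cohort specification\n")
  cat(sprintf("  n_patients: %d, seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  age: %.1f (sd %.1f); female %.1f%%; exon19 %.1f%%\n",
              x$age_mean, x$age_sd, 100 * x$female_prop, 100 * x$exon19_prop))
  cat(sprintf("  action distribution (codes 0-3): %s\n",
              paste(format(x$line_dist), collapse = ", ")))
  cat("  planted effect table P(PFS >= 12 mo):\n")
  print(round(x$effect_table, 3))
  invisible(x)
}

stratum_of <- function(mutation, first_line) {
  paste(ifelse(mutation == "exon19", "exon19", "other"),
        ifelse(first_line, "first", "later"), sep = ".")
}

#' Generate a seeded synthetic patient table
#'
#' Samples each clinical feature from its configured marginal, assigns the
#' received action (treatment line x TKI generation) from `line_dist`, and
#' draws the one-year progression outcome from the planted effect table for
#' the patient's stratum and assigned action. Administrative censoring then
#' truncates a configurable share of follow-up times, so the inclusion
#' filters downstream have genuinely excludable rows to act on.
#'
#' Progression-free times: patients progression-free at one year carry
#' PFS of 12 months plus an exponential tail (mean 8 months); early
#' progressors get a uniform time below 12 months. Neutrophil and lymphocyte
#' counts are back-solved from a log-normal NLR draw and a log-normal
#' lymphocyte draw, since only the ratio's distribution is specified.
#'
#' @param spec A [cohort_spec()].
#' @return `data.frame` with columns [cohort_columns()], one row per patient.
#' @examples
#' tab <- generate_cohort(cohort_spec(n_patients = 50, seed = 7))
#' table(tab$tki_generation)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- as.integer(spec$n_patients)
  cols <- cohort_columns()
  if (n == 0L) {
    empty <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    return(empty)
  }
  set.seed(spec$seed)

  age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd), 25), 95)
  gender <- ifelse(stats::runif(n) < spec$female_prop, "female", "male")
  ecog <- ifelse(stats::runif(n) < spec$ecog_high_prop, "2-4", "0-1")
  mutation <- ifelse(stats::runif(n) < spec$exon19_prop, "exon19", "other")
  smoking <- ifelse(stats::runif(n) < spec$smoker_prop, "current", "never_former")
  n_mets_cat <- ifelse(stats::runif(n) < spec$mets_4plus_prop, "4+", "1-3")
  bone_or_liver_met <- as.integer(stats::runif(n) < spec$bone_liver_prop)
  brain_met <- as.integer(stats::runif(n) < spec$brain_prop)
  comorbidity <- as.integer(stats::runif(n) < spec$comorbidity_prop)

  nlr <- stats::rlnorm(n, spec$nlr_meanlog, spec$nlr_sdlog)
  lymphocytes <- round(stats::rlnorm(n, log(1800), 0.35))
  lymphocytes <- pmax(lymphocytes, 100)
  neutrophils <- round(nlr * lymphocytes)

  action <- sample(0:3, n, replace = TRUE, prob = spec$line_dist)
  first_line <- action <= 1L
  tki_line <- ifelse(first_line, 1L,
                     sample(2:5, n, replace = TRUE,
                            prob = c(0.70, 0.20, 0.07, 0.03)))
  tki_generation <- ifelse(action %in% c(1L, 3L), "2+", "1")

  stratum <- stratum_of(mutation, first_line)
  p_good <- spec$effect_table[cbind(stratum, paste0("action_", action))]
  good <- stats::runif(n) < p_good

  pfs <- ifelse(good, 12 + stats::rexp(n, rate = 1 / 8),
                0.5 + stats::runif(n) * 11.4)
  event <- ifelse(good, as.integer(stats::runif(n) < 0.6), 1L)
  followup <- ifelse(event == 1L, pfs + stats::rexp(n, rate = 1 / 6), pfs)

  censored <- stats::runif(n) < spec$censor_prop
  ctime <- stats::runif(n, 0.2, followup)
  cut <- censored & ctime < pfs
  pfs[cut] <- ctime[cut]
  event[cut] <- 0L
  followup[censored] <- pmin(followup[censored], pmax(ctime[censored], pfs[censored]))

  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = round(age, 1), gender = gender, ecog = ecog, mutation = mutation,
    smoking = smoking, n_mets_cat = n_mets_cat,
    bone_or_liver_met = bone_or_liver_met, brain_met = brain_met,
    comorbidity = comorbidity, neutrophils = neutrophils,
    lymphocytes = lymphocytes, tki_line = tki_line,
    tki_generation = tki_generation, pfs_months = round(pfs, 2),
    event = event, followup_months = round(followup, 2),
    stringsAsFactors = FALSE
  )
}

#' Known-optimal action per stratum implied by the effect table
#'
#' The generator plants a treatment effect; this returns the action with the
#' highest planted probability of a progression-free year in each stratum,
#' breaking ties by the lowest action code. It is the oracle against which
#' policy recovery is judged.
#'
#' @param spec A [cohort_spec()].
#' @return Named integer vector, one action code (0-3) per stratum.
#' @export
planted_policy <- function(spec) {
  validate_cohort_spec(spec)
  et <- spec$effect_table
  missing <- setdiff(cohort_strata(), rownames(et))
  if (length(missing)) {
    stop("effect_table is missing strata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vapply(cohort_strata(), function(s) {
    p <- et[s, ]
    as.integer(which(p == max(p))[1L] - 1L)
  }, integer(1))
}

#' Read or write the patient table as CSV
#'
#' Plain CSV with the fixed column dictionary [cohort_columns()], header
#' required, one row per patient.
#'
#' @param table Patient `data.frame`.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the patient `data.frame`.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table[, cohort_columns(), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns(), names(tab))
  if (length(missing)) {
    stop("cohort CSV is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab[, cohort_columns(), drop = FALSE]
}

#' Serialize a cohort specification to JSON
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `write_cohort_spec()` returns `path` invisibly; `read_cohort_spec()`
#'   returns the `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  validate_cohort_spec(spec)
  out <- unclass(spec)
  out$effect_table <- list(
    strata = rownames(spec$effect_table),
    actions = colnames(spec$effect_table),
    probs = unname(apply(spec$effect_table, 1, as.numeric, simplify = FALSE))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  et <- raw$effect_table$probs
  if (!is.matrix(et)) et <- do.call(rbind, et)
  rownames(et) <- raw$effect_table$strata
  colnames(et) <- raw$effect_table$actions
  cohort_spec(
    n_patients = raw$n_patients, age_mean = raw$age_mean, age_sd = raw$age_sd,
    female_prop = raw$female_prop, ecog_high_prop = raw$ecog_high_prop,
    exon19_prop = raw$exon19_prop, smoker_prop = raw$smoker_prop,
    mets_4plus_prop = raw$mets_4plus_prop, bone_liver_prop = raw$bone_liver_prop,
    brain_prop = raw$brain_prop, comorbidity_prop = raw$comorbidity_prop,
    nlr_meanlog = raw$nlr_meanlog, nlr_sdlog = raw$nlr_sdlog,
    line_dist = raw$line_dist, effect_table = et,
    censor_prop = raw$censor_prop, seed = raw$seed
  )
}
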