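#' Inclusion rules for the analysis cohort
#'
#' A record enters the analysis set only if it has complete required fields,
#' at least `min_followup_months` of follow-up after TKI start, and either a
#' progression/death event within the first year or at least
#' `min_followup_if_progression_free` months of follow-up. Records censored
#' progression-free before one year are uninformative for the one-year
#' endpoint and are excluded.
#'
#' @param min_followup_months Minimum follow-up in months (default 1).
#' @param min_followup_if_progression_free Months of follow-up required of
#'   progression-free records (default 12).
#' @param required_fields Columns that must be non-missing.
#' @return Object of class `inclusion_rules`.
#' @export
inclusion_rules <- function(min_followup_months = 1,
                            min_followup_if_progression_free = 12,
                            required_fields = cohort_columns()) {
  if (min_followup_months <= 0 || min_followup_if_progression_free <= 0) {
    stop("inclusion rule thresholds must be positive", call. = FALSE)
  }
  structure(list(min_followup_months = min_followup_months,
                 min_followup_if_progression_free = min_followup_if_progression_free,
                 required_fields = required_fields),
            class = "inclusion_rules")
}

#' Apply inclusion filters to a patient table
#'
#' Partitions the input into kept and excluded rows. Each excluded row is
#' logged with the first rule it fails, checked in order: missing required
#' fields, follow-up shorter than the minimum, then insufficient follow-up
#' for a record without an event in the first year.
#'
#' @param records Patient `data.frame` (see [cohort_columns()]).
#' @param rules An [inclusion_rules()] object.
#' @return List with `kept` (data.frame), `excluded` (data.frame), and
#'   `log` (data.frame of `patient_id`, `rule` for each excluded row).
#' @export
apply_inclusion_filters <- function(records, rules = inclusion_rules()) {
  stopifnot(inherits(rules, "inclusion_rules"))
  missing_cols <- setdiff(rules$required_fields, names(records))
  if (length(missing_cols)) {
    stop("records are missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  rule <- rep(NA_character_, n)
  if (n > 0) {
    req <- records[, rules$required_fields, drop = FALSE]
    incomplete <- apply(req, 1L, function(r) any(is.na(r) | r == ""))
    short <- records$followup_months < rules$min_followup_months
    # no event inside the first year and follow-up too short to certify a
    # progression-free year
    event_in_year <- records$event == 1 &
      records$pfs_months < rules$min_followup_if_progression_free
    underfollowed <- !event_in_year &
      records$followup_months < rules$min_followup_if_progression_free
    rule[incomplete] <- "missing_fields"
    rule[is.na(rule) & short] <- "min_followup"
    rule[is.na(rule) & underfollowed] <- "insufficient_followup_progression_free"
  }
  keep <- is.na(rule)
  list(
    kept = records[keep, , drop = FALSE],
    excluded = records[!keep, , drop = FALSE],
    log = data.frame(patient_id = records$patient_id[!keep],
                     rule = rule[!keep], stringsAsFactors = FALSE)
  )
}

#' Encode the action variable from line and generation of the first TKI
#'
#' Four-level action code: 0 = first-line first-generation, 1 = first-line
#' second-or-higher generation, 2 = later-line first-generation, 3 =
#' later-line second-or-higher generation.
#'
#' @param tki_line Treatment line of the first TKI (integer >= 1).
#' @param tki_generation `"1"` or `"2+"`.
#' @return Integer vector of action codes in 0..3.
#' @examples
#' derive_action_code(c(1, 1, 2, 5), c("1", "2+", "2+", "1"))
#' @export
derive_action_code <- function(tki_line, tki_generation) {
  if (any(is.na(tki_line)) || any(tki_line < 1)) {
    stop("tki_line must be >= 1", call. = FALSE)
  }
  gen <- as.character(tki_generation)
  if (!all(gen %in% c("1", "2+"))) {
    stop("tki_generation must be '1' or '2+'", call. = FALSE)
  }
  later <- tki_line >= 2
  higher <- gen == "2+"
  as.integer(2L * later + higher)
}

#' Human-readable labels for the four action codes
#'
#' @param action Integer action codes in 0..3.
#' @return Character vector of labels.
#' @export
action_label <- function(action = 0:3) {
  labs <- c("first-line, first-generation TKI",
            "first-line, second- or higher-generation TKI",
            "second- or later-line, first-generation TKI",
            "second- or later-line, second- or higher-generation TKI")
  if (any(!action %in% 0:3)) stop("action codes must lie in 0..3", call. = FALSE)
  labs[action + 1L]
}

#' Dichotomize progression-free survival at one year
#'
#' Category 1: progression or death before 12 months. Category 0:
#' progression-free for 12 months or more (the boundary is inclusive). A
#' record censored progression-free before 12 months cannot be classified
#' and must already have been removed by [apply_inclusion_filters()].
#'
#' @param pfs_months Progression-free survival in months.
#' @param event 1 if progression or death occurred, 0 if censored.
#' @param followup_months Total follow-up in months.
#' @return Integer vector of 0/1 progression categories.
#' @export
derive_progression_category <- function(pfs_months, event, followup_months) {
  out <- rep(NA_integer_, length(pfs_months))
  out[pfs_months >= 12] <- 0L
  out[event == 1 & pfs_months < 12] <- 1L
  if (any(is.na(out))) {
    stop("record censored before 12 months is unclassifiable under the ",
         "inclusion rules; filter records first", call. = FALSE)
  }
  out
}

#' Derive the modeling variables
#'
#' Adds to a filtered patient table the log neutrophil-to-lymphocyte ratio
#' (`lognlr`), log age (`logage`), the four-level `action_code`, and the
#' one-year `progression_category`. Natural logarithms throughout. Raw
#' columns are left untouched and row count is preserved.
#'
#' @param records Filtered patient `data.frame`.
#' @return `data.frame` of engineered records.
#' @export
engineer_features <- function(records) {
  bad <- which(records$neutrophils <= 0 | records$lymphocytes <= 0 |
                 records$age <= 0)
  if (length(bad)) {
    stop("non-positive counts or age in rows: ",
         paste(records$patient_id[bad], collapse = ", "), call. = FALSE)
  }
  out <- records
  out$lognlr <- log(records$neutrophils / records$lymphocytes)
  out$logage <- log(records$age)
  out$action_code <- derive_action_code(records$tki_line, records$tki_generation)
  out$progression_category <- derive_progression_category(
    records$pfs_months, records$event, records$followup_months)
  out
}

#' Descriptive summary of a patient table
#'
#' Counts and percentages (one decimal) per level of each categorical
#' variable; mean, standard deviation, median, minimum and maximum per
#' numeric variable.
#'
#' @param records Patient `data.frame` (raw or engineered).
#' @return List of class `cohort_summary` with data.frames `categorical`
#'   and `numeric`, plus `n`.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0) stop("cannot summarize an empty table", call. = FALSE)
  n <- nrow(records)
  cat_vars <- intersect(
    c("gender", "ecog", "mutation", "smoking", "n_mets_cat",
      "bone_or_liver_met", "brain_met", "comorbidity", "tki_generation",
      "action_code", "progression_category", "event"),
    names(records))
  num_vars <- intersect(
    c("age", "neutrophils", "lymphocytes", "tki_line", "pfs_months",
      "followup_months", "lognlr", "logage"),
    names(records))

  cat_rows <- do.call(rbind, lapply(cat_vars, function(v) {
    tab <- table(records[[v]])
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  }))
  num_rows <- do.call(rbind, lapply(num_vars, function(v) {
    x <- records[[v]]
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               median = stats::median(x), min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  }))
  structure(list(n = n, categorical = cat_rows, numeric = num_rows),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n\nCategorical variables:\n", x$n))
  print(x$categorical, row.names = FALSE)
  cat("\nNumeric variables:\n")
  print(cbind(x$numeric[1], round(x$numeric[-1], 2)), row.names = FALSE)
  invisible(x)
}

#' Two-sample t-test of the NLR across progression categories
#'
#' Pooled-variance (Student) two-sample t-test comparing the raw
#' neutrophil-to-lymphocyte ratio between patients progressing within a year
#' and those progression-free at one year; degrees of freedom are
#' n1 + n2 - 2.
#'
#' @param records Engineered `data.frame` with `neutrophils`, `lymphocytes`
#'   and `progression_category`.
#' @return List of class `tki_ttest` with `statistic`, `df`, `p_value`.
#' @export
nlr_progression_ttest <- function(records) {
  nlr <- records$neutrophils / records$lymphocytes
  g <- records$progression_category
  if (length(unique(g)) != 2L || any(table(g) < 2L)) {
    stop("both progression categories must be present with at least 2 rows",
         call. = FALSE)
  }
  # group order: early progression (1) vs progression-free (0), so a lower
  # mean NLR in the progressing group yields a negative statistic
  tt <- stats::t.test(nlr[g == 1], nlr[g == 0], var.equal = TRUE)
  structure(list(statistic = unname(tt$statistic),
                 df = as.integer(unname(tt$parameter)),
                 p_value = tt$p.value),
            class = "tki_ttest")
}

#' @export
print.tki_ttest <- function(x, ...) {
  cat(sprintf("Pooled two-sample t-test: t = %.2f, df = %d, p = %.3f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Numeric model matrix for an engineered patient table
#'
#' One-hot/dummy encoding of the engineered features used by both the
#' supervised screen and the reinforcement-learning state. Binary levels are
#' coded 0/1; the treatment line enters either as the raw line number
#' (`line = "quantitative"`, used by the feature screen) or dichotomized
#' first vs later (`line = "dichotomized"`, used by the policy model).
#'
#' @param engineered Engineered `data.frame` from [engineer_features()].
#' @param line `"dichotomized"` or `"quantitative"`.
#' @return Numeric matrix, one row per patient.
#' @export
encode_features <- function(engineered, line = c("dichotomized", "quantitative")) {
  line <- match.arg(line)
  m <- cbind(
    logage = engineered$logage,
    lognlr = engineered$lognlr,
    male = as.numeric(engineered$gender == "male"),
    ecog_high = as.numeric(engineered$ecog == "2-4"),
    exon19 = as.numeric(engineered$mutation == "exon19"),
    smoker = as.numeric(engineered$smoking == "current"),
    mets_4plus = as.numeric(engineered$n_mets_cat == "4+"),
    bone_or_liver_met = as.numeric(engineered$bone_or_liver_met),
    brain_met = as.numeric(engineered$brain_met),
    comorbidity = as.numeric(engineered$comorbidity)
  )
  if (line == "quantitative") {
    m <- cbind(m, line_treatment = as.numeric(engineered$tki_line))
  } else {
    m <- cbind(m, line_later = as.numeric(engineered$tki_line >= 2))
  }
  rownames(m) <- engineered$patient_id
  m
}
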