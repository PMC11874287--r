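validate_survival <- function(records) {
  req <- c("time", "event")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop_("missing survival column '%s'", miss[1])
  if (!nrow(records)) stop_("need at least one survival record")
  if (any(!is.finite(records$time) | records$time <= 0))
    stop_("validation error: survival times must be finite and positive")
  records$event <- as.logical(records$event)
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function with its median (the
#' earliest time at which the estimate drops to 0.5 or below; `NA` when
#' never reached).
#'
#' @param records data.frame with `time` (months, > 0) and `event`
#'   (TRUE = progression/death observed, FALSE = censored).
#' @return object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (event-time grid), `median`, and `survfun`, a right-
#'   continuous step function of time.
#' @export
km_curve <- function(records) {
  records <- validate_survival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  med <- if (any(fit$surv <= 0.5 + 1e-12))
    min(fit$time[fit$surv <= 0.5 + 1e-12]) else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, median = med,
                 survfun = stats::stepfun(fit$time, c(1, fit$surv),
                                          right = FALSE)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, median %s\n",
              length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

as_group_df <- function(groups) {
  if (is.data.frame(groups)) {
    if (is.null(groups$group)) stop_("data.frame input needs a group column")
    return(groups)
  }
  if (!is.list(groups) || length(groups) < 2)
    stop_("need at least two groups")
  nm <- names(groups) %||% as.character(seq_along(groups))
  do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (!nrow(g)) stop_("group '%s' is empty", nm[i])
    g$group <- nm[i]
    g[, c("time", "event", "group")]
  }))
}

#' Log-rank test
#'
#' Standard log-rank chi-square comparing the survival of two or more
#' groups, with `g - 1` degrees of freedom. When no events occurred at all,
#' the statistic is 0 and p = 1.
#'
#' @param groups named list of survival record data.frames (`time`,
#'   `event`), or one data.frame with a `group` column.
#' @return list: `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
logrank_test <- function(groups) {
  d <- validate_survival(as_group_df(groups))
  g <- length(unique(d$group))
  if (g < 2) stop_("need at least two groups")
  if (sum(d$event) == 0)
    return(list(statistic = 0, df = g - 1, p_value = 1,
                observed = rep(0, g), expected = rep(0, g)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  list(statistic = unname(sd$chisq), df = g - 1,
       p_value = pchisq(sd$chisq, g - 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Log-rank test for trend
#'
#' Tests for an ordered survival difference across three or more ordered
#' groups: the score-weighted sum of the groupwise observed-minus-expected
#' event counts, normalised by its variance, is chi-square with 1 degree of
#' freedom. Group order carries the ordinal hypothesis; default scores are
#' 1, 2, 3, ...
#'
#' @param ordered_groups ordered named list of survival record data.frames,
#'   or a data.frame whose `group` column is an ordered factor.
#' @param scores monotone ordinal weights (default `1:g`).
#' @return list: `statistic`, `df` (1), `p_value`, `direction` (sign of the
#'   weighted trend).
#' @export
logrank_trend <- function(ordered_groups, scores = NULL) {
  d <- validate_survival(as_group_df(ordered_groups))
  lev <- if (is.factor(d$group)) levels(d$group) else unique(d$group)
  g <- length(lev)
  if (g < 3)
    stop_("trend test needs at least 3 ordered groups; use logrank_test")
  scores <- scores %||% seq_len(g)
  if (length(scores) != g || any(diff(scores) <= 0))
    stop_("scores must be strictly increasing, one per group")
  if (sum(d$event) == 0)
    return(list(statistic = 0, df = 1, p_value = 1, direction = 0))
  d$group <- factor(d$group, levels = lev)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  oe <- sd$obs - sd$exp
  z <- sum(scores * oe)
  v <- drop(t(scores) %*% sd$var %*% scores)
  stat <- if (v > 0) z^2 / v else 0
  list(statistic = stat, df = 1,
       p_value = pchisq(stat, 1, lower.tail = FALSE),
       direction = sign(z))
}

#' Dichotomise a per-patient marker
#'
#' Splits patients into high/low groups by the cohort median (high when
#' strictly above) or a fixed threshold (high when strictly above; a value
#' exactly at a fixed threshold goes to the low group and is flagged).
#'
#' @param values named numeric vector (names = patient ids).
#' @param rule `"median"` or `"fixed"`.
#' @param threshold required for the fixed rule.
#' @return data.frame: `patient_id`, `value`, `group` (`"high"`/`"low"`),
#'   `flagged` (value exactly at a fixed threshold).
#' @export
dichotomise_marker <- function(values, rule = c("median", "fixed"),
                               threshold = NULL) {
  rule <- match.arg(rule)
  if (length(values) < 2) stop_("need at least two patients")
  if (rule == "median") {
    if (length(unique(values)) == 1)
      stop_("degenerate marker: all values identical under median rule")
    threshold <- median(values)
    flagged <- rep(FALSE, length(values))
  } else {
    if (is.null(threshold)) stop_("fixed rule needs a threshold")
    flagged <- values == threshold
  }
  data.frame(patient_id = names(values) %||%
               as.character(seq_along(values)),
             value = unname(values),
             group = ifelse(values > threshold, "high", "low"),
             flagged = flagged, stringsAsFactors = FALSE)
}

#' ROC curve and AUC for survival beyond a horizon
#'
#' Binary outcome: progression-free survival reaching the horizon
#' (`time >= horizon`, whether or not an event followed later) versus
#' progression before it. Patients censored before the horizon carry no
#' outcome information and are excluded (their number is reported). AUC is
#' the rank statistic (equivalently, the trapezoid over all thresholds) with
#' mid-rank handling of ties, computed via `pROC`.
#'
#' @param marker named numeric vector of per-patient marker values.
#' @param records survival records with `patient_id`, `time`, `event`.
#' @param horizon months (default 8).
#' @return list: `auc`, `curve` (data.frame of threshold, sensitivity,
#'   specificity), `n_excluded`, `n_reached`, `n_progressed`.
#' @export
roc_auc_pfs <- function(marker, records, horizon = 8) {
  if (horizon <= 0) stop_("horizon must be positive")
  records <- validate_survival(records)
  if (is.null(records$patient_id))
    stop_("records must carry patient_id")
  m <- marker[records$patient_id]
  if (anyNA(m)) stop_("marker missing for some patients")
  outcome <- ifelse(records$time >= horizon, 1L,
                    ifelse(records$event, 0L, NA_integer_))
  excl <- is.na(outcome)
  outcome <- outcome[!excl]; m <- m[!excl]
  if (sum(outcome == 1) < 2 || sum(outcome == 0) < 2)
    stop_("AUC undefined: fewer than 2 patients in an outcome class after exclusion")
  r <- pROC::roc(response = outcome, predictor = as.numeric(m),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       curve = data.frame(threshold = r$thresholds,
                          sensitivity = r$sensitivities,
                          specificity = r$specificities),
       n_excluded = sum(excl), n_reached = sum(outcome == 1),
       n_progressed = sum(outcome == 0))
}

#' Bonferroni correction helper
#'
#' Family-wise correction for a set of group-comparison p values. Provided
#' as an explicit helper; never applied automatically by other functions.
#'
#' @param p numeric vector of p values.
#' @param n family size (defaults to `length(p)`).
#' @return adjusted p values.
#' @export
bonferroni_adjust <- function(p, n = length(p)) {
  p.adjust(p, method = "bonferroni", n = n)
}
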