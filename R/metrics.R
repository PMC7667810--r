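#' Harrell's concordance index
#'
#' Proportion of comparable subject pairs whose scalar risk scores order
#' them concordantly with their survival times, accounting for censoring.
#' Comparable pairs are (i, j) with t_i < t_j and d_i = 1; a pair is
#' concordant when score_i > score_j (higher score = worse prognosis).
#' Tied risk scores on comparable pairs count 1/2; pairs with tied times
#' are excluded (Harrell's original convention). Not defined for PLANN
#' predictions, which have no single subject ordering — pass a Cox
#' prognostic index or an ensemble mortality instead.
#'
#' @param risk_scores One scalar per subject, higher = worse prognosis.
#' @param data A [survival_data()] object.
#' @return Concordance in \[0, 1\].
#' @export
concordance_index <- function(risk_scores, data) {
  stopifnot(inherits(data, "survdata"))
  if (length(risk_scores) != n_subjects(data))
    stop("one risk score per subject required")
  t <- data$time; d <- data$event; s <- risk_scores
  comp <- outer(t, t, "<") & (d == 1L)        # [i, j]: t_i < t_j, d_i = 1
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs; concordance undefined")
  conc <- sum(comp & outer(s, s, ">")) + 0.5 * sum(comp & outer(s, s, "=="))
  conc / n_comp
}

#' Reverse Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimator with the roles of event and censoring swapped:
#' estimates C(t), the probability of remaining uncensored beyond t, used
#' as the IPCW weight denominator and to report median follow-up (the
#' first time at which C drops to 0.5 or below).
#'
#' @param data A [survival_data()] object.
#' @return An object of class `"censoring_fit"` with the step function
#'   (times, surv), the median follow-up (NA if C never reaches 0.5) and
#'   the underlying [survival::survfit] object.
#' @export
reverse_km <- function(data) {
  stopifnot(inherits(data, "survdata"))
  sf <- survival::survfit(survival::Surv(data$time, 1 - data$event) ~ 1)
  med <- if (any(sf$surv <= 0.5)) min(sf$time[sf$surv <= 0.5]) else NA_real_
  structure(list(times = sf$time, surv = sf$surv,
                 median_followup = med, survfit = sf),
            class = "censoring_fit")
}

#' @export
print.censoring_fit <- function(x, ...) {
  cat(sprintf("<censoring_fit> reverse Kaplan-Meier, median follow-up %s\n",
              format(x$median_followup)))
  invisible(x)
}

#' Evaluate the censoring survival function
#'
#' Right-continuous step evaluation of the reverse Kaplan-Meier C(t), or
#' its left limit C(t-) (`left = TRUE`), the value just before t; by
#' convention C(0-) = C(0) = 1.
#'
#' @param C A `"censoring_fit"` from [reverse_km()].
#' @param t Evaluation time(s).
#' @param left Evaluate the left limit C(t-) instead of C(t).
#' @return Numeric vector of probabilities.
#' @export
censoring_survival <- function(C, t, left = FALSE) {
  stopifnot(inherits(C, "censoring_fit"))
  f <- stats::stepfun(C$times, c(1, C$surv), right = FALSE)
  if (left) {
    # value of the step function just before t: shift evaluation below every
    # jump located exactly at t
    eps <- .Machine$double.eps
    sapply(t, function(ti) {
      if (ti <= 0) return(1)
      jump <- C$times[C$times < ti]
      if (!length(jump)) 1 else f(max(jump))
    })
  } else {
    f(t)
  }
}

#' IPCW Brier score at a fixed time
#'
#' Inverse-probability-of-censoring-weighted estimate of the expected
#' squared prediction error at t0:
#' (1/n) sum_i 1(d_i = 1 or t_i > t0) (1(t_i > t0) - S(t0 | x_i))^2 /
#' C(min(t_i-, t0)), where C is the reverse Kaplan-Meier censoring
#' survival. Subjects censored before t0 contribute 0; events before t0
#' are weighted by the left limit C(t_i-) and survivors by C(t0); the
#' denominator n counts all subjects.
#'
#' @param surv_prob Predicted survival probability S(t0 | x_i), one per
#'   subject, in \[0, 1\].
#' @param data A [survival_data()] object (the test set).
#' @param t0 Evaluation time (> 0).
#' @param C Optional `"censoring_fit"`; computed from `data` if missing.
#' @return The weighted Brier score (>= 0, typically <= 0.25).
#' @export
brier_ipcw <- function(surv_prob, data, t0, C = NULL) {
  stopifnot(inherits(data, "survdata"))
  n <- n_subjects(data)
  if (length(surv_prob) != n) stop("one prediction per subject required")
  if (any(surv_prob < 0 | surv_prob > 1)) stop("predictions must be in [0, 1]")
  if (t0 <= 0) stop("t0 must be positive")
  if (is.null(C)) C <- reverse_km(data)
  t <- data$time; d <- data$event
  contrib <- numeric(n)
  early_event <- d == 1L & t <= t0
  survivor <- t > t0
  if (any(early_event)) {
    w <- censoring_survival(C, t[early_event], left = TRUE)
    if (any(w <= 0))
      stop("censoring survival is 0 at the event time of subject(s) ",
           paste(data$id[early_event][w <= 0], collapse = ", "),
           "; IPCW weight undefined")
    contrib[early_event] <- (0 - surv_prob[early_event])^2 / w
  }
  if (any(survivor)) {
    w <- censoring_survival(C, t0)
    if (w <= 0)
      stop("censoring survival is 0 at t0 = ", t0, "; IPCW weight undefined")
    contrib[survivor] <- (1 - surv_prob[survivor])^2 / w
  }
  sum(contrib) / n
}

#' Prediction error curve (Brier score over time)
#'
#' Evaluates [brier_ipcw()] at each requested time, using a common
#' censoring estimate.
#'
#' @param surv_matrix Matrix of predicted survival probabilities, one row
#'   per subject and one column per entry of `times`.
#' @param data A [survival_data()] object.
#' @param times Evaluation times (default years 1..10).
#' @param C Optional `"censoring_fit"`; computed from `data` if missing.
#' @return Named numeric vector of Brier scores (names = times).
#' @export
prediction_error_curve <- function(surv_matrix, data, times = 1:10, C = NULL) {
  if (is.vector(surv_matrix)) surv_matrix <- matrix(surv_matrix, ncol = 1)
  if (ncol(surv_matrix) != length(times))
    stop("surv_matrix needs one column per evaluation time")
  if (is.null(C)) C <- reverse_km(data)
  stats::setNames(vapply(seq_along(times), function(j)
    brier_ipcw(surv_matrix[, j], data, times[j], C), 1.0),
    as.character(times))
}

#' Integrated Brier Score
#'
#' Time-averaged prediction error (1/t_hor) integral of Err(t) over
#' \[0, t_hor\]. The default is the trapezoid rule on the curve's grid with
#' an Err(0) = 0 anchor (no subject can be misclassified at t = 0);
#' `method = "mean"` instead averages the curve values on their grid.
#'
#' @param curve Named numeric vector from [prediction_error_curve()]
#'   (names are the evaluation times).
#' @param t_hor Time horizon; defaults to the last curve time.
#' @param method `"trapezoid"` (anchored, default) or `"mean"`.
#' @return The IBS, on the Brier scale.
#' @export
integrated_brier <- function(curve, t_hor = NULL,
                             method = c("trapezoid", "mean")) {
  method <- match.arg(method)
  if (!length(curve)) stop("empty prediction error curve")
  times <- as.numeric(names(curve))
  if (anyNA(times)) stop("curve must be named by its evaluation times")
  ord <- order(times)
  times <- times[ord]; vals <- as.numeric(curve)[ord]
  if (is.null(t_hor)) t_hor <- max(times)
  if (max(times) > t_hor) stop("curve extends beyond t_hor")
  if (method == "mean") return(mean(vals))
  tt <- c(0, times); vv <- c(0, vals)
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2) / t_hor
}

#' Decile calibration table against Kaplan-Meier
#'
#' Splits subjects into `n_groups` equally sized groups (sizes within 1)
#' by the deciles of their predicted survival probability at time t, and
#' compares the mean prediction per group with the Kaplan-Meier observed
#' survival at t and its 95% confidence interval (Greenwood variance,
#' complementary log-log transform). Ties in the predictions are assigned
#' stably by subject order. If all predictions are identical the groups are
#' degenerate: a single row is returned with a warning.
#'
#' @param surv_prob Predicted S(t | x_i), one per subject.
#' @param data A [survival_data()] object.
#' @param t Evaluation time.
#' @param n_groups Number of groups (default 10).
#' @return Data frame with one row per group: `group`, `n`, `mean_predicted`,
#'   `km_observed`, `km_lower`, `km_upper`.
#' @export
calibration_table <- function(surv_prob, data, t, n_groups = 10) {
  stopifnot(inherits(data, "survdata"))
  n <- n_subjects(data)
  if (length(surv_prob) != n) stop("one prediction per subject required")
  if (n < n_groups) stop("fewer subjects than groups")
  if (length(unique(surv_prob)) == 1L) {
    warning("all predictions identical; returning a single calibration group")
    n_groups <- 1L
  }
  ord <- order(surv_prob, seq_len(n))   # stable under ties
  cuts <- floor(seq(0, n, length.out = n_groups + 1L))
  grp <- integer(n)
  grp[ord] <- rep.int(seq_len(n_groups), diff(cuts))
  rows <- lapply(seq_len(n_groups), function(g) {
    in_g <- grp == g
    sf <- survival::survfit(
      survival::Surv(data$time[in_g], data$event[in_g]) ~ 1,
      conf.type = "log-log")
    sm <- summary(sf, times = t, extend = TRUE)
    data.frame(group = g, n = sum(in_g),
               mean_predicted = mean(surv_prob[in_g]),
               km_observed = sm$surv, km_lower = sm$lower,
               km_upper = sm$upper)
  })
  do.call(rbind, rows)
}

#' Evaluation report for one model on a test set
#'
#' Bundles the global performance measures: Harrell C-index (NA for
#' models, like PLANN, without a scalar risk ordering), the yearly Brier
#' curve, and the Integrated Brier Score up to the horizon.
#'
#' @param surv_matrix Predicted survival matrix (subjects x times).
#' @param data The test [survival_data()].
#' @param times Brier evaluation times.
#' @param t_hor Horizon for the IBS (default `max(times)`).
#' @param risk_scores Optional scalar risk scores for the C-index.
#' @param model Label for the model.
#' @return An object of class `"eval_report"`.
#' @export
evaluate_model <- function(surv_matrix, data, times = 1:10, t_hor = NULL,
                           risk_scores = NULL, model = "model") {
  C <- reverse_km(data)
  curve <- prediction_error_curve(surv_matrix, data, times, C)
  structure(list(model = model,
                 c_index = if (is.null(risk_scores)) NA_real_
                           else concordance_index(risk_scores, data),
                 brier_by_time = curve,
                 ibs = integrated_brier(curve, t_hor),
                 t_hor = t_hor %||% max(times),
                 n_test = n_subjects(data)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: IBS = %.4f%s (n = %d, t_hor = %g)\n",
              x$model, x$ibs,
              if (is.na(x$c_index)) "" else sprintf(", C-index = %.4f",
                                                    x$c_index),
              x$n_test, x$t_hor))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  rbind(
    data.frame(model = x$model, metric = "ibs", time = NA_real_,
               value = x$ibs),
    if (!is.na(x$c_index))
      data.frame(model = x$model, metric = "c_index", time = NA_real_,
                 value = x$c_index),
    data.frame(model = x$model, metric = "brier",
               time = as.numeric(names(x$brier_by_time)),
               value = as.numeric(x$brier_by_time)))
}

#' Serialize one or more evaluation reports
#'
#' Writes a JSON file (one object per report) and/or a flat CSV
#' (model, metric, time, value).
#'
#' @param reports An `"eval_report"` or list of them.
#' @param json_path,csv_path Output paths (either may be NULL).
#' @return Invisibly, the list of reports.
#' @export
write_eval_reports <- function(reports, json_path = NULL, csv_path = NULL) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  if (!is.null(json_path))
    jsonlite::write_json(lapply(reports, function(r) {
      r <- unclass(r)
      r$brier_by_time <- as.list(r$brier_by_time)
      r
    }), json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(csv_path)) {
    flat <- do.call(rbind, lapply(reports, as.data.frame))
    utils::write.table(flat, csv_path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(reports)
}
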