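#' Stratified split-sample protocol
#'
#' Splits a cohort into complementary training and test sets, stratified
#' by event status so both parts keep the cohort's event/censoring
#' proportions; reproducible given the seed.
#'
#' @param data A [survival_data()] object.
#' @param train_frac Training fraction in (0, 1); default 2/3.
#' @param seed Integer seed.
#' @return List with `train` and `test` `"survdata"` objects.
#' @export
split_sample <- function(data, train_frac = 2 / 3, seed = 1L) {
  stopifnot(inherits(data, "survdata"))
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  set.seed(seed)
  in_train <- logical(n_subjects(data))
  for (g in unique(data$event)) {
    idx <- which(data$event == g)
    n_tr <- round(train_frac * length(idx))
    if (n_tr == 0 || n_tr == length(idx))
      stop("a stratum is too small to split at this fraction")
    in_train[sample(idx, n_tr)] <- TRUE
  }
  list(train = subset_subjects(data, in_train),
       test = subset_subjects(data, !in_train))
}

#' Tune PLANN hyper-parameters by 5-fold cross-validated IBS
#'
#' Grid search: each candidate configuration is trained on 4 of 5
#' event-stratified folds of the training set and its Integrated Brier
#' Score measured on the held-out fold (predictions via the test-format
#' expansion of the fold; the censoring distribution is estimated on the 4
#' training folds to avoid leakage). The configuration with the smallest
#' mean fold IBS wins; exact ties go to the smaller node size, then the
#' lower dropout rate. A configuration whose training fails in any fold is
#' excluded with a warning.
#'
#' @param train Training [survival_data()].
#' @param param_grid Named list of candidate vectors over any of:
#'   `n_hidden_layers`, `node_size`, `activation`, `dropout_rate`,
#'   `learning_rate`, `momentum`, `event_class_weight`, `n_epochs`,
#'   `batch_size`. Unlisted parameters use [plann_config()] defaults.
#' @param grid An [interval_grid()].
#' @param n_folds Number of CV folds (default 5).
#' @param seed Seed for folds and network initialization.
#' @return List with `best_config` (a [plann_config()]), `best_ibs` and
#'   the full `cv_table` (one row per candidate).
#' @export
tune_plann <- function(train, param_grid, grid, n_folds = 5, seed = 1L) {
  stopifnot(inherits(train, "survdata"), inherits(grid, "interval_grid"))
  candidates <- expand.grid(param_grid, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
  if (!nrow(candidates)) stop("empty tuning grid")
  fold <- stratified_folds(train$event, n_folds, seed)
  times <- grid$boundaries[-1L]
  cv_ibs <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    args <- as.list(candidates[i, , drop = FALSE])
    cfg <- do.call(plann_config, c(args, list(seed = seed)))
    fold_ibs <- tryCatch(vapply(seq_len(n_folds), function(f) {
      tr <- subset_subjects(train, fold != f)
      va <- subset_subjects(train, fold == f)
      model <- build_plann(cfg, ncol(tr$x), grid$k,
                           feature_names = c(colnames(tr$x),
                                             paste0("interval_",
                                                    seq_len(grid$k))))
      model <- plann_train(model, to_long_train(tr, grid))
      surv <- hazards_to_survival(predict_hazards(model,
                                                  to_long_test(va, grid)))
      C_tr <- reverse_km(tr)
      integrated_brier(prediction_error_curve(surv, va, times, C = C_tr))
    }, 1.0), error = function(e) {
      warning("configuration ", i, " failed and was excluded: ",
              conditionMessage(e))
      NA_real_
    })
    cv_ibs[i] <- mean(fold_ibs)
  }
  cv_table <- cbind(candidates, cv_ibs = cv_ibs)
  ok <- which(!is.na(cv_ibs))
  if (!length(ok)) stop("every candidate configuration failed")
  best_val <- min(cv_ibs[ok])
  tied <- ok[cv_ibs[ok] == best_val]
  if (length(tied) > 1L) {
    ns <- if ("node_size" %in% names(candidates))
      candidates$node_size[tied] else rep(0, length(tied))
    tied <- tied[ns == min(ns)]
    if (length(tied) > 1L && "dropout_rate" %in% names(candidates)) {
      dr <- candidates$dropout_rate[tied]
      tied <- tied[dr == min(dr)]
    }
  }
  best <- tied[1L]
  best_config <- do.call(plann_config,
                         c(as.list(candidates[best, , drop = FALSE]),
                           list(seed = seed)))
  list(best_config = best_config, best_ibs = cv_ibs[best],
       cv_table = cv_table)
}

#' Fit and evaluate the model family on a train/test split
#'
#' Fits any of `cox_all` (all covariates), `cox_backward` (group-wise
#' backward elimination), `cox_lasso` (penalty selected by CVPL),
#' `plann_1h` and `plann_2h`, then evaluates each on the test set: IBS on
#' the yearly grid for every model, C-index only for Cox models (from the
#' prognostic index) — a discrete-hazard network induces no single subject
#' ordering, so its C-index entry stays NA.
#'
#' @param train,test [survival_data()] objects.
#' @param grid An [interval_grid()] (also sets the Brier evaluation times,
#'   its interior boundaries, and the IBS horizon).
#' @param models Character subset of
#'   `c("cox_all", "cox_backward", "cox_lasso", "plann_1h", "plann_2h")`.
#' @param config_1h,config_2h [plann_config()]s for the networks.
#' @param lambda_grid Candidate penalties for `cox_lasso`; default a
#'   10-point geometric grid under `lambda_max(train)`.
#' @param alpha_stay Stay level for `cox_backward`.
#' @param seed Seed for CVPL folds.
#' @return Named list of `"eval_report"` objects, plus attribute `"fits"`
#'   with the fitted model objects.
#' @export
compare_models <- function(train, test, grid,
                           models = c("cox_all", "cox_backward",
                                      "cox_lasso", "plann_1h", "plann_2h"),
                           config_1h = plann_config(n_hidden_layers = 1),
                           config_2h = plann_config(n_hidden_layers = 2),
                           lambda_grid = NULL, alpha_stay = 0.05,
                           seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  times <- grid$boundaries[-1L]
  t_hor <- max(grid$boundaries)
  reports <- list()
  fits <- list()
  eval_cox <- function(fit, label) {
    surv <- predict_cox_survival(fit, test$x, times)
    evaluate_model(surv, test, times, t_hor,
                   risk_scores = cox_risk_score(fit, test$x), model = label)
  }
  if ("cox_all" %in% models) {
    fits$cox_all <- fit_cox(train)
    reports$cox_all <- eval_cox(fits$cox_all, "cox_all")
  }
  if ("cox_backward" %in% models) {
    fits$cox_backward <- backward_eliminate(train, alpha_stay)
    reports$cox_backward <- eval_cox(fits$cox_backward, "cox_backward")
  }
  if ("cox_lasso" %in% models) {
    if (is.null(lambda_grid))
      lambda_grid <- lambda_max(train) * 0.5^(seq(1, 10))
    sel <- select_lambda(train, lambda_grid, seed = seed)
    fits$cox_lasso <- fit_cox_lasso(train, sel$lambda)
    reports$cox_lasso <- eval_cox(fits$cox_lasso, "cox_lasso")
  }
  eval_plann <- function(cfg, label) {
    model <- build_plann(cfg, ncol(train$x), grid$k,
                         feature_names = c(colnames(train$x),
                                           paste0("interval_",
                                                  seq_len(grid$k))))
    model <- plann_train(model, to_long_train(train, grid))
    fits[[label]] <<- model
    surv <- hazards_to_survival(predict_hazards(model,
                                                to_long_test(test, grid)))
    evaluate_model(surv, test, times, t_hor, risk_scores = NULL,
                   model = label)
  }
  if ("plann_1h" %in% models)
    reports$plann_1h <- eval_plann(config_1h, "plann_1h")
  if ("plann_2h" %in% models)
    reports$plann_2h <- eval_plann(config_2h, "plann_2h")
  attr(reports, "fits") <- fits
  reports
}
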