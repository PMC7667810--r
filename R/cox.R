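#' Breslow log partial likelihood and its gradient
#'
#' Evaluates the Cox log partial likelihood (Breslow tie handling) and its
#' gradient at an arbitrary coefficient vector. Used by the cross-validated
#' partial likelihood, the LASSO KKT checks and the score-equation tests;
#' invariant to covariate centering.
#'
#' @param beta Coefficient vector (length p; may be empty for the null
#'   model).
#' @param x Covariate matrix (n x p).
#' @param time,event Follow-up times and event indicators.
#' @return List with `loglik` and `gradient` (length p).
#' @export
cox_loglik <- function(beta, x, time, event) {
  x <- as.matrix(x)
  p <- ncol(x)
  eta <- if (p) drop(x %*% beta) else numeric(nrow(x))
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]; d_s <- event[ord]
  x_s <- x[ord, , drop = FALSE]
  w <- exp(eta[ord])
  cs <- cumsum(w)
  # risk set of t includes all tied times: use the last index of each tie group
  last <- cummax_by_ties(t_s)
  denom <- cs[last]
  ev <- d_s == 1L
  ll <- sum(log(w[ev])) - sum(log(denom[ev]))
  grad <- numeric(p)
  if (p) {
    csx <- apply(x_s * w, 2, cumsum)
    if (is.null(dim(csx))) csx <- matrix(csx, nrow = 1)
    grad <- colSums(x_s[ev, , drop = FALSE]) -
      colSums(csx[last[ev], , drop = FALSE] / denom[ev])
  }
  list(loglik = ll, gradient = grad)
}

# for a non-increasing time vector, index of the last element of each tie group
cummax_by_ties <- function(t_sorted) {
  n <- length(t_sorted)
  last <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && t_sorted[j + 1L] == t_sorted[i]) j <- j + 1L
    last[i:j] <- j
    i <- j + 1L
  }
  last
}

# assemble a cox_fit object: Breslow baseline cumulative hazard computed at
# the unique event times with the mean-centered prognostic index
make_cox_fit <- function(beta, se, data, lambda = NULL, trace = NULL,
                         method = "coxph") {
  x <- data$x
  center <- colMeans(x)
  p <- length(beta)
  eta <- if (p) drop(sweep(x[, names(beta), drop = FALSE], 2,
                           center[names(beta)], "-") %*% beta)
         else numeric(nrow(x))
  ll <- cox_loglik(beta, x[, names(beta), drop = FALSE],
                   data$time, data$event)$loglik
  ll0 <- cox_loglik(numeric(0), x[, 0, drop = FALSE],
                    data$time, data$event)$loglik
  ut <- sort(unique(data$time[data$event == 1L]))
  risk <- exp(eta)
  inc <- vapply(ut, function(tt)
    sum(data$event == 1L & data$time == tt) / sum(risk[data$time >= tt]), 1.0)
  structure(list(beta = beta, se = se,
                 z = if (!is.null(se)) beta / se else NULL,
                 loglik = c(null = ll0, model = ll),
                 baseline_time = ut, baseline_cumhaz = cumsum(inc),
                 center = center, lambda = lambda,
                 active = names(beta)[beta != 0],
                 group_map = data$group_map, trace = trace,
                 method = method),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %s: %d coefficients (%d active), loglik %.3f\n",
              x$method, length(x$beta), length(x$active),
              x$loglik["model"]))
  invisible(x)
}

#' Fit a Cox proportional hazards model
#'
#' Maximum partial likelihood fit of h(t | x) = h0(t) exp(x' beta) with
#' Breslow tie handling, via [survival::coxph]. The baseline cumulative
#' hazard is the Breslow estimator at the mean-centered prognostic index.
#'
#' @param data A [survival_data()] object with at least one event.
#' @param columns Optional subset of covariate columns to use.
#' @return An object of class `"cox_fit"` with coefficients, standard
#'   errors, z-scores, log partial likelihoods (null and model) and the
#'   baseline hazard step function.
#' @export
fit_cox <- function(data, columns = NULL) {
  stopifnot(inherits(data, "survdata"))
  if (sum(data$event) == 0) stop("no events; Cox model undefined")
  x <- if (is.null(columns)) data$x else data$x[, columns, drop = FALSE]
  if (ncol(x) == 0)
    return(make_cox_fit(stats::setNames(numeric(0), character(0)), NULL,
                        data, method = "null"))
  fit <- survival::coxph(survival::Surv(data$time, data$event) ~ x,
                         ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  if (any(is.na(stats::coef(fit))))
    stop("Cox fit failed (collinear covariates or monotone likelihood)")
  beta <- stats::setNames(stats::coef(fit), colnames(x))
  se <- stats::setNames(sqrt(diag(stats::vcov(fit))), colnames(x))
  out <- make_cox_fit(beta, se, data, method = "coxph")
  out$vcov <- stats::vcov(fit)
  dimnames(out$vcov) <- list(colnames(x), colnames(x))
  out
}

#' Predicted survival from a Cox fit
#'
#' S(t | x) = exp(-H0(t) exp((x - center)' beta)) with the Breslow
#' baseline cumulative hazard H0; beyond the last event time the last
#' value is carried forward.
#'
#' @param fit A `"cox_fit"`.
#' @param covariates Covariate matrix for new subjects (all original
#'   columns; the fit's active columns are selected internally).
#' @param times Evaluation times.
#' @return Survival matrix, subjects x times.
#' @export
predict_cox_survival <- function(fit, covariates, times) {
  stopifnot(inherits(fit, "cox_fit"))
  covariates <- as.matrix(covariates)
  eta <- cox_risk_score(fit, covariates)
  H0 <- stats::stepfun(fit$baseline_time, c(0, fit$baseline_cumhaz))(times)
  outer(exp(eta), H0, function(r, h) exp(-h * r))
}

#' Cox prognostic index
#'
#' The mean-centered linear predictor (x - center)' beta; the scalar risk
#' score used for concordance.
#'
#' @param fit A `"cox_fit"`.
#' @param covariates Covariate matrix for new subjects.
#' @return Numeric vector, one score per subject.
#' @export
cox_risk_score <- function(fit, covariates) {
  covariates <- as.matrix(covariates)
  nm <- names(fit$beta)
  if (!length(nm)) return(numeric(nrow(covariates)))
  drop(sweep(covariates[, nm, drop = FALSE], 2, fit$center[nm], "-") %*%
         fit$beta)
}

#' Largest useful LASSO penalty
#'
#' The smallest lambda (on the scale of -loglik + lambda * sum |beta_j|)
#' at which all coefficients are exactly 0: the sup-norm of the partial
#' likelihood gradient at beta = 0 on internally standardized covariates.
#'
#' @param data A [survival_data()] object.
#' @return Numeric lambda_max.
#' @export
lambda_max <- function(data) {
  xs <- scale(data$x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  max(abs(cox_loglik(numeric(ncol(xs)), xs, data$time,
                     data$event)$gradient))
}

#' Fit a LASSO-penalized Cox model
#'
#' Minimizes -loglik(beta) + lambda sum_j |beta_j| by cyclic coordinate
#' descent ([glmnet::glmnet], cox family) on internally standardized
#' covariates; coefficients are returned on the original scale. `lambda`
#' is on the penalized-partial-likelihood scale above (glmnet's own
#' per-observation scale is converted internally).
#'
#' @param data A [survival_data()] object.
#' @param lambda Non-negative penalty.
#' @return A `"cox_fit"` with the sparse `active` set and `lambda` recorded.
#' @export
fit_cox_lasso <- function(data, lambda) {
  stopifnot(inherits(data, "survdata"))
  if (lambda < 0) stop("lambda must be non-negative")
  n <- n_subjects(data)
  sds <- apply(data$x, 2, stats::sd)
  if (any(sds == 0)) stop("constant covariate column(s); drop them first")
  xs <- scale(data$x)
  lam_g <- lambda / n
  lmax_g <- max(lambda_max(data), .Machine$double.eps) / n
  hi <- max(lmax_g * 1.05, lam_g * 1.05)
  lo <- max(min(lam_g, lmax_g * 1e-3), lmax_g * 1e-5)
  path <- sort(unique(c(exp(seq(log(hi), log(lo), length.out = 40)), lam_g)),
               decreasing = TRUE)
  y <- survival::Surv(data$time, data$event)
  gfit <- glmnet::glmnet(xs, y, family = "cox", lambda = path,
                         standardize = FALSE, thresh = 1e-12, maxit = 1e6)
  # read the coefficients at lam_g straight off the fitted path (no
  # interpolation); refit exactly if glmnet truncated the path early
  j <- which(abs(gfit$lambda - lam_g) <= 1e-10 * max(1, lam_g))[1L]
  beta_std <- if (!is.na(j)) gfit$beta[, j] else
    drop(as.matrix(stats::coef(gfit, s = lam_g, exact = TRUE, x = xs, y = y,
                               family = "cox", standardize = FALSE,
                               thresh = 1e-12, maxit = 1e6)))
  beta_std <- polish_lasso(beta_std, xs, data$time, data$event, lam = lambda)
  beta <- stats::setNames(beta_std / sds, colnames(data$x))
  make_cox_fit(beta, NULL, data, lambda = lambda, method = "glmnet-lasso")
}

# Newton refinement of a LASSO solution on its (fixed) active set: solves
# grad(loglik)_A = lambda * sign(beta_A) to near machine precision, using a
# finite-difference Jacobian of the analytic gradient. Backs off if a sign
# flips or the stationarity residual worsens.
polish_lasso <- function(beta, x, time, event, lam, max_iter = 10) {
  act <- which(beta != 0)
  if (!length(act)) return(beta)
  s <- sign(beta[act])
  resid <- function(b) cox_loglik(b, x, time, event)$gradient[act] - lam * s
  b <- beta
  r <- resid(b)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < 1e-10 * max(1, lam)) break
    eps <- 1e-6
    J <- vapply(act, function(j) {
      bp <- b; bp[j] <- bp[j] + eps
      (resid(bp) - r) / eps
    }, numeric(length(act)))
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    b_new <- b
    b_new[act] <- b[act] - step
    if (any(sign(b_new[act]) != s)) break
    r_new <- resid(b_new)
    if (max(abs(r_new)) >= max(abs(r))) break
    b <- b_new
    r <- r_new
  }
  b
}

# stratified fold labels (by event status), seeded
stratified_folds <- function(event, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(event))
  for (g in unique(event)) {
    idx <- which(event == g)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated log partial likelihood (CVPL)
#'
#' Verweij-van Houwelingen fold-wise CVPL at a fixed penalty: for each
#' fold, the model is fitted on the complement and its contribution is
#' loglik_full(beta_hat) - loglik_complement(beta_hat), summed over folds.
#' Folds are stratified by event status. Larger is better.
#'
#' @param data A [survival_data()] object.
#' @param lambda LASSO penalty (0 = unpenalized).
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return The CVPL value.
#' @export
cvpl <- function(data, lambda, n_folds = 5, seed = 1L) {
  stopifnot(inherits(data, "survdata"), n_folds >= 2)
  fold <- stratified_folds(data$event, n_folds, seed)
  total <- 0
  for (f in seq_len(n_folds)) {
    rest <- subset_subjects(data, fold != f)
    if (sum(rest$event) == 0)
      stop("a training fold has zero events; use fewer folds or reseed")
    fit <- if (lambda > 0) fit_cox_lasso(rest, lambda) else fit_cox(rest)
    b <- fit$beta
    ll_full <- cox_loglik(b, data$x[, names(b), drop = FALSE],
                          data$time, data$event)$loglik
    ll_rest <- cox_loglik(b, rest$x[, names(b), drop = FALSE],
                          rest$time, rest$event)$loglik
    total <- total + (ll_full - ll_rest)
  }
  total
}

#' Select the LASSO penalty by CVPL
#'
#' Evaluates [cvpl()] on a penalty grid and returns the maximizer; exact
#' ties go to the larger (sparser) lambda.
#'
#' @param data A [survival_data()] object.
#' @param grid Numeric vector of candidate lambdas.
#' @param n_folds,seed Passed to [cvpl()].
#' @return List with `lambda` (selected) and `cvpl_table` (data frame).
#' @export
select_lambda <- function(data, grid, n_folds = 5, seed = 1L) {
  if (!length(grid)) stop("empty lambda grid")
  vals <- vapply(grid, function(l) cvpl(data, l, n_folds, seed), 1.0)
  best <- max(grid[vals == max(vals)])
  list(lambda = best,
       cvpl_table = data.frame(lambda = grid, cvpl = vals))
}

#' Group-wise backward elimination for the Cox model
#'
#' Numerically stable factor-level backward selection: the full model is
#' fitted once per step and each remaining parent variable's multi-df Wald
#' statistic beta_g' V_gg^{-1} beta_g is computed from that fit's
#' coefficients and covariance (no per-candidate refit). The group with
#' the largest p-value above `alpha_stay` is dropped as a whole and the
#' model refitted, until every remaining group has p <= alpha_stay.
#' Factors spanning several dummy columns are dropped or retained as a
#' group; single-column factors reduce to ordinary 1-df Wald selection.
#'
#' @param data A [survival_data()] object (its `group_map` defines the
#'   factor groups).
#' @param alpha_stay Significance level required to stay (default 0.05).
#' @return A `"cox_fit"` on the retained columns, with an elimination
#'   `trace` data frame (step, dropped group, Wald statistic, df, p).
#'   If everything is eliminated, the null model is returned with a
#'   warning.
#' @export
backward_eliminate <- function(data, alpha_stay = 0.05) {
  stopifnot(inherits(data, "survdata"))
  groups <- unique(data$group_map)
  trace <- data.frame(step = integer(0), dropped = character(0),
                      wald = numeric(0), df = integer(0), p = numeric(0))
  step <- 0L
  repeat {
    cols <- names(data$group_map)[data$group_map %in% groups]
    if (!length(cols)) {
      warning("all factors eliminated; returning the null model")
      fit <- fit_cox(data, columns = character(0))
      fit$trace <- trace
      return(fit)
    }
    fit <- fit_cox(data, columns = cols)
    pvals <- vapply(groups, function(g) {
      gc <- names(data$group_map)[data$group_map == g]
      b <- fit$beta[gc]
      V <- fit$vcov[gc, gc, drop = FALSE]
      w <- drop(t(b) %*% solve(V, b))
      stats::pchisq(w, df = length(gc), lower.tail = FALSE)
    }, 1.0)
    if (max(pvals) <= alpha_stay) {
      fit$trace <- trace
      return(fit)
    }
    worst <- names(pvals)[which.max(pvals)]
    gc <- names(data$group_map)[data$group_map == worst]
    b <- fit$beta[gc]
    V <- fit$vcov[gc, gc, drop = FALSE]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = worst,
                                     wald = drop(t(b) %*% solve(V, b)),
                                     df = length(gc),
                                     p = max(pvals)))
    groups <- setdiff(groups, worst)
  }
}
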