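test_that("the partial likelihood fit matches a direct grid-search oracle", {
  # n = 8 toy, single binary covariate, distinct times
  tt <- c(0.9, 1.7, 2.3, 3.1, 4.6, 5.2, 6.8, 8.4)
  dd <- c(1, 1, 0, 1, 1, 0, 1, 0)
  xx <- c(1, 0, 1, 1, 0, 0, 1, 0)
  d <- survival_data(time = tt, event = dd, covariates = cbind(g = xx))
  # independent oracle: direct evaluation of the partial likelihood product
  pl <- function(beta) {
    ll <- 0
    for (i in which(dd == 1)) {
      risk <- which(tt >= tt[i])
      ll <- ll + beta * xx[i] - log(sum(exp(beta * xx[risk])))
    }
    ll
  }
  beta_grid <- optimize(pl, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  fit <- fit_cox(d)
  expect_equal(unname(fit$beta), beta_grid, tolerance = 1e-6)
  # null log partial likelihood by direct evaluation
  expect_equal(unname(fit$loglik["null"]), pl(0), tolerance = 1e-12)
  # score equation at the optimum
  g <- cox_loglik(fit$beta, d$x, d$time, d$event)$gradient
  expect_lt(max(abs(g)), 1e-6)
  expect_error(fit_cox(survival_data(time = 1:3, event = c(0, 0, 0),
                                     covariates = cbind(z = 1:3))),
               "no events")
})

test_that("simulated proportional-hazards coefficients are recovered", {
  set.seed(77)
  n <- 2000
  x <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
  lp <- 0.5 * x[, 1] - 0.3 * x[, 2]
  tev <- rexp(n, 0.1 * exp(lp))
  cens <- pmin(rexp(n, 0.05), 10)
  d <- survival_data(pmin(tev, cens), as.integer(tev <= cens), x)
  fit <- fit_cox(d)
  expect_lt(abs(fit$beta["a"] - 0.5), 3 * fit$se["a"])
  expect_lt(abs(fit$beta["b"] + 0.3), 3 * fit$se["b"])
  # score ~ 0 at the fitted maximum
  g <- cox_loglik(fit$beta, d$x, d$time, d$event)$gradient
  expect_lt(max(abs(g)), 1e-6)
})

test_that("survival prediction follows the Breslow baseline and the PH form", {
  d <- toy_survdata(n = 50, seed = 19, cens_rate = 0.1)
  # null model: prediction equals the Nelson-Aalen-based baseline survival
  null_fit <- fit_cox(d, columns = character(0))
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  at <- sf$time[sf$n.event > 0]
  pred0 <- predict_cox_survival(null_fit, d$x[1, , drop = FALSE], at)
  na_cumhaz <- cumsum(sf$n.event / sf$n.risk)[sf$n.event > 0]
  expect_equal(unname(pred0[1, ]), exp(-na_cumhaz), tolerance = 1e-12)
  # PH identity: doubling the hazard ratio squares the survival
  fit <- fit_cox(d)
  x1 <- d$x[3, , drop = FALSE]
  x2 <- x1
  x2[1, 1] <- x2[1, 1] + log(2) / fit$beta[1]   # exp(lp) doubles
  s <- predict_cox_survival(fit, rbind(x1, x2), c(1, 3, 6))
  expect_equal(s[2, ], s[1, ]^2, tolerance = 1e-10)
  # monotone, S(0) = 1
  expect_true(all(s[, -1] <= s[, -3]))
  expect_equal(predict_cox_survival(fit, x1, 0)[1, 1], 1)
  # small toy: Breslow increments are d_j / sum over the risk set of exp(PI)
  d1 <- survival_data(time = c(2, 3, 5, 7), event = c(0, 1, 1, 0),
                      covariates = cbind(z = c(0.5, -1, 2, 0)))
  f1 <- fit_cox(d1)
  eta <- cox_risk_score(f1, d1$x)
  inc <- c(1 / sum(exp(eta[d1$time >= 3])), 1 / sum(exp(eta[d1$time >= 5])))
  expect_equal(f1$baseline_cumhaz, cumsum(inc), tolerance = 1e-9)
})

test_that("the LASSO path shrinks, matches the unpenalized limit and satisfies KKT", {
  d <- toy_survdata(n = 250, p = 6, seed = 23, cens_rate = 0.08)
  lmax <- lambda_max(d)
  # full shrinkage at lambda >= lambda_max
  expect_true(all(fit_cox_lasso(d, lmax * 1.0001)$beta == 0))
  expect_true(all(fit_cox_lasso(d, lmax * 3)$beta == 0))
  # lambda = 0 reproduces the unpenalized fit
  expect_equal(fit_cox_lasso(d, 0)$beta, fit_cox(d)$beta, tolerance = 1e-4)
  # KKT at a moderate penalty, on the standardized scale
  lam <- lmax * 0.25
  fl <- fit_cox_lasso(d, lam)
  sds <- apply(d$x, 2, sd)
  bstd <- fl$beta * sds
  gr <- cox_loglik(bstd, scale(d$x), d$time, d$event)$gradient
  act <- bstd != 0
  expect_true(any(act) && any(!act))
  expect_lt(max(abs(gr[act] - lam * sign(bstd[act]))) / lam, 1e-6)
  expect_true(all(abs(gr[!act]) <= lam * (1 + 1e-6)))
  # optimality sandwich: penalized objective at the solution beats both the
  # unpenalized optimum and the null vector
  obj <- function(b) -cox_loglik(b, d$x, d$time, d$event)$loglik +
    lam * sum(abs(b * sds))   # penalty applies on the standardized scale
  expect_lte(obj(fl$beta), obj(fit_cox(d)$beta))
  expect_lte(obj(fl$beta), obj(setNames(rep(0, 6), names(fl$beta))))
  # active-set size non-increasing along an increasing penalty grid
  na <- vapply(lmax * c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8),
               function(l) length(fit_cox_lasso(d, l)$active), 1L)
  expect_true(all(diff(na) <= 0))
})

test_that("cross-validated partial likelihood follows its fold-wise definition", {
  d <- toy_survdata(n = 120, p = 3, seed = 31, cens_rate = 0.1)
  lmax <- lambda_max(d)
  # at full shrinkage CVPL equals its closed form at beta = 0
  fold <- plannsurv:::stratified_folds(d$event, 5, 4)
  ll0 <- function(sub) cox_loglik(numeric(0),
                                  sub$x[, 0, drop = FALSE],
                                  sub$time, sub$event)$loglik
  closed <- sum(vapply(1:5, function(f)
    ll0(d) - ll0(subset_subjects(d, fold != f)), 1.0))
  expect_equal(cvpl(d, lmax * 2, n_folds = 5, seed = 4), closed,
               tolerance = 1e-9)
  # 2-fold direct evaluation oracle at lambda = 0 (unpenalized refits)
  fold2 <- plannsurv:::stratified_folds(d$event, 2, 7)
  direct <- 0
  for (f in 1:2) {
    rest <- subset_subjects(d, fold2 != f)
    cf <- survival::coxph(survival::Surv(rest$time, rest$event) ~ rest$x,
                          ties = "breslow",
                          control = survival::coxph.control(eps = 1e-9))
    b <- coef(cf)
    pl_direct <- function(time, event, x) {   # explicit Breslow product
      ll <- 0
      for (i in which(event == 1))
        ll <- ll + sum(x[i, ] * b) -
          log(sum(exp(x[time >= time[i], , drop = FALSE] %*% b)))
      ll
    }
    direct <- direct + (pl_direct(d$time, d$event, d$x) -
                        pl_direct(rest$time, rest$event, rest$x))
  }
  expect_equal(cvpl(d, 0, n_folds = 2, seed = 7), direct, tolerance = 1e-6)
  # fold-wise CVPL is finite across a grid, and selection is deterministic
  grid <- lmax * c(0.05, 0.2, 0.8)
  vals <- vapply(grid, function(l) cvpl(d, l, seed = 2), 1.0)
  expect_true(all(is.finite(vals)))
  s1 <- select_lambda(d, grid, seed = 2)
  s2 <- select_lambda(d, grid, seed = 2)
  expect_identical(s1, s2)
  expect_equal(select_lambda(d, grid[2], seed = 2)$lambda, grid[2])
})

test_that("penalty selection keeps truly prognostic coefficients active", {
  set.seed(55)
  n <- 1500
  x <- cbind(s1 = rbinom(n, 1, 0.5), s2 = rnorm(n), n1 = rnorm(n),
             n2 = rnorm(n), n3 = rbinom(n, 1, 0.5), n4 = rnorm(n))
  lp <- 0.7 * x[, 1] + 0.6 * x[, 2]
  tev <- rexp(n, 0.1 * exp(lp))
  cens <- pmin(rexp(n, 0.06), 10)
  d <- survival_data(pmin(tev, cens), as.integer(tev <= cens), x)
  sel <- select_lambda(d, lambda_max(d) * 0.5^(1:8), seed = 3)
  fit <- fit_cox_lasso(d, sel$lambda)
  expect_true(all(c("s1", "s2") %in% fit$active))
})

test_that("group-wise backward elimination drops noise factors and keeps signal", {
  set.seed(88)
  n <- 1200
  # factor "f" has two dummy levels (a real group); s and noise are single df
  f <- sample(0:2, n, replace = TRUE)
  x <- cbind(f_b = as.numeric(f == 1), f_c = as.numeric(f == 2),
             s = rnorm(n), n1 = rnorm(n), n2 = rbinom(n, 1, 0.5))
  lp <- 0.6 * x[, "f_b"] + 0.9 * x[, "f_c"] + 0.5 * x[, "s"]
  tev <- rexp(n, 0.1 * exp(lp))
  cens <- pmin(rexp(n, 0.05), 10)
  d <- survival_data(pmin(tev, cens), as.integer(tev <= cens), x,
                     group_map = c(f_b = "f", f_c = "f", s = "s",
                                   n1 = "n1", n2 = "n2"))
  fit <- backward_eliminate(d, alpha_stay = 0.05)
  kept <- unique(d$group_map[names(fit$beta)])
  expect_true(all(c("f", "s") %in% kept))
  expect_false(any(c("n1", "n2") %in% kept))
  expect_true(all(fit$trace$dropped %in% c("n1", "n2")))
  # factor levels are dropped or retained as a group
  expect_true(all(c("f_b", "f_c") %in% names(fit$beta)))
  # pure noise model: everything eliminated, null model with warning
  dn <- survival_data(d$time, d$event, cbind(n1 = rnorm(n)),
                      group_map = c(n1 = "n1"))
  expect_warning(nf <- backward_eliminate(dn, alpha_stay = 1e-6),
                 "null model")
  expect_equal(length(nf$beta), 0L)
})
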