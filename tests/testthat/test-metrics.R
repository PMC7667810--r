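test_that("concordance matches exhaustive pair enumeration", {
  # perfect discrimination: scores anti-ordered with uncensored times
  d <- survival_data(time = c(1, 2, 3, 4), event = rep(1, 4),
                     covariates = cbind(z = 1:4))
  expect_equal(concordance_index(c(4, 3, 2, 1), d), 1)
  expect_equal(concordance_index(rep(2, 4), d), 0.5)    # all tied: 1/2
  # brute-force oracle over all ordered pairs, mixed censoring
  set.seed(33)
  n <- 200
  dd <- toy_survdata(n = n, seed = 33, cens_rate = 0.12)
  s <- rnorm(n) + dd$x[, 1]
  num <- den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (dd$event[i] == 1 && dd$time[i] < dd$time[j]) {
      den <- den + 1
      if (s[i] > s[j]) num <- num + 1
      else if (s[i] == s[j]) num <- num + 0.5
    }
  }
  expect_equal(concordance_index(s, dd), num / den, tolerance = 1e-12)
  d_none <- survival_data(time = c(1, 2), event = c(0, 0),
                          covariates = cbind(z = 1:2))
  expect_error(concordance_index(c(1, 2), d_none), "comparable")
})

test_that("reverse Kaplan-Meier estimates the censoring distribution", {
  # no censored subjects: C stays 1
  d1 <- survival_data(time = 1:5, event = rep(1, 5),
                      covariates = cbind(z = 1:5))
  C1 <- reverse_km(d1)
  expect_true(all(censoring_survival(C1, c(0.5, 3, 4.9)) == 1))
  # all censored: reverse KM is the plain KM of the times
  d2 <- survival_data(time = c(2, 4, 4, 7), event = rep(0, 4),
                      covariates = cbind(z = 1:4))
  C2 <- reverse_km(d2)
  km <- oracle_km(d2$time, rep(1, 4))
  expect_equal(censoring_survival(C2, km$times), km$surv)
  # 6-subject hand product-limit table: censorings at 2, 4, 5
  d3 <- survival_data(time = 1:6, event = c(1, 0, 1, 0, 0, 1),
                      covariates = cbind(z = 1:6))
  C3 <- reverse_km(d3)
  expect_equal(censoring_survival(C3, 2), 4 / 5)
  expect_equal(censoring_survival(C3, 4), 4 / 5 * 2 / 3)
  expect_equal(censoring_survival(C3, 5), 4 / 5 * 2 / 3 * 1 / 2)
  # left limits: value just before each drop; C(0-) = 1
  expect_equal(censoring_survival(C3, 2, left = TRUE), 1)
  expect_equal(censoring_survival(C3, 4.5, left = TRUE), 4 / 5 * 2 / 3)
  expect_equal(censoring_survival(C3, 0, left = TRUE), 1)
  expect_equal(C3$median_followup, 5)
  # cross-check against an independent product-limit implementation
  d4 <- toy_survdata(n = 80, seed = 14, cens_rate = 0.2)
  C4 <- reverse_km(d4)
  km4 <- oracle_km(d4$time, 1 - d4$event)
  expect_equal(censoring_survival(C4, km4$times), km4$surv, tolerance = 1e-12)
})

test_that("the IPCW Brier score follows the weighting scheme term by term", {
  # no censoring: perfect predictions score 0, constant 0.5 scores 0.25
  d <- survival_data(time = c(1, 2, 6, 9), event = rep(1, 4),
                     covariates = cbind(z = 1:4))
  expect_equal(brier_ipcw(as.numeric(d$time > 5), d, 5), 0)
  expect_equal(brier_ipcw(rep(0.5, 4), d, 5), 0.25)
  # 8-subject toy, 3 censored: independent term-by-term evaluation
  t8 <- c(0.5, 1.2, 2.0, 2.5, 3.5, 4.0, 6.0, 8.0)
  d8 <- c(1, 0, 1, 0, 1, 0, 1, 1)
  dd <- survival_data(time = t8, event = d8, covariates = cbind(z = 1:8))
  set.seed(5)
  shat <- runif(8)
  t0 <- 5
  ckm <- oracle_km(t8, 1 - d8)  # independent censoring product-limit
  terms <- numeric(8)
  for (i in 1:8) {
    if (d8[i] == 1 && t8[i] <= t0) {
      terms[i] <- (0 - shat[i])^2 / oracle_km_at(ckm, t8[i], left = TRUE)
    } else if (t8[i] > t0) {
      terms[i] <- (1 - shat[i])^2 / oracle_km_at(ckm, t0)
    } # censored before t0: contributes 0
  }
  expect_equal(brier_ipcw(shat, dd, t0), sum(terms) / 8, tolerance = 1e-12)
  # zero censoring: IPCW reduces to the plain mean squared error
  for (seed in 1:3) {
    du <- toy_survdata(n = 40, seed = seed, cens_rate = 0)
    du$event <- rep(1L, 40)
    p <- runif(40)
    expect_equal(brier_ipcw(p, du, 3),
                 mean((as.numeric(du$time > 3) - p)^2), tolerance = 1e-12)
  }
})

test_that("prediction error curves evaluate the Brier score per time point", {
  d <- toy_survdata(n = 60, seed = 8, cens_rate = 0.1)
  sm <- matrix(runif(60 * 3), 60, 3)
  curve <- prediction_error_curve(sm, d, times = c(1, 3, 5))
  expect_equal(unname(curve["3"]), brier_ipcw(sm[, 2], d, 3))
  expect_true(all(curve >= 0 & curve <= 1))
  single <- prediction_error_curve(sm[, 1], d, times = 2)
  expect_equal(unname(single), brier_ipcw(sm[, 1], d, 2))
})

test_that("the integrated Brier score matches quadrature oracles", {
  flat <- setNames(rep(0.21, 10), 1:10)
  expect_equal(integrated_brier(flat, method = "mean"), 0.21)
  # linear curve rising from the Err(0) = 0 anchor: mean of the endpoints
  lin <- setNames(0.02 * (1:10), 1:10)
  expect_equal(integrated_brier(lin, 10), (0 + 0.2) / 2)
  # piecewise-linear curve: anchored trapezoid equals quadrature on a 10x
  # finer grid of the linear interpolant
  set.seed(3)
  vals <- runif(10, 0, 0.25)
  curve <- setNames(vals, 1:10)
  fine_t <- seq(0, 10, by = 0.1)
  fine_v <- approx(c(0, 1:10), c(0, vals), xout = fine_t)$y
  oracle <- sum(diff(fine_t) * (head(fine_v, -1) + tail(fine_v, -1)) / 2) / 10
  expect_equal(integrated_brier(curve, 10), oracle, tolerance = 1e-12)
  # linearity and boundedness
  expect_equal(integrated_brier(setNames(2 * vals, 1:10), 10), 2 * oracle)
  expect_lte(integrated_brier(curve, 10), max(vals))
  expect_error(integrated_brier(numeric(0)), "empty")
})

test_that("calibration deciles are equal-sized and compared to Kaplan-Meier", {
  # integer partition: n = 62294 into 10 groups -> sizes 6229/6230
  set.seed(10)
  n <- 62294
  dbig <- survival_data(time = rexp(n, 0.1), event = rbinom(n, 1, 0.5),
                        covariates = cbind(z = rnorm(n)))
  tab <- calibration_table(runif(n), dbig, t = 2)
  expect_equal(sort(unique(tab$n)), c(6229, 6230))
  expect_equal(sum(tab$n), n)
  expect_equal(nrow(tab), 10L)
  # groups ordered by predicted risk; KM values and CIs well-formed
  expect_true(all(diff(tab$mean_predicted) > 0))
  expect_true(all(tab$km_lower <= tab$km_observed + 1e-12 &
                  tab$km_observed <= tab$km_upper + 1e-12))
  # degenerate: identical predictions collapse to one group, with a warning
  dsm <- toy_survdata(n = 30, seed = 2)
  expect_warning(tab1 <- calibration_table(rep(0.4, 30), dsm, 2), "identical")
  expect_equal(nrow(tab1), 1L)
  expect_error(calibration_table(runif(5), toy_survdata(n = 5), 2,
                                 n_groups = 10), "fewer subjects")
})

test_that("evaluation reports bundle the metrics and serialize cleanly", {
  d <- toy_survdata(n = 100, seed = 44, cens_rate = 0.1)
  sm <- matrix(rep(seq(0.9, 0.45, length.out = 5), each = 100), 100, 5)
  rep1 <- evaluate_model(sm, d, times = 1:5, risk_scores = d$x[, 1],
                         model = "toy")
  expect_s3_class(rep1, "eval_report")
  expect_equal(rep1$ibs, integrated_brier(rep1$brier_by_time, 5))
  expect_equal(rep1$c_index, concordance_index(d$x[, 1], d))
  rep2 <- evaluate_model(sm, d, times = 1:5, model = "plann-like")
  expect_true(is.na(rep2$c_index))
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_eval_reports(list(rep1, rep2), jp, cp)
  flat <- read.csv(cp)
  expect_false("c_index" %in% flat$metric[flat$model == "plann-like"])
  expect_equal(jsonlite::read_json(jp)[[1]]$ibs, rep1$ibs)
})
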