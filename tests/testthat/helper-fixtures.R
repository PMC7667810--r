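# Shared fixture builders: everything is generated in code, seeded.

# small random right-censored dataset
toy_survdata <- function(n = 20, p = 2, seed = 1, cens_rate = 0.1,
                         base_rate = 0.15) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  tev <- rexp(n, base_rate * exp(0.5 * x[, 1]))
  cc <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  survival_data(time = pmin(tev, cc, 10), event = as.integer(tev <= pmin(cc, 10)),
                covariates = x)
}

# a plann object with weights set by hand (bypasses build_plann's init)
manual_plann <- function(W, b, n_covariates, k,
                         activation = "sigmoid", feature_names = NULL) {
  n_hidden <- length(W) - 1L
  cfg <- plann_config(n_hidden_layers = n_hidden, node_size = ncol(W[[1]]),
                      activation = activation)
  sizes <- c(nrow(W[[1]]), vapply(W, ncol, 1L))
  if (is.null(feature_names))
    feature_names <- c(paste0("x", seq_len(n_covariates)),
                       paste0("interval_", seq_len(k)))
  structure(list(config = cfg, n_covariates = as.integer(n_covariates),
                 k = as.integer(k), n_inputs = nrow(W[[1]]), sizes = sizes,
                 W = W, b = b, feature_names = feature_names,
                 center = NULL, scale = NULL, loss_trace = numeric(0),
                 trained = TRUE),
            class = "plann")
}

# flatten / restore all weights of a plann (for finite-difference checks)
plann_get_flat <- function(m) unlist(c(lapply(m$W, as.vector), m$b))
plann_set_flat <- function(m, v) {
  i <- 1L
  for (l in seq_along(m$W)) {
    n <- length(m$W[[l]]); m$W[[l]][] <- v[i:(i + n - 1L)]; i <- i + n
  }
  for (l in seq_along(m$b)) {
    n <- length(m$b[[l]]); m$b[[l]][] <- v[i:(i + n - 1L)]; i <- i + n
  }
  m
}

# independent product-limit estimator (plain loop), event indicator as given
oracle_km <- function(time, ind) {
  ut <- sort(unique(time[ind == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & ind == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(times = ut, surv = surv)
}
# evaluate the oracle KM at t (right-continuous) or its left limit
oracle_km_at <- function(km, t, left = FALSE) {
  keep <- if (left) km$times < t else km$times <= t
  if (!any(keep)) 1 else km$surv[max(which(keep))]
}
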