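#' PLANN configuration
#'
#' Hyper-parameters of the partial logistic artificial neural network.
#' The network maps person-period rows (covariates plus k time-interval
#' indicators) through 1 or 2 hidden layers to a single sigmoid output node
#' estimating the discrete conditional hazard of the row's interval.
#'
#' @param n_hidden_layers 1 or 2. With 2 hidden layers both share
#'   `node_size` and the activation.
#' @param node_size Nodes per hidden layer.
#' @param activation Hidden-layer activation: `"sigmoid"`, `"relu"` or
#'   `"tanh"`. The output activation is always sigmoid.
#' @param dropout_rate Dropout probability on hidden activations during
#'   training, in \[0, 1).
#' @param learning_rate SGD step size.
#' @param momentum Classical momentum coefficient in \[0, 1).
#' @param event_class_weight Loss multiplier for event rows (y = 1);
#'   1 means unweighted cross-entropy.
#' @param n_epochs Training epochs.
#' @param batch_size Mini-batch size, or `"full"` for full-batch.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @return An object of class `"plann_config"`.
#' @export
plann_config <- function(n_hidden_layers = 1, node_size = 16,
                         activation = c("sigmoid", "relu", "tanh"),
                         dropout_rate = 0, learning_rate = 0.2,
                         momentum = 0.9, event_class_weight = 1,
                         n_epochs = 50, batch_size = 256, seed = 1L) {
  activation <- match.arg(activation)
  if (!n_hidden_layers %in% c(1, 2))
    stop("n_hidden_layers must be 1 or 2")
  if (node_size < 1 || node_size != as.integer(node_size))
    stop("node_size must be a positive integer")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  if (event_class_weight <= 0) stop("event_class_weight must be positive")
  if (!identical(batch_size, "full") &&
      (batch_size < 1 || batch_size != as.integer(batch_size)))
    stop("batch_size must be a positive integer or \"full\"")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 node_size = as.integer(node_size), activation = activation,
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 momentum = momentum, event_class_weight = event_class_weight,
                 n_epochs = as.integer(n_epochs), batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "plann_config")
}

#' Activation functions
#'
#' The three hidden-layer transformation functions supported by the
#' network: logistic sigmoid 1/(1+e^-eta), rectified linear unit
#' max(0, eta) and hyperbolic tangent (1-e^-2eta)/(1+e^-2eta).
#'
#' @param name One of `"sigmoid"`, `"relu"`, `"tanh"`.
#' @param eta Numeric input (vectorized).
#' @return Transformed values.
#' @examples
#' activation_fn("sigmoid", 0)  # 0.5
#' activation_fn("relu", c(-3.2, 1.7))
#' @export
activation_fn <- function(name, eta) {
  switch(name,
         sigmoid = 1 / (1 + exp(-eta)),
         relu = pmax(eta, 0),
         tanh = tanh(eta),
         stop("unknown activation: ", name))
}

# derivative of the activation w.r.t. its input, given the activated value a
activation_deriv <- function(name, a) {
  switch(name,
         sigmoid = a * (1 - a),
         relu = (a > 0) * 1,
         tanh = 1 - a^2)
}

#' Build a PLANN with seeded Glorot initialization
#'
#' The input layer has `n_covariates + k` nodes (covariates plus the k
#' interval indicators); each hidden layer has `config$node_size` nodes and
#' the output layer is a single sigmoid node. Weights are drawn uniformly
#' in +/- sqrt(6 / (fan_in + fan_out)); biases start at zero.
#'
#' @param config A [plann_config()].
#' @param n_covariates Number of covariate columns (p).
#' @param k Number of time intervals.
#' @param feature_names Optional character vector of the p + k input names.
#' @return An object of class `"plann"` with weight matrices `W` (list, one
#'   per layer transition), biases `b`, the config, and bookkeeping fields.
#' @export
build_plann <- function(config, n_covariates, k, feature_names = NULL) {
  stopifnot(inherits(config, "plann_config"))
  if (n_covariates < 1 || k < 1)
    stop("n_covariates and k must be >= 1")
  n_in <- as.integer(n_covariates + k)
  sizes <- c(n_in, rep(config$node_size, config$n_hidden_layers), 1L)
  if (is.null(feature_names))
    feature_names <- c(paste0("x", seq_len(n_covariates)),
                       paste0("interval_", seq_len(k)))
  set.seed(config$seed)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(config = config, n_covariates = as.integer(n_covariates),
                 k = as.integer(k), n_inputs = n_in, sizes = sizes,
                 W = W, b = b, feature_names = feature_names,
                 center = NULL, scale = NULL, loss_trace = numeric(0),
                 trained = FALSE),
            class = "plann")
}

#' @export
print.plann <- function(x, ...) {
  cat(sprintf("<plann> %d inputs -> %s -> 1 (%s), %d weights%s\n",
              x$n_inputs,
              paste(rep(x$config$node_size, x$config$n_hidden_layers),
                    collapse = " -> "),
              x$config$activation, count_weights(x),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

#' Count trainable connection weights
#'
#' Counts all entries of the layer weight matrices plus one bias per
#' non-input node: with h hidden nodes per layer this is
#' (n_inputs + 1) h + (h + 1) for one hidden layer and
#' (n_inputs + 1) h + (h + 1) h + (h + 1) for two.
#'
#' @param model A `"plann"` model.
#' @return Integer weight count.
#' @examples
#' cfg <- plann_config(n_hidden_layers = 1, node_size = 85)
#' count_weights(build_plann(cfg, n_covariates = 119, k = 10))  # 11136
#' @export
count_weights <- function(model) {
  stopifnot(inherits(model, "plann"))
  sum(vapply(model$W, length, 1L)) + sum(vapply(model$b, length, 1L))
}

# forward pass; returns activations per layer. dropout_masks: NULL (inference)
# or list of per-hidden-layer multiplier matrices (inverted dropout).
plann_forward <- function(model, X, dropout_masks = NULL) {
  act <- model$config$activation
  n_hidden <- model$config$n_hidden_layers
  A <- vector("list", n_hidden + 1L)
  a <- X
  for (l in seq_len(n_hidden)) {
    a <- activation_fn(act, sweep(a %*% model$W[[l]], 2, model$b[[l]], "+"))
    if (!is.null(dropout_masks)) a <- a * dropout_masks[[l]]
    A[[l]] <- a
  }
  out <- 1 / (1 + exp(-(a %*% model$W[[n_hidden + 1L]] +
                          model$b[[n_hidden + 1L]])))
  A[[n_hidden + 1L]] <- out
  A
}

# class-weighted binary cross-entropy; predictions clipped inside the loss only
plann_loss <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(w * (-y * log(p) - (1 - y) * log(1 - p)))
}

# mean weighted cross-entropy loss and its gradients w.r.t. all weights/biases
plann_loss_grad <- function(model, X, y, w, dropout_masks = NULL) {
  n_hidden <- model$config$n_hidden_layers
  A <- plann_forward(model, X, dropout_masks)
  p <- A[[n_hidden + 1L]]
  n <- nrow(X)
  gW <- vector("list", n_hidden + 1L)
  gb <- vector("list", n_hidden + 1L)
  # output node: d(loss)/d(preactivation) for sigmoid + cross-entropy
  delta <- matrix(w * (p - y) / n, n, 1)
  a_prev <- A[[n_hidden]]
  gW[[n_hidden + 1L]] <- crossprod(a_prev, delta)
  gb[[n_hidden + 1L]] <- colSums(delta)
  back <- delta %*% t(model$W[[n_hidden + 1L]])
  for (l in rev(seq_len(n_hidden))) {
    if (!is.null(dropout_masks)) back <- back * dropout_masks[[l]]
    delta <- back * activation_deriv(model$config$activation, A[[l]])
    a_prev <- if (l == 1L) X else A[[l - 1L]]
    gW[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) back <- delta %*% t(model$W[[l]])
  }
  list(loss = plann_loss(p, y, w), gW = gW, gb = gb)
}

# standardize continuous feature columns (non-0/1) with train-set mean/sd;
# indicator columns pass through untouched
standardize_features <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) {
    is_binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
    center <- ifelse(is_binary, 0, colMeans(X))
    scale <- ifelse(is_binary, 1, apply(X, 2, stats::sd))
    scale[scale == 0 | is.na(scale)] <- 1
  }
  list(X = sweep(sweep(X, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}

#' Train a PLANN on person-period data
#'
#' Minimizes the class-weighted binary cross-entropy
#' sum w(y) \[-y log h - (1-y) log(1-h)\] over long-format rows by
#' mini-batch stochastic gradient descent with classical momentum
#' (v <- mu v - lr g; w <- w + v) and inverted dropout on hidden
#' activations. Continuous covariate columns are standardized with
#' train-set mean/sd (stored in the model and re-applied at prediction);
#' 0/1 indicator columns pass through unchanged. Fully deterministic given
#' the config seed.
#'
#' @param model A `"plann"` from [build_plann()].
#' @param long_train A `"plann_long"` table with role `"train"` (from
#'   [to_long_train()]).
#' @param standardize Standardize continuous features (default TRUE).
#' @return The trained model, with `loss_trace` holding the mean training
#'   loss per epoch.
#' @export
plann_train <- function(model, long_train, standardize = TRUE) {
  stopifnot(inherits(model, "plann"), inherits(long_train, "plann_long"))
  if (!identical(attr(long_train, "role"), "train"))
    stop("long_train must have role \"train\"")
  X <- long_features(long_train)
  if (ncol(X) != model$n_inputs)
    stop("feature count (", ncol(X), ") does not match model inputs (",
         model$n_inputs, ")")
  y <- long_train$y
  cfg <- model$config
  w <- ifelse(y == 1, cfg$event_class_weight, 1)
  if (standardize) {
    std <- standardize_features(X)
    X <- std$X
    model$center <- std$center
    model$scale <- std$scale
  }
  n <- nrow(X)
  bs <- if (identical(cfg$batch_size, "full")) n else min(cfg$batch_size, n)
  vW <- lapply(model$W, function(m) m * 0)
  vb <- lapply(model$b, function(v) v * 0)
  n_hidden <- cfg$n_hidden_layers
  keep <- 1 - cfg$dropout_rate
  set.seed(cfg$seed + 1L)
  trace <- numeric(cfg$n_epochs)
  for (epoch in seq_len(cfg$n_epochs)) {
    ord <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      masks <- NULL
      if (cfg$dropout_rate > 0)
        masks <- lapply(seq_len(n_hidden), function(l)
          matrix(stats::rbinom(length(idx) * cfg$node_size, 1, keep) / keep,
                 length(idx), cfg$node_size))
      g <- plann_loss_grad(model, X[idx, , drop = FALSE], y[idx], w[idx],
                           dropout_masks = masks)
      if (!is.finite(g$loss))
        stop("training diverged (non-finite loss); try a lower learning_rate")
      for (l in seq_along(model$W)) {
        vW[[l]] <- cfg$momentum * vW[[l]] - cfg$learning_rate * g$gW[[l]]
        vb[[l]] <- cfg$momentum * vb[[l]] - cfg$learning_rate * g$gb[[l]]
        model$W[[l]] <- model$W[[l]] + vW[[l]]
        model$b[[l]] <- model$b[[l]] + vb[[l]]
      }
      batch_losses <- c(batch_losses, g$loss)
    }
    trace[epoch] <- mean(batch_losses)
  }
  model$loss_trace <- trace
  model$trained <- TRUE
  model
}

#' Predict discrete hazards for test subjects
#'
#' Runs the forward pass (dropout disabled) on a test-role long table with
#' exactly k rows per subject and returns the per-subject conditional
#' hazard vector h_1..h_k, each in (0, 1).
#'
#' @param model A trained (or built) `"plann"`.
#' @param long_test A `"plann_long"` table with role `"test"` (from
#'   [to_long_test()]).
#' @return Numeric matrix, one row per subject (rownames = subject ids),
#'   one column per interval.
#' @export
predict_hazards <- function(model, long_test) {
  stopifnot(inherits(model, "plann"), inherits(long_test, "plann_long"))
  if (!identical(attr(long_test, "role"), "test"))
    stop("long_test must have role \"test\"")
  k <- attr(long_test, "grid")$k
  if (k != model$k) stop("interval grid does not match the model")
  tab <- table(long_test$id)
  if (any(tab != k))
    stop("every subject must have exactly k = ", k, " rows")
  X <- long_features(long_test)
  if (ncol(X) != model$n_inputs) stop("feature count mismatch")
  if (!is.null(model$center))
    X <- standardize_features(X, model$center, model$scale)$X
  p <- plann_forward(model, X)[[model$config$n_hidden_layers + 1L]]
  ids <- unique(long_test$id)
  h <- matrix(NA_real_, length(ids), k,
              dimnames = list(ids, paste0("h_", seq_len(k))))
  h[cbind(match(long_test$id, ids), long_test$interval)] <- p
  h
}

#' Compose discrete hazards into survival probabilities
#'
#' Applies the product-limit identity S(tau_m) = prod_{j <= m} (1 - h_j)
#' row-wise; every row is monotone non-increasing.
#'
#' @param h Matrix (or vector) of per-interval hazards in \[0, 1\].
#' @return Matrix of survival probabilities at the interval endpoints.
#' @examples
#' hazards_to_survival(matrix(0.5, 1, 3))  # 0.5 0.25 0.125
#' @export
hazards_to_survival <- function(h) {
  if (is.vector(h)) h <- matrix(h, 1)
  if (any(h < 0 | h > 1)) stop("hazards must lie in [0, 1]")
  s <- t(apply(1 - h, 1, cumprod))
  if (ncol(h) == 1L) s <- matrix(s, ncol = 1L)
  rownames(s) <- rownames(h)
  if (!is.null(colnames(h))) colnames(s) <- sub("^h_", "S_", colnames(h))
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a PLANN checkpoint as self-describing JSON
#'
#' Stores the configuration, layer shapes, flattened weights and biases,
#' feature names and standardization constants so a forward pass is exactly
#' reproducible in a later session.
#'
#' @param model A `"plann"`.
#' @param path Output path (.json).
#' @return Invisibly, `path`.
#' @export
write_plann <- function(model, path) {
  stopifnot(inherits(model, "plann"))
  obj <- list(config = unclass(model$config),
              n_covariates = model$n_covariates, k = model$k,
              sizes = model$sizes, feature_names = model$feature_names,
              W = lapply(model$W, as.vector), b = model$b,
              center = model$center, scale = model$scale,
              loss_trace = model$loss_trace, trained = model$trained)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a PLANN checkpoint written by [write_plann()]
#' @param path Path to the JSON checkpoint.
#' @return A `"plann"` model.
#' @export
read_plann <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(plann_config, obj$config[setdiff(names(obj$config), NULL)])
  sizes <- obj$sizes
  W <- lapply(seq_len(length(sizes) - 1L), function(l)
    matrix(obj$W[[l]], sizes[l], sizes[l + 1L]))
  structure(list(config = cfg, n_covariates = obj$n_covariates, k = obj$k,
                 n_inputs = sizes[1L], sizes = sizes, W = W,
                 b = lapply(obj$b, as.numeric),
                 feature_names = obj$feature_names,
                 center = obj$center, scale = obj$scale,
                 loss_trace = obj$loss_trace %||% numeric(0),
                 trained = isTRUE(obj$trained)),
            class = "plann")
}
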