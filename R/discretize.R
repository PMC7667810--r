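#' Time-interval grid for discrete-time survival
#'
#' Defines k non-overlapping, half-open intervals I_j = (tau_{j-1}, tau_j]
#' with tau_0 = 0 that partition (0, tau_k]. Either an equal-width grid is
#' built from `max_time` and `k`, or explicit `boundaries` are given.
#'
#' @param max_time Upper end of follow-up (tau_k), used with `k` for an
#'   equal-width grid.
#' @param k Number of intervals.
#' @param boundaries Explicit strictly increasing boundary vector starting
#'   at 0 (overrides `max_time`/`k`).
#' @return An object of class `"interval_grid"` with elements `boundaries`
#'   and `k`.
#' @examples
#' interval_grid(10, 10)  # yearly intervals (0,1], ..., (9,10]
#' @export
interval_grid <- function(max_time = NULL, k = NULL, boundaries = NULL) {
  if (is.null(boundaries)) {
    if (is.null(max_time) || is.null(k))
      stop("provide either boundaries or max_time and k")
    if (!is.numeric(max_time) || max_time <= 0)
      stop("max_time must be positive")
    if (k < 1 || k != as.integer(k))
      stop("k must be a positive integer")
    boundaries <- seq(0, max_time, length.out = k + 1L)
  } else {
    boundaries <- as.numeric(boundaries)
    if (boundaries[1L] != 0) stop("boundaries must start at 0")
    if (any(diff(boundaries) <= 0))
      stop("boundaries must be strictly increasing")
  }
  structure(list(boundaries = boundaries, k = length(boundaries) - 1L),
            class = "interval_grid")
}

#' @export
print.interval_grid <- function(x, ...) {
  cat(sprintf("<interval_grid> %d intervals on (0, %g]\n", x$k,
              max(x$boundaries)))
  invisible(x)
}

#' Interval membership of a time point
#'
#' Returns the index j such that tau_{j-1} < time <= tau_j. Boundaries
#' belong to the lower interval (right-closed convention).
#'
#' @param time Positive time(s) in (0, tau_k].
#' @param grid An [interval_grid()].
#' @return Integer vector of interval indices in 1..k.
#' @examples
#' interval_of(c(1, 5.36, 10), interval_grid(10, 10))
#' @export
interval_of <- function(time, grid) {
  stopifnot(inherits(grid, "interval_grid"))
  b <- grid$boundaries
  if (any(time <= 0) || any(time > b[length(b)]))
    stop("time out of range: must lie in (0, ", b[length(b)], "]")
  findInterval(time, b, left.open = TRUE)
}

# internal: assemble the person-period data frame
long_format <- function(data, rows_per_subject, y, role, grid) {
  idx <- rep.int(seq_along(rows_per_subject), rows_per_subject)
  interval <- sequence(rows_per_subject)
  k <- grid$k
  ind <- matrix(0, length(interval), k,
                dimnames = list(NULL, paste0("interval_", seq_len(k))))
  ind[cbind(seq_along(interval), interval)] <- 1
  df <- data.frame(id = data$id[idx], interval = interval,
                   data$x[idx, , drop = FALSE], ind, check.names = FALSE)
  if (!is.null(y)) df$y <- y
  structure(df, class = c("plann_long", "data.frame"),
            grid = grid, role = role,
            covariate_names = colnames(data$x),
            group_map = data$group_map)
}

#' Transform training data to person-period (long) format
#'
#' Each subject is repeated once for every interval in which they were
#' observed. A subject with the event in interval m contributes rows for
#' intervals 1..m with binary target y = (0, ..., 0, 1). Under the default
#' convention a subject censored within interval m also contributes rows
#' 1..m, all with y = 0 (they were observed, partially, in interval m);
#' `censored_partial = "drop"` drops that last partial-exposure row instead.
#'
#' @param data A [survival_data()] object; all times must lie in
#'   (0, tau_k] (apply [censor_at()] first if needed).
#' @param grid An [interval_grid()].
#' @param censored_partial Handling of a censored subject's final, partially
#'   observed interval: `"include"` (default) keeps its row with y = 0,
#'   `"drop"` removes it.
#' @return A `"plann_long"` data frame with columns `id`, `interval`, the
#'   covariates, k interval indicator columns (exactly one hot per row) and
#'   the target `y`. Attributes carry the grid, role and covariate names.
#' @examples
#' d <- survival_data(time = c(2.5, 0.12), event = c(1, 1),
#'                    covariates = cbind(z = c(1, 0)))
#' to_long_train(d, interval_grid(10, 10))
#' @export
to_long_train <- function(data, grid, censored_partial = c("include", "drop")) {
  stopifnot(inherits(data, "survdata"), inherits(grid, "interval_grid"))
  censored_partial <- match.arg(censored_partial)
  if (any(data$time == 0))
    stop("time = 0 rows are not representable; shift or drop them")
  if (any(data$time > max(grid$boundaries)))
    stop("times beyond the grid horizon found; apply censor_at() first")
  m <- interval_of(data$time, grid)
  n_rows <- m
  if (censored_partial == "drop")
    n_rows <- ifelse(data$event == 0L, pmax(m - 1L, 0L), m)
  if (any(n_rows == 0L))
    warning(sum(n_rows == 0L),
            " subject(s) censored in interval 1 contribute no rows")
  y <- unlist(lapply(seq_along(n_rows), function(i) {
    if (n_rows[i] == 0L) return(integer(0))
    yy <- integer(n_rows[i])
    if (data$event[i] == 1L) yy[n_rows[i]] <- 1L
    yy
  }))
  long_format(data, n_rows, y, role = "train", grid = grid)
}

#' Transform test data to person-period (long) format
#'
#' Every subject is expanded to exactly k rows, one per interval, so that a
#' trained network can predict the full discrete hazard vector h_1..h_k.
#' No target column is produced.
#'
#' @inheritParams to_long_train
#' @return A `"plann_long"` data frame with k rows per subject.
#' @export
to_long_test <- function(data, grid) {
  stopifnot(inherits(data, "survdata"), inherits(grid, "interval_grid"))
  n <- n_subjects(data)
  long_format(data, rep.int(grid$k, n), NULL, role = "test", grid = grid)
}

#' Write person-period data to delimited text
#' @param long A `"plann_long"` data frame.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_long_csv <- function(long, path, sep = ",") {
  utils::write.table(as.data.frame(long), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: feature matrix (covariates then interval indicators) of a long table
long_features <- function(long) {
  covs <- attr(long, "covariate_names")
  k <- attr(long, "grid")$k
  as.matrix(long[, c(covs, paste0("interval_", seq_len(k))), drop = FALSE])
}
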