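#' Subject-level right-censored survival dataset
#'
#' Container for one row per subject: follow-up time, event indicator and a
#' numeric covariate matrix (dummy-coded categoricals and/or continuous
#' columns). A `group_map` links every covariate column to its parent
#' variable so that factor-level importances can later be aggregated.
#'
#' @param time Non-negative numeric vector of follow-up times (years).
#' @param event Binary vector (1 = event observed, 0 = right-censored).
#' @param covariates Numeric matrix or data frame, one column per
#'   (dummy-coded) covariate; no missing values (imputation is upstream).
#' @param id Optional subject identifiers; defaults to `seq_along(time)`.
#' @param group_map Named character vector mapping each covariate column name
#'   to its parent variable. Defaults to the identity mapping.
#'
#' @return An object of class `"survdata"`: a list with elements `id`,
#'   `time`, `event`, `x` (numeric matrix) and `group_map`.
#' @examples
#' d <- survival_data(time = c(2.5, 7), event = c(1, 0),
#'                    covariates = cbind(age = c(50, 61)))
#' d
#' @export
survival_data <- function(time, event, covariates, id = NULL, group_map = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(time) != length(event) || nrow(x) != length(time))
    stop("time, event and covariates must have one entry per subject")
  if (any(is.na(time)) || any(time < 0))
    stop("all times must be non-negative and non-missing")
  if (!all(event %in% c(0L, 1L)))
    stop("event must be binary (0/1)")
  if (anyNA(x))
    stop("covariates contain missing values; impute upstream")
  if (is.null(id)) id <- seq_along(time)
  if (anyDuplicated(id)) stop("subject ids must be unique")
  if (is.null(group_map)) {
    group_map <- stats::setNames(colnames(x), colnames(x))
  } else {
    group_map <- unlist(group_map)
    if (!setequal(names(group_map), colnames(x)))
      stop("group_map must cover every covariate column exactly once")
    group_map <- group_map[colnames(x)]
  }
  structure(list(id = id, time = time, event = event, x = x,
                 group_map = group_map),
            class = "survdata")
}

#' @export
print.survdata <- function(x, ...) {
  cat(sprintf("<survdata> %d subjects, %d covariates, %.1f%% events\n",
              length(x$time), ncol(x$x), 100 * mean(x$event)))
  invisible(x)
}

#' @export
as.data.frame.survdata <- function(x, ...) {
  data.frame(id = x$id, time = x$time, event = x$event, x$x,
             check.names = FALSE)
}

#' Number of subjects in a survival dataset
#' @param data A [survival_data()] object.
#' @return Integer count.
#' @export
n_subjects <- function(data) length(data$time)

#' Subset a survival dataset by subject index
#' @param data A [survival_data()] object.
#' @param idx Integer or logical index over subjects.
#' @return A `"survdata"` object with the selected rows.
#' @export
subset_subjects <- function(data, idx) {
  survival_data(time = data$time[idx], event = data$event[idx],
                covariates = data$x[idx, , drop = FALSE],
                id = data$id[idx], group_map = data$group_map)
}

#' Apply administrative censoring at a fixed horizon
#'
#' Subjects with follow-up beyond `horizon` are censored there: their time
#' is truncated to `horizon` and the event indicator set to 0. All other
#' rows are unchanged.
#'
#' @param data A [survival_data()] object.
#' @param horizon Positive time horizon (years).
#' @return A `"survdata"` object.
#' @examples
#' d <- survival_data(time = c(12.3, 5.36), event = c(1, 0),
#'                    covariates = cbind(z = c(0, 1)))
#' censor_at(d, 10)$time
#' @export
censor_at <- function(data, horizon) {
  stopifnot(inherits(data, "survdata"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be a single positive number")
  over <- data$time > horizon
  data$event[over] <- 0L
  data$time[over] <- horizon
  data
}

#' Read a subject-level survival table from delimited text
#'
#' Expects columns `id`, `time`, `event`; every remaining column is taken as
#' a covariate.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @param group_map Optional named map from covariate column to parent
#'   variable (see [survival_data()]).
#' @return A `"survdata"` object.
#' @export
read_survival_csv <- function(path, sep = ",", group_map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "time", "event")
  if (!all(need %in% names(df)))
    stop("input must contain columns id, time, event")
  covs <- df[, setdiff(names(df), need), drop = FALSE]
  survival_data(time = df$time, event = df$event, covariates = covs,
                id = df$id, group_map = group_map)
}

#' Write a subject-level survival table to delimited text
#' @param data A [survival_data()] object.
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @return Invisibly, `path`.
#' @export
write_survival_csv <- function(data, path, sep = ",") {
  utils::write.table(as.data.frame(data), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
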