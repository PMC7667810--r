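#' Connection-weight relative importance, 1 hidden layer (Garson)
#'
#' Partitions the absolute connection weights of a single-hidden-layer
#' network among its inputs: for input i, hidden node j with input-hidden
#' weights w_ij and hidden-output weights v_j (biases excluded),
#' c_ij = |w_ij| |v_j| / sum_i' |w_i'j|, and the importance of input i is
#' sum_j c_ij normalized so all importances sum to 1. Sign-blind: it ranks
#' strength of signal transfer, not direction of effect.
#'
#' @param model A `"plann"` with exactly one hidden layer.
#' @return Named numeric vector of class `"rel_importance"`, one
#'   non-negative entry per input feature (in input order), summing to 1.
#' @export
garson_1h <- function(model) {
  stopifnot(inherits(model, "plann"))
  if (model$config$n_hidden_layers != 1L)
    stop("model has 2 hidden layers; use garson_2h()")
  W <- abs(model$W[[1L]])              # n_in x h
  v <- abs(model$W[[2L]])              # h x 1
  shares <- sweep(W, 2, colSums(W), "/")
  imp <- drop(shares %*% v)
  imp <- imp / sum(imp)
  structure(stats::setNames(imp, model$feature_names),
            class = "rel_importance")
}

#' Connection-weight relative importance, 2 hidden layers
#'
#' Extends the Garson partition through a second hidden layer by chaining
#' the per-layer weight shares: for input i, first-layer node j,
#' second-layer node l,
#' c_ijl = (|w_ij| / sum_i' |w_i'j|) (|u_jl| / sum_j' |u_j'l|) |v_l|,
#' and importance_i = sum_jl c_ijl, normalized to total 1. With a
#' pass-through second layer this collapses exactly to [garson_1h()].
#'
#' @param model A `"plann"` with exactly two hidden layers.
#' @return Named `"rel_importance"` vector as in [garson_1h()].
#' @export
garson_2h <- function(model) {
  stopifnot(inherits(model, "plann"))
  if (model$config$n_hidden_layers != 2L)
    stop("model has 1 hidden layer; use garson_1h()")
  W <- abs(model$W[[1L]])              # n_in x h1
  U <- abs(model$W[[2L]])              # h1 x h2
  v <- abs(model$W[[3L]])              # h2 x 1
  shares1 <- sweep(W, 2, colSums(W), "/")
  shares2 <- sweep(U, 2, colSums(U), "/")
  imp <- drop(shares1 %*% shares2 %*% v)
  imp <- imp / sum(imp)
  structure(stats::setNames(imp, model$feature_names),
            class = "rel_importance")
}

#' Relative importance of every input of a PLANN
#'
#' Dispatches to [garson_1h()] or [garson_2h()] on the architecture.
#' @param model A `"plann"`.
#' @return A `"rel_importance"` vector.
#' @export
garson_importance <- function(model) {
  if (model$config$n_hidden_layers == 1L) garson_1h(model) else garson_2h(model)
}

#' @export
print.rel_importance <- function(x, ...) {
  cat("<rel_importance>", length(x), "features (top 5):\n")
  top <- rank_importance(x, min(5L, length(x)))
  print(round(top, 4))
  invisible(x)
}

#' Aggregate feature importances to parent variables
#'
#' Dummy-coded factor levels are summed into their parent variable via the
#' `group_map`; the k time-interval indicators are summed into a single
#' entry named `time_label`, reported alongside the covariates. Totals are
#' preserved (the result still sums to 1).
#'
#' @param ri A `"rel_importance"` vector over input features.
#' @param group_map Named character vector mapping each covariate feature
#'   to its parent variable (as stored on a [survival_data()] object).
#'   Interval-indicator features (`interval_1`, ...) need not be mapped.
#' @param time_label Name for the pooled time-interval entry.
#' @return A `"rel_importance"` vector over parent variables, with
#'   attribute `"time_table"` holding the per-interval importances.
#' @export
aggregate_importance <- function(ri, group_map, time_label = "time") {
  stopifnot(inherits(ri, "rel_importance"))
  feats <- names(ri)
  is_time <- grepl("^interval_[0-9]+$", feats) & !feats %in% names(group_map)
  parent <- character(length(feats))
  parent[is_time] <- time_label
  mapped <- match(feats[!is_time], names(group_map))
  if (anyNA(mapped))
    stop("unmapped feature(s): ",
         paste(feats[!is_time][is.na(mapped)], collapse = ", "))
  parent[!is_time] <- unname(group_map[mapped])
  agg <- tapply(as.numeric(ri), parent, sum)
  out <- structure(stats::setNames(as.numeric(agg), names(agg)),
                   class = "rel_importance")
  attr(out, "time_table") <- stats::setNames(as.numeric(ri[is_time]),
                                             feats[is_time])
  out
}

#' Rank importances in decreasing order
#'
#' Sorts descending by importance; exact ties are broken alphabetically by
#' feature name for reproducible reports.
#'
#' @param ri A `"rel_importance"` vector.
#' @param top_n Number of leading entries to keep; values beyond the number
#'   of features return the full ranking.
#' @return Named numeric vector, sorted.
#' @export
rank_importance <- function(ri, top_n = length(ri)) {
  if (top_n <= 0) stop("top_n must be positive")
  ord <- order(-as.numeric(ri), names(ri))
  out <- as.numeric(ri)[ord]
  names(out) <- names(ri)[ord]
  utils::head(out, top_n)
}

#' Write an importance report to delimited text
#'
#' Writes a two-column (term, importance) table of the ranked variable
#' importances, and, when present, a companion `<path>_time.csv` with the
#' per-interval contributions.
#'
#' @param ri A `"rel_importance"` vector (typically aggregated).
#' @param path Output CSV path.
#' @param sep Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_importance_report <- function(ri, path, sep = ",") {
  ranked <- rank_importance(ri)
  utils::write.table(data.frame(term = names(ranked), importance = ranked),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  tt <- attr(ri, "time_table")
  if (!is.null(tt) && length(tt)) {
    tpath <- sub("(\\.[^.]+)?$", "_time\\1", path)
    if (identical(tpath, path)) tpath <- paste0(path, "_time")
    utils::write.table(data.frame(interval = names(tt), importance = tt),
                       tpath, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
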