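#' Balanced subsets for random-forest training
#'
#' Random forests receive no balancing bootstrap, so class balance must be
#' imposed on the data: each subset keeps the minority class entire and
#' pairs it with an equally sized random draw (without replacement) from
#' the majority class. Five subsets are used by default and their fitted
#' forests averaged.
#'
#' @param table occurrence table with a `presence` column.
#' @param n_subsets number of balanced subsets.
#' @param seed integer seed.
#' @return list of integer row-index vectors, each of length
#'   `2 * min(class counts)`.
#' @export
make_balanced_subsets <- function(table, n_subsets = 5L, seed = 1L) {
  ip <- which(table$presence == 1L)
  ia <- which(table$presence == 0L)
  if (length(ip) == 0L || length(ia) == 0L)
    stop("both classes must be non-empty")
  minority <- if (length(ip) <= length(ia)) ip else ia
  majority <- if (length(ip) <= length(ia)) ia else ip
  lapply(seq_len(n_subsets), function(i) {
    set.seed(child_seed(seed, i))
    c(minority, sample(majority, length(minority)))
  })
}

#' Fit one probability forest on a balanced subset
#'
#' Classification trees are grown on bootstraps of the subset, each split
#' chosen by Gini impurity among `mtry` randomly drawn candidate features;
#' leaves hold presence fractions so tree (and forest) output is a
#' continuous suitability in `[0, 1]`. Importance is the total decrease in
#' Gini impurity attributed to each feature's splits.
#'
#' @param subset a balanced occurrence table.
#' @param features feature column names.
#' @param n_trees trees per forest.
#' @param mtry candidate features per split (default `floor(sqrt(p))`).
#' @param seed integer seed.
#' @param min_node minimal node size (1 grows to purity).
#' @return object of class `suit_forest` wrapping the fitted forest.
#' @export
fit_forest <- function(subset, features, n_trees = 500L, mtry = NULL,
                       seed = 1L, min_node = 1L) {
  if (nrow(subset) < 2L) stop("degenerate subset: fewer than 2 records")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  rf <- ranger::ranger(
    x = as.data.frame(subset[, features, drop = FALSE]),
    y = factor(subset$presence, levels = c(0L, 1L)),
    num.trees = n_trees, mtry = mtry, min.node.size = min_node,
    probability = TRUE, importance = "impurity",
    seed = as.integer(seed), num.threads = 1L)
  structure(list(rf = rf, features = features,
                 gini = rf$variable.importance),
            class = "suit_forest")
}

#' Suitability from one fitted forest
#'
#' @param model a `suit_forest`.
#' @param x feature matrix or data.frame.
#' @return numeric vector: mean presence fraction over the trees.
#' @export
predict_forest <- function(model, x) {
  missing <- setdiff(model$features, colnames(x))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(as.matrix(x)[, model$features, drop = FALSE])
  stats::predict(model$rf, data = df, num.threads = 1L)$predictions[, "1"]
}

# 5-subset forest ensemble behind the common suit_ensemble surface
fit_forest_ensemble <- function(table, features, n_subsets = 5L, seed = 1L,
                                control = list()) {
  ctl <- utils::modifyList(list(n_trees = 500L, mtry = NULL, min_node = 1L),
                           control)
  subsets <- make_balanced_subsets(table, n_subsets, seed)
  submodels <- vector("list", n_subsets)
  seeds <- integer(n_subsets)
  failures <- character(0)
  for (i in seq_len(n_subsets)) {
    seeds[i] <- child_seed(seed, i)
    fit <- tryCatch(
      fit_forest(table[subsets[[i]], , drop = FALSE], features,
                 n_trees = ctl$n_trees, mtry = ctl$mtry,
                 seed = seeds[i], min_node = ctl$min_node),
      error = function(e) structure(conditionMessage(e),
                                    class = "suit_fit_failure"))
    if (inherits(fit, "suit_fit_failure")) {
      failures <- c(failures, sprintf("subset %d: %s", i, unclass(fit)))
      submodels[i] <- list(NULL)
    } else submodels[[i]] <- fit
  }
  if (length(failures) > 0.1 * n_subsets && length(failures) > 0)
    stop("forest ensemble failed: ", paste(failures, collapse = "; "))
  structure(list(submodels = submodels, seeds = seeds,
                 m = length(subsets[[1]]) %/% 2L,
                 n_submodels = as.integer(n_subsets),
                 failures = failures, master_seed = as.integer(seed),
                 subset_indices = subsets),
            class = "suit_ensemble")
}

#' Average suitability over a list of fitted forests
#'
#' The forest family's final prediction: the plain mean of the (typically
#' five) balanced-subset forests, with no further bootstrapping.
#'
#' @param models list of `suit_forest` objects.
#' @param x feature matrix or data.frame.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict_forest_ensemble <- function(models, x) {
  preds <- lapply(models, predict_forest, x = x)
  Reduce(`+`, preds) / length(preds)
}

#' @rdname importance
#' @export
importance.suit_rf <- function(object, ...) {
  aggregate_importance(lapply(object$submodels, function(s)
    if (is.null(s)) NULL else s$gini), type = "gini")
}
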