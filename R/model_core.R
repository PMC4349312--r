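# Deterministic child-seed stream: one substream per submodel index, all
# below 2^31 so they are valid R integer seeds.
child_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483629 * 69069 + i * 104729) %%
               2147483629)
}

#' Draw a balanced presence/absence sample
#'
#' Samples exactly `m` presence records and `m` absence records (seeded),
#' the balancing that prevents the more prevalent class from biasing the
#' fitted suitability.
#'
#' @param table an occurrence table with a `presence` column.
#' @param m records per class.
#' @param with_replacement sample with replacement (the bootstrap case);
#'   without replacement `m` must not exceed the smaller class.
#' @param seed integer seed.
#' @return list with integer row indices `presence`, `absence`, plus `m`
#'   and `with_replacement`.
#' @export
draw_balanced_sample <- function(table, m, with_replacement = TRUE,
                                 seed = 1L) {
  ip <- which(table$presence == 1L)
  ia <- which(table$presence == 0L)
  if (length(ip) == 0L || length(ia) == 0L)
    stop("both classes must be present")
  if (!with_replacement && m > min(length(ip), length(ia)))
    stop("m = ", m, " exceeds the smaller class (",
         min(length(ip), length(ia)), ") without replacement")
  set.seed(as.integer(seed))
  list(presence = sample(ip, m, replace = with_replacement),
       absence = sample(ia, m, replace = with_replacement),
       m = as.integer(m), with_replacement = with_replacement)
}

#' Fit a balanced-bootstrap ensemble of submodels
#'
#' Generic ensembling engine: submodel `i` is trained on a balanced sample
#' drawn with a seed derived from `(seed, i)`, and the ensemble prediction
#' is the arithmetic mean of the submodel suitabilities. Individual fit
#' failures are recorded; the ensemble fails if more than
#' `max_fail_frac` of submodels fail.
#'
#' @param fit_one function `(sample_table, seed, ...)` returning a fitted
#'   submodel with a `predict` method yielding suitabilities in `[0, 1]`.
#' @param table occurrence table.
#' @param n_submodels number of bootstrap submodels.
#' @param m balanced sample size per class.
#' @param seed master seed.
#' @param with_replacement passed to [draw_balanced_sample()].
#' @param max_fail_frac tolerated fraction of submodel failures.
#' @param ... passed to `fit_one`.
#' @return object of class `suit_ensemble`.
#' @export
fit_ensemble <- function(fit_one, table, n_submodels, m, seed = 1L,
                         with_replacement = TRUE, max_fail_frac = 0.1, ...) {
  stopifnot(n_submodels >= 1)
  submodels <- vector("list", n_submodels)
  seeds <- integer(n_submodels)
  failures <- character(0)
  for (i in seq_len(n_submodels)) {
    s <- child_seed(seed, i)
    seeds[i] <- s
    bs <- draw_balanced_sample(table, m, with_replacement, seed = s)
    sub <- table[c(bs$presence, bs$absence), , drop = FALSE]
    fit <- tryCatch(fit_one(sub, seed = s, ...),
                    error = function(e) structure(conditionMessage(e),
                                                  class = "suit_fit_failure"))
    if (inherits(fit, "suit_fit_failure")) {
      failures <- c(failures, sprintf("submodel %d: %s", i, unclass(fit)))
      submodels[i] <- list(NULL)
    } else submodels[[i]] <- fit
  }
  if (length(failures) > max_fail_frac * n_submodels)
    stop("ensemble fit failed: ", length(failures), "/", n_submodels,
         " submodels failed\n", paste(utils::head(failures, 5),
                                      collapse = "\n"))
  structure(list(submodels = submodels, seeds = seeds, m = as.integer(m),
                 n_submodels = as.integer(n_submodels), failures = failures,
                 master_seed = as.integer(seed)),
            class = "suit_ensemble")
}

#' Fit a suitability ensemble to occurrence data
#'
#' The package's main fitting function. Three model families are
#' available, each producing an environmental suitability score in
#' `[0, 1]` as the average of balanced submodels:
#'
#' * `"nlda"` — non-linear discriminant analysis: presences and absences
#'   are k-means-clustered on generic seasonality variables and a Gaussian
#'   discriminant over the clusters yields the posterior probability of the
#'   presence super-class; 100 balanced bootstrap replicates are averaged.
#' * `"rf"` — random forest: five balanced subsets of the data (minority
#'   class kept whole, majority downsampled) each train a probability
#'   forest; the five forests are averaged and are not additionally
#'   bootstrapped.
#' * `"glm"` — logistic regression: 100 balanced bootstrap replicates of a
#'   binomial GLM, averaged; variable importance is by mean rank of |z|.
#'
#' @param formula model formula, e.g. `presence ~ .` (the dot expands to
#'   every feature column of `data`) or an explicit feature list.
#' @param data an `occurrence_table` from [extract_features()] (any
#'   data.frame with a 0/1 response and numeric features works).
#' @param method `"nlda"`, `"rf"` or `"glm"`.
#' @param n_submodels number of submodels; defaults: 100 bootstraps for
#'   nlda/glm, 5 balanced subsets for rf.
#' @param m balanced sample size per class for nlda/glm; default
#'   `min(class counts)` capped at 150.
#' @param seed master seed; submodel seeds are derived from it.
#' @param control named list of family-specific settings; see
#'   [fit_nlda()], [fit_forest()], [fit_logistic()]. For `"glm"`,
#'   `control$cor_filter` (default `TRUE`) drops one of each feature pair
#'   with |correlation| > 0.95 (keep-first) before fitting.
#' @return an object of class `c("suit_<method>", "suit_ensemble")` with
#'   `print`, `summary`, `predict`, `plot` and [importance()] methods.
#' @export
suitability_ensemble <- function(formula = presence ~ ., data,
                                 method = c("nlda", "rf", "glm"),
                                 n_submodels = NULL, m = NULL, seed = 1L,
                                 control = list()) {
  method <- match.arg(method)
  pf <- parse_suit_formula(formula, data)
  response <- pf$response; feats <- pf$features
  y <- data[[response]]
  if (!all(y %in% c(0L, 1L))) stop("response must be 0/1")
  tab <- data
  tab$presence <- as.integer(y)
  n_pres <- sum(tab$presence == 1L); n_abs <- sum(tab$presence == 0L)
  if (is.null(m)) m <- min(n_pres, n_abs, 150L)

  if (method == "rf") {
    ens <- fit_forest_ensemble(tab, feats,
                               n_subsets = n_submodels %||% 5L,
                               seed = seed, control = control)
  } else if (method == "nlda") {
    n_submodels <- n_submodels %||% 100L
    ctl <- utils::modifyList(list(k_presence = 4L, k_absence = 4L,
                                  generic = NULL, lambda_rel = 1e-6,
                                  pooled = FALSE), control)
    generic <- ctl$generic
    if (is.null(generic))
      generic <- tryCatch(select_generic_variables(feats),
                          error = function(e) feats)
    ens <- fit_ensemble(fit_nlda, tab, n_submodels, m, seed = seed,
                        features = feats, generic = generic,
                        k_presence = ctl$k_presence,
                        k_absence = ctl$k_absence,
                        lambda_rel = ctl$lambda_rel, pooled = ctl$pooled)
  } else {
    n_submodels <- n_submodels %||% 100L
    ctl <- utils::modifyList(list(cor_filter = TRUE, cor_cut = 0.95),
                             control)
    if (isTRUE(ctl$cor_filter) && length(feats) > 1L) {
      feats_used <- cor_screen(tab[, feats, drop = FALSE], ctl$cor_cut)
    } else feats_used <- feats
    ens <- fit_ensemble(fit_logistic_sub, tab, n_submodels, m, seed = seed,
                        features = feats_used)
    ens$screened_out <- setdiff(feats, feats_used)
    feats <- feats_used
  }
  ens$method <- method
  ens$response <- response
  ens$features <- feats
  ens$class_counts <- c(presence = n_pres, absence = n_abs)
  # training-set ensemble predictions, kept for evaluation and residuals
  ens$fitted <- predict_ensemble_matrix(ens,
                                        as.matrix(tab[, feats, drop = FALSE]))
  ens$training_presence <- tab$presence
  ens$training_xy <- if (all(c("x", "y") %in% names(tab)))
    tab[, c("x", "y")] else NULL
  class(ens) <- c(paste0("suit_", method), "suit_ensemble")
  ens
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_suit_formula <- function(formula, data) {
  response <- as.character(formula[[2]])
  rhs <- attr(stats::terms(formula,
                           data = data[1, , drop = FALSE]), "term.labels")
  meta <- c("point_id", "x", "y", "presence", "origin", "cell", "stratum",
            "week", "trap_id", "abundance")
  candidates <- feature_names(data) %||%
    setdiff(names(data)[vapply(data, is.numeric, TRUE)], meta)
  if (identical(deparse(formula[[3]]), ".")) {
    feats <- candidates
  } else {
    missing <- setdiff(rhs, names(data))
    if (length(missing)) stop("features not in data: ",
                              paste(missing, collapse = ", "))
    feats <- rhs
  }
  if (length(feats) == 0L) stop("no feature columns found")
  list(response = response, features = setdiff(feats, response))
}

# keep-first greedy screen: drop later feature of any pair with |r| > cut
cor_screen <- function(x, cut = 0.95) {
  keep <- names(x)
  cm <- suppressWarnings(abs(stats::cor(as.matrix(x))))
  cm[is.na(cm)] <- 0
  drop <- logical(ncol(cm))
  for (j in seq_len(ncol(cm))[-1])
    if (any(cm[seq_len(j - 1), j] > cut & !drop[seq_len(j - 1)]))
      drop[j] <- TRUE
  keep[!drop]
}

# mean over non-failed submodels of per-submodel suitability on a matrix
predict_ensemble_matrix <- function(ensemble, x) {
  preds <- lapply(ensemble$submodels, function(s)
    if (is.null(s)) NULL else predict_submodel(s, x))
  preds <- preds[!vapply(preds, is.null, TRUE)]
  if (length(preds) == 0L) stop("ensemble has no fitted submodels")
  Reduce(`+`, preds) / length(preds)
}

# dispatch on the stored submodel type
predict_submodel <- function(submodel, x) {
  if (inherits(submodel, "nlda_model")) predict_nlda(submodel, x)
  else if (inherits(submodel, "logistic_fit")) predict_logistic(submodel, x)
  else if (inherits(submodel, "suit_forest")) predict_forest(submodel, x)
  else stop("unknown submodel type: ", paste(class(submodel), collapse = "/"))
}

#' Predict suitability from a fitted ensemble
#'
#' @param object a [suitability_ensemble()] fit.
#' @param newdata a data.frame/matrix with the fit-time feature columns, or
#'   a `feature_stack` (then a suitability `env_grid` is returned via
#'   [predict_grid()]).
#' @param ... unused.
#' @return numeric vector of suitabilities in `[0, 1]`, or an `env_grid`.
#' @export
predict.suit_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_stack"))
    return(predict_grid(object, newdata))
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  predict_ensemble_matrix(object, x)
}

#' Predict a suitability map over a feature stack
#'
#' @param ensemble a fitted `suit_ensemble`.
#' @param features a `feature_stack` containing every fit-time feature.
#' @return an `env_grid` of suitabilities in `[0, 1]`; nodata propagates.
#' @export
predict_grid <- function(ensemble, features) {
  missing <- setdiff(ensemble$features, names(features$layers))
  if (length(missing))
    stop("feature raster(s) missing from stack: ",
         paste(missing, collapse = ", "))
  nr <- nrow(features$layers[[1]]); nc <- ncol(features$layers[[1]])
  x <- vapply(ensemble$features, function(nm) as.vector(features$layers[[nm]]),
              numeric(nr * nc))
  ok <- rowSums(!is.finite(x)) == 0L
  out <- rep(NA_real_, nr * nc)
  if (any(ok))
    out[ok] <- predict_ensemble_matrix(ensemble, x[ok, , drop = FALSE])
  env_grid(matrix(out, nr, nc), origin = features$origin,
           cell_size = features$cell_size)
}

#' @export
print.suit_ensemble <- function(x, ...) {
  cat(sprintf("<suitability ensemble: %s> %d submodel(s), m = %s\n",
              x$method %||% "custom", x$n_submodels,
              x$m %||% "(balanced subsets)"))
  cat(sprintf("  training data: %d presences, %d absences; %d features\n",
              x$class_counts["presence"], x$class_counts["absence"],
              length(x$features)))
  if (length(x$failures))
    cat("  failed submodels:", length(x$failures), "\n")
  invisible(x)
}

#' @export
summary.suit_ensemble <- function(object, ...) {
  print(object)
  f <- object$fitted
  cat(sprintf("  fitted suitability: min %.3f, mean %.3f, max %.3f\n",
              min(f), mean(f), max(f)))
  imp <- importance(object)
  cat("  top variables:\n")
  print(utils::head(as.data.frame(imp), 5))
  invisible(object)
}

#' @export
residuals.suit_ensemble <- function(object,
                                    type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  y <- object$training_presence
  p <- pmin(pmax(object$fitted, 1e-12), 1 - 1e-12)
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Plot a suitability map
#'
#' Renders the ensemble's predicted suitability over a feature stack with
#' the conventional blue (low) to red (high) gradient.
#'
#' @param x a fitted `suit_ensemble`.
#' @param features a `feature_stack`; alternatively pass a precomputed
#'   suitability `env_grid` as `grid`.
#' @param grid optional precomputed suitability grid.
#' @param ... passed to [graphics::image()].
#' @export
plot.suit_ensemble <- function(x, features = NULL, grid = NULL, ...) {
  if (is.null(grid)) {
    if (is.null(features)) stop("supply `features` or `grid`")
    grid <- predict_grid(x, features)
  }
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(64)
  graphics::image(t(grid$values), col = pal, zlim = c(0, 1), axes = FALSE,
                  main = sprintf("suitability (%s)", x$method), ...)
  invisible(grid)
}

#' Variable importance of a fitted ensemble
#'
#' For NLDA and GLM ensembles, variables are ranked within each submodel
#' (rank 1 = most important) and the ranks averaged over submodels; for
#' random forests, importance is the mean decrease in Gini impurity
#' accumulated by each variable's splits, averaged over the five forests.
#'
#' @param object a fitted model.
#' @param ... method-specific arguments.
#' @return an `importance_table` data.frame, sorted most-important first.
#' @export
importance <- function(object, ...) UseMethod("importance")

#' Aggregate per-submodel importance contributions
#'
#' @param contributions list of named numeric vectors: per-submodel ranks
#'   (`type = "rank"`, rank 1 = most important) or per-forest Gini
#'   decreases (`type = "gini"`).
#' @param type aggregation type.
#' @return data.frame (class `importance_table`) with columns `variable`,
#'   `score` and `n_submodels`; sorted ascending by mean rank or descending
#'   by mean Gini decrease, ties broken alphabetically.
#' @export
aggregate_importance <- function(contributions, type = c("rank", "gini")) {
  type <- match.arg(type)
  contributions <- contributions[!vapply(contributions, is.null, TRUE)]
  if (length(contributions) == 0L) stop("no submodel contributions")
  vars <- sort(unique(unlist(lapply(contributions, names))))
  counts <- score <- stats::setNames(numeric(length(vars)), vars)
  for (ct in contributions) {
    score[names(ct)] <- score[names(ct)] + ct
    counts[names(ct)] <- counts[names(ct)] + 1
  }
  score <- score / pmax(counts, 1)
  ord <- if (type == "rank") order(score, vars) else order(-score, vars)
  out <- data.frame(variable = vars[ord], score = unname(score[ord]),
                    n_submodels = as.integer(unname(counts[ord])))
  attr(out, "type") <- type
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Top rows of an importance table
#'
#' @param imp an `importance_table`.
#' @param n number of rows (default 10, the layout used for reporting).
#' @export
top_importance <- function(imp, n = 10L) utils::head(imp, n)
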