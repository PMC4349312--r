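#' Confusion counts at a suitability threshold
#'
#' A point is predicted present iff its suitability is at or above the
#' threshold.
#'
#' @param predictions suitabilities in `[0, 1]`.
#' @param labels 0/1 observed presence.
#' @param threshold decision threshold (default 0.5).
#' @return named integer vector `(TP, FP, TN, FN)` partitioning `n`.
#' @export
confusion_counts <- function(predictions, labels, threshold = 0.5) {
  stopifnot(length(predictions) == length(labels))
  if (length(predictions) == 0L) stop("empty input")
  pos <- predictions >= threshold
  c(TP = sum(pos & labels == 1L), FP = sum(pos & labels == 0L),
    TN = sum(!pos & labels == 0L), FN = sum(!pos & labels == 1L))
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity is the proportion of known positive sites correctly
#' identified, `TP/(TP+FN)`; specificity the proportion of known negative
#' sites correctly identified, `TN/(TN+FP)`. A metric whose class is
#' absent is `NA` (flagged with a warning).
#'
#' @param counts output of [confusion_counts()].
#' @return named numeric `(sensitivity, specificity)`.
#' @export
sens_spec <- function(counts) {
  np <- counts[["TP"]] + counts[["FN"]]
  nn <- counts[["TN"]] + counts[["FP"]]
  if (np == 0L || nn == 0L)
    warning("a class is absent; its metric is undefined")
  c(sensitivity = if (np > 0) counts[["TP"]] / np else NA_real_,
    specificity = if (nn > 0) counts[["TN"]] / nn else NA_real_)
}

#' Stratified bootstrap confidence interval for sensitivity/specificity
#'
#' Each replicate resamples the presence and the absence stratum
#' separately, with replacement, at their original sizes (so both classes
#' stay represented), and the interval is the percentile interval of the
#' replicate metrics — 2000 replicates at the 95% level by default.
#'
#' @param predictions suitabilities.
#' @param labels 0/1 presence.
#' @param metric `"sensitivity"` or `"specificity"`.
#' @param n_reps bootstrap replicates.
#' @param level confidence level.
#' @param threshold decision threshold.
#' @param seed integer seed.
#' @return named numeric `(low, high)`.
#' @export
bootstrap_ci <- function(predictions, labels,
                         metric = c("sensitivity", "specificity"),
                         n_reps = 2000L, level = 0.95, threshold = 0.5,
                         seed = 1L) {
  metric <- match.arg(metric)
  cls <- if (metric == "sensitivity") 1L else 0L
  correct_raw <- if (metric == "sensitivity")
    predictions >= threshold else predictions < threshold
  idx <- which(labels == cls)
  if (length(idx) == 0L || length(idx) == length(labels))
    stop("both classes must be present")
  correct <- correct_raw[idx]
  n <- length(correct)
  set.seed(as.integer(seed))
  draws <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n)
  stat <- colMeans(matrix(correct[draws], nrow = n))
  alpha <- (1 - level) / 2
  q <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Accuracy report for one or more fitted ensembles
#'
#' Sensitivity and specificity of each ensemble on its own training
#' occurrence table (evaluation is on training data by design: the aim is
#' a suitability score describing the observed pattern, so internal
#' validation is the appropriate check, with the caveat that accuracy is
#' optimistic), with stratified bootstrap confidence intervals.
#'
#' @param ensembles a fitted `suit_ensemble` or a named list of them (one
#'   per model); a named list of named lists gives a species x model
#'   report.
#' @param threshold decision threshold, reported in the output.
#' @param n_reps bootstrap replicates for the CIs.
#' @param level confidence level.
#' @param seed integer seed.
#' @return data.frame of class `accuracy_report` with one row per
#'   (species, model, metric): point estimate and CI bounds.
#' @export
accuracy_report <- function(ensembles, threshold = 0.5, n_reps = 2000L,
                            level = 0.95, seed = 1L) {
  if (inherits(ensembles, "suit_ensemble"))
    ensembles <- list(species = stats::setNames(list(ensembles),
                                                ensembles$method))
  if (inherits(ensembles[[1]], "suit_ensemble"))
    ensembles <- list(species = ensembles)
  rows <- list()
  for (sp in names(ensembles)) for (mod in names(ensembles[[sp]])) {
    e <- ensembles[[sp]][[mod]]
    ss <- sens_spec(confusion_counts(e$fitted, e$training_presence,
                                     threshold))
    for (metric in c("sensitivity", "specificity")) {
      ci <- bootstrap_ci(e$fitted, e$training_presence, metric,
                         n_reps = n_reps, level = level,
                         threshold = threshold,
                         seed = child_seed(seed, length(rows) + 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, model = mod, metric = metric,
        estimate = unname(ss[[metric]]), ci_low = unname(ci[["low"]]),
        ci_high = unname(ci[["high"]]), threshold = threshold,
        n_replicates = n_reps)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Accuracy (training data, stratified percentile bootstrap CIs)\n")
  df <- as.data.frame(x)
  df$value <- sprintf("%.3f (%.3f-%.3f)", df$estimate, df$ci_low,
                      df$ci_high)
  print(df[, c("species", "model", "metric", "value")], row.names = FALSE)
  invisible(x)
}
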