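#' Fit one logistic-regression submodel
#'
#' Maximum-likelihood binomial GLM by iteratively reweighted least squares
#' (relative tolerance 1e-8, at most 100 iterations) on z-scored features.
#' If complete or quasi-complete separation is detected (fitted
#' probabilities numerically 0 or 1, or non-convergence), the fit falls
#' back to a lightly ridge-penalised logistic regression
#' (`glmnet`, alpha = 0, lambda = 1e-4) and is flagged: its predictions
#' are used but it carries no Wald z-statistics.
#'
#' @param sample a balanced sample with `presence` and feature columns.
#' @param features feature column names (defaults to the table's feature
#'   attribute).
#' @param standardize z-score features with sample statistics (constant
#'   columns get scale 1 and coefficient 0).
#' @return object of class `logistic_fit` with standardized-scale
#'   coefficients (`coef_std`), original-scale `coefficients`, standard
#'   errors, z-statistics, and `converged` / `ridge` flags.
#' @export
fit_logistic <- function(sample, features = NULL, standardize = TRUE) {
  if (is.null(features)) features <- feature_names(sample)
  y <- sample$presence
  if (length(unique(y)) < 2L) stop("sample must contain both classes")
  x <- as.matrix(sample[, features, drop = FALSE])
  if (nrow(x) <= ncol(x) + 1L)
    stop("n (", nrow(x), ") must exceed number of features (", ncol(x), ")")
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  names(center) <- names(scl) <- features
  z <- sweep(sweep(x, 2L, center), 2L, scl, "/")

  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, z), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L)))
  # complete/quasi-complete separation shows up as diverging standardized
  # coefficients (|log-odds per SD| beyond any plausible effect) or as
  # IRLS failing to converge
  separated <- !fit$converged ||
    any(!is.finite(fit$coefficients)) ||
    max(abs(fit$coefficients[-1L]), 0, na.rm = TRUE) > 15

  ridge <- FALSE
  if (separated) {
    ridge <- TRUE
    rg <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
    beta <- as.numeric(rg$beta[, 1L])
    b0 <- rg$a0[[1L]]
    se <- zstat <- rep(NA_real_, length(beta))
    iter <- NA_integer_
    converged <- TRUE
  } else {
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    b0 <- cf[1L]; beta <- cf[-1L]
    # Wald SEs from the IRLS weighted cross-product
    w <- fit$weights
    xw <- cbind(1, z) * sqrt(w)
    cov <- tryCatch(solve(crossprod(xw)), error = function(e) NULL)
    if (is.null(cov)) {
      se <- zstat <- rep(NA_real_, length(beta))
    } else {
      se_all <- sqrt(diag(cov))
      se <- se_all[-1L]
      zstat <- ifelse(se > 0, beta / se, NA_real_)
    }
    iter <- fit$iter
    converged <- fit$converged
  }
  names(beta) <- features
  coef_orig <- beta / scl
  intercept_orig <- b0 - sum(beta * center / scl)
  structure(list(intercept = unname(b0), coef_std = beta,
                 coefficients = c(`(Intercept)` = unname(intercept_orig),
                                  coef_orig),
                 se_std = stats::setNames(se, features),
                 se = stats::setNames(se / scl, features),
                 z = stats::setNames(zstat, features),
                 converged = converged, ridge = ridge, iterations = iter,
                 center = center, scale = scl, features = features),
            class = "logistic_fit")
}

# fit_ensemble adapter (seed is consumed by the balanced sampling upstream)
fit_logistic_sub <- function(sample, seed = NULL, features = NULL) {
  fit_logistic(sample, features = features)
}

#' Predicted presence probability from one logistic submodel
#'
#' @param fit a `logistic_fit`.
#' @param x feature matrix or data.frame.
#' @return probabilities in `(0, 1)`.
#' @export
predict_logistic <- function(fit, x) {
  x <- as.matrix(x)[, fit$features, drop = FALSE]
  z <- sweep(sweep(x, 2L, fit$center), 2L, fit$scale, "/")
  stats::plogis(fit$intercept + drop(z %*% fit$coef_std))
}

#' Average |z|-based variable ranks over bootstrap logistic fits
#'
#' Within each converged maximum-likelihood fit, variables are ranked by
#' descending absolute Wald z-statistic (rank 1 = largest |z|); ranks are
#' averaged across fits. Ridge-fallback fits have no z-statistics and are
#' excluded from the ranking (their count is reported in the
#' `n_excluded` attribute).
#'
#' @param fits list of `logistic_fit` objects.
#' @return an `importance_table` (see [aggregate_importance()]).
#' @export
rank_variables_logistic <- function(fits) {
  fits <- fits[!vapply(fits, is.null, TRUE)]
  usable <- vapply(fits, function(f)
    isTRUE(f$converged) && !isTRUE(f$ridge) && any(is.finite(f$z)), TRUE)
  if (!any(usable)) stop("no converged fits with z-statistics")
  contribs <- lapply(fits[usable], function(f) {
    z <- abs(f$z)
    z[!is.finite(z)] <- -Inf
    r <- rank(-z, ties.method = "first")
    names(r) <- f$features
    r
  })
  out <- aggregate_importance(contribs, type = "rank")
  attr(out, "n_excluded") <- sum(!usable)
  out
}

#' @rdname importance
#' @export
importance.suit_glm <- function(object, ...) {
  tryCatch(rank_variables_logistic(object$submodels),
           error = function(e) {
             # every submodel hit the ridge fallback: no Wald statistics
             # exist, so rank by |standardized coefficient| instead
             warning("no maximum-likelihood fits with z-statistics; ",
                     "ranking by |standardized coefficient|")
             fits <- object$submodels[!vapply(object$submodels, is.null,
                                              TRUE)]
             contribs <- lapply(fits, function(f) {
               r <- rank(-abs(f$coef_std), ties.method = "first")
               names(r) <- f$features
               r
             })
             aggregate_importance(contribs, type = "rank")
           })
}

#' @export
coef.suit_glm <- function(object, ...) {
  fits <- object$submodels[!vapply(object$submodels, is.null, TRUE)]
  cf <- vapply(fits, function(f) f$coefficients,
               numeric(length(fits[[1]]$coefficients)))
  rowMeans(cf)
}

#' Moran's I correlogram of residuals
#'
#' Spatial autocorrelation of model residuals by distance class. For bin
#' `b` with binary neighbour weights `w_ij = 1` iff the pair's distance
#' falls in the bin: `I_b = (n / S0) * sum_ij(w_ij z_i z_j) / sum_i(z_i^2)`
#' with `z` the centred residuals and `S0` the total weight. Bins with no
#' pairs, or zero residual variance, give `NA` (flagged in the output),
#' not an error. Under no autocorrelation the expected value is
#' `-1/(n-1)`.
#'
#' @param residuals numeric residuals at the points.
#' @param coords two-column matrix/data.frame of point coordinates.
#' @param breaks distance bin edges; default 10 equal-width bins from 0 to
#'   half the maximum pairwise distance (Moran's I is erratic at extreme
#'   distances where few pairs remain).
#' @param n_bins number of default bins.
#' @return data.frame with `bin_low, bin_high, n_pairs, moran_i`.
#' @export
moran_correlogram <- function(residuals, coords, breaks = NULL,
                              n_bins = 10L) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  stopifnot(nrow(coords) == n, n >= 2L)
  dmat <- as.matrix(stats::dist(coords))
  if (is.null(breaks))
    breaks <- seq(0, max(dmat) / 2, length.out = n_bins + 1L)
  z <- residuals - mean(residuals)
  denom <- sum(z^2)
  out <- data.frame(bin_low = breaks[-length(breaks)],
                    bin_high = breaks[-1L], n_pairs = NA_integer_,
                    moran_i = NA_real_)
  zz <- tcrossprod(z)
  for (b in seq_len(nrow(out))) {
    w <- dmat > out$bin_low[b] & dmat <= out$bin_high[b]
    diag(w) <- FALSE
    s0 <- sum(w)
    out$n_pairs[b] <- s0 / 2L
    if (s0 > 0 && denom > 0)
      out$moran_i[b] <- (n / s0) * sum(zz[w]) / denom
  }
  out
}

#' Moran's I for one distance band
#'
#' @inheritParams moran_correlogram
#' @param low,high band limits; pairs with `low < d <= high` are
#'   neighbours.
#' @export
moran_i <- function(residuals, coords, low, high) {
  moran_correlogram(residuals, coords, breaks = c(low, high))$moran_i[1L]
}
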