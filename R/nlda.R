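#' Select the generic seasonality variables used for NLDA clustering
#'
#' The clustering step of the discriminant model uses a fixed "generic"
#' variable list rather than species-specific selections: elevation (DEM)
#' plus the mean, amplitudes, maximum, minimum, total variance and phases
#' (components A0, A1, A2, A3, MN, MX, VR, P1, P2, P3) of the middle
#' infra-red, day and night land surface temperature, and NDVI signals —
#' 41 variables in total on the standard 74-feature stack.
#'
#' @param features character vector of available feature names (the
#'   `<VAR>_<COMPONENT>` naming of [fourier_stack()]).
#' @return character vector of generic variable names, all present in
#'   `features`.
#' @export
select_generic_variables <- function(features) {
  comps <- c("A0", "A1", "A2", "A3", "MN", "MX", "VR", "P1", "P2", "P3")
  vars <- c("MIR", "DLST", "NLST", "NDVI")
  wanted <- c("DEM", as.vector(outer(vars, comps, paste, sep = "_")))
  missing <- setdiff(wanted, features)
  if (length(missing))
    stop("generic variable(s) absent from feature set: ",
         paste(missing, collapse = ", "))
  wanted
}

#' Fit one non-linear discriminant submodel
#'
#' Presence and absence records are clustered separately with k-means
#' (Euclidean distance on z-scored generic variables, 10 random restarts),
#' and each cluster becomes a Gaussian discriminant class: mean, covariance
#' regularised by `lambda * I` with `lambda = lambda_rel * trace/dim`
#' (escalated tenfold, up to `trace/dim`, only if the Cholesky
#' factorisation fails), and prior proportional to cluster size. An empty
#' or infeasible clustering is retried with `k - 1` for that class. By
#' default the discriminant densities live in the same generic-variable
#' space as the clustering.
#'
#' @param sample a balanced sample table with `presence` and feature
#'   columns.
#' @param seed integer seed for the k-means restarts.
#' @param features full feature set of the ensemble (used only to validate
#'   columns).
#' @param generic variables used for clustering and (by default) the
#'   densities; see [select_generic_variables()].
#' @param k_presence,k_absence number of clusters per class.
#' @param lambda_rel relative covariance ridge.
#' @param pooled use one covariance matrix pooled over all clusters (with
#'   `k = 1` per class this makes the decision surface linear).
#' @return object of class `nlda_model`.
#' @export
fit_nlda <- function(sample, seed = 1L, features = NULL, generic = NULL,
                     k_presence = 4L, k_absence = 4L, lambda_rel = 1e-6,
                     pooled = FALSE) {
  if (is.null(generic))
    generic <- select_generic_variables(features %||% feature_names(sample))
  x <- as.matrix(sample[, generic, drop = FALSE])
  y <- sample$presence
  if (length(unique(y)) < 2L) stop("sample must contain both classes")
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(x, 2L, center), 2L, scl, "/")

  set.seed(as.integer(seed))
  cluster_class <- function(zc, k) {
    k <- min(k, nrow(unique(zc)))
    repeat {
      km <- tryCatch(suppressWarnings(
        stats::kmeans(zc, centers = k, nstart = 10L, iter.max = 50L)),
        error = function(e) NULL)
      if (!is.null(km) && all(km$size > 0L)) return(km)
      if (k == 1L) stop("k-means failed at k = 1")
      k <- k - 1L
    }
  }
  km_p <- cluster_class(z[y == 1L, , drop = FALSE], k_presence)
  km_a <- cluster_class(z[y == 0L, , drop = FALSE], k_absence)

  d <- ncol(z)
  n_total <- nrow(z)
  make_clusters <- function(zc, km, label) {
    lapply(seq_len(max(km$cluster)), function(c) {
      pts <- zc[km$cluster == c, , drop = FALSE]
      sigma <- if (nrow(pts) >= 2L) stats::cov(pts) else matrix(0, d, d)
      list(label = label, mu = colMeans(pts), sigma = sigma,
           n = nrow(pts), prior = nrow(pts) / n_total)
    })
  }
  clusters <- c(make_clusters(z[y == 1L, , drop = FALSE], km_p, "presence"),
                make_clusters(z[y == 0L, , drop = FALSE], km_a, "absence"))

  if (pooled) {
    scatter <- matrix(0, d, d)
    for (cl in clusters)
      if (cl$n >= 2L) scatter <- scatter + (cl$n - 1L) * cl$sigma
    pool <- scatter / max(n_total - length(clusters), 1L)
    for (i in seq_along(clusters)) clusters[[i]]$sigma <- pool
  }

  lambda_log <- character(0)
  for (i in seq_along(clusters)) {
    sigma <- clusters[[i]]$sigma
    tr <- sum(diag(sigma))
    base <- if (tr > 0) tr / d else 1
    lambda <- lambda_rel * base
    cap <- base
    repeat {
      ch <- tryCatch(chol(sigma + lambda * diag(d)), error = function(e) NULL)
      if (!is.null(ch)) break
      if (lambda >= cap)
        stop("singular covariance in cluster ", i, " despite regularization")
      lambda <- min(max(lambda * 10, 1e-10 * cap), cap)
      lambda_log <- c(lambda_log,
                      sprintf("cluster %d: lambda escalated to %g", i, lambda))
    }
    clusters[[i]]$chol <- ch
    clusters[[i]]$logdet <- 2 * sum(log(diag(ch)))
    clusters[[i]]$lambda <- lambda
  }

  # per-variable separation score for importance ranking: absolute
  # standardized presence-vs-absence mean difference in the sample
  sep <- abs(colMeans(z[y == 1L, , drop = FALSE]) -
               colMeans(z[y == 0L, , drop = FALSE]))
  var_rank <- rank(-sep, ties.method = "first")
  names(var_rank) <- generic

  structure(list(clusters = clusters, center = center, scale = scl,
                 dfeat = generic, k = c(presence = max(km_p$cluster),
                                        absence = max(km_a$cluster)),
                 pooled = pooled, lambda_log = lambda_log,
                 var_rank = var_rank),
            class = "nlda_model")
}

#' Suitability from a fitted NLDA submodel
#'
#' The suitability of a point is the posterior probability of the presence
#' super-class: the prior-weighted Gaussian density mass of the presence
#' clusters divided by the total over all clusters, computed with
#' log-density (log-sum-exp) stabilisation.
#'
#' @param model an `nlda_model`.
#' @param x feature matrix (columns must include the model's density
#'   variables) or a single named vector.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict_nlda <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  x <- as.matrix(x)[, model$dfeat, drop = FALSE]
  z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  n <- nrow(z); d <- ncol(z)
  logp <- matrix(NA_real_, n, length(model$clusters))
  for (i in seq_along(model$clusters)) {
    cl <- model$clusters[[i]]
    w <- backsolve(cl$chol, t(sweep(z, 2L, cl$mu)), transpose = TRUE)
    quad <- colSums(w^2)
    logp[, i] <- log(cl$prior) - 0.5 * (d * log(2 * pi) + cl$logdet + quad)
    if (any(!is.finite(logp[, i])))
      stop("non-finite discriminant density in cluster ", i)
  }
  pres <- vapply(model$clusters, function(cl) cl$label == "presence", TRUE)
  mx <- apply(logp, 1L, max)
  num <- rowSums(exp(logp[, pres, drop = FALSE] - mx))
  den <- rowSums(exp(logp - mx))
  num / den
}

#' @rdname importance
#' @export
importance.suit_nlda <- function(object, ...) {
  aggregate_importance(lapply(object$submodels, function(s)
    if (is.null(s)) NULL else s$var_rank), type = "rank")
}
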