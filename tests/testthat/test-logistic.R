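test_that("an intercept-only balanced fit predicts 0.5 everywhere", {
  tab <- toy_table(40, 40, p = 1, seed = 1)
  fit <- fit_logistic(tab, features = character(0))
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(unname(predict_logistic(fit, tab[, "f1", drop = FALSE])),
               rep(0.5, 80), tolerance = 1e-8)
})

test_that("the maximum likelihood matches a direct optimiser on a small dataset", {
  # deliberately overlapping classes so the MLE is finite
  x <- cbind(f1 = c(-0.63, 0.18, -0.84, 1.60, 0.33, -0.82, 0.49, 0.74),
             f2 = c(0.58, -0.31, 1.51, 0.39, -0.62, -2.21, 1.12, -0.04))
  y <- c(0L, 0L, 1L, 1L, 1L, 0L, 1L, 0L)
  tab <- data.frame(presence = y, f1 = x[, 1], f2 = x[, 2])
  fit <- suppressWarnings(
    fit_logistic(tab, features = c("f1", "f2"), standardize = FALSE))
  expect_false(fit$ridge)
  loglik <- function(b)
    sum(y * stats::plogis(b[1] + x %*% b[2:3], log.p = TRUE) +
          (1 - y) * stats::plogis(-(b[1] + x %*% b[2:3]), log.p = TRUE))
  oracle <- stats::optim(c(0, 0, 0), function(b) -loglik(b),
                         method = "BFGS",
                         control = list(reltol = 1e-14, maxit = 1000))
  got <- loglik(c(fit$intercept, fit$coef_std))
  expect_equal(got, -oracle$value, tolerance = 1e-6)
})

test_that("coefficients are recovered from a known three-parameter logit", {
  set.seed(3)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 + 1.2 * x1 - 0.8 * x2))
  tab <- data.frame(presence = y, x1 = x1, x2 = x2)
  fit <- fit_logistic(tab, features = c("x1", "x2"))
  truth <- c(0.5, 1.2, -0.8)
  est <- fit$coefficients
  se <- c(Inf, fit$se)  # intercept SE not needed for the slope check
  expect_lt(abs(est[["x1"]] - 1.2) / fit$se[["x1"]], 3)
  expect_lt(abs(est[["x2"]] + 0.8) / fit$se[["x2"]], 3)
  expect_true(fit$converged && !fit$ridge)
  expect_true(all(is.finite(fit$z)))
})

test_that("separation triggers the flagged ridge fallback", {
  tab <- data.frame(presence = rep(c(1L, 0L), each = 20),
                    f1 = c(runif(20, 1, 2), runif(20, -2, -1)),
                    f2 = rnorm(40))
  fit <- fit_logistic(tab, features = c("f1", "f2"))
  expect_true(fit$ridge)
  expect_true(all(is.na(fit$z)))
  p <- predict_logistic(fit, tab[, c("f1", "f2")])
  expect_true(all(p[tab$presence == 1] > 0.5) &&
                all(p[tab$presence == 0] < 0.5))
})

test_that("variables are ranked by |z| and averaged over usable fits", {
  mk_fit <- function(z, ridge = FALSE) {
    structure(list(z = z, features = names(z), converged = TRUE,
                   ridge = ridge, coef_std = z), class = "logistic_fit")
  }
  one <- rank_variables_logistic(list(mk_fit(c(a = 5, b = 2, c = 1))))
  expect_equal(one$variable, c("a", "b", "c"))
  expect_equal(one$score, c(1, 2, 3))
  # signs do not matter, and ridge fits are excluded but counted
  fits <- list(mk_fit(c(a = -5, b = 2, c = 1)),
               mk_fit(c(a = 1, b = -4, c = 2)),
               mk_fit(c(a = 9, b = 9, c = 9), ridge = TRUE))
  t2 <- rank_variables_logistic(fits)
  expect_equal(attr(t2, "n_excluded"), 1L)
  manual <- rowMeans(cbind(c(1, 2, 3), c(3, 1, 2)))
  expect_equal(t2$score[match(c("a", "b", "c"), t2$variable)], manual)
})

test_that("ensemble coefficient recovery sharpens with sample size", {
  rmse_at <- function(n, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      x1 <- rnorm(n); x2 <- rnorm(n)
      y <- rbinom(n, 1, plogis(0.5 + 1.2 * x1 - 0.8 * x2))
      fit <- fit_logistic(data.frame(presence = y, x1 = x1, x2 = x2),
                          features = c("x1", "x2"))
      sqrt(mean((fit$coefficients[c("x1", "x2")] - c(1.2, -0.8))^2))
    }, numeric(1))
  }
  expect_lt(mean(rmse_at(4000, 1:8)), mean(rmse_at(500, 1:8)))
})

test_that("shared-sign submodels give a monotone ensemble in that feature", {
  mk_fit <- function(b0, b1) structure(
    list(intercept = b0, coef_std = c(f1 = b1), center = c(f1 = 0),
         scale = c(f1 = 1), features = "f1"), class = "logistic_fit")
  ens <- structure(list(submodels = list(mk_fit(0, 0.5), mk_fit(-1, 2),
                                         mk_fit(0.3, 1.1)),
                        features = "f1", n_submodels = 3L),
                   class = "suit_ensemble")
  xs <- matrix(seq(-3, 3, length.out = 31), ncol = 1,
               dimnames = list(NULL, "f1"))
  p <- predict(ens, xs)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("Moran's I is negative for alternating residuals on a transect", {
  n <- 20
  coords <- cbind(seq_len(n), 0)
  res <- rep(c(1, -1), n / 2)
  i_adj <- moran_i(res, coords, low = 0.5, high = 1.5)
  expect_lt(i_adj, 0)
})

test_that("a six-point correlogram matches the direct double sum", {
  coords <- cbind(c(0, 1, 2, 0, 1, 2), c(0, 0, 0, 1, 1, 1))
  res <- c(0.3, -0.2, 0.5, -0.4, 0.1, -0.3)
  z <- res - mean(res)
  d <- as.matrix(dist(coords))
  for (band in list(c(0.5, 1.5), c(1.5, 2.5))) {
    w <- d > band[1] & d <= band[2]; diag(w) <- FALSE
    manual <- 0
    for (i in 1:6) for (j in 1:6)
      if (w[i, j]) manual <- manual + z[i] * z[j]
    manual <- (6 / sum(w)) * manual / sum(z^2)
    expect_equal(moran_i(res, coords, band[1], band[2]), manual,
                 tolerance = 1e-12)
  }
})

test_that("degenerate correlogram bins are flagged as NA, not errors", {
  coords <- cbind(c(0, 1, 5), c(0, 0, 0))
  # empty band
  out <- moran_correlogram(c(1, -1, 0.5), coords, breaks = c(2, 3))
  expect_true(is.na(out$moran_i[1]))
  expect_equal(out$n_pairs[1], 0L)
  # zero residual variance
  out2 <- moran_correlogram(c(1, 1, 1), coords, breaks = c(0.5, 1.5))
  expect_true(is.na(out2$moran_i[1]))
})

test_that("default binning spans half the maximum distance in ten bins", {
  set.seed(5)
  coords <- cbind(runif(30, 0, 10), runif(30, 0, 10))
  out <- moran_correlogram(rnorm(30), coords)
  expect_equal(nrow(out), 10L)
  expect_equal(out$bin_high[10], max(dist(coords)) / 2, tolerance = 1e-12)
})
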