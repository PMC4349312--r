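test_that("the generic variable list is DEM plus 10 components of 4 signals", {
  ls <- generate_landscape(10, 10, seed = 1)
  cov <- generate_covariates(ls, years = 1, seed = 2)
  fs <- fourier_stack(cov)
  gv <- select_generic_variables(names(fs$layers))
  expect_length(gv, 41L)
  expect_true("DEM" %in% gv)
  expect_true(all(gv %in% names(fs$layers)))
  for (v in c("MIR", "DLST", "NLST", "NDVI"))
    expect_length(grep(paste0("^", v, "_"), gv), 10L)
  # EVI and the D components are not generic
  expect_length(grep("^EVI_", gv), 0L)
  expect_length(grep("_D[123A]*$", gv), 0L)
  expect_error(select_generic_variables(setdiff(names(fs$layers), "DEM")),
               "DEM")
})

test_that("k=1 per class reduces to a two-Gaussian quadratic discriminant", {
  set.seed(20)
  n <- 30
  tab <- data.frame(
    presence = rep(c(1L, 0L), each = n),
    g1 = c(rnorm(n, 1), rnorm(n, -1)),
    g2 = c(rnorm(n, 0.5, 1.5), rnorm(n, -0.5, 0.8)))
  fit <- fit_nlda(tab, seed = 1, generic = c("g1", "g2"),
                  k_presence = 1, k_absence = 1, lambda_rel = 0)
  # the single clusters are the class means in standardized space
  zp <- fit$clusters[[1]]; za <- fit$clusters[[2]]
  expect_equal(zp$label, "presence")
  expect_equal(zp$prior + za$prior, 1)
  x <- as.matrix(tab[, c("g1", "g2")])
  z <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  oracle <- qda_posterior_oracle(z, zp$mu, zp$sigma + zp$lambda * diag(2),
                                 zp$prior,
                                 za$mu, za$sigma + za$lambda * diag(2),
                                 za$prior)
  got <- predict_nlda(fit, x)
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("posteriors of the two super-classes sum to one", {
  set.seed(21)
  tab <- data.frame(presence = rep(c(1L, 0L), each = 40),
                    g1 = rnorm(80), g2 = rnorm(80), g3 = rnorm(80))
  fit <- fit_nlda(tab, seed = 2, generic = c("g1", "g2", "g3"),
                  k_presence = 2, k_absence = 2)
  flipped <- tab
  flipped$presence <- 1L - tab$presence
  fit_flip <- fit_nlda(flipped, seed = 2, generic = c("g1", "g2", "g3"),
                       k_presence = 2, k_absence = 2)
  x <- as.matrix(tab[, c("g1", "g2", "g3")])
  expect_equal(predict_nlda(fit, x) + predict_nlda(fit_flip, x),
               rep(1, 80), tolerance = 1e-9)
})

test_that("well-separated blobs are found by the clustering", {
  # exhaustive 2-partition oracle on 12 points
  set.seed(22)
  blob1 <- matrix(rnorm(12, 0, 0.1), 6, 2) + matrix(c(5, 0), 6, 2,
                                                    byrow = TRUE)
  blob2 <- matrix(rnorm(12, 0, 0.1), 6, 2) + matrix(c(-5, 0), 6, 2,
                                                    byrow = TRUE)
  pts <- rbind(blob1, blob2)
  best_ss <- Inf; best_split <- NULL
  for (code in 1:(2^11)) {
    grp <- c(0L, as.integer(intToBits(code)[1:11]))
    if (all(grp == 0L) || all(grp == 1L)) next
    ss <- 0
    for (g in 0:1) {
      sub <- pts[grp == g, , drop = FALSE]
      ss <- ss + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    if (ss < best_ss) { best_ss <- ss; best_split <- grp }
  }
  oracle_centroids <- rbind(colMeans(pts[best_split == 0, ]),
                            colMeans(pts[best_split == 1, ]))
  tab <- data.frame(presence = c(rep(1L, 12), rep(0L, 4)),
                    g1 = c(pts[, 1], rnorm(4, 0, 0.1)),
                    g2 = c(pts[, 2], rnorm(4, 0, 0.1)))
  fit <- fit_nlda(tab, seed = 3, generic = c("g1", "g2"),
                  k_presence = 2, k_absence = 1)
  got <- t(vapply(fit$clusters[1:2], function(cl)
    cl$mu * fit$scale + fit$center, numeric(2)))
  ord_got <- got[order(got[, 1]), ]
  ord_orc <- oracle_centroids[order(oracle_centroids[, 1]), ]
  expect_equal(ord_got, ord_orc, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("suitability saturates at a presence centroid and splits symmetric setups", {
  set.seed(23)
  tab <- data.frame(presence = rep(c(1L, 0L), each = 25),
                    g1 = c(rnorm(25, 4, 0.5), rnorm(25, -4, 0.5)),
                    g2 = rnorm(50))
  fit <- fit_nlda(tab, seed = 4, generic = c("g1", "g2"),
                  k_presence = 1, k_absence = 1)
  at_centroid <- c(g1 = 4, g2 = 0)
  expect_gt(predict_nlda(fit, at_centroid), 0.99)
  # mirror-image classes with equal priors: the midpoint scores 1/2
  mirror <- data.frame(presence = rep(c(1L, 0L), each = 25),
                       g1 = c(rnorm(25, 3, 1)))
  mirror$g1[26:50] <- -mirror$g1[1:25]
  mirror$g2 <- c(rnorm(25), rnorm(25))
  fitm <- fit_nlda(mirror, seed = 5, generic = "g1",
                   k_presence = 1, k_absence = 1)
  expect_equal(predict_nlda(fitm, c(g1 = 0)), 0.5, tolerance = 1e-9)
})

test_that("pooled covariance with k=1 gives a monotone linear sweep", {
  set.seed(24)
  tab <- data.frame(presence = rep(c(1L, 0L), each = 40),
                    g1 = c(rnorm(40, 1.5), rnorm(40, -1.5)),
                    g2 = rnorm(80))
  fit <- fit_nlda(tab, seed = 6, generic = c("g1", "g2"),
                  k_presence = 1, k_absence = 1, pooled = TRUE)
  sweep_x <- cbind(g1 = seq(-4, 4, length.out = 41), g2 = 0)
  p <- predict_nlda(fit, sweep_x)
  expect_true(all(diff(p) > 0))
})

test_that("fitting is deterministic in the seed", {
  w <- toy_table(60, 60, p = 4, seed = 25, beta = c(1, -1, 0.5, 0))
  f1 <- fit_nlda(w, seed = 9, generic = paste0("f", 1:4))
  f2 <- fit_nlda(w, seed = 9, generic = paste0("f", 1:4))
  expect_identical(f1$clusters, f2$clusters)
})

test_that("an NLDA ensemble separates true presence and absence cells", {
  w <- make_world(seed = 61, width = 30, height = 30, n_traps = 250,
                  beta = c(NDVI_A1 = 2, DLST_A0 = 2),
                  seasonal_config = recovery_seasonal_config())
  fit <- suitability_ensemble(presence ~ ., w$occurrence, method = "nlda",
                              n_submodels = 20, seed = 3)
  occ <- w$occurrence
  p <- predict(fit, occ)
  expect_gt(mean(p[occ$presence == 1]), mean(p[occ$presence == 0]))
})
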