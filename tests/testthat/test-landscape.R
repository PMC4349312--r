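test_that("landscape class shares match targets within 5% and classes are patchy", {
  props <- c(urban = 0.2, agricultural_sampled = 0.3,
             agricultural_excluded = 0.2, natural = 0.25, water = 0.05)
  ls <- generate_landscape(50, 50, props, seed = 1)
  expect_equal(dim(ls$values), c(50L, 50L))
  share <- prop.table(table(factor(ls$levels[ls$values],
                                   levels = ls$levels)))
  expect_true(all(abs(share - props[names(share)]) <= 0.05))
  # patchiness: adjacent cells agree far more often than the p^2 baseline
  # of a spatially random labelling
  v <- ls$values
  agree <- mean(v[, -1] == v[, -ncol(v)])
  expect_gt(agree, sum(props^2) + 0.2)
})

test_that("degenerate single-class proportions give a uniform map", {
  ls <- generate_landscape(20, 20, c(urban = 1), seed = 3)
  expect_true(all(ls$levels[ls$values] == "urban"))
})

test_that("landscape generation is deterministic and validates proportions", {
  a <- generate_landscape(30, 30, seed = 9)
  b <- generate_landscape(30, 30, seed = 9)
  expect_identical(a$values, b$values)
  expect_error(generate_landscape(20, 20, c(urban = 0.5, water = 0.4)),
               "sum to 1")
})

test_that("zero-noise covariates equal their harmonic construction exactly", {
  ls <- generate_landscape(12, 12, c(natural = 1), seed = 2)
  cfg <- default_seasonal_config()["NDVI"]
  cfg$NDVI$noise_sd <- 0
  cfg$NDVI$field_sd_mean <- 0
  cfg$NDVI$field_sd_amp <- 0
  cov <- generate_covariates(ls, years = 2, seed = 4, seasonal_config = cfg)
  series <- cov$seasonal$NDVI[3, 3, ]
  p <- cfg$NDVI
  t <- 0:23
  expected <- p$mean[["natural"]] +
    p$amp1[["natural"]] * cos(2 * pi * (t - p$phase1) / 12) +
    p$amp2[["natural"]] * cos(4 * pi * (t - p$phase2) / 12)
  expect_equal(series, expected, tolerance = 1e-12)
})

test_that("configured annual amplitude is recovered by refitting", {
  ls <- generate_landscape(15, 15, c(natural = 1), seed = 6)
  cfg <- default_seasonal_config()["NDVI"]
  cfg$NDVI$field_sd_amp <- 0          # amplitude exactly the configured 0.3
  cfg$NDVI$field_sd_mean <- 0
  cov <- generate_covariates(ls, years = 3, seed = 7, seasonal_config = cfg)
  comp <- fourier_components(cov$seasonal$NDVI[8, 8, ])
  # LS amplitude estimate has sd = noise_sd * sqrt(2/N)
  sigma <- cfg$NDVI$noise_sd * sqrt(2 / 36)
  expect_lt(abs(comp[["A1"]] - 0.3), 3 * sigma)
})

test_that("population density is zero on water and non-negative", {
  ls <- generate_landscape(20, 20, c(urban = 0.5, water = 0.5), seed = 8)
  cov <- generate_covariates(ls, years = 1, seed = 9)
  pop <- cov$static$POPDEN
  expect_true(all(pop[class_mask(ls, "water")] == 0))
  expect_true(all(pop >= 0))
})

test_that("survey respects strata, exclusion zones and single sampling", {
  w <- make_world(seed = 21, n_traps = 766, width = 60, height = 60)
  sv <- w$survey
  counts <- table(sv$stratum)
  expect_equal(as.integer(counts[c("urban", "agricultural_sampled",
                                   "natural")]),
               c(307L, 306L, 153L))
  cls <- landcover_names(w$landscape)
  idx <- cell_of(sv$x, sv$y, w$landscape)
  trap_class <- cls[cbind(idx$row + 1L, idx$col + 1L)]
  expect_true(all(trap_class %in% sampleable_classes()))
  expect_false(any(trap_class %in% c("agricultural_excluded", "water")))
  expect_equal(anyDuplicated(idx$cell), 0L)
  expect_true(all(sv$week %in% 1:30))
  expect_true(all(sv$abundance >= 0))
})

test_that("survey is deterministic and saturates when suitability is 1", {
  ls <- generate_landscape(20, 20, c(urban = 0.4, agricultural_sampled = 0.4,
                                     natural = 0.2), seed = 31)
  ones <- env_grid(matrix(1, 20, 20), cell_size = 1)
  a <- simulate_survey(ls, n_traps = 100, seed = 5, suitability = ones)
  b <- simulate_survey(ls, n_traps = 100, seed = 5, suitability = ones)
  expect_identical(a, b)
  expect_true(all(a$abundance >= 1))
})

test_that("observed prevalence tracks true suitability and the intercept", {
  ls <- generate_landscape(80, 80, seed = 41)
  cov <- generate_covariates(ls, years = 2, seed = 42)
  fs <- fourier_stack(cov)
  prev <- vapply(c(-1.5, 0, 1.5), function(b0) {
    truth <- truth_model(c(NDVI_A1 = 1), intercept = b0)
    st <- true_suitability(truth, fs, ls)
    sv <- simulate_survey(ls, n_traps = 2000, seed = 43, suitability = st)
    mean(sv$abundance >= 1)
  }, numeric(1))
  # monotone in the intercept
  expect_true(all(diff(prev) > 0))
  # and consistent with the mean true suitability at the trap cells:
  # presence count ~ Binomial(n, mean p); check the middle intercept at a
  # 99% normal bound
  truth <- truth_model(c(NDVI_A1 = 1), intercept = 0)
  st <- true_suitability(truth, fs, ls)
  sv <- simulate_survey(ls, n_traps = 2000, seed = 43, suitability = st)
  idx <- cell_of(sv$x, sv$y, ls)
  pbar <- mean(st$values[cbind(idx$row + 1L, idx$col + 1L)])
  se <- sqrt(pbar * (1 - pbar) / nrow(sv))
  expect_lt(abs(mean(sv$abundance >= 1) - pbar), 2.58 * se)
})
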