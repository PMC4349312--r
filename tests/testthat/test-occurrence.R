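test_that("abundance reclassifies to presence/absence", {
  expect_equal(reclassify_presence(c(0L, 1L, 17L)), c(0L, 1L, 1L))
  expect_error(reclassify_presence(-1), "non-negative")
  expect_error(reclassify_presence(1.5), "integer")
})

test_that("deduplication keeps presences and is idempotent", {
  g <- env_grid(matrix(0, 5, 5), cell_size = 1)
  pts <- data.frame(
    point_id = 1:6,
    x = c(0.2, 0.8, 2.5, 2.1, 4.5, 4.9),   # cells: A, A, B, B, C, C
    y = c(0.5, 0.5, 0.5, 0.5, 3.5, 3.5),
    presence = c(0L, 1L, 0L, 0L, 1L, 1L),
    origin = "observed")
  out <- dedup_cells(pts, g)
  expect_equal(nrow(out), 3L)
  # mixed cell keeps the presence point
  expect_equal(out$point_id[out$cell == cell_of(0.2, 0.5, g)$cell], 2L)
  # absence-only cell keeps the lowest point_id
  expect_equal(out$point_id[out$cell == cell_of(2.5, 0.5, g)$cell], 3L)
  # presence tie keeps the lowest point_id
  expect_equal(out$point_id[out$cell == cell_of(4.5, 3.5, g)$cell], 5L)
  # idempotent
  expect_equal(dedup_cells(out, g), out)
  # shuffling the input changes nothing
  out2 <- dedup_cells(pts[sample(6), ], g)
  expect_equal(out2[order(out2$cell), ], out[order(out$cell), ],
               ignore_attr = TRUE)
})

test_that("points in distinct cells pass dedup unchanged", {
  g <- env_grid(matrix(0, 10, 10), cell_size = 1)
  set.seed(2)
  pts <- data.frame(point_id = 1:10, x = (0:9) + 0.5, y = (0:9) + 0.5,
                    presence = rbinom(10, 1, 0.5), origin = "observed")
  out <- dedup_cells(pts, g)
  expect_equal(nrow(out), 10L)
  expect_equal(sum(out$presence), sum(pts$presence))
})

test_that("pseudo-absences land only in free excluded cells, deterministically", {
  ls <- generate_landscape(30, 30, seed = 4)
  set.seed(9)
  pts <- data.frame(point_id = 1:50,
                    x = runif(50, 0, 30), y = runif(50, 0, 30),
                    presence = rbinom(50, 1, 0.6), origin = "observed")
  pts <- dedup_cells(pts, ls)
  out <- add_pseudo_absences(pts, ls, n = 43, seed = 7)
  pa <- out[out$origin == "pseudo_absence", ]
  expect_equal(nrow(pa), 43L)
  expect_true(all(pa$presence == 0L))
  idx <- cell_of(pa$x, pa$y, ls)
  cls <- landcover_names(ls)[cbind(idx$row + 1L, idx$col + 1L)]
  expect_true(all(cls == "agricultural_excluded"))
  expect_length(intersect(pa$cell, pts$cell), 0L)
  expect_equal(anyDuplicated(out$cell), 0L)
  # determinism and the n = 0 identity
  out2 <- add_pseudo_absences(pts, ls, n = 43, seed = 7)
  expect_identical(out, out2)
  expect_identical(add_pseudo_absences(pts, ls, n = 0), pts)
  # observed-origin prevalence untouched
  obs <- out[out$origin == "observed", ]
  expect_equal(mean(obs$presence), mean(pts$presence))
  # impossible requests fail loudly
  expect_error(add_pseudo_absences(pts, ls, n = 1e6, seed = 1), "free")
})

test_that("feature extraction reads the pixel under each point", {
  ls <- generate_landscape(10, 10, seed = 5)
  cov <- generate_covariates(ls, years = 1, seed = 6)
  fs <- fourier_stack(cov)
  pts <- data.frame(point_id = 1:3, x = c(0.5, 5.5, 9.5),
                    y = c(0.5, 5.2, 9.9), presence = c(1L, 0L, 1L),
                    origin = "observed")
  occ <- extract_features(pts, fs)
  expect_equal(nrow(occ), 3L)
  expect_length(feature_names(occ), 74L)
  idx <- cell_of(pts$x, pts$y, ls)
  for (i in 1:3)
    expect_equal(occ$DEM[i], fs$layers$DEM[idx$row[i] + 1L, idx$col[i] + 1L])
})

test_that("points on nodata pixels are dropped with a logged count", {
  ls <- generate_landscape(10, 10, seed = 5)
  cov <- generate_covariates(ls, years = 1, seed = 6)
  cov$seasonal$MIR[1, 1, 2] <- NA   # row 1, col 1 -> cell at (0.5, 0.5)
  fs <- fourier_stack(cov)
  pts <- data.frame(point_id = 1:2, x = c(0.5, 5.5), y = c(0.5, 5.5),
                    presence = c(1L, 0L), origin = "observed")
  expect_message(occ <- extract_features(pts, fs), "1 point")
  expect_equal(occ$point_id, 2L)
  cov$seasonal$MIR[, , 2] <- NA
  fs_bad <- fourier_stack(cov)
  expect_error(suppressMessages(extract_features(pts, fs_bad)), "all points")
})

test_that("extraction on constant rasters yields identical feature vectors", {
  fs <- structure(list(layers = list(a = matrix(3, 8, 8),
                                     b = matrix(-1, 8, 8)),
                       origin = c(0, 0), cell_size = 1),
                  class = "feature_stack")
  set.seed(3)
  pts <- data.frame(point_id = 1:12, x = runif(12, 0, 8), y = runif(12, 0, 8),
                    presence = 1L, origin = "observed")
  occ <- extract_features(pts, fs)
  expect_true(all(occ$a == 3) && all(occ$b == -1))
})

test_that("occurrence tables round-trip through CSV", {
  tab <- toy_table(5, 5, p = 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrence_csv(tab, path)
  back <- read_occurrence_csv(path)
  expect_equal(feature_names(back), c("f1", "f2"))
  expect_equal(back$f1, tab$f1, tolerance = 1e-12)
  expect_equal(back$presence, tab$presence)
})
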