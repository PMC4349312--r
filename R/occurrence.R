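#' Reclassify trap counts to presence/absence
#'
#' Catches are collapsed to a binary indicator because abundance varies with
#' the sampling week, whereas occurrence does not: at least one individual
#' in the trap means presence, an empty trap means absence.
#'
#' @param abundance non-negative integer vector of catch counts.
#' @return integer vector of 0 (absence) / 1 (presence).
#' @export
reclassify_presence <- function(abundance) {
  if (any(!is.finite(abundance)) || any(abundance < 0) ||
      any(abundance != floor(abundance)))
    stop("abundance must be non-negative integer counts")
  as.integer(abundance >= 1)
}

#' Convert a trap survey to occurrence points
#'
#' @param survey a [simulate_survey()]-shaped data.frame.
#' @return data.frame with `point_id, x, y, presence, origin` where
#'   `origin` is `"observed"`.
#' @export
survey_to_points <- function(survey) {
  data.frame(point_id = survey$trap_id, x = survey$x, y = survey$y,
             presence = reclassify_presence(survey$abundance),
             origin = "observed", stringsAsFactors = FALSE)
}

#' Deduplicate occurrence points to one record per grid cell
#'
#' When several points fall in the same 1-km^2 cell, a presence point is
#' kept in preference to absences: a presence shows the cell is
#' environmentally suitable, while an absence does not prove the opposite.
#' Ties within a class keep the lowest `point_id` (deterministic,
#' order-independent).
#'
#' @param points data.frame with `point_id, x, y, presence` (and any other
#'   columns, carried along).
#' @param grid geometry provider (a `landscape` or `env_grid`).
#' @return the deduplicated data.frame, with a `cell` column added.
#' @export
dedup_cells <- function(points, grid) {
  idx <- cell_of(points$x, points$y, grid)
  points$cell <- idx$cell
  ord <- order(points$cell, -points$presence, points$point_id)
  pts <- points[ord, , drop = FALSE]
  keep <- !duplicated(pts$cell)
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Add pseudo-absences in unsuitable, unsampled land cover
#'
#' Areas of high-productivity agriculture are known to be unsuitable and
#' are never surveyed, so a model fitted to trap data alone has no
#' information about them and can extrapolate high suitability there.
#' This adds `n` "probable absence" records placed uniformly at random
#' (seeded) in `agricultural_excluded` cells that hold no existing record.
#'
#' @param points occurrence points (after [dedup_cells()], so that a `cell`
#'   column exists; computed if absent).
#' @param landscape the `landscape`.
#' @param n number of pseudo-absences; the default is 5% of the observed
#'   records (rounded up).
#' @param seed integer seed.
#' @return the augmented data.frame; new records have
#'   `origin = "pseudo_absence"`, `presence = 0`, coordinates at cell
#'   centres.
#' @export
add_pseudo_absences <- function(points, landscape, n = NULL, seed = 1L) {
  if (is.null(points$cell))
    points$cell <- cell_of(points$x, points$y, landscape)$cell
  if (is.null(n)) n <- ceiling(0.05 * nrow(points))
  if (n == 0L) return(points)
  excl <- which(class_mask(landscape, "agricultural_excluded"))  # col-major
  nr <- nrow(landscape$values); nc <- ncol(landscape$values)
  row0 <- (excl - 1L) %% nr
  col0 <- (excl - 1L) %/% nr
  cell_ids <- row0 * nc + col0
  free <- which(!(cell_ids %in% points$cell))
  if (n > length(free))
    stop("requested ", n, " pseudo-absences but only ", length(free),
         " free excluded cells")
  set.seed(as.integer(seed))
  pick <- free[sample.int(length(free), n)]
  ctr <- cell_center(row0[pick], col0[pick], landscape)
  add <- data.frame(point_id = max(points$point_id) + seq_len(n),
                    x = ctr$x, y = ctr$y, presence = 0L,
                    origin = "pseudo_absence", cell = cell_ids[pick],
                    stringsAsFactors = FALSE)
  out <- rbind(points[, c("point_id", "x", "y", "presence", "origin", "cell")],
               add)
  rownames(out) <- NULL
  out
}

#' Attach feature values to occurrence points
#'
#' Looks up every feature raster at each point's cell. Points over nodata
#' pixels (any feature missing) are dropped with a message reporting the
#' count.
#'
#' @param points occurrence points with coordinates (a `cell` column is
#'   recomputed from x/y against the stack geometry).
#' @param features a [fourier_stack()] result.
#' @return data.frame of class `occurrence_table`: the point columns plus
#'   one numeric column per feature; the feature names are stored in
#'   `attr(, "feature_names")`.
#' @export
extract_features <- function(points, features) {
  geom <- list(values = features$layers[[1]], origin = features$origin,
               cell_size = features$cell_size)
  idx <- cell_of(points$x, points$y, geom)
  lin <- idx$row + 1L + idx$col * nrow(features$layers[[1]])  # col-major
  fm <- feature_matrix_at(features, lin)
  ok <- rowSums(!is.finite(fm)) == 0L
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(n_drop, " point(s) dropped on nodata pixels")
  if (!any(ok)) stop("all points fall on nodata pixels")
  out <- cbind(points[ok, , drop = FALSE],
               as.data.frame(fm[ok, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "feature_names") <- colnames(fm)
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Names of the feature columns of an occurrence table
#' @param table an `occurrence_table`.
#' @export
feature_names <- function(table) attr(table, "feature_names")

#' Write / read occurrence tables as CSV
#'
#' @param table an `occurrence_table` (or plain points data.frame).
#' @param path CSV file path.
#' @export
write_occurrence_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrence_csv
#' @param feature_cols names of the feature columns (columns other than
#'   the point metadata are used when `NULL`).
#' @export
read_occurrence_csv <- function(path, feature_cols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- c("point_id", "x", "y", "presence", "origin", "cell")
  if (is.null(feature_cols)) feature_cols <- setdiff(names(df), meta)
  attr(df, "feature_names") <- feature_cols
  class(df) <- c("occurrence_table", "data.frame")
  df
}
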