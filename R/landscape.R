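#' Land-cover classes used throughout the package
#'
#' Five classes: `urban`, `agricultural_sampled`, `natural` are sampleable
#' by traps; `agricultural_excluded` (high-productivity arable land, deemed
#' unsuitable for mosquito breeding and never surveyed) and `water` form the
#' unsampled region. Pseudo-absences are drawn from `agricultural_excluded`.
#'
#' @export
landcover_classes <- function() {
  c("urban", "agricultural_sampled", "agricultural_excluded",
    "natural", "water")
}

#' Classes where traps may be placed
#' @export
sampleable_classes <- function() c("urban", "agricultural_sampled", "natural")

#' Generate a synthetic land-cover landscape
#'
#' Classes are spatially autocorrelated (patchy): a Gaussian-smoothed white
#' noise field is thresholded at the quantiles matching the cumulative class
#' proportions, so realised class shares match the configured targets up to
#' quantile ties.
#'
#' @param width,height grid size in cells.
#' @param class_proportions named numeric vector over (a subset of)
#'   [landcover_classes()], summing to 1.
#' @param seed integer seed; identical seeds give identical landscapes.
#' @param cell_size cell edge in km (1 km -> 1 km^2 pixels).
#' @param origin lower-left corner coordinates.
#' @param patch_sigma smoothing bandwidth in cells; larger means bigger
#'   patches.
#' @return object of class `landscape`: an `env_grid` of integer class codes
#'   with a `levels` field, plus the target proportions.
#' @export
generate_landscape <- function(width, height,
                               class_proportions = c(
                                 urban = 0.2, agricultural_sampled = 0.3,
                                 agricultural_excluded = 0.2, natural = 0.25,
                                 water = 0.05),
                               seed = 1L, cell_size = 1, origin = c(0, 0),
                               patch_sigma = 3) {
  stopifnot(width * height >= 100)
  if (abs(sum(class_proportions) - 1) > 1e-6)
    stop("class_proportions must sum to 1")
  unknown <- setdiff(names(class_proportions), landcover_classes())
  if (length(unknown)) stop("unknown land-cover class: ",
                            paste(unknown, collapse = ", "))
  keep <- class_proportions > 0
  props <- class_proportions[keep]
  set.seed(as.integer(seed))
  field <- gauss_smooth(matrix(stats::rnorm(height * width), height, width),
                        patch_sigma)
  # quantile thresholds at cumulative proportions -> realised shares ~ targets
  cuts <- stats::quantile(field, probs = cumsum(props), names = FALSE)
  cuts[length(cuts)] <- Inf
  codes <- matrix(findInterval(field, c(-Inf, cuts[-length(cuts)])),
                  height, width)
  lc <- env_grid(codes, origin = origin, cell_size = cell_size)
  structure(list(values = lc$values, origin = lc$origin,
                 cell_size = lc$cell_size, levels = names(props),
                 proportions = props),
            class = c("landscape", "env_grid"))
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d cells (%g km/cell)\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  tab <- table(factor(x$levels[x$values], levels = x$levels))
  share <- prop.table(tab)
  for (i in seq_along(tab))
    cat(sprintf("  %-22s %6d cells (%.1f%%)\n", names(tab)[i], tab[i],
                100 * share[i]))
  invisible(x)
}

#' Land-cover class name per cell
#'
#' @param landscape a `landscape`.
#' @return character matrix of class names.
#' @export
landcover_names <- function(landscape) {
  matrix(landscape$levels[landscape$values], nrow(landscape$values),
         ncol(landscape$values))
}

# logical matrix of cells belonging to any of the given classes
class_mask <- function(landscape, classes) {
  matrix(landscape$levels[landscape$values] %in% classes,
         nrow(landscape$values), ncol(landscape$values))
}

#' Largest-remainder apportionment of n among proportions
#'
#' Splits an integer total over strata so counts sum exactly to `n`:
#' floor each quota, then distribute leftover units to the largest
#' fractional remainders (ties by stratum order).
#'
#' @param n integer total.
#' @param proportions named numeric vector summing to 1.
#' @return named integer vector summing to `n`.
#' @export
apportion_largest_remainder <- function(n, proportions) {
  quota <- n * proportions / sum(proportions)
  base <- floor(quota)
  left <- round(n - sum(base))
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}
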