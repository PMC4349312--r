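#' Default seasonal covariate configuration
#'
#' Per-variable harmonic parameters for the five monthly remote-sensing
#' signals (MIR reflectance, day/night land surface temperature in deg C,
#' EVI and NDVI). Each parameter is a named vector over the land-cover
#' classes; a pixel's seasonal series is
#' `mean + amp1*cos(2*pi*(t - phase1)/12) + amp2*cos(4*pi*(t - phase2)/12)`
#' plus white Gaussian noise, with the mean and annual amplitude additionally
#' modulated by smooth, variable-specific random fields so that covariates
#' are not collinear across variables. Values are temperate-climate monthly
#' climatology scales (LST peaks in July, vegetation indices peak in early
#' summer and are higher in natural land than in built-up areas).
#'
#' @return nested list of per-variable parameters.
#' @export
default_seasonal_config <- function() {
  cls <- landcover_classes()
  per_class <- function(urban, agri_s, agri_e, natural, water)
    stats::setNames(c(urban, agri_s, agri_e, natural, water), cls)
  list(
    MIR = list(mean = per_class(0.12, 0.09, 0.10, 0.07, 0.02),
               amp1 = per_class(0.02, 0.03, 0.03, 0.025, 0.005),
               amp2 = per_class(0.005, 0.008, 0.008, 0.006, 0.002),
               phase1 = 7, phase2 = 3, noise_sd = 0.008,
               field_sd_mean = 0.015, field_sd_amp = 0.005),
    DLST = list(mean = per_class(13, 11.5, 11.5, 10.5, 9),
                amp1 = per_class(8.5, 8, 8, 7.5, 6),
                amp2 = per_class(0.8, 0.7, 0.7, 0.6, 0.4),
                phase1 = 6.5, phase2 = 1, noise_sd = 0.8,
                field_sd_mean = 1.2, field_sd_amp = 0.5),
    NLST = list(mean = per_class(8.5, 7, 7, 6.5, 7.5),
                amp1 = per_class(6, 6.2, 6.2, 6, 5),
                amp2 = per_class(0.5, 0.5, 0.5, 0.5, 0.3),
                phase1 = 6.8, phase2 = 1.5, noise_sd = 0.7,
                field_sd_mean = 1.0, field_sd_amp = 0.4),
    EVI = list(mean = per_class(0.20, 0.35, 0.38, 0.42, 0.05),
               amp1 = per_class(0.08, 0.15, 0.16, 0.17, 0.01),
               amp2 = per_class(0.02, 0.04, 0.04, 0.03, 0.005),
               phase1 = 6, phase2 = 2.5, noise_sd = 0.02,
               field_sd_mean = 0.05, field_sd_amp = 0.02),
    NDVI = list(mean = per_class(0.30, 0.55, 0.60, 0.65, 0.05),
                amp1 = per_class(0.12, 0.25, 0.27, 0.30, 0.02),
                amp2 = per_class(0.03, 0.05, 0.05, 0.04, 0.01),
                phase1 = 6, phase2 = 2.5, noise_sd = 0.03,
                field_sd_mean = 0.06, field_sd_amp = 0.03))
}

#' Generate a synthetic covariate stack over a landscape
#'
#' Produces the full predictor set emulated by the package: five monthly
#' seasonal signals over `years` whole years (MIR, DLST, NLST, EVI, NDVI),
#' and four static layers (DEM elevation in m, two annual precipitation
#' products in mm, and human population density in persons/km^2, zero on
#' water). Seasonal parameters depend on land cover and on smooth random
#' fields; see [default_seasonal_config()].
#'
#' @param landscape a [generate_landscape()] result.
#' @param years number of whole years of monthly data (>= 1).
#' @param seed integer seed.
#' @param seasonal_config optional override of [default_seasonal_config()].
#' @param field_sigma smoothing bandwidth (cells) of the parameter fields.
#' @return object of class `covariate_stack` with elements `static` (named
#'   list of matrices), `seasonal` (named list of `nrow x ncol x 12*years`
#'   arrays), `years`, and the shared geometry.
#' @export
generate_covariates <- function(landscape, years = 3, seed = 1L,
                                seasonal_config = default_seasonal_config(),
                                field_sigma = 4) {
  stopifnot(years >= 1)
  set.seed(as.integer(seed))
  nr <- nrow(landscape$values); nc <- ncol(landscape$values)
  cls <- landcover_names(landscape)
  nt <- 12L * as.integer(years)
  tt <- seq_len(nt) - 1L

  seasonal <- lapply(seasonal_config, function(cfg) {
    mu <- matrix(cfg$mean[cls], nr, nc) +
      cfg$field_sd_mean * random_field(nr, nc, field_sigma)
    a1 <- matrix(cfg$amp1[cls], nr, nc) +
      cfg$field_sd_amp * random_field(nr, nc, field_sigma)
    a1 <- pmax(a1, 0)
    a2 <- matrix(cfg$amp2[cls], nr, nc)
    arr <- array(0, dim = c(nr, nc, nt))
    for (k in seq_len(nt)) {
      det <- mu +
        a1 * cos(2 * pi * (tt[k] - cfg$phase1) / 12) +
        a2 * cos(4 * pi * (tt[k] - cfg$phase2) / 12)
      noise <- if (cfg$noise_sd > 0)
        matrix(stats::rnorm(nr * nc, sd = cfg$noise_sd), nr, nc) else 0
      arr[, , k] <- det + noise
    }
    arr
  })
  names(seasonal) <- names(seasonal_config)

  dem <- 20 + 80 * matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc) +
    15 * random_field(nr, nc, field_sigma)
  precip_wc <- 750 + 100 * random_field(nr, nc, field_sigma)
  precip_cm <- 800 + 120 * random_field(nr, nc, field_sigma)
  popbase <- c(urban = 1500, agricultural_sampled = 100,
               agricultural_excluded = 50, natural = 20, water = 0)
  pop <- matrix(popbase[cls], nr, nc) *
    exp(0.4 * random_field(nr, nc, field_sigma))
  pop[cls == "water"] <- 0

  structure(list(
    static = list(DEM = dem, WCPREC = precip_wc, CMPREC = precip_cm,
                  POPDEN = pop),
    seasonal = seasonal, years = as.integer(years),
    origin = landscape$origin, cell_size = landscape$cell_size),
    class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  d <- dim(x$seasonal[[1]])
  cat(sprintf("<covariate_stack> %d x %d cells, %d seasonal variables x %d months, %d static layers\n",
              d[1], d[2], length(x$seasonal), d[3], length(x$static)))
  invisible(x)
}

#' Define a known ("true") suitability model for synthetic surveys
#'
#' The truth is a logistic-linear model on named derived features (the
#' temporal-Fourier components and static layers produced by
#' [fourier_stack()]): `suitability = plogis(intercept + sum(beta * z))`
#' where `z` are the named features standardised over valid cells, so
#' coefficients are in SD units. Optionally, land-cover classes can be
#' forced to zero suitability (used for the unsuitable excluded class).
#'
#' @param beta named numeric vector of coefficients on derived features.
#' @param intercept scalar intercept on the logit scale.
#' @param zero_classes land-cover classes whose cells get suitability 0.
#' @return object of class `truth_model`.
#' @export
truth_model <- function(beta, intercept = 0,
                        zero_classes = "agricultural_excluded") {
  stopifnot(is.numeric(beta), !is.null(names(beta)), all(nzchar(names(beta))))
  structure(list(beta = beta, intercept = intercept,
                 zero_classes = zero_classes),
            class = "truth_model")
}

#' Evaluate the true suitability surface
#'
#' @param truth a [truth_model()].
#' @param features a feature stack from [fourier_stack()].
#' @param landscape the landscape (needed when `zero_classes` is non-empty).
#' @return an `env_grid` of suitabilities in (0, 1) (0 on zeroed classes).
#' @export
true_suitability <- function(truth, features, landscape = NULL) {
  missing <- setdiff(names(truth$beta), names(features$layers))
  if (length(missing))
    stop("truth features not in stack: ", paste(missing, collapse = ", "))
  lin <- matrix(truth$intercept, nrow(features$layers[[1]]),
                ncol(features$layers[[1]]))
  for (nm in names(truth$beta)) {
    v <- features$layers[[nm]]
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    lin <- lin + truth$beta[[nm]] * z
  }
  p <- stats::plogis(lin)
  if (length(truth$zero_classes) && !is.null(landscape))
    p[class_mask(landscape, truth$zero_classes)] <- 0
  env_grid(p, origin = features$origin, cell_size = features$cell_size)
}
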