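#' Names of the 14 temporal-Fourier seasonality components
#'
#' `A0` series mean; `MN`/`MX` raw series minimum/maximum; `A1`--`A3`
#' amplitudes of the annual, bi-annual and tri-annual cycles; `VR` total
#' (population) variance; `P1`--`P3` phases as month-of-peak in
#' `[0, 12/k)`; `D1`--`D3` the proportion of total variance due to each
#' cycle; `DA = D1 + D2 + D3`.
#'
#' @export
fourier_component_names <- function() {
  c("A0", "MN", "MX", "A1", "A2", "A3", "VR",
    "P1", "P2", "P3", "D1", "D2", "D3", "DA")
}

# cos/sin design matrix for harmonics 1..3 over n monthly steps
harmonic_design <- function(n) {
  t <- seq_len(n) - 1
  cbind(1,
        cos(2 * pi * t / 12), sin(2 * pi * t / 12),
        cos(4 * pi * t / 12), sin(4 * pi * t / 12),
        cos(6 * pi * t / 12), sin(6 * pi * t / 12))
}

#' Temporal Fourier components of a monthly series
#'
#' Decomposes a monthly environmental time series covering whole years into
#' the 14 seasonality summaries used as model features. The three harmonics
#' (periods 12, 6 and 4 months) are estimated by least squares of cosine and
#' sine terms, which coincides with the discrete Fourier transform when the
#' series length is a multiple of 12. Amplitude `Ak` and phase `Pk` come
#' from the coefficient pair `(a, b)` of `a*cos + b*sin`:
#' `Ak = sqrt(a^2 + b^2)` and `Pk = (atan2(b, a) / (2*pi)) * (12/k)` mapped
#' into `[0, 12/k)`, i.e. the month at which that cycle peaks. Variance
#' proportions use the Parseval identity: a harmonic of amplitude `A`
#' contributes `A^2/2` to the series variance, so `Dk = (Ak^2/2)/VR` with
#' `VR` the population variance of the raw series. A constant series has
#' `VR = 0` and all `Dk`, `DA` defined as 0.
#'
#' @param series numeric vector of monthly values, length a multiple of 12.
#' @param design optional precomputed [harmonic_design()] matrix (internal
#'   fast path for whole stacks).
#' @return named numeric vector over [fourier_component_names()].
#' @export
fourier_components <- function(series, design = NULL) {
  n <- length(series)
  if (n < 12 || n %% 12 != 0)
    stop("series length must be a positive multiple of 12, got ", n)
  if (!all(is.finite(series)))
    stop("series contains non-finite values; mask nodata upstream")
  if (is.null(design)) design <- harmonic_design(n)
  beta <- stats::.lm.fit(design, series)$coefficients
  a0 <- mean(series)
  vr <- sum((series - a0)^2) / n
  out <- numeric(14)
  names(out) <- fourier_component_names()
  out["A0"] <- a0
  out["MN"] <- min(series)
  out["MX"] <- max(series)
  out["VR"] <- vr
  for (k in 1:3) {
    a <- beta[2 * k]; b <- beta[2 * k + 1]
    amp <- sqrt(a^2 + b^2)
    period <- 12 / k
    phase <- (atan2(b, a) / (2 * pi)) * period
    out[paste0("A", k)] <- amp
    out[paste0("P", k)] <- phase %% period
    out[paste0("D", k)] <- if (vr > 0) (amp^2 / 2) / vr else 0
  }
  out["DA"] <- out["D1"] + out["D2"] + out["D3"]
  out
}

#' Feature stack: Fourier components of every seasonal variable
#'
#' Applies [fourier_components()] to the per-pixel monthly series of each
#' seasonal variable in a covariate stack and passes static layers through
#' unchanged. Layer naming is `<VAR>_<COMPONENT>` (e.g. `NDVI_A1`,
#' `NLST_P2`); with 5 seasonal variables and 4 static layers this yields
#' `5 * 14 + 4 = 74` feature rasters. A pixel with any missing month is
#' nodata in all 14 of that variable's components.
#'
#' @param covariates a [generate_covariates()]-shaped `covariate_stack`.
#' @return object of class `feature_stack`: named list of matrices
#'   (`$layers`) sharing the stack geometry.
#' @export
fourier_stack <- function(covariates) {
  if (is.null(covariates$seasonal) || length(covariates$seasonal) == 0L)
    stop("covariate stack has no seasonal layers")
  dims <- dim(covariates$seasonal[[1]])
  nr <- dims[1]; nc <- dims[2]
  layers <- list()
  for (vn in names(covariates$seasonal)) {
    arr <- covariates$seasonal[[vn]]
    if (!all(dim(arr)[1:2] == c(nr, nc)))
      stop("seasonal layer '", vn, "' does not share the stack geometry")
    nt <- dim(arr)[3]
    design <- harmonic_design(nt)
    m <- matrix(arr, nrow = nr * nc, ncol = nt)  # pixels x months
    comp <- matrix(NA_real_, nr * nc, 14)
    ok <- rowSums(!is.finite(m)) == 0L
    if (any(ok))
      comp[ok, ] <- t(apply(m[ok, , drop = FALSE], 1L, fourier_components,
                            design = design))
    for (j in seq_len(14))
      layers[[paste0(vn, "_", fourier_component_names()[j])]] <-
        matrix(comp[, j], nr, nc)
  }
  for (sn in names(covariates$static)) {
    s <- covariates$static[[sn]]
    if (!all(dim(s) == c(nr, nc)))
      stop("static layer '", sn, "' does not share the stack geometry")
    layers[[sn]] <- s
  }
  structure(list(layers = layers, origin = covariates$origin,
                 cell_size = covariates$cell_size),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d layers, %d x %d cells\n", length(x$layers),
              nrow(x$layers[[1]]), ncol(x$layers[[1]])))
  invisible(x)
}

#' Extract the feature matrix of a stack at given cells
#'
#' @param features a `feature_stack`.
#' @param cells 1-based linear (column-major) cell indices into the grids.
#' @return numeric matrix, one row per cell, one named column per layer.
#' @export
feature_matrix_at <- function(features, cells) {
  out <- vapply(features$layers, function(l) l[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, names(features$layers)))
  out
}

#' Write every layer of a feature stack as ESRI ASCII rasters
#'
#' @param features a `feature_stack`.
#' @param dir output directory (created if missing); files are
#'   `<LAYER>.asc`.
#' @export
write_feature_stack <- function(features, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(features$layers))
    write_asc(env_grid(features$layers[[nm]], features$origin,
                       features$cell_size),
              file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}
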