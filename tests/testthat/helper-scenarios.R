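# Shared synthetic scenarios for the test suite. Everything is generated
# in code under fixed seeds; no fixture files.

# Seasonal config with land-cover-neutral parameters, inflated month noise
# and stronger amplitude fields: every derived feature varies through its
# own independent smooth field, so a truth model on three named features
# really has exactly three identifiable drivers (min/max/variance
# components become noise-dominated instead of shadowing the mean and
# amplitude).
recovery_seasonal_config <- function() {
  cfg <- default_seasonal_config()
  for (v in names(cfg)) {
    cfg[[v]]$mean[] <- mean(cfg[[v]]$mean)
    cfg[[v]]$amp1[] <- mean(cfg[[v]]$amp1)
    cfg[[v]]$amp2[] <- mean(cfg[[v]]$amp2)
    cfg[[v]]$noise_sd <- cfg[[v]]$noise_sd * 5
    cfg[[v]]$field_sd_amp <- cfg[[v]]$field_sd_amp * 2
  }
  cfg
}

# landscape + covariates + features + survey + occurrence table in one call
make_world <- function(seed = 1L, width = 40L, height = 40L, years = 2L,
                       n_traps = 300L,
                       beta = c(NDVI_A1 = 1.5, DLST_A0 = 1.2, POPDEN = -1),
                       intercept = 0,
                       seasonal_config = default_seasonal_config(),
                       n_pseudo = 0L) {
  ls <- generate_landscape(width, height, seed = seed)
  cov <- generate_covariates(ls, years = years, seed = seed + 1000L,
                             seasonal_config = seasonal_config)
  fs <- fourier_stack(cov)
  truth <- truth_model(beta, intercept = intercept)
  st <- true_suitability(truth, fs, ls)
  sv <- simulate_survey(ls, n_traps = n_traps, seed = seed + 2000L,
                        suitability = st)
  pts <- dedup_cells(survey_to_points(sv), ls)
  if (n_pseudo > 0L)
    pts <- add_pseudo_absences(pts, ls, n = n_pseudo, seed = seed + 3000L)
  occ <- extract_features(pts, fs)
  list(landscape = ls, covariates = cov, features = fs, truth = truth,
       suitability = st, survey = sv, occurrence = occ)
}

# small iid-feature presence/absence table for model-machinery tests
toy_table <- function(n_presence, n_absence, p = 3L, seed = 1L,
                      beta = NULL) {
  set.seed(seed)
  n <- n_presence + n_absence
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  if (is.null(beta)) {
    y <- c(rep(1L, n_presence), rep(0L, n_absence))
  } else {
    y <- rbinom(n, 1L, plogis(drop(x %*% beta)))
  }
  df <- data.frame(point_id = seq_len(n), x = runif(n, 0, 10),
                   y = runif(n, 0, 10), presence = y, origin = "observed")
  df <- cbind(df, as.data.frame(x))
  attr(df, "feature_names") <- colnames(x)
  class(df) <- c("occurrence_table", "data.frame")
  df
}

# independent least-squares oracle for the harmonic components: explicit
# normal-equations fit of the 7-parameter model, amplitude/phase from the
# coefficient pairs, everything written out directly
fourier_oracle <- function(series) {
  n <- length(series)
  t <- seq_len(n) - 1
  X <- cbind(1, cos(2 * pi * t / 12), sin(2 * pi * t / 12),
             cos(4 * pi * t / 12), sin(4 * pi * t / 12),
             cos(6 * pi * t / 12), sin(6 * pi * t / 12))
  beta <- solve(t(X) %*% X, t(X) %*% series)
  m <- mean(series)
  vr <- mean((series - m)^2)
  out <- c(A0 = m, MN = min(series), MX = max(series))
  for (k in 1:3) {
    a <- beta[2 * k]; b <- beta[2 * k + 1]
    amp <- sqrt(a^2 + b^2)
    ph <- (atan2(b, a) / (2 * pi)) * (12 / k)
    out[paste0("A", k)] <- amp
    out[paste0("P", k)] <- ph %% (12 / k)
    out[paste0("D", k)] <- if (vr > 0) amp^2 / 2 / vr else 0
  }
  out["VR"] <- vr
  out["DA"] <- out["D1"] + out["D2"] + out["D3"]
  out[fourier_component_names()]
}

# circular difference for phase comparison (period of harmonic k is 12/k)
phase_diff <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# direct two-Gaussian posterior: plain density formula, no log tricks
qda_posterior_oracle <- function(x, mu1, S1, pi1, mu0, S0, pi0) {
  dens <- function(v, mu, S) {
    d <- length(mu)
    exp(-0.5 * t(v - mu) %*% solve(S) %*% (v - mu)) /
      sqrt((2 * pi)^d * det(S))
  }
  apply(x, 1L, function(v) {
    f1 <- pi1 * dens(v, mu1, S1)
    f0 <- pi0 * dens(v, mu0, S0)
    as.numeric(f1 / (f1 + f0))
  })
}
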