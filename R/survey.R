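#' Simulate a stratified one-visit trap survey
#'
#' Places traps uniformly at random within each land-cover stratum at the
#' configured proportions (largest-remainder rounding of `n_traps *
#' proportion`), one trap per cell, never in excluded or water cells. Each
#' trap is assigned a sampling week in 1..30 (an April--October season) and
#' a catch: presence is Bernoulli with the true suitability at the trap's
#' cell, and positive catches get a positive count (week and count carry no
#' further information once reclassified to presence/absence).
#'
#' @param landscape a [generate_landscape()] result.
#' @param covariates a [generate_covariates()] result (used to derive the
#'   suitability surface when `suitability` is not supplied).
#' @param truth a [truth_model()].
#' @param n_traps total number of traps.
#' @param strata_props named proportions over [sampleable_classes()]
#'   (default 40% urban, 40% agricultural, 20% natural).
#' @param seed integer seed.
#' @param suitability optional precomputed `env_grid` of true suitability
#'   (skips the Fourier feature computation).
#' @return a `data.frame` (class `trap_survey`) with columns
#'   `trap_id, x, y, stratum, week, abundance`.
#' @export
simulate_survey <- function(landscape, covariates = NULL, truth = NULL,
                            n_traps = 766,
                            strata_props = c(urban = 0.4,
                                             agricultural_sampled = 0.4,
                                             natural = 0.2),
                            seed = 1L, suitability = NULL) {
  stopifnot(abs(sum(strata_props) - 1) < 1e-6)
  if (is.null(suitability)) {
    feats <- fourier_stack(covariates)
    suitability <- true_suitability(truth, feats, landscape)
  }
  counts <- apportion_largest_remainder(n_traps, strata_props)
  cls <- landcover_names(landscape)
  nc <- ncol(landscape$values)
  set.seed(as.integer(seed))
  recs <- lapply(names(counts), function(st) {
    eligible <- which(cls == st)  # column-major linear indices
    if (length(eligible) == 0L)
      stop("no eligible cells in stratum '", st, "'")
    if (counts[[st]] > length(eligible))
      stop("stratum '", st, "' has ", length(eligible),
           " cells but needs ", counts[[st]], " traps")
    pick <- sample(eligible, counts[[st]])
    row0 <- (pick - 1L) %% nrow(cls)        # 0-based
    col0 <- (pick - 1L) %/% nrow(cls)
    ctr <- cell_center(row0, col0, landscape)
    data.frame(x = ctr$x, y = ctr$y, stratum = st,
               p = suitability$values[pick])
  })
  recs <- do.call(rbind, recs)
  n <- nrow(recs)
  recs$week <- sample.int(30L, n, replace = TRUE)
  pres <- stats::rbinom(n, 1L, recs$p)
  recs$abundance <- ifelse(pres == 1L, 1L + stats::rpois(n, 2), 0L)
  out <- data.frame(trap_id = seq_len(n), x = recs$x, y = recs$y,
                    stratum = recs$stratum, week = recs$week,
                    abundance = recs$abundance)
  class(out) <- c("trap_survey", "data.frame")
  out
}
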