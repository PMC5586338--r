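#' Time lag between two factor levels from a fitted model
#'
#' The lag in days (or GDD units, under the thermal clock) between levels i
#' and j of a factor is the difference in time at which half the strobili
#' at one level reach any given stage relative to the other, obtained from
#' the fitted coefficients as `(beta_j - beta_i) / beta_time`.  The
#' reference level's coefficient is exactly zero.  Lags are antisymmetric
#' (`lag(i, j) = -lag(j, i)`), additive across levels of a single fit, and
#' invariant both to the choice of reference level and to translating the
#' time covariate.
#'
#' @param fit a [fit_clm()] result.
#' @param level_i,level_j levels of `factor` to compare; a negative lag
#'   means level i reaches each stage earlier.
#' @param factor `"site"` or `"year"`.
#' @return lag in time-covariate units (days for the calendar clock).
#' @export
time_lag <- function(fit, level_i, level_j, factor = "site") {
  stopifnot(inherits(fit, "pheno_clm"))
  b_time <- fit$beta[[fit$design$time]]
  if (!is.finite(b_time) || abs(b_time) < 1e-10) {
    stop("time coefficient is numerically zero; lag undefined for a flat ",
         "time response")
  }
  bi <- level_coef(fit, factor, level_i)
  bj <- level_coef(fit, factor, level_j)
  (bj - bi) / b_time
}

level_coef <- function(fit, factor, level) {
  known <- fit$design$xlevels[[factor]]
  if (is.null(known)) stop("model has no '", factor, "' factor")
  level <- as.character(level)
  if (!level %in% known) {
    stop("unknown ", factor, " level '", level, "'")
  }
  if (level == known[1L]) return(0)
  fit$beta[[paste0(factor, level)]]
}

#' Penalized significance rule for a time-lag estimate
#'
#' Widens the bootstrap confidence interval by a fixed number of days on
#' each side — by default 3 days, the length of an individual tree's peak
#' pollen-shedding period — and flags the lag significant only when the
#' penalized interval excludes zero.  The penalty guards against within-site
#' variability that the interval alone was judged too narrow to absorb.
#'
#' @param estimate a `time_lag_estimate` (one row of a
#'   [pairwise_lag_table()], or a [bootstrap_lag_ci()] result).
#' @param penalty_days nonnegative penalty, days; default 3.
#' @return the estimate with `pen_lo`, `pen_hi`, `significant` filled in.
#' @export
penalized_significance <- function(estimate, penalty_days = 3) {
  if (penalty_days < 0) stop("penalty_days must be nonnegative")
  estimate$pen_lo <- estimate$ci_lo - penalty_days
  estimate$pen_hi <- estimate$ci_hi + penalty_days
  estimate$significant <- estimate$pen_lo > 0 | estimate$pen_hi < 0
  estimate
}

# Cluster-bootstrap engine: resample trees with replacement within each
# site, re-weight the aggregated design, refit warm-started from the
# full-data optimum, and evaluate all requested pairwise lags per replicate.
# Returns a replicate x pair matrix (NA rows = dropped replicates).
boot_lags <- function(design, fit, pairs, factor, n_boot, seed) {
  set.seed(as.integer(seed))
  K <- design$K
  P <- nrow(design$X)
  by_site <- split(seq_along(design$tree_site), design$tree_site)
  if (any(lengths(by_site) < 2L)) {
    stop("cluster bootstrap needs at least 2 trees per site")
  }
  warm <- c(theta_to_z(fit$thresholds), fit$beta)
  out <- matrix(NA_real_, n_boot, nrow(pairs))
  n_failed <- 0L
  for (r in seq_len(n_boot)) {
    idx <- unlist(lapply(by_site, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
    Wb <- matrix(colSums(design$tree_counts[idx, , drop = FALSE]),
                 P, K, byrow = TRUE)
    bdes <- design
    bdes$W <- Wb
    lag_r <- tryCatch({
      bfit <- suppressWarnings(
        fit_clm(bdes, control = list(start = warm, maxit = 200L,
                                     polish = FALSE)))
      if (!bfit$converged) stop("no convergence")
      vapply(seq_len(nrow(pairs)), function(p) {
        time_lag(bfit, pairs$level_i[p], pairs$level_j[p], factor)
      }, numeric(1))
    }, error = function(e) NULL)
    if (is.null(lag_r) || any(!is.finite(lag_r))) {
      n_failed <- n_failed + 1L
    } else {
      out[r, ] <- lag_r
    }
  }
  if (n_failed > 0.2 * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap replicates failed; ",
         "estimates unreliable")
  }
  attr(out, "n_failed") <- n_failed
  out
}

#' Bootstrap confidence interval for one pairwise time lag
#'
#' Fits the model, then resamples trees (the dependence clusters) with
#' replacement within each site, refits per replicate, and recomputes the
#' lag; the CI is the 2.5/97.5 percentile interval of the replicate lags.
#' Replicates that fail to converge or produce a degenerate design are
#' dropped and counted (more than 20% failures is an error).  Reproducible
#' under a fixed seed.  The penalized significance rule is applied to the
#' resulting interval.
#'
#' @param survey a [phenology_survey()].
#' @param spec a [clm_spec()].
#' @param level_i,level_j factor levels to compare.
#' @param n_boot bootstrap replicates (>= 100); default 1000.
#' @param seed integer RNG seed.
#' @param factor `"site"` or `"year"`.
#' @param penalty_days penalty for the significance rule, days.
#' @return a one-row `time_lag_estimate` data frame with columns `level_i`,
#'   `level_j`, `lag`, `ci_lo`, `ci_hi`, `pen_lo`, `pen_hi`, `significant`,
#'   `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_lag_ci <- function(survey, spec, level_i, level_j,
                             n_boot = 1000L, seed, factor = "site",
                             penalty_days = 3) {
  if (n_boot < 100L) stop("n_boot must be at least 100")
  design <- build_design(survey, spec)
  fit <- fit_clm(design)
  pairs <- data.frame(level_i = as.character(level_i),
                      level_j = as.character(level_j),
                      stringsAsFactors = FALSE)
  reps <- boot_lags(design, fit, pairs, factor, n_boot, seed)
  make_lag_estimates(fit, pairs, reps, factor, n_boot, seed, penalty_days)
}

make_lag_estimates <- function(fit, pairs, reps, factor, n_boot, seed,
                               penalty_days) {
  est <- data.frame(level_i = pairs$level_i, level_j = pairs$level_j,
                    lag = vapply(seq_len(nrow(pairs)), function(p) {
                      time_lag(fit, pairs$level_i[p], pairs$level_j[p],
                               factor)
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  qs <- apply(reps, 2L, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  est$ci_lo <- qs[1L, ]
  est$ci_hi <- qs[2L, ]
  est$n_boot <- n_boot
  est$n_failed <- attr(reps, "n_failed")
  est$seed <- as.integer(seed)
  est <- penalized_significance(est, penalty_days)
  class(est) <- c("time_lag_estimate", "data.frame")
  est[c("level_i", "level_j", "lag", "ci_lo", "ci_hi", "pen_lo", "pen_hi",
        "significant", "n_boot", "n_failed", "seed")]
}

#' Pairwise time-lag table
#'
#' Estimates the lag for every unordered pair of levels of the comparison
#' factor from a single fit, with one shared cluster-bootstrap run (each
#' replicate refits once and evaluates all pairs).  Point estimates are
#' exactly antisymmetric and additive because they derive from one
#' coefficient vector.  For between-year lags, fit the pooled model on the
#' sites observed in all years (`clm_spec(factors = c("site", "year"),
#' interaction = TRUE)`) and compare with `factor = "year"`.
#'
#' @inheritParams bootstrap_lag_ci
#' @return a `time_lag_estimate` data frame, one row per unordered pair.
#' @export
pairwise_lag_table <- function(survey, spec, n_boot = 1000L, seed,
                               factor = "site", penalty_days = 3) {
  if (n_boot < 100L) stop("n_boot must be at least 100")
  design <- build_design(survey, spec)
  fit <- fit_clm(design)
  levs <- design$xlevels[[factor]]
  if (is.null(levs) || length(levs) < 2L) {
    stop("need at least 2 levels of '", factor, "' to compare")
  }
  cmb <- utils::combn(levs, 2L)
  pairs <- data.frame(level_i = cmb[1L, ], level_j = cmb[2L, ],
                      stringsAsFactors = FALSE)
  reps <- boot_lags(design, fit, pairs, factor, n_boot, seed)
  make_lag_estimates(fit, pairs, reps, factor, n_boot, seed, penalty_days)
}
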