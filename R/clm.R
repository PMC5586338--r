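#' Specify a cumulative link model for strobilus scores
#'
#' Defines the response/covariate structure of a proportional-odds
#' cumulative link model (logit link): ordinal stage scores 1-7 regressed
#' on a continuous time covariate (calendar day from May 1, or accumulated
#' growing degree days) plus categorical site and/or year terms with
#' treatment (reference-level) coding.  A common slope is shared by all
#' stages: differences between factor levels are the same at every response
#' level, which is what makes coefficient-ratio time lags well defined.
#'
#' @param time `"day"` or `"gdd"` — the continuous development clock — or
#'   `"none"` for an intercept-only (thresholds-only) model.
#' @param factors character subset of `c("site", "year")`.
#' @param interaction logical; include the site-by-year interaction.  Only
#'   meaningful when both factors are present, and requires every site to be
#'   observed in every year of the data (else the design is rank deficient
#'   and fitting refuses with an explicit error).
#' @param reference named list of baseline levels per factor; default is the
#'   alphabetically first level.  Time lags are invariant to this choice.
#' @param sites,years optional filters applied to the survey before coding.
#' @return an object of class `clm_spec`.
#' @seealso [fit_clm()], [build_design()]
#' @export
clm_spec <- function(time = c("day", "gdd", "none"), factors = "site",
                     interaction = FALSE, reference = list(),
                     sites = NULL, years = NULL) {
  time <- match.arg(time)
  factors <- match.arg(factors, c("site", "year"), several.ok = TRUE)
  if (interaction && !all(c("site", "year") %in% factors)) {
    stop("interaction requires both site and year factors")
  }
  structure(list(time = time, factors = factors, interaction = interaction,
                 reference = reference, sites = sites, years = years),
            class = "clm_spec")
}

#' Build the design for a cumulative link model fit
#'
#' Applies the spec's subset, codes the factors with treatment contrasts,
#' and checks the design for rank deficiency.  When the site-by-year
#' interaction is requested on data whose site-year coverage is unbalanced
#' (some sites never observed in some years), the design is rank deficient
#' and an explicit error tells the caller to drop the interaction or
#' restrict to the sites visited in all years.
#'
#' For speed the design is aggregated: observations sharing a covariate
#' pattern (same time value and factor levels) and category are collapsed
#' into weighted cells.  Tree-level cell counts are kept so the cluster
#' bootstrap can re-weight cells without rebuilding the design.
#'
#' @param survey a [phenology_survey()] (for `time = "gdd"`, one carrying a
#'   `gdd` column from [attach_gdd()]).
#' @param spec a [clm_spec()].
#' @return an object of class `clm_design`.
#' @export
build_design <- function(survey, spec) {
  stopifnot(inherits(spec, "clm_spec"))
  d <- as.data.frame(survey)
  if (!is.null(spec$sites)) d <- d[d$site %in% spec$sites, , drop = FALSE]
  if (!is.null(spec$years)) d <- d[d$year %in% spec$years, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty subset: no observations match the spec")
  if (spec$time == "gdd" && is.null(d$gdd)) {
    stop("spec uses the GDD clock but the survey has no 'gdd' column; ",
         "run attach_gdd() first")
  }
  tvar <- switch(spec$time, gdd = d$gdd, day = d$day, none = NULL)

  xlevels <- list()
  fvars <- list()
  for (f in spec$factors) {
    lev <- sort(unique(as.character(d[[f]])))
    ref <- spec$reference[[f]]
    if (!is.null(ref)) {
      if (!ref %in% lev) stop("reference level '", ref,
                              "' not present in factor ", f)
      lev <- c(ref, setdiff(lev, ref))
    }
    xlevels[[f]] <- lev
    fvars[[f]] <- factor(as.character(d[[f]]), levels = lev)
  }

  mf <- data.frame(row.names = seq_len(nrow(d)))
  if (!is.null(tvar)) mf$..time <- tvar
  for (f in names(fvars)) mf[[f]] <- fvars[[f]]
  rhs <- c(if (!is.null(tvar)) "..time",
           spec$factors[vapply(spec$factors,
                               function(f) nlevels(fvars[[f]]) > 1L,
                               logical(1))])
  if (spec$interaction) rhs <- c(rhs, "site:year")
  if (length(rhs) == 0L) rhs <- "1"
  form <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  X <- stats::model.matrix(form, mf)
  qr_rank <- qr(X)$rank
  if (qr_rank < ncol(X)) {
    if (spec$interaction) {
      stop("design is rank deficient: site-year coverage is unbalanced, ",
           "so the site x year interaction is not estimable; drop the ",
           "interaction or restrict to the sites visited in all years")
    }
    stop("design is rank deficient (rank ", qr_rank, " < ", ncol(X),
         " columns)")
  }
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  colnames(X) <- sub("^\\.\\.time$", spec$time, colnames(X))

  # collapse to observed response levels so empty top/bottom stages do not
  # push their thresholds to infinity; threshold names keep original stages
  score_levels <- sort(unique(as.integer(d$score)))
  K <- length(score_levels)
  if (K < 2L) stop("response has a single observed level; nothing to fit")
  score <- match(as.integer(d$score), score_levels)
  key <- if (ncol(X) > 0L) {
    do.call(paste, c(as.data.frame(X), list(sep = "\r")))
  } else {
    rep("", nrow(X))
  }
  upos <- which(!duplicated(key))
  pid <- match(key, key[upos])
  P <- length(upos)
  Xu <- X[upos, , drop = FALSE]
  W <- matrix(0, P, K)
  tab <- table(factor(pid, levels = seq_len(P)),
               factor(score, levels = seq_len(K)))
  W[] <- as.numeric(tab)

  # per-tree cell counts for the cluster bootstrap: cell = (pattern, category)
  tree_key <- paste(d$site, d$tree, sep = "\r")
  utrees <- which(!duplicated(tree_key))
  tid <- match(tree_key, tree_key[utrees])
  cell <- (pid - 1L) * K + score
  C <- matrix(0, length(utrees), P * K)
  ctab <- table(factor(tid, levels = seq_along(utrees)),
                factor(cell, levels = seq_len(P * K)))
  C[] <- as.numeric(ctab)

  structure(list(X = Xu, W = W, K = K, score_levels = score_levels,
                 n_obs = nrow(d),
                 coef_names = colnames(Xu), formula = form,
                 time = spec$time, xlevels = xlevels, spec = spec,
                 tree_counts = C,
                 tree_site = d$site[utrees],
                 tree_id = d$tree[utrees],
                 score_range_by_level = factor_score_ranges(d, spec$factors)),
            class = "clm_design")
}

# min/max observed category per factor level, for separation warnings
factor_score_ranges <- function(d, factors) {
  out <- list()
  for (f in factors) {
    rng <- tapply(d$score, d[[f]], range)
    out[[f]] <- rng
  }
  out
}

#' Negative log-likelihood of a cumulative link model
#'
#' For observation with score x and linear predictor eta, the category
#' probability is `plogis(theta[x] - eta) - plogis(theta[x-1] - eta)` with
#' `theta[0] = -Inf` and `theta[7] = +Inf`; the NLL is minus the sum of log
#' category probabilities (cells weighted by their observation counts).
#'
#' @param thresholds strictly increasing numeric vector of length 6 (logit
#'   units); non-increasing input is a domain error.
#' @param beta coefficient vector matching `design$coef_names`.
#' @param design a [build_design()] result.
#' @return the scalar negative log-likelihood.
#' @export
clm_nll <- function(thresholds, beta, design) {
  stopifnot(inherits(design, "clm_design"))
  if (length(thresholds) != design$K - 1L) {
    stop("expected ", design$K - 1L, " thresholds")
  }
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  nll_cells(thresholds, beta, design$X, design$W)
}

# Cell probabilities: stable evaluation of F(a) - F(b) for a > b under the
# logistic CDF, switching to the survival form when both arguments are
# positive to avoid cancellation.
cell_probs <- function(thresholds, beta, X) {
  K <- length(thresholds) + 1L
  eta <- if (length(beta) > 0L) drop(X %*% beta) else rep(0, nrow(X))
  A <- matrix(c(thresholds, Inf), nrow(X), K, byrow = TRUE) - eta
  B <- matrix(c(-Inf, thresholds), nrow(X), K, byrow = TRUE) - eta
  lower <- stats::plogis(A) - stats::plogis(B)
  upper <- stats::plogis(B, lower.tail = FALSE) -
    stats::plogis(A, lower.tail = FALSE)
  use_upper <- B > 0
  lower[use_upper] <- upper[use_upper]
  list(PI = lower, A = A, B = B)
}

nll_cells <- function(thresholds, beta, X, W) {
  pr <- cell_probs(thresholds, beta, X)
  -sum(W * log(pmax(pr$PI, 1e-300)))
}

# Analytic gradient of nll_cells with respect to (thresholds, beta).
nll_grad_cells <- function(thresholds, beta, X, W) {
  K <- length(thresholds) + 1L
  pr <- cell_probs(thresholds, beta, X)
  PI <- pmax(pr$PI, 1e-300)
  fa <- stats::dlogis(pr$A)
  fb <- stats::dlogis(pr$B)
  fa[!is.finite(pr$A)] <- 0
  fb[!is.finite(pr$B)] <- 0
  R1 <- W * fa / PI   # d/d theta at the upper cut
  R2 <- W * fb / PI   # d/d theta at the lower cut
  g_theta <- -(colSums(R1)[seq_len(K - 1L)] - colSums(R2)[2:K])
  g_eta <- rowSums(R1 - R2)  # dNLL/d eta per pattern
  g_beta <- if (length(beta) > 0L) drop(crossprod(X, g_eta)) else numeric()
  c(g_theta, g_beta)
}

# threshold reparametrization: z -> theta with theta_1 = z_1 and
# log-increments thereafter, guaranteeing strict ordering during search
z_to_theta <- function(z, K) {
  if (K == 2L) return(z[1L])
  cumsum(c(z[1L], exp(z[2:(K - 1L)])))
}

theta_to_z <- function(theta) {
  c(theta[1L], log(diff(theta)))
}

#' Fit a cumulative link model by maximum likelihood
#'
#' Maximizes the proportional-odds likelihood with thresholds parametrized
#' as the first cutpoint plus log-increments (so ordering is enforced by
#' construction), using BFGS with the analytic gradient.  Thresholds are
#' initialized at the logits of the pooled empirical cumulative proportions
#' and slopes at zero.  The coefficient covariance is the inverse of the
#' observed information, numerically differentiated at the optimum on the
#' direct (threshold, slope) scale.
#'
#' @param survey a [phenology_survey()] or a prebuilt [build_design()].
#' @param spec a [clm_spec()]; ignored when `survey` is already a design.
#' @param control list of optimizer controls: `maxit` (default 500),
#'   `reltol` (default 1e-10), `start` (optional warm-start parameter vector
#'   on the internal scale), `polish` (`FALSE` skips the Newton refinement
#'   after BFGS; used by the bootstrap, where percentile ends do not need
#'   machine-tight coefficients).
#' @return an object of class `pheno_clm` with elements `thresholds`
#'   (named `1|2` .. `6|7`), `beta`, `coefficients`, `vcov`, `logLik`,
#'   `n_obs`, `converged`, `design`.
#' @examples
#' p <- simulation_params(sites = c(A = 0, B = 6), years = c(`2015` = 0),
#'                        n_trees = 8)
#' fit <- fit_clm(simulate_survey(p, seed = 42), clm_spec())
#' coef(fit)
#' @export
fit_clm <- function(survey, spec = clm_spec(), control = list()) {
  design <- if (inherits(survey, "clm_design")) survey
            else build_design(survey, spec)
  maxit <- control$maxit %||% 500L
  reltol <- control$reltol %||% 1e-10
  K <- design$K
  q <- length(design$coef_names)

  if (is.null(control$start)) {
    tot <- colSums(design$W)
    cum <- cumsum(tot + 0.5)[seq_len(K - 1L)] / (sum(tot) + 0.5 * K)
    theta0 <- stats::qlogis(cum)
    theta0 <- cummax_strict(theta0)
    par0 <- c(theta_to_z(theta0), rep(0, q))
  } else {
    par0 <- control$start
  }

  fn <- function(p) {
    nll_cells(z_to_theta(p[seq_len(K - 1L)], K), p[-seq_len(K - 1L)],
              design$X, design$W)
  }
  gr <- function(p) {
    z <- p[seq_len(K - 1L)]
    theta <- z_to_theta(z, K)
    g <- nll_grad_cells(theta, p[-seq_len(K - 1L)], design$X, design$W)
    g_theta <- g[seq_len(K - 1L)]
    # chain rule through the log-increment map
    rev_cum <- rev(cumsum(rev(g_theta)))
    gz <- c(rev_cum[1L], rev_cum[-1L] * exp(z[-1L]))
    c(gz, g[-seq_len(K - 1L)])
  }
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  # Newton polish: BFGS stops on function-value change, which leaves
  # coefficients at ~1e-3 precision; a couple of damped Newton steps push
  # the gradient to machine-level zero so derived quantities (lags) are
  # reproducible to 1e-6 under reparametrizations
  n_polish <- if (isFALSE(control$polish)) 0L else 5L
  for (step in seq_len(n_polish)) {
    g <- gr(opt$par)
    if (max(abs(g)) < 1e-8) break
    H <- tryCatch(stats::optimHess(opt$par, fn, gr),
                  error = function(e) NULL)
    if (is.null(H)) break
    dir <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(dir) || any(!is.finite(dir))) break
    alpha <- 1
    improved <- FALSE
    for (half in 1:6) {
      cand <- opt$par - alpha * dir
      v <- fn(cand)
      if (is.finite(v) && v <= opt$value) {
        opt$par <- cand
        opt$value <- v
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
  }
  converged <- opt$convergence == 0L
  if (!converged) {
    warning("cumulative link fit did not converge within ", maxit,
            " iterations")
  }
  theta <- z_to_theta(opt$par[seq_len(K - 1L)], K)
  beta <- opt$par[-seq_len(K - 1L)]
  lev <- design$score_levels
  names(theta) <- paste(lev[-K], lev[-1L], sep = "|")
  names(beta) <- design$coef_names

  warn_separation(design)

  vc <- clm_vcov(theta, beta, design)
  structure(list(thresholds = theta, beta = beta,
                 coefficients = c(theta, beta), vcov = vc,
                 logLik = -opt$value, n_obs = design$n_obs,
                 converged = converged, design = design,
                 spec = design$spec),
            class = "pheno_clm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# enforce strict increase on initial thresholds built from (possibly tied)
# empirical cumulative proportions
cummax_strict <- function(x, eps = 1e-3) {
  for (i in seq_along(x)[-1L]) {
    if (x[i] <= x[i - 1L]) x[i] <- x[i - 1L] + eps
  }
  x
}

warn_separation <- function(design) {
  ext <- range(design$score_levels)
  for (f in names(design$score_range_by_level)) {
    rng <- design$score_range_by_level[[f]]
    for (lev in names(rng)) {
      r <- rng[[lev]]
      if (r[1L] == r[2L] && r[1L] %in% ext) {
        warning("possible complete separation: ", f, " level '", lev,
                "' observed only at extreme category ", r[1L])
      }
    }
  }
}

clm_vcov <- function(theta, beta, design) {
  par <- c(theta, beta)
  k <- length(theta)
  fn <- function(p) nll_cells(p[seq_len(k)], p[-seq_len(k)],
                              design$X, design$W)
  gr <- function(p) nll_grad_cells(p[seq_len(k)], p[-seq_len(k)],
                                   design$X, design$W)
  H <- tryCatch(stats::optimHess(par, fn, gr), error = function(e) NULL)
  vc <- if (is.null(H)) NULL else tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc)) {
    vc <- matrix(NA_real_, length(par), length(par))
  }
  dimnames(vc) <- list(names(c(theta, beta)), names(c(theta, beta)))
  vc
}

#' @export
print.pheno_clm <- function(x, ...) {
  cat("Cumulative link model (logit link), ", x$n_obs, " observations\n",
      sep = "")
  cat("log-likelihood: ", format(x$logLik, digits = 6),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("\nThresholds:\n")
  print(round(x$thresholds, 4))
  cat("\nCoefficients:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.pheno_clm <- function(object, ...) object$coefficients

#' @export
vcov.pheno_clm <- function(object, ...) object$vcov

#' @export
logLik.pheno_clm <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

# linear predictor at covariate points (time values + one set of factor
# levels), rebuilt through the stored design formula; errors on unseen levels
clm_eta <- function(fit, time, levels = list()) {
  design <- fit$design
  mf <- data.frame(..time = time)
  for (f in names(design$xlevels)) {
    lev <- levels[[f]]
    if (is.null(lev)) stop("factor level for '", f, "' must be supplied")
    lev <- as.character(lev)
    known <- design$xlevels[[f]]
    if (!lev %in% known) {
      stop("unknown ", f, " level '", lev, "' (model knows: ",
           paste(known, collapse = ", "), ")")
    }
    mf[[f]] <- factor(lev, levels = known)
  }
  X <- stats::model.matrix(design$formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  colnames(X) <- sub("^\\.\\.time$", design$time, colnames(X))
  unname(drop(X[, names(fit$beta), drop = FALSE] %*% fit$beta))
}

#' Exceedance probability from a fitted cumulative link model
#'
#' Probability that a strobilus has minimally reached a given stage,
#' `P(score >= stage) = 1 - plogis(theta[stage - 1] - eta)`, at a covariate
#' point.  With a positive time slope this is nondecreasing in the time
#' covariate — the modelled developmental progress curve (stage 5 gives the
#' peak-pollen-shedding curve).
#'
#' @param fit a [fit_clm()] result.
#' @param time numeric vector of time-covariate values (day or GDD,
#'   matching the fitted spec).
#' @param levels named list of factor levels, e.g.
#'   `list(site = "BE", year = "2014")`; unseen levels are an error, not an
#'   extrapolation.
#' @param stage integer in 2..7; a stage above every observed level gives
#'   probability 0, at or below the lowest observed level probability 1.
#' @return numeric vector of probabilities, one per `time` value.
#' @export
predict_exceedance <- function(fit, time, levels = list(), stage = 5L) {
  stopifnot(inherits(fit, "pheno_clm"))
  stage <- as.integer(stage)
  if (stage < 2L || stage > 7L) stop("stage must be between 2 and 7")
  eta <- clm_eta(fit, time, levels)
  idx <- which(fit$design$score_levels >= stage)[1L]
  if (is.na(idx)) return(rep(0, length(time)))
  if (idx == 1L) return(rep(1, length(time)))
  unname(stats::plogis(fit$thresholds[[idx - 1L]] - eta,
                       lower.tail = FALSE))
}

#' Category probabilities from a fitted cumulative link model
#'
#' Probability mass over all seven stages at one covariate point; the
#' masses sum to one.
#'
#' @inheritParams predict_exceedance
#' @return numeric matrix, one row per `time` value, one column per stage.
#' @export
predict_categories <- function(fit, time, levels = list()) {
  stopifnot(inherits(fit, "pheno_clm"))
  eta <- clm_eta(fit, time, levels)
  K <- fit$design$K
  cum <- stats::plogis(outer(eta, c(fit$thresholds, Inf), function(e, th) th - e))
  pr <- cbind(cum[, 1L, drop = FALSE], cum[, -1L, drop = FALSE] -
                cum[, -K, drop = FALSE])
  colnames(pr) <- fit$design$score_levels
  pr
}
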