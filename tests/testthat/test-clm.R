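test_that("treatment coding gives one column per non-reference level plus the slope", {
  sv <- sim_small(sites = c(AC = 0, BE = 6, RM = 3), n_trees = 3, seed = 2)
  des <- build_design(sv, clm_spec())
  expect_equal(des$coef_names, c("day", "siteBE", "siteRM"))
  des2 <- build_design(sv, clm_spec(reference = list(site = "RM")))
  expect_equal(des2$coef_names, c("day", "siteAC", "siteBE"))
  expect_error(build_design(sv, clm_spec(sites = "ZZ")), "empty subset")
})

test_that("unbalanced site-year coverage makes the interaction design rank deficient", {
  common <- sim_small(sites = c(AC = 0, BE = 8, RM = 4),
                      years = c(`2014` = 0, `2015` = -3, `2016` = 2),
                      n_trees = 4, seed = 5)
  extra14 <- sim_small(sites = c(BL = 6), years = c(`2014` = 0),
                       n_trees = 4, seed = 6)
  extra15 <- sim_small(sites = c(LD = 2), years = c(`2015` = -3),
                       n_trees = 4, seed = 7)
  cols <- c("site", "tree", "date", "score", "replicate")
  full <- phenology_survey(rbind(as.data.frame(common)[cols],
                                 as.data.frame(extra14)[cols],
                                 as.data.frame(extra15)[cols]))
  spec_int <- clm_spec(factors = c("site", "year"), interaction = TRUE)
  expect_error(build_design(full, spec_int), "rank deficient")
  # restricting to the fully crossed sites restores a full-rank design
  spec_sub <- clm_spec(factors = c("site", "year"), interaction = TRUE,
                       sites = c("AC", "BE", "RM"))
  des <- build_design(full, spec_sub)
  expect_s3_class(fit_clm(des), "pheno_clm")
})

test_that("the likelihood matches hand values and refuses unordered thresholds", {
  # one observation at stage 1 of a symmetric two-level split contributes
  # exactly log 2 at theta_1 = 0, eta = 0
  expect_equal(brute_nll(0, numeric(0), matrix(0, 1, 0), 1L), log(2))
  sv <- balanced_survey(1)  # all 7 stages observed
  des <- build_design(sv, clm_spec(time = "none"))
  theta <- c(0, 1, 2, 3, 4, 5)
  expect_equal(clm_nll(theta, numeric(0), des),
               brute_nll(theta, numeric(0), matrix(0, nrow(sv), 0),
                         sv$score))
  expect_error(clm_nll(c(0, 0, 1, 2, 3, 4), numeric(0), des),
               "strictly increasing")
})

test_that("the likelihood agrees with the brute-force evaluator on random instances", {
  set.seed(99)
  worst <- 0
  for (i in 1:100) {
    n_sites <- sample(2:3, 1)
    sites <- LETTERS[1:n_sites]
    n <- sample(30:60, 1)
    d <- data.frame(site = rep(sites, length.out = n),
                    tree = sprintf("t%03d", 1:n),
                    day = sample(1:61, n, replace = TRUE),
                    replicate = 1L)
    d$day[seq_len(2 * n_sites)] <- rep(c(3L, 59L), each = n_sites)
    d$score <- c(1:7, sample(1:7, n - 7, replace = TRUE))
    d$date <- as.Date("2014-05-01") + d$day - 1
    theta <- sort(rnorm(6, sd = 2))
    while (any(diff(theta) < 1e-3)) theta <- sort(rnorm(6, sd = 2))
    beta <- c(rnorm(1, sd = 0.03), rnorm(n_sites - 1))  # day slope + site contrasts
    X <- cbind(d$day,
               sapply(sites[-1], function(s) as.numeric(d$site == s)))
    sv <- phenology_survey(d[c("site", "tree", "date", "score", "replicate")])
    des <- build_design(sv, clm_spec())
    worst <- max(worst, abs(clm_nll(theta, beta, des) -
                              brute_nll(theta, beta, X, d$score)))
  }
  expect_lt(worst, 1e-10)
})

test_that("intercept-only fit on balanced counts recovers logit cumulative proportions", {
  fit <- fit_clm(balanced_survey(10), clm_spec(time = "none"))
  expect_true(fit$converged)
  expect_equal(unname(fit$thresholds), qlogis((1:6) / 7), tolerance = 1e-6)
})

test_that("two-category data reduces exactly to binary logistic regression", {
  set.seed(31)
  d <- data.frame(site = "A", tree = rep(sprintf("T%02d", 1:20), each = 10),
                  date = rep(seq(as.Date("2014-05-02"), by = 6,
                                 length.out = 10), 20),
                  replicate = 1L)
  eta <- 0.25 * (day_from_may1(d$date) - 30)
  d$score <- ifelse(runif(nrow(d)) < plogis(eta), 5L, 1L)
  sv <- phenology_survey(d)
  fit <- fit_clm(sv, clm_spec())
  ref <- stats::glm(I(score == 5) ~ day, data = as.data.frame(sv),
                    family = binomial)
  expect_equal(fit$beta[["day"]], unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(unname(fit$thresholds), unname(-coef(ref)[1]),
               tolerance = 1e-6)
})

test_that("fits agree with an independent proportional-odds implementation", {
  skip_if_not_installed("MASS")
  sv <- sim_small(sites = c(AC = 0, BE = 10, RM = 4),
                  years = c(`2014` = 0, `2015` = -3), n_trees = 8, seed = 13)
  fit <- fit_clm(sv, clm_spec(factors = c("site", "year")))
  d <- as.data.frame(sv)
  ref <- MASS::polr(factor(score) ~ day + site + factor(year), data = d)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-3)
  expect_equal(unname(fit$thresholds), unname(ref$zeta), tolerance = 1e-3)
  expect_gte(fit$logLik, as.numeric(logLik(ref)) - 1e-4)
})

test_that("translating the day covariate shifts thresholds, not the slope", {
  sv <- sim_small(n_trees = 5, seed = 17)
  fit <- fit_clm(sv, clm_spec())
  sv2 <- sv
  sv2$day <- sv2$day + 10L
  fit2 <- fit_clm(sv2, clm_spec())
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-6)
  expect_equal(unname(fit2$thresholds - fit$thresholds),
               rep(10 * fit$beta[["day"]], 6), tolerance = 1e-5)
})

test_that("the slope is recovered within 3 SE at large n", {
  p <- simulation_params(sites = c(A = 0, B = 6), years = c(`2014` = 0),
                         n_trees = 60, tree_sd = 0)
  for (seed in c(101, 202, 303)) {
    fit <- fit_clm(simulate_survey(p, seed), clm_spec())
    se <- sqrt(fit$vcov["day", "day"])
    expect_lt(abs(fit$beta[["day"]] - 0.3), 3 * se)
  }
})

test_that("the optimum dominates the generating parameters (MLE property)", {
  for (seed in 1:5) {
    p <- simulation_params(sites = c(A = 0, B = 6), years = c(`2014` = 0),
                           n_trees = 10, tree_sd = 0)
    sv <- simulate_survey(p, seed)
    des <- build_design(sv, clm_spec())
    fit <- fit_clm(des)
    nll_true <- clm_nll(p$thresholds, c(0.3, 0.3 * 6), des)
    expect_lte(-fit$logLik, nll_true + 1e-8)
  }
})

test_that("exceedance predictions behave like a proportional-odds model", {
  sv <- sim_small(n_trees = 8, seed = 23)
  fit <- fit_clm(sv, clm_spec())
  # logistic midpoint: eta equal to a threshold gives probability one half
  day_half <- fit$thresholds[[4]] / fit$beta[["day"]]
  expect_equal(predict_exceedance(fit, day_half, list(site = "AC"), 5), 0.5)
  # limits and monotonicity in time
  days <- seq(-50, 200, by = 5)
  pr <- predict_exceedance(fit, days, list(site = "AC"), 5)
  expect_true(all(diff(pr) >= 0))
  expect_gt(predict_exceedance(fit, 1e4, list(site = "AC"), 5), 1 - 1e-10)
  # category masses sum to one; cumulative curves never cross across stages
  pm <- predict_categories(fit, c(10, 30, 50), list(site = "BE"))
  expect_equal(rowSums(pm), rep(1, 3))
  exc <- sapply(2:7, function(s)
    predict_exceedance(fit, 30, list(site = "BE"), s))
  expect_true(all(diff(exc) <= 0))
  expect_error(predict_exceedance(fit, 30, list(site = "XX"), 5),
               "unknown site level")
})

test_that("a factor level stuck at one extreme category triggers a separation warning", {
  d <- rbind(
    data.frame(site = "A", tree = rep(sprintf("a%d", 1:4), each = 2),
               date = rep(c("2014-05-05", "2014-06-05"), 4),
               score = rep(c(2L, 6L), 4), replicate = 1L),
    data.frame(site = "B", tree = rep(sprintf("b%d", 1:4), each = 2),
               date = rep(c("2014-05-05", "2014-06-05"), 4),
               score = 7L, replicate = 1L))
  sv <- phenology_survey(d)
  # a separated fit may also warn about convergence; look for the
  # separation diagnostic among whatever is raised
  w <- capture_warnings(fit_clm(sv, clm_spec()))
  expect_true(any(grepl("separation.*'B'", w)))
})
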