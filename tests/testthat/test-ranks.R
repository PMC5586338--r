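test_that("visit score sums add the replicate scores per tree and flag absences", {
  d <- data.frame(site = "BE", tree = rep(c("t1", "t2"), each = 5),
                  date = "2014-05-10",
                  score = c(5L, 5L, 5L, 4L, 4L, rep(1L, 5)),
                  replicate = rep(1:5, 2))
  d2 <- data.frame(site = "BE", tree = "t1", date = "2014-05-20",
                   score = 6L, replicate = 1L)
  sv <- phenology_survey(rbind(d, d2))
  sums <- visit_score_sums(sv, "BE", 2014)
  expect_equal(sums$score_sum[sums$tree == "t1" &
                                sums$date == as.Date("2014-05-10")], 23)
  expect_equal(sums$score_sum[sums$tree == "t2" &
                                sums$date == as.Date("2014-05-10")], 5)
  miss <- attr(sums, "missing")
  expect_equal(nrow(miss), 1L)  # t2 absent at the second visit, not zeroed
  expect_equal(miss$tree, "t2")
  expect_error(visit_score_sums(sv, "BE", 1999), "no visits")
})

test_that("the most developed tree ranks first each visit and finishes with the lowest final rank", {
  # per-visit sums always ordered A > B > C
  d <- expand.grid(tree = c("A", "B", "C"),
                   date = c("2014-05-05", "2014-05-15", "2014-05-25"),
                   stringsAsFactors = FALSE)
  d$site <- "S"
  d$replicate <- 1L
  d$score <- c(A = 7L, B = 4L, C = 1L)[d$tree]
  ranks <- annual_rank_sum(visit_score_sums(phenology_survey(d), "S", 2014))
  expect_equal(ranks$final_rank[match(c("A", "B", "C"), ranks$tree)],
               c(1, 2, 3))
  # permuting visit order cannot change the final ranks
  d_perm <- d[sample(nrow(d)), ]
  ranks_perm <- annual_rank_sum(visit_score_sums(phenology_survey(d_perm),
                                                 "S", 2014))
  expect_equal(ranks_perm[order(ranks_perm$tree), ],
               ranks[order(ranks$tree), ], ignore_attr = TRUE)
})

test_that("ties receive average ranks at both ranking steps", {
  d <- expand.grid(tree = c("A", "B", "C"),
                   date = c("2014-05-05", "2014-05-15"),
                   stringsAsFactors = FALSE)
  d$site <- "S"
  d$replicate <- 1L
  d$score <- c(A = 5L, B = 5L, C = 1L)[d$tree]
  ranks <- annual_rank_sum(visit_score_sums(phenology_survey(d), "S", 2014))
  expect_equal(ranks$final_rank[match(c("A", "B"), ranks$tree)], c(1.5, 1.5))
  expect_equal(ranks$final_rank[ranks$tree == "C"], 3)
  # fully tied data is degenerate, returned with a warning
  d$score <- 2L
  expect_warning(
    annual_rank_sum(visit_score_sums(phenology_survey(d), "S", 2014)),
    "degenerate")
})

test_that("spearman_rho matches the reference implementation and handles ties", {
  expect_equal(spearman_rho(1:8, 1:8)$rho, 1)
  expect_equal(spearman_rho(1:8, 8:1)$rho, -1)
  set.seed(5)
  x <- c(3, 1, 4, 1, 5, 9)  # one tie
  y <- c(2, 7, 1, 8, 2, 8)  # ties too
  got <- spearman_rho(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate))
  # t-approximation p-value equals a Pearson t test on the average ranks
  ref_p <- stats::cor.test(rank(x), rank(y))$p.value
  expect_equal(got$p_value, ref_p, tolerance = 1e-12)
  # permutation p-value agrees with the t approximation to Monte Carlo error
  got_perm <- spearman_rho(x, y, method = "permutation", n_perm = 4000,
                           seed = 2)
  expect_lt(abs(got_perm$p_value - got$p_value), 0.1)
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
  expect_warning(out <- spearman_rho(rep(1, 6), 1:6), "zero variance")
  expect_true(is.na(out$rho))
})

test_that("rho depends only on ranks: monotone relabeling changes nothing", {
  set.seed(7)
  x <- rnorm(12)
  y <- x + rnorm(12)
  base <- spearman_rho(x, y)
  warped <- spearman_rho(exp(2 * x), y^3 + 5 * y)
  expect_equal(warped$rho, base$rho)
  expect_equal(warped$p_value, base$p_value)
})

test_that("consistency tables track the simulated tree effect", {
  years <- c(`2014` = 0, `2015` = -3)
  # strong persistent tree effect: high between-year correlation
  sv_hi <- sim_small(sites = c(S = 0), years = years, n_trees = 20,
                     tree_sd = 6, seed = 31)
  tab_hi <- consistency_table(sv_hi)
  expect_equal(nrow(tab_hi), 1L)
  expect_gt(tab_hi$rho, 0.5)
  expect_lt(tab_hi$p_value, 0.001)
  # no tree effect: correlations center on zero across seeds
  rhos <- vapply(1:40, function(s) {
    consistency_table(sim_small(sites = c(S = 0), years = years,
                                n_trees = 20, tree_sd = 0, seed = s))$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.12)
})

test_that("sites observed in a single year are omitted from the table", {
  years <- c(`2014` = 0, `2015` = -3)
  sv2 <- sim_small(sites = c(A = 0, B = 5), years = years, n_trees = 6,
                   seed = 3)
  solo <- sim_small(sites = c(C = 2), years = c(`2015` = -3), n_trees = 6,
                    seed = 4)
  cols <- c("site", "tree", "date", "score", "replicate")
  sv <- phenology_survey(rbind(as.data.frame(sv2)[cols],
                               as.data.frame(solo)[cols]))
  expect_message(tab <- consistency_table(sv), "single year")
  expect_setequal(unique(tab$site), c("A", "B"))
  expect_equal(nrow(tab), 2L)
})
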