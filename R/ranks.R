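#' Per-visit strobilus score sums for one site-year
#'
#' Sums the (up to five) replicate scores of each tree at each visit —
#' the quantity that is subsequently ranked to order trees by developmental
#' advancement.  Trees present in the site-year but absent from a
#' particular visit are flagged as missing, never zero-filled.
#'
#' @param survey a [phenology_survey()].
#' @param site,year the site-year to summarize.
#' @return data frame `tree`, `date`, `score_sum`, `n_scores`; attribute
#'   `"missing"` lists (tree, date) combinations with no observations.
#' @export
visit_score_sums <- function(survey, site, year) {
  d <- as.data.frame(survey)
  d <- d[d$site == site & d$year == year, , drop = FALSE]
  if (nrow(d) == 0L) stop("no visits for site ", site, " in year ", year)
  agg <- stats::aggregate(score ~ tree + date, data = d,
                          FUN = function(s) c(sum = sum(s), n = length(s)))
  out <- data.frame(tree = agg$tree, date = agg$date,
                    score_sum = agg$score[, "sum"],
                    n_scores = agg$score[, "n"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$date, out$tree), ]
  rownames(out) <- NULL
  grid <- expand.grid(tree = unique(d$tree), date = unique(d$date),
                      stringsAsFactors = FALSE)
  have <- paste(out$tree, out$date)
  missing <- grid[!paste(grid$tree, grid$date) %in% have, , drop = FALSE]
  rownames(missing) <- NULL
  attr(out, "missing") <- missing
  out
}

#' Final within-site tree ranking for one year
#'
#' Ranks trees at each visit by their score sum — rank 1 goes to the most
#' developed tree, ties receive average ranks — sums each tree's ranks over
#' the year's visits, and ranks those sums (average ties again).  The tree
#' with the lowest final rank developed earliest.  Trees missing any visit
#' get an `NA` final rank (their rank sum is not comparable) and are
#' reported in the `"incomplete"` attribute.
#'
#' @param sums a [visit_score_sums()] result.
#' @return data frame `tree`, `rank_sum`, `final_rank`, ordered by final
#'   rank.
#' @export
annual_rank_sum <- function(sums) {
  if (length(unique(sums$tree)) < 2L) {
    stop("ranking needs at least 2 trees")
  }
  # rank 1 = most developed at that visit (highest score sum)
  sums$visit_rank <- stats::ave(-sums$score_sum, sums$date,
                                FUN = function(x) rank(x, ties.method = "average"))
  n_visits <- length(unique(sums$date))
  per_tree <- stats::aggregate(visit_rank ~ tree, data = sums,
                               FUN = sum)
  counts <- stats::aggregate(visit_rank ~ tree, data = sums,
                             FUN = length)
  incomplete <- counts$tree[counts$visit_rank < n_visits]
  rank_sum <- per_tree$visit_rank
  rank_sum[per_tree$tree %in% incomplete] <- NA_real_
  final <- rep(NA_real_, nrow(per_tree))
  ok <- !is.na(rank_sum)
  final[ok] <- rank(rank_sum[ok], ties.method = "average")
  if (all(ok) && length(unique(rank_sum)) == 1L) {
    warning("all trees tied at every visit; ranking is degenerate")
  }
  out <- data.frame(tree = per_tree$tree, rank_sum = rank_sum,
                    final_rank = final, stringsAsFactors = FALSE)
  out <- out[order(out$final_rank, out$tree), ]
  rownames(out) <- NULL
  attr(out, "incomplete") <- incomplete
  out
}

#' Spearman rank correlation with tie correction
#'
#' The tie-corrected Spearman coefficient — the Pearson correlation of the
#' average ranks of the two vectors — with a p-value from the t
#' approximation on n - 2 degrees of freedom (the usual choice at the
#' 20-tree scale), or from an exact permutation test when requested.
#' Pairs with a missing value in either vector are dropped.
#'
#' @param x,y numeric vectors of equal length (raw values or ranks; only
#'   their ranks matter).
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutation count for `method = "permutation"`.
#' @param seed RNG seed for the permutation test.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y, method = c("t", "permutation"),
                         n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance in ranks; correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (method == "t") {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  } else {
    set.seed(as.integer(seed))
    null_rho <- replicate(n_perm, stats::cor(rx, sample(ry)))
    p <- (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  list(rho = rho, p_value = min(p, 1), n = n)
}

#' Between-year rank-consistency table
#'
#' For each site observed in at least two years, computes the final tree
#' ranking per year ([annual_rank_sum()] of [visit_score_sums()]) and the
#' Spearman correlation of every year pair — the test of whether trees
#' within a site develop in the same order each year.  Trees lacking a
#' usable rank in either year of a pair are dropped pairwise.
#'
#' @param survey a [phenology_survey()].
#' @param method,n_perm,seed passed to [spearman_rho()].
#' @return data frame `site`, `year_a`, `year_b`, `rho`, `p_value`, `n`;
#'   single-year sites are omitted (with a message).  Attribute `"ranks"`
#'   holds the per-site-year rank tables.
#' @export
consistency_table <- function(survey, method = "t", n_perm = 10000L,
                              seed = 1L) {
  d <- as.data.frame(survey)
  sites <- sort(unique(d$site))
  rows <- list()
  rank_tabs <- list()
  for (s in sites) {
    yrs <- sort(unique(d$year[d$site == s]))
    if (length(yrs) < 2L) {
      message("site ", s, " observed in a single year; omitted from table")
      next
    }
    ranks <- lapply(yrs, function(y) {
      annual_rank_sum(visit_score_sums(survey, s, y))
    })
    names(ranks) <- yrs
    rank_tabs[[s]] <- ranks
    for (a in seq_along(yrs)[-length(yrs)]) {
      for (b in (a + 1L):length(yrs)) {
        ra <- ranks[[a]]
        rb <- ranks[[b]]
        shared <- intersect(ra$tree, rb$tree)
        xa <- ra$final_rank[match(shared, ra$tree)]
        xb <- rb$final_rank[match(shared, rb$tree)]
        sp <- spearman_rho(xa, xb, method = method, n_perm = n_perm,
                           seed = seed)
        rows[[length(rows) + 1L]] <-
          data.frame(site = s, year_a = yrs[a], year_b = yrs[b],
                     rho = sp$rho, p_value = sp$p_value, n = sp$n,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stop("no site with at least 2 years of data")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ranks") <- rank_tabs
  out
}
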