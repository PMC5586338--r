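# Shared fixtures, built in code at test time.

# small multi-site survey generator with study-design defaults scaled down
sim_small <- function(sites = c(AC = 0, BE = 12, RM = 5),
                      years = c(`2014` = 0), n_trees = 10, tree_sd = 2,
                      seed = 1, ...) {
  simulate_survey(
    simulation_params(sites = sites, years = years, n_trees = n_trees,
                      tree_sd = tree_sd, ...),
    seed = seed)
}

# hand-built survey from a data frame of observation fields
survey_from <- function(...) {
  phenology_survey(data.frame(..., stringsAsFactors = FALSE))
}

# balanced single-factor survey: each tree carries one fixed score
balanced_survey <- function(n_per_score = 10) {
  trees <- sprintf("T%02d", seq_len(7 * n_per_score))
  obs <- expand.grid(tree = trees,
                     date = c("2014-05-10", "2014-05-20"),
                     stringsAsFactors = FALSE)
  obs$site <- "A"
  obs$replicate <- 1L
  obs$score <- (match(obs$tree, trees) - 1L) %% 7L + 1L
  phenology_survey(obs)
}

# independent brute-force CLM negative log-likelihood: per-observation loop
# over explicit category probabilities (written before the optimizer; kept
# deliberately naive)
brute_nll <- function(theta, beta, X, y) {
  total <- 0
  for (i in seq_along(y)) {
    eta <- sum(X[i, ] * beta)
    cum <- c(0, plogis(theta - eta), 1)
    total <- total - log(cum[y[i] + 1L] - cum[y[i]])
  }
  total
}

# write a survey CSV in an arbitrary dialect for reader tests
write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
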